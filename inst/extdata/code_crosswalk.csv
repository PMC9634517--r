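raw_code,scheme,icd10_code
290.0,ICD9,F03
291.0,ICD9,F10.4
291.2,ICD9,F10.7
292.1,ICD9,F19.5
293.0,ICD9,F05.9
294.1,ICD9,F02.8
295.0,ICD9,F20.6
295.3,ICD9,F20.0
295.7,ICD9,F25.9
295.9,ICD9,F20.9
296.0,ICD9,F30.9
296.2,ICD9,F32.9
296.3,ICD9,F33.9
296.4,ICD9,F31.1
296.80,ICD9,F31.9
297.1,ICD9,F22.0
298.9,ICD9,F29
299.00,ICD9,F84.0
300.00,ICD9,F41.9
300.01,ICD9,F41.0
300.02,ICD9,F41.1
300.21,ICD9,F40.0
300.3,ICD9,F42.9
300.4,ICD9,F34.1
301.7,ICD9,F60.2
301.83,ICD9,F60.3
301.9,ICD9,F60.9
303.90,ICD9,F10.2
304.00,ICD9,F11.2
304.20,ICD9,F14.2
304.30,ICD9,F12.2
304.40,ICD9,F15.2
304.90,ICD9,F19.2
305.00,ICD9,F10.1
305.20,ICD9,F12.1
307.1,ICD9,F50.0
307.51,ICD9,F50.2
309.81,ICD9,F43.1
311,ICD9,F32.9
312.9,ICD9,F91.9
313.81,ICD9,F91.3
314.00,ICD9,F90.0
315.9,ICD9,F89
317,ICD9,F70
319,ICD9,F79
331.0,ICD9,G30.9
333.4,ICD9,G10
345.9,ICD9,G40.9
758.0,ICD9,Q90.9
780.1,ICD9,R44.3
780.97,ICD9,R41.0
V62.84,ICD9,R45.8
E950.9,ICD9,X64
E958.9,ICD9,X84
854.0,ICD9,S06.9
959.9,ICD9,T14.9
42344001,SNOMED,F10.5
7200002,SNOMED,F10.2
15277004,SNOMED,F10.3
26416006,SNOMED,F19.1
75544000,SNOMED,F11.2
85005007,SNOMED,F12.2
78267003,SNOMED,F14.2
32358001,SNOMED,F15.2
58214004,SNOMED,F20.9
64905009,SNOMED,F20.0
68890003,SNOMED,F25.9
48500005,SNOMED,F22.0
69322001,SNOMED,F29
35489007,SNOMED,F32.9
13746004,SNOMED,F31.9
28475009,SNOMED,F33.9
46244001,SNOMED,F34.1
197480006,SNOMED,F41.9
371631005,SNOMED,F41.0
21897009,SNOMED,F41.1
47505003,SNOMED,F43.1
191736004,SNOMED,F42.9
44376007,SNOMED,F44.9
72366004,SNOMED,F50.9
56882008,SNOMED,F50.0
33449004,SNOMED,F60.9
20010003,SNOMED,F60.3
110359009,SNOMED,F79
408856003,SNOMED,F84.0
406506008,SNOMED,F90.0
91138005,SNOMED,F91.9
73097000,SNOMED,F99
52448006,SNOMED,F03
26929004,SNOMED,G30.9
58756001,SNOMED,G10
84757009,SNOMED,G40.9
41040004,SNOMED,Q90.9
6471006,SNOMED,R45.8
84229001,SNOMED,R44.0
248062006,SNOMED,X84
127295002,SNOMED,S06.9
417746004,SNOMED,T14.9
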