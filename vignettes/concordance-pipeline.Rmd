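---
title: "Window-period concordance between narrative mentions and hospital diagnoses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-period concordance between narrative mentions and hospital diagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvconcord)
```

## The problem

Two record systems observe the mental health of people involved in
domestic-violence events. Police narratives mention illnesses
opportunistically, in free text, attributed to a role — the person of
interest (POI) or the victim. Hospital collections (admitted-patient and
emergency-department data) record coded diagnoses with admission
intervals. Neither system is a gold standard for the other: police see
many conditions that never reach a hospital, and hospitals diagnose
conditions police never hear about. The quantity of interest is therefore
*concordance*: among events where both systems say something about the
same individual, how often do they name the same condition?

Three modelling commitments define the analysis:

* **Unit of agreement.** Mentions range from very specific ("oppositional
  defiance disorder") to generic ("mental health issues"), and hospital
  codes are similarly heterogeneous. Both sides are rolled up to
  first-level groups — the top-tier blocks of the ICD-10 mental and
  behavioural disorders chapter plus a small closed set of adjacent
  categories — and agreement is an exact match at that level. A
  "depression" mention agrees with a bipolar-disorder admission: both roll
  up to mood (affective) disorders.
* **Unit of analysis.** Agreement is counted per event and role, not per
  person or mention: an event agrees for the POI if the intersection of
  the POI's mention groups and the POI's linked hospital groups is
  nonempty, irrespective of how many other diagnoses the individual
  carries. The event-level 2×2 cross-tabulation takes an OR over roles,
  which is what makes the "different individuals" pattern visible: a POI
  mention plus a victim-only hospital record is a BOTH event with no
  agreement for either role.
* **Temporal eligibility.** Hospital contact rarely coincides with the
  event date, so records are eligible within a symmetric window of ±1, 3,
  6 or 12 calendar months; an unrestricted join bounds the windows from
  above, and a forward-looking 48-hour window isolates immediate
  presentations.

## The first-level group set

The closed set has 26 labels (`level1_groups()`). Eleven are the F-chapter
blocks (F00–F09 physiological, F10–F19 substance use, F20–F29
schizophrenia-spectrum, F30–F39 mood, F40–F48 anxiety-spectrum, F50–F59
behavioural syndromes, F60–F69 adult personality, F70–F79 intellectual
disability, F80–F89 developmental, F90–F98 childhood-onset, F99
unspecified). The rest cover what narratives and emergency codes actually
contain but chapter V does not: intentional self-harm (X60–X84),
symptoms-and-signs codes (R40–R46), traumatic brain injury (S00–S09),
injury of unspecified body region (T14), degenerative and atrophic
nervous-system disease (G30–G32, G10–G14), other nervous-system disease
(G-chapter remainder), chromosomal abnormalities (Q90–Q99), and reserved
tokens with no diagnosis code at all: unspecified mental illness,
unspecified substance abuse, drug-induced disorder, prescription-drug
abuse, and the four psychotropic-medication categories (antidepressants,
antipsychotics, anxiolytics, neuroleptics). Reserved-token groups can by
construction never be concordant — no hospital code maps to them — and so
appear only in the mention-only discordance profile, never in the
concordance tables.

The shipped lexicon (195 surface forms) and ICD-9/SNOMED-CT crosswalk are
curated reconstructions assembled for this package: large enough to cover
every group with realistic vocabulary (drug brand names, abbreviations
like PTSD/OCD/ADHD, colloquialisms like "nervous breakdown"), small enough
to audit, and user-replaceable via `load_lexicon(path)` /
`load_crosswalk(path)`. Ambiguous code mappings are resolved to a single
authoritative row in the file; there is no runtime disambiguation.

## Extraction grammar

A mention requires three elements in order within one sentence: a role
anchor, a trigger phrase, and a lexicon term. Sentences are split on
sentence-final punctuation followed by whitespace; matching is
case-insensitive exact phrase match on word boundaries (no stemming or
fuzzy matching), with longer phrases winning over embedded shorter ones
("paranoid schizophrenia" suppresses the inner "schizophrenia" match).
Narratives are whitespace-normalized first, and all reported character
spans are 0-based half-open offsets into the normalized text, so
`substring(normalized, start + 1, end)` always reproduces the matched
surface.

Design choices where the design was genuinely open:

* **Anchor attribution.** When both role anchors occur in a sentence
  ("The victim said the POI has schizophrenia"), the term attaches to the
  nearest anchor by character distance, ties breaking to the anchor that
  precedes the term. Nearest-anchor is the standard heuristic for clause
  association in gazetteer systems.
* **Trigger requirement.** The trigger must lie strictly between the
  anchor and the term. This is what gives the grammar its precision: a
  sentence that merely juxtaposes an anchor and a term ("The POI was upset
  about depression in the economy") yields nothing. Generic patterns such
  as "has mental health issues" are handled by the trigger `has` plus the
  unspecified-illness lexicon entries rather than by a separate bare-term
  rule.
* **Negation is not handled.** "No history of depression" yields a
  mention. This is a known limitation of the pattern inventory, accepted
  deliberately: narrative negations of mental illness are rare, and
  negation scope detection would require syntactic analysis out of
  proportion to the rest of the grammar.
* **Deduplication.** Output is unique per (event, role, first-level
  group), keeping the earliest match, so repeated phrasing does not
  inflate counts; the dedup rule is idempotent.

Extraction quality is scored against gold labels by precision, recall and
F1 (harmonic mean), per role and micro-averaged; undefined ratios (empty
prediction or gold sets) are reported as `NaN` with a warning, never
silently zeroed.

## Window semantics

Month windows shift the event date by whole calendar months with the day
of month clamped to the target month's length (31 January − 1 month = 31
December), and both endpoints closed. The default membership test is
*interval overlap*: an admission `[start, end]` links if it intersects the
window at all, on the reasoning that an admission spanning the window edge
plausibly relates to the event; `semantics = "start"` restricts to the
admission start date for sensitivity analyses. The 48-hour window is
forward-looking from the event-date midnight and tests the admission start
only, reading "a hospital record within 48 hours of the event" as
post-event presentation. Windows are validated against an independent
day-enumeration oracle in the test suite, and linked-set size is
provably nondecreasing in window width, with the unrestricted join as
supremum.

## The synthetic-cohort generator

The generator emulates the *structure* of the study data — not its
population values, which are properties of confidential administrative
collections. Its defaults state the conditions the package is tested
under:

* 500 events (tests and the acceptance script scale this to 1000–2000);
  event dates uniform over 2006–2015.
* Mention prevalence 13% for POIs and 4% for victims — the police record
  far more about perpetrators than victims, with roughly one event in six
  carrying any mention.
* Group weights echoing the observed rank order of mention profiles
  (unspecified illness > mood > childhood-onset behavioural > substance
  use > schizophrenia-spectrum for POIs; anxiety elevated for victims);
  hospital-side weights dominated by substance-use, mood, anxiety and
  schizophrenia-spectrum diagnoses. Exact proportions are deliberately
  *not* matched to any published cohort.
* `concordant_fraction = 0.08`: a planted mention gains a same-person
  hospital record with a code from the same group, at a start offset drawn
  from a mixture spanning ±2 years (a quarter within two weeks of the
  event, so every window — including 48 hours — sees a different linked
  set). `cross_role_fraction = 0.04` plants the different-individuals
  pattern; `hospital_only_rate ≈ 0.04` per role plants diagnoses with no
  mention.
* `distractor_rate = 0.5` fills narrative slots with non-mention sentences
  — including dictionary terms without an anchor and anchors without a
  term, the two failure modes the grammar must reject; `noise_rate = 0.3`
  applies casing changes and filler clauses to planted sentences.

Two structural guarantees make the generator a usable oracle. First, every
planted phrase is composed from the extraction grammar's own pattern
inventory, and the noise model never destroys the anchor–trigger–term
order, so gold recall is well-defined and on clean cohorts the pipeline
must reproduce `expected_tables()` — the tables computed directly from the
gold labels — cell for cell. Second, same-role agreement can arise *only*
through `concordant_fraction`: hospital-only and cross-role draws exclude
the target person's own mention groups, and each synthetic individual
appears in exactly one event (person IDs are still reused consistently
across that individual's hospital records). Setting
`concordant_fraction = 0` therefore forces zero same-role agreement at
every window, by construction.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: clinical language variety beyond the template
library (~20 sentence frames), misspellings and police shorthand,
negation, repeat individuals across events, seasonal or secular trends in
event dates, code-assignment error in hospital data, and identity-linkage
error (person IDs are exact by design; probabilistic linkage is upstream
of this package's scope). Measured extraction F1 on synthetic cohorts is
consequently an upper bound on real-world performance, and the package
treats published extraction-quality figures for comparable systems
(mid-80s F1) as external context, not as something these tests reproduce.

## Numerical conventions and degenerate inputs

* Percentages are rounded half-up to 2 decimal places (`rate()`), with a
  small epsilon guarding values that sit exactly on the `.xx5` boundary in
  binary floating point. Zero denominators are flagged with a warning and
  rendered as 0, and zero-denominator groups stay in the output with a
  `zero_denominator` flag rather than being dropped, keeping the table
  schema stable.
* Unmappable hospital codes are excluded from linkage and counted
  (`n_unmappable` attribute, echoed in the run manifest), never silently
  dropped.
* Empty narratives warn and yield empty mention sets; empty cohorts
  tabulate to all-zero tables; duplicate event IDs and events whose POI
  and victim IDs coincide are hard errors at load time (the analysis is
  defined only for single-POI/single-victim events).
* Determinism: every stochastic step runs under a scoped seed, and the
  run manifest (seed, config echo, versions, exclusion counts) is
  sufficient to re-derive every output file.

## Problem sizes

The shipped test-suite and acceptance configurations use cohorts of
60–1000 events (2000 in the acceptance script), 100 random configurations
for the conservation property, 20 cohorts for window monotonicity, and
1000-case oracle comparisons for window membership and tabulation — sizes
chosen so the full suite completes in a couple of minutes while every
property is exercised across its input space.

## Limitations

Beyond the generator's realism bounds above: the grammar is a
representative reconstruction of a production rule set, not a port of one;
the lexicon and crosswalk are curated rather than exhaustive (no UMLS or
full ICD-10 ontology ingestion); inferential statistics on concordance
(kappa, confidence intervals) are an extension point, not implemented —
the pipeline reports descriptive counts and rates only.
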