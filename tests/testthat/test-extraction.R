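test_that("anchor + trigger + term patterns are extracted with role attribution", {
  cases <- list(
    list(text = "The POI is suffering from dementia.",
         role = "POI",
         group = "Mental disorders due to known physiological conditions"),
    list(text = "Police noted the victim was diagnosed with paranoid schizophrenia.",
         role = "VICTIM",
         group = "Schizophrenia, schizotypal, delusional, and other nonmood psychotic disorders"),
    list(text = "The accused takes a number of antidepressants.",
         role = "POI",
         group = "Medications: antidepressants"),
    list(text = "The defendant has mental health issues.",
         role = "POI",
         group = "Unspecified mental disorder"),
    list(text = "The PINOP is on Valium.",
         role = "VICTIM",
         group = "Medications for anxiety"))
  for (case in cases) {
    m <- extract_mentions(make_event(narrative = case$text), pkg_lexicon)
    expect_equal(nrow(m), 1, info = case$text)
    expect_equal(m$role, case$role, info = case$text)
    expect_equal(m$level1_group, case$group, info = case$text)
  }
})

test_that("sentences without an anchor, trigger or term yield nothing", {
  for (text in c("Neighbours reported loud shouting.",
                 "A packet of diazepam was located on the bench.",
                 "The POI left the scene before police arrived.",
                 "The POI was upset about depression in the economy.")) {
    m <- extract_mentions(make_event(narrative = text), pkg_lexicon)
    expect_equal(nrow(m), 0, info = text)
  }
})

test_that("matching is case-insensitive and tolerates filler clauses", {
  m1 <- extract_mentions(make_event(
    narrative = "THE VICTIM SUFFERS FROM DEPRESSION."), pkg_lexicon)
  expect_equal(m1$level1_group, "Mood (affective) disorders")
  m2 <- extract_mentions(make_event(
    narrative = "The POI, who is well known to police, has a history of schizophrenia."),
    pkg_lexicon)
  expect_equal(m2$role, "POI")
})

test_that("char spans reproduce the matched surface from the normalized narrative", {
  text <- "Some  noise here.   The victim  was diagnosed with   bipolar disorder."
  ev <- make_event(narrative = text)
  m <- extract_mentions(ev, pkg_lexicon)
  norm <- normalize_narrative(text)
  expect_equal(substring(norm, m$start + 1L, m$end), m$surface)
  expect_true(all(m$end > m$start))
  expect_true(all(m$end <= nchar(norm)))
})

test_that("terms attach to the nearest anchor, ties to the preceding one", {
  m <- extract_mentions(make_event(
    narrative = "The victim said the POI has schizophrenia."), pkg_lexicon)
  expect_equal(m$role, "POI")
})

test_that("anchors belong to exactly one role set", {
  g <- dv_grammar()
  expect_length(intersect(g$poi_anchors, g$victim_anchors), 0)
  expect_error(dv_grammar(poi_anchors = "poi", victim_anchors = c("poi", "vic")),
               "disjoint")
})

test_that("mentions deduplicate to unique (role, group) pairs, idempotently", {
  text <- paste("The POI suffers from depression.",
                "The POI was diagnosed with major depression.",
                "The victim has depression.")
  m <- extract_mentions(make_event(narrative = text), pkg_lexicon)
  expect_equal(nrow(m), 2)
  expect_equal(anyDuplicated(m[, c("role", "level1_group")]), 0L)
  # re-applying the dedup rule changes nothing
  expect_identical(m, m[!duplicated(m[, c("role", "level1_group")]), ])
})

test_that("empty narratives warn and return an empty mention set", {
  expect_warning(m <- extract_mentions(make_event(narrative = "  "), pkg_lexicon),
                 "empty narrative")
  expect_equal(nrow(m), 0)
})

test_that("extract_corpus counts events with mentions by role and is deterministic", {
  events <- dplyr::bind_rows(
    make_event("E1", "The POI suffers from anxiety.", poi_id = "P1", victim_id = "P2"),
    make_event("E2", "Nothing to report.", poi_id = "P3", victim_id = "P4"),
    make_event("E3", "The victim takes diazepam. The POI has schizophrenia.",
               poi_id = "P5", victim_id = "P6"),
    make_event("E4", "Witnesses saw both parties arguing in the street.",
               poi_id = "P7", victim_id = "P8"))
  out1 <- extract_corpus(events, pkg_lexicon)
  expect_equal(out1$summary$n_events_with_mention, 2)
  expect_equal(out1$summary$n_events_poi_mention, 2)
  expect_equal(out1$summary$n_events_victim_mention, 1)
  out2 <- extract_corpus(events, pkg_lexicon)
  expect_identical(out1, out2)
})

test_that("extract_corpus rejects duplicate event IDs", {
  events <- dplyr::bind_rows(make_event("E1"), make_event("E1"))
  expect_error(extract_corpus(events, pkg_lexicon), "duplicate event_id")
})

test_that("precision/recall/F1 follow the closed form, per role and overall", {
  identical_set <- tibble::tibble(event_id = c("E1", "E2"), role = c("POI", "VICTIM"),
                                  level1_group = c("Mood (affective) disorders",
                                                   "Unspecified mental disorder"))
  s <- score_extraction(identical_set, identical_set)
  expect_equal(s$precision, c(1, 1, 1))
  expect_equal(s$recall, c(1, 1, 1))
  expect_equal(s$f1, c(1, 1, 1))

  # tp = 36, fp = 9, fn = 4: P = 0.8, R = 0.9, F1 = 2PR/(P+R)
  gold <- tibble::tibble(event_id = sprintf("E%02d", 1:40), role = "POI",
                         level1_group = "Mood (affective) disorders")
  pred <- dplyr::bind_rows(
    gold[1:36, ],
    tibble::tibble(event_id = sprintf("X%02d", 1:9), role = "POI",
                   level1_group = "Mood (affective) disorders"))
  s2 <- suppressWarnings(score_extraction(pred, gold))  # VICTIM stratum empty
  poi <- s2[s2$role == "POI", ]
  expect_equal(poi$precision, 0.8)
  expect_equal(poi$recall, 0.9)
  expect_equal(poi$f1, 2 * 0.8 * 0.9 / (0.8 + 0.9), tolerance = 1e-12)
})

test_that("degenerate scoring inputs are flagged, not fabricated", {
  gold <- tibble::tibble(event_id = "E1", role = "POI",
                         level1_group = "Mood (affective) disorders")
  none <- gold[0, ]
  warns <- capture_warnings(s <- score_extraction(none, gold))
  expect_match(warns, "precision undefined", all = FALSE)
  expect_true(all(is.nan(s$precision[s$role %in% c("POI", "overall")])))
  expect_equal(s$recall[s$role == "POI"], 0)
  warns2 <- capture_warnings(s2 <- score_extraction(gold, none))
  expect_match(warns2, "recall undefined", all = FALSE)
  expect_true(is.nan(s2$recall[s2$role == "POI"]))
})

test_that("read_events enforces the single-POI/single-victim design", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(make_event("E1", "text", poi_id = "P1", victim_id = "P1"), path)
  expect_error(read_events(path), "poi_id equals victim_id")
})
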