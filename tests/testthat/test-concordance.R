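mood <- "Mood (affective) disorders"
subst <- "Mental and behavioral disorders due to psychoactive substance use"
anx <- "Anxiety, dissociative, stress related, somatoform, and other nonpsychotic mental disorders"

mention_row <- function(event_id, role, group) {
  tibble::tibble(event_id = event_id, role = role, level1_group = group)
}
link_row <- function(event_id, role, group) {
  tibble::tibble(event_id = event_id, role = role, person_id = "P",
                 record_index = 1L, level1_group = group,
                 start_date = as.Date("2010-01-01"))
}

test_that("agreement is a nonempty intersection of role group sets", {
  ev <- make_event("E1", "x")
  conc <- classify_events(ev,
                          mention_row("E1", "POI", mood),
                          dplyr::bind_rows(link_row("E1", "POI", mood),
                                           link_row("E1", "POI", subst)))
  poi <- conc[conc$role == "POI", ]
  expect_true(poi$agreement)
  expect_equal(poi$matched_groups[[1]], mood)
  expect_equal(poi$cell, "BOTH")
})

test_that("both-sides-present without a shared group is BOTH without agreement", {
  ev <- make_event("E1", "x")
  conc <- classify_events(ev, mention_row("E1", "POI", anx),
                          link_row("E1", "POI", mood))
  poi <- conc[conc$role == "POI", ]
  expect_equal(poi$cell, "BOTH")
  expect_false(poi$agreement)
})

test_that("cross-role events land in the event-level BOTH cell without agreement", {
  ev <- make_event("E1", "x")
  conc <- classify_events(ev, mention_row("E1", "POI", mood),
                          link_row("E1", "VICTIM", mood))
  expect_equal(unique(conc$event_cell), "BOTH")
  expect_false(any(conc$agreement))
  expect_equal(conc$cell[conc$role == "POI"], "MENTION_ONLY")
  expect_equal(conc$cell[conc$role == "VICTIM"], "HOSPITAL_ONLY")
})

test_that("rate reproduces printed fraction/percentage arithmetic, half-up to 2 dp", {
  expect_equal(rate(382, 2395), 15.95)
  expect_equal(rate(3020, 416441), 0.73)
  expect_equal(rate(0, 100), 0)
  expect_equal(rate(1, 8), 12.5)
  expect_equal(rate(1, 3), 33.33)
  expect_equal(rate(2, 3), 66.67)
  expect_equal(rate(125, 1000), 12.5)   # half-up at the boundary
  expect_equal(rate(1005, 100000), 1.01)
  expect_warning(z <- rate(5, 0), "zero denominator")
  expect_equal(z, 0)
})

test_that("tabulate matches a hand-audited 20-event fixture and the brute-force oracle", {
  set.seed(99)
  events <- dplyr::bind_rows(lapply(1:20, function(i) {
    make_event(sprintf("E%02d", i), "x",
               poi_id = sprintf("A%02d", i), victim_id = sprintf("B%02d", i))
  }))
  mentions <- dplyr::bind_rows(
    mention_row("E01", "POI", mood),          # agreement
    mention_row("E02", "POI", anx),           # discordant BOTH
    mention_row("E03", "VICTIM", mood),       # mention only
    mention_row("E04", "POI", mood),          # cross-role
    mention_row("E05", "POI", subst),         # agreement
    mention_row("E05", "POI", mood),          # second group, no hospital match
    mention_row("E06", "VICTIM", subst))      # mention only
  links <- dplyr::bind_rows(
    link_row("E01", "POI", mood),
    link_row("E02", "POI", mood),
    link_row("E04", "VICTIM", subst),
    link_row("E05", "POI", subst),
    link_row("E07", "VICTIM", mood))          # hospital only
  conc <- classify_events(events, mentions, links)
  tab <- tabulate_concordance(conc)

  expect_equal(tab$n_events, 20)
  got_cells <- setNames(tab$two_by_two$n, tab$two_by_two$cell)
  expect_equal(got_cells,
               c(BOTH = 4, MENTION_ONLY = 2, HOSPITAL_ONLY = 1, NEITHER = 13))
  expect_equal(sum(tab$two_by_two$n), 20)

  per_role <- tab$per_role
  expect_equal(per_role$n_agreement[per_role$role == "POI"], 2)
  expect_equal(per_role$n_agreement[per_role$role == "VICTIM"], 0)

  pg <- tab$per_group_concordance
  poi_mood <- pg[pg$role == "POI" & pg$level1_group == mood, ]
  expect_equal(poi_mood$n_total, 3)
  expect_equal(poi_mood$n_concordant, 1)
  expect_equal(poi_mood$concordance_rate, rate(1, 3))

  oracle <- tabulate_oracle(events, mentions, links)
  expect_equal(got_cells, oracle$cells)
  expect_equal(setNames(per_role$n_both, per_role$role), oracle$per_role_both)
  expect_equal(setNames(per_role$n_agreement, per_role$role), oracle$per_role_agree)
  for (r in dv_roles()) {
    sub <- pg[pg$role == r, ]
    expect_equal(setNames(sub$n_total, sub$level1_group),
                 oracle$n_total[r, sub$level1_group])
    expect_equal(setNames(sub$n_concordant, sub$level1_group),
                 oracle$n_conc[r, sub$level1_group])
  }
})

test_that("discordance profiles count within their event-level strata", {
  events <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_event(sprintf("E%d", i), "x",
               poi_id = sprintf("A%d", i), victim_id = sprintf("B%d", i))
  }))
  mentions <- dplyr::bind_rows(
    mention_row("E1", "POI", mood),
    mention_row("E1", "VICTIM", anx),
    mention_row("E2", "POI", mood),
    mention_row("E3", "POI", subst))
  links <- link_row("E3", "POI", subst)  # E3 is BOTH, out of the profile
  tab <- tabulate_concordance(classify_events(events, mentions, links))
  mo <- tab$mention_only_profile
  expect_equal(mo$n[mo$role == "POI" & mo$level1_group == mood], 2)
  expect_equal(mo$n[mo$role == "POI" & mo$level1_group == subst], 0)
  # POI stratum denominator is 2 mention-only events with a POI mention
  expect_equal(unique(mo$n_role[mo$role == "POI"]), 2)
  expect_equal(mo$pct[mo$role == "POI" & mo$level1_group == mood], 100)
  expect_equal(unique(mo$n_role[mo$role == "VICTIM"]), 1)
  ho <- tab$hospital_only_profile
  expect_equal(sum(ho$n), 0)
})

test_that("an all-quiet cohort tabulates to (0, 0, 0, N) with flagged zero rates", {
  events <- dplyr::bind_rows(make_event("E1", "x"),
                             make_event("E2", "y", poi_id = "P3", victim_id = "P4"))
  none <- mention_row(character(0), character(0), character(0))
  tab <- tabulate_concordance(classify_events(events, none, link_row(character(0),
                                                                     character(0),
                                                                     character(0))))
  expect_equal(setNames(tab$two_by_two$n, tab$two_by_two$cell),
               c(BOTH = 0, MENTION_ONLY = 0, HOSPITAL_ONLY = 0, NEITHER = 2))
  pg <- tab$per_group_concordance
  expect_true(all(pg$zero_denominator))
  expect_true(all(pg$concordance_rate == 0))
})

test_that("agreement implies the BOTH cell for that role", {
  cfg <- cohort_config(n_events = 120, concordant_fraction = 0.6, seed = 5)
  cohort <- generate_cohort(cfg, pkg_lexicon, pkg_crosswalk)
  res <- run_cohort(cohort, parse_window("12m"))
  conc <- classify_events(cohort$events, res$mentions, res$links)
  expect_true(all(conc$cell[conc$agreement] == "BOTH"))
})
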