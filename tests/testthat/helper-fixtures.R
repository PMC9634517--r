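# Shared fixtures and independent brute-force oracles, built in code.

pkg_lexicon <- suppressMessages(load_lexicon())
pkg_crosswalk <- load_crosswalk()

write_mini_lexicon <- function(rows, path = withr::local_tempfile(fileext = ".csv",
                                                                  .local_envir = parent.frame())) {
  header <- "surface_form,canonical,icd10_code,level1,level2,level3"
  writeLines(c(header, rows), path)
  path
}

mini_lexicon_rows <- c(
  'schizophrenia,schizophrenia,F20.9,"Schizophrenia, schizotypal, delusional, and other nonmood psychotic disorders",Schizophrenia,Unspecified',
  "depression,depressive episode,F32.9,Mood (affective) disorders,Depressive episode,Unspecified",
  'anxiety,anxiety disorder,F41.9,"Anxiety, dissociative, stress related, somatoform, and other nonpsychotic mental disorders",Other anxiety disorders,Unspecified')

make_event <- function(event_id = "E1", narrative = "",
                       event_date = as.Date("2010-06-15"),
                       poi_id = "P1", victim_id = "P2") {
  tibble::tibble(event_id = event_id, event_date = event_date,
                 poi_id = poi_id, victim_id = victim_id,
                 relationship_flag = "spouse/partner", narrative = narrative)
}

make_record <- function(person_id, start, end = start, code = "F32.9",
                        scheme = "ICD10", source = "APDC") {
  tibble::tibble(person_id = person_id, source = source,
                 start_date = as.Date(start), end_date = as.Date(end),
                 raw_code = code, scheme = scheme)
}

# Independent month-shift: numeric year/month bookkeeping with day-of-month
# clamped to the target month's length (no lubridate).
shift_months_oracle <- function(date, k) {
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  tm <- m - 1L + k
  ty <- y + tm %/% 12L
  tm <- tm %% 12L + 1L
  first <- as.Date(sprintf("%04d-%02d-01", ty, tm))
  next_first <- if (tm == 12L) as.Date(sprintf("%04d-01-01", ty + 1L)) else
    as.Date(sprintf("%04d-%02d-01", ty, tm + 1L))
  last_day <- as.integer(next_first - first)
  as.Date(sprintf("%04d-%02d-%02d", ty, tm, min(d, last_day)))
}

# Brute-force window membership: enumerate every day of the admission
# interval and test it against the shifted bounds.
in_window_oracle <- function(event_date, start_date, end_date, months_width) {
  lo <- shift_months_oracle(event_date, -months_width)
  hi <- shift_months_oracle(event_date, months_width)
  days <- seq(start_date, end_date, by = "day")
  any(days >= lo & days <= hi)
}

# Brute-force tabulation: enumerates every (event, role, group) triple from
# the raw mention and link tibbles, independent of classify_events /
# tabulate_concordance internals.
tabulate_oracle <- function(events, mentions, links) {
  roles <- dv_roles()
  groups <- level1_groups()
  cells <- c(BOTH = 0L, MENTION_ONLY = 0L, HOSPITAL_ONLY = 0L, NEITHER = 0L)
  per_role_both <- c(POI = 0L, VICTIM = 0L)
  per_role_agree <- c(POI = 0L, VICTIM = 0L)
  n_total <- matrix(0L, 2, length(groups), dimnames = list(roles, groups))
  n_conc <- n_total
  for (e in events$event_id) {
    ev_has_m <- FALSE; ev_has_h <- FALSE
    for (r in roles) {
      mg <- unique(mentions$level1_group[mentions$event_id == e & mentions$role == r])
      hg <- unique(links$level1_group[links$event_id == e & links$role == r])
      if (length(mg) > 0) ev_has_m <- TRUE
      if (length(hg) > 0) ev_has_h <- TRUE
      if (length(mg) > 0 && length(hg) > 0) per_role_both[r] <- per_role_both[r] + 1L
      if (length(intersect(mg, hg)) > 0) per_role_agree[r] <- per_role_agree[r] + 1L
      for (g in mg) {
        n_total[r, g] <- n_total[r, g] + 1L
        if (g %in% hg) n_conc[r, g] <- n_conc[r, g] + 1L
      }
    }
    cell <- if (ev_has_m && ev_has_h) "BOTH" else if (ev_has_m) "MENTION_ONLY" else
      if (ev_has_h) "HOSPITAL_ONLY" else "NEITHER"
    cells[cell] <- cells[cell] + 1L
  }
  list(cells = cells, per_role_both = per_role_both,
       per_role_agree = per_role_agree, n_total = n_total, n_conc = n_conc)
}

# Convenience: run extraction + linkage + tabulation on a cohort.
run_cohort <- function(cohort, window, semantics = "overlap") {
  ex <- extract_corpus(cohort$events, pkg_lexicon)
  h <- harmonize_records(cohort$hospital, pkg_crosswalk)
  links <- link_events(cohort$events, h, window, semantics)
  list(mentions = ex$mentions, links = links,
       tables = tabulate_concordance(
         classify_events(cohort$events, ex$mentions, links)))
}
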