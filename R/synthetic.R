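# Labelled synthetic-cohort generator: events with template-composed
# narratives, hospital records with configurable temporal offsets and
# concordant/discordant code structure, and gold mention labels so that
# extraction recall is well-defined.

# Mention-side group weights, echoing the rank order of the published
# mention profiles (unspecified illness > mood > childhood-onset
# behavioural > substance use > schizophrenia-spectrum for persons of
# interest; anxiety elevated for victims) without attempting to match
# exact proportions, which are properties of the confidential source data.
.default_weights_poi <- c(
  "Unspecified mental disorder" = 0.28,
  "Mood (affective) disorders" = 0.21,
  "Behavioral and emotional disorders with onset usually occurring in childhood and adolescence" = 0.12,
  "Mental and behavioral disorders due to psychoactive substance use" = 0.10,
  "Schizophrenia, schizotypal, delusional, and other nonmood psychotic disorders" = 0.08,
  "Anxiety, dissociative, stress related, somatoform, and other nonpsychotic mental disorders" = 0.05,
  "Intentional self-harm" = 0.045,
  "Substance abuse" = 0.035,
  "Pervasive and specific developmental disorders" = 0.022,
  "Intellectual disability" = 0.02,
  "Disorders of adult personality and behavior" = 0.018,
  "Injury of unspecified body region" = 0.011,
  "Traumatic brain injury" = 0.009,
  "Mental disorders due to known physiological conditions" = 0.008,
  "Medications: antidepressants" = 0.006,
  "Symptoms and signs involving cognition, perception, emotional state, and behavior" = 0.004,
  "Medications (antipsychotics)" = 0.002,
  "Medications for anxiety" = 0.0015,
  "Other degenerative diseases of the nervous system" = 0.001,
  "Chromosomal abnormalities, not elsewhere classified" = 0.001,
  "Unspecified drug-induced disorders" = 0.001,
  "Behavioral syndromes associated with physiological disturbances and physical factors" = 0.0005,
  "Systematic atrophies primarily affecting the central nervous system" = 0.0004,
  "Diseases of the nervous system" = 0.0003,
  "Drug prescription abuse" = 0.0002,
  "Medications (neuroleptics)" = 0.0001)

.default_weights_victim <- c(
  "Unspecified mental disorder" = 0.22,
  "Mood (affective) disorders" = 0.22,
  "Anxiety, dissociative, stress related, somatoform, and other nonpsychotic mental disorders" = 0.10,
  "Behavioral and emotional disorders with onset usually occurring in childhood and adolescence" = 0.09,
  "Mental and behavioral disorders due to psychoactive substance use" = 0.06,
  "Schizophrenia, schizotypal, delusional, and other nonmood psychotic disorders" = 0.05,
  "Intentional self-harm" = 0.045,
  "Intellectual disability" = 0.04,
  "Mental disorders due to known physiological conditions" = 0.031,
  "Pervasive and specific developmental disorders" = 0.022,
  "Disorders of adult personality and behavior" = 0.02,
  "Substance abuse" = 0.017,
  "Injury of unspecified body region" = 0.012,
  "Traumatic brain injury" = 0.011,
  "Medications: antidepressants" = 0.006,
  "Symptoms and signs involving cognition, perception, emotional state, and behavior" = 0.004,
  "Other degenerative diseases of the nervous system" = 0.0025,
  "Chromosomal abnormalities, not elsewhere classified" = 0.0017,
  "Medications for anxiety" = 0.0012,
  "Behavioral syndromes associated with physiological disturbances and physical factors" = 0.001,
  "Medications (antipsychotics)" = 0.0008,
  "Systematic atrophies primarily affecting the central nervous system" = 0.0004,
  "Diseases of the nervous system" = 0.0002,
  "Unspecified drug-induced disorders" = 0.0001,
  "Drug prescription abuse" = 0.0001,
  "Medications (neuroleptics)" = 0.0001)

# Hospital-side weights (diagnoses without a narrative mention), shaped
# like the hospital-only profile: substance-use disorders dominate,
# followed by mood, anxiety and schizophrenia-spectrum disorders. Reserved
# token groups (medications etc.) have no diagnosis codes, so they cannot
# occur on the hospital side.
.default_weights_hospital <- c(
  "Mental and behavioral disorders due to psychoactive substance use" = 0.34,
  "Mood (affective) disorders" = 0.15,
  "Anxiety, dissociative, stress related, somatoform, and other nonpsychotic mental disorders" = 0.13,
  "Schizophrenia, schizotypal, delusional, and other nonmood psychotic disorders" = 0.10,
  "Disorders of adult personality and behavior" = 0.065,
  "Behavioral and emotional disorders with onset usually occurring in childhood and adolescence" = 0.025,
  "Unspecified mental disorder" = 0.024,
  "Intentional self-harm" = 0.023,
  "Mental disorders due to known physiological conditions" = 0.024,
  "Symptoms and signs involving cognition, perception, emotional state, and behavior" = 0.019,
  "Intellectual disability" = 0.012,
  "Pervasive and specific developmental disorders" = 0.009,
  "Behavioral syndromes associated with physiological disturbances and physical factors" = 0.007,
  "Other degenerative diseases of the nervous system" = 0.003,
  "Systematic atrophies primarily affecting the central nervous system" = 0.001,
  "Chromosomal abnormalities, not elsewhere classified" = 0.001,
  "Traumatic brain injury" = 0.004,
  "Injury of unspecified body region" = 0.003)

.illness_frames <- c(
  "The %s %s %s.",
  "Police observed that the %s %s %s.",
  "Officers were advised that the %s %s %s.",
  "It was disclosed that the %s %s %s.",
  "Records indicate the %s %s %s.",
  "Family members stated the %s %s %s.")

.illness_triggers <- c("suffers from", "is suffering from", "was diagnosed with",
                       "has", "has a history of")
.medication_triggers <- c("takes", "is on", "is taking")

.filler_clauses <- c(", who is well known to police,",
                     ", aged in their thirties,",
                     ", who resides at the premises,",
                     ", according to a neighbour,")

.distractors <- c(
  "Neighbours reported loud shouting coming from the unit.",
  "The argument started over unpaid bills.",
  "Property was damaged during the incident.",
  "Witnesses saw both parties arguing in the street.",
  "Police attended the address a short time later.",
  "Empty bottles were located in the kitchen.",
  "A packet of diazepam was located on the bench.",
  "Loose tablets of sertraline were found at the scene.",
  "The POI left the scene before police arrived.",
  "The victim declined to provide a written statement.",
  "Children were present at the time of the incident.",
  "The parties have been in a relationship for several years.")

.med_groups <- c("Medications: antidepressants", "Medications (antipsychotics)",
                 "Medications for anxiety", "Medications (neuroleptics)")

.norm_weights <- function(w) {
  if (any(w < 0)) stop("group weights must be nonnegative", call. = FALSE)
  w / sum(w)
}

#' Configure a synthetic cohort
#'
#' All probabilities must lie in \[0, 1\]; group weights are normalized to
#' sum to 1 per role. The defaults describe the study conditions the
#' generator emulates: sparse, role-skewed mention prevalence (persons of
#' interest mentioned far more often than victims), a small probability
#' that a mentioned illness also appears in a hospital record for the same
#' person, a cross-role component in which the hospital record belongs to
#' the other party, and hospital-only diagnoses at a few percent per role.
#' Record start offsets are drawn from a mixture spanning the inside and
#' outside of every window period.
#'
#' @param n_events Number of events (> 0).
#' @param mention_prevalence Named numeric `c(POI = , VICTIM = )`:
#'   probability that a role has at least one planted mention.
#' @param group_weights Named list with `POI` and `VICTIM` weight vectors
#'   over first-level groups.
#' @param concordant_fraction Probability that a planted mention group also
#'   appears as a hospital record for the same person (only realisable for
#'   groups that have diagnosis codes; the reserved medication and
#'   unspecified-substance tokens cannot occur in hospital data).
#' @param cross_role_fraction Probability that an event with a mention also
#'   receives a hospital record for the *other* party (the
#'   different-individuals pattern).
#' @param hospital_only_rate Named numeric per role: probability of a
#'   hospital record with no corresponding mention.
#' @param hospital_weights Weights for hospital-side (non-concordant)
#'   diagnosis groups.
#' @param window_offset_sampler Function `(n)` returning integer day
#'   offsets of record starts from the event date.
#' @param distractor_rate Probability that each of three distractor slots
#'   in a narrative is filled.
#' @param noise_rate Probability of surface noise (casing changes, filler
#'   clauses) on a planted sentence; the noise never removes the planted
#'   pattern, so gold recall stays well-defined.
#' @param date_range Length-2 `Date` vector of admissible event dates.
#' @param seed Integer seed; the cohort is a pure function of the
#'   configuration including the seed.
#' @return A list of class `dv_cohort_config`.
#' @export
cohort_config <- function(n_events = 500,
                          mention_prevalence = c(POI = 0.13, VICTIM = 0.04),
                          group_weights = list(POI = .default_weights_poi,
                                               VICTIM = .default_weights_victim),
                          concordant_fraction = 0.08,
                          cross_role_fraction = 0.04,
                          hospital_only_rate = c(POI = 0.04, VICTIM = 0.045),
                          hospital_weights = .default_weights_hospital,
                          window_offset_sampler = default_offset_sampler,
                          distractor_rate = 0.5,
                          noise_rate = 0.3,
                          date_range = as.Date(c("2006-01-01", "2015-12-31")),
                          seed = 1L) {
  probs <- c(mention_prevalence, concordant_fraction, cross_role_fraction,
             hospital_only_rate, distractor_rate, noise_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_events <= 0) stop("n_events must be positive", call. = FALSE)
  stopifnot(all(c("POI", "VICTIM") %in% names(group_weights)),
            all(c("POI", "VICTIM") %in% names(mention_prevalence)),
            all(c("POI", "VICTIM") %in% names(hospital_only_rate)))
  for (role in dv_roles()) {
    unknown <- setdiff(names(group_weights[[role]]), level1_groups())
    if (length(unknown) > 0) {
      stop("unknown group(s) in ", role, " weights: ",
           paste(unknown, collapse = "; "), call. = FALSE)
    }
    group_weights[[role]] <- .norm_weights(group_weights[[role]])
  }
  hospital_weights <- .norm_weights(hospital_weights)
  structure(list(n_events = as.integer(n_events),
                 mention_prevalence = mention_prevalence,
                 group_weights = group_weights,
                 concordant_fraction = concordant_fraction,
                 cross_role_fraction = cross_role_fraction,
                 hospital_only_rate = hospital_only_rate,
                 hospital_weights = hospital_weights,
                 window_offset_sampler = window_offset_sampler,
                 distractor_rate = distractor_rate,
                 noise_rate = noise_rate,
                 date_range = date_range,
                 seed = as.integer(seed)),
            class = "dv_cohort_config")
}

#' Default record-start offset sampler
#'
#' A mixture over day offsets from the event date chosen to span the
#' inside and outside of every window period: about a quarter of records
#' start within two weeks of the event (including same-day presentations
#' that fall inside the 48-hour window), with progressively wider bands up
#' to roughly two years out, so the 1-, 3-, 6- and 12-month windows and
#' the unrestricted join all see different linked sets.
#'
#' @param n Number of offsets to draw.
#' @return Integer vector of signed day offsets.
#' @export
default_offset_sampler <- function(n) {
  band <- sample.int(5L, n, replace = TRUE,
                     prob = c(0.25, 0.2, 0.2, 0.2, 0.15))
  lo <- c(0L, 16L, 91L, 181L, 366L)[band]
  hi <- c(15L, 90L, 180L, 365L, 730L)[band]
  mag <- lo + floor(runif(n) * (hi - lo + 1L))
  sign <- ifelse(runif(n) < 0.5, -1L, 1L)
  as.integer(ifelse(mag == 0L, 1L, sign) * mag)
}

# Code pools per first-level group, derived from the shipped lexicon and
# crosswalk so generated records always harmonize.
.code_pools <- function(lexicon, crosswalk) {
  icd10 <- unique(c(lexicon$icd10_code, crosswalk$icd10_code))
  icd10 <- icd10[grepl("^[A-Z][0-9]", icd10)]
  pools <- split(icd10, roll_up(icd10))
  cw9 <- crosswalk[crosswalk$scheme == "ICD9", ]
  cwsn <- crosswalk[crosswalk$scheme == "SNOMED", ]
  list(icd10 = pools,
       icd9 = split(cw9$raw_code, roll_up(cw9$icd10_code)),
       snomed = split(cwsn$raw_code, roll_up(cwsn$icd10_code)))
}

.pick <- function(pool) pool[[sample.int(length(pool), 1L)]]

# Compose one planted sentence; returns the sentence text. The planted
# pattern (anchor, trigger, term in order, one sentence) always survives
# the noise model, which is restricted to casing changes and filler
# clauses.
.plant_sentence <- function(role, term, is_medication, grammar, noise_rate) {
  anchor <- if (role == "POI") .pick(grammar$poi_anchors) else .pick(grammar$victim_anchors)
  trigger <- if (is_medication) .pick(.medication_triggers) else .pick(.illness_triggers)
  frame <- .pick(.illness_frames)
  anchor_txt <- if (anchor %in% c("poi", "vic", "pinop")) toupper(anchor) else anchor
  if (runif(1) < noise_rate) {
    anchor_txt <- paste0(anchor_txt, sub(",$", "", .pick(.filler_clauses)))
  }
  s <- sprintf(frame, anchor_txt, trigger, term)
  if (runif(1) < noise_rate / 2) s <- toupper(s)
  s
}

#' Generate a labelled synthetic cohort
#'
#' Deterministic given the configuration seed. Narratives are composed
#' from a versioned library of sentence frames mixing planted mention
#' phrases (role anchor + trigger + lexicon term, always within one
#' sentence), distractor sentences (including dictionary terms without an
#' anchor and anchors without a term), and surface noise. Hospital records
#' carry ICD-10, ICD-9 or SNOMED-CT codes consistent with the packaged
#' crosswalk, with start dates at configurable offsets from the event
#' date. Gold labels record exactly what was planted and, for mentions
#' with a concordant record, the window periods at which agreement should
#' hold. By construction, same-role agreement arises *only* through
#' `concordant_fraction`: hospital-only and cross-role records never reuse
#' a group mentioned for the same person at that event, and each
#' individual appears in exactly one event.
#'
#' @param config A `dv_cohort_config`.
#' @param lexicon A `dv_lexicon` (defaults to the packaged lexicon).
#' @param crosswalk A `dv_crosswalk` (defaults to the packaged table).
#' @param grammar A `dv_grammar` whose pattern inventory the planted
#'   phrases are drawn from.
#' @return A list of class `dv_cohort`: `events`, `hospital`, `gold`
#'   tibbles and the `config`.
#' @export
generate_cohort <- function(config,
                            lexicon = load_lexicon(),
                            crosswalk = load_crosswalk(),
                            grammar = dv_grammar()) {
  stopifnot(inherits(config, "dv_cohort_config"))
  withr::with_seed(config$seed, {
    n <- config$n_events
    pools <- .code_pools(lexicon, crosswalk)
    windows <- lapply(c("1m", "3m", "6m", "12m", "48h", "none"), parse_window)
    names(windows) <- vapply(windows, window_label, character(1))

    event_id <- sprintf("E%06d", seq_len(n))
    poi_id <- sprintf("P%06d", seq_len(n) * 2L - 1L)
    victim_id <- sprintf("P%06d", seq_len(n) * 2L)
    days <- as.integer(config$date_range[2] - config$date_range[1])
    event_date <- config$date_range[1] + sample.int(days + 1L, n, replace = TRUE) - 1L
    relationship <- sample(c("spouse/partner", "ex-partner", "parent/guardian",
                             "sibling", "carer", "other family member"),
                           n, replace = TRUE)

    narratives <- character(n)
    gold_rows <- list()
    hosp_rows <- list()
    gi <- 0L; hi <- 0L

    add_hospital <- function(person, date_start, group, concordant) {
      # draw a code that rolls up to `group`; APDC records are ICD-10 only
      src <- if (runif(1) < 0.5) "APDC" else "EDDC"
      scheme <- "ICD10"
      if (src == "EDDC") {
        u <- runif(1)
        scheme <- if (u < 0.5) "ICD10" else if (u < 0.8) "ICD9" else "SNOMED"
      }
      pool <- switch(scheme, ICD10 = pools$icd10[[group]],
                     ICD9 = pools$icd9[[group]], SNOMED = pools$snomed[[group]])
      if (is.null(pool) || length(pool) == 0) {
        scheme <- "ICD10"
        pool <- pools$icd10[[group]]
      }
      hi <<- hi + 1L
      hosp_rows[[hi]] <<- tibble::tibble(
        person_id = person, source = src,
        start_date = date_start,
        end_date = date_start + sample.int(6L, 1L) - 1L,
        raw_code = .pick(pool), scheme = scheme)
      hi
    }

    for (i in seq_len(n)) {
      sentences <- character(0)
      persons <- c(POI = poi_id[i], VICTIM = victim_id[i])
      mention_groups <- list(POI = character(0), VICTIM = character(0))

      for (role in dv_roles()) {
        if (runif(1) >= config$mention_prevalence[[role]]) next
        w <- config$group_weights[[role]]
        k <- 1L + rbinom(1L, 1L, 0.2)
        k <- min(k, sum(w > 0))
        grps <- sample(names(w), k, prob = w)
        mention_groups[[role]] <- grps
        for (g in grps) {
          cand <- lexicon$surface_form[lexicon$level1 == g]
          term <- .pick(cand)
          s <- .plant_sentence(role, term, g %in% .med_groups, grammar,
                               config$noise_rate)
          sentences <- c(sentences, s)

          concordant_at <- character(0)
          codeable <- !is.null(pools$icd10[[g]]) && length(pools$icd10[[g]]) > 0
          if (codeable && runif(1) < config$concordant_fraction) {
            off <- config$window_offset_sampler(1L)
            rs <- event_date[i] + off
            idx <- add_hospital(persons[[role]], rs, g, TRUE)
            re <- hosp_rows[[idx]]$end_date
            hit <- vapply(windows, function(wd) {
              in_window(event_date[i], rs, re, wd)
            }, logical(1))
            concordant_at <- names(windows)[hit]
          }
          gi <- gi + 1L
          gold_rows[[gi]] <- tibble::tibble(
            event_id = event_id[i], role = role, level1_group = g,
            planted_phrase = s,
            expected_concordant_at = paste(concordant_at, collapse = ";"))
        }
      }

      any_mention <- any(lengths(mention_groups) > 0)
      if (any_mention && runif(1) < config$cross_role_fraction) {
        # different-individuals pattern: hospital record for the party with
        # the fewer mentions, avoiding that party's own mention groups
        other <- if (length(mention_groups$POI) >= length(mention_groups$VICTIM))
          "VICTIM" else "POI"
        w <- config$hospital_weights
        w[names(w) %in% mention_groups[[other]]] <- 0
        if (sum(w) > 0) {
          g <- sample(names(w), 1L, prob = w)
          add_hospital(persons[[other]],
                       event_date[i] + config$window_offset_sampler(1L), g, FALSE)
        }
      }
      for (role in dv_roles()) {
        if (runif(1) < config$hospital_only_rate[[role]]) {
          w <- config$hospital_weights
          w[names(w) %in% mention_groups[[role]]] <- 0
          if (sum(w) > 0) {
            g <- sample(names(w), 1L, prob = w)
            add_hospital(persons[[role]],
                         event_date[i] + config$window_offset_sampler(1L), g, FALSE)
          }
        }
      }

      n_distract <- rbinom(1L, 3L, config$distractor_rate)
      if (n_distract > 0) {
        sentences <- c(sentences, sample(.distractors, n_distract))
      }
      if (length(sentences) == 0) {
        sentences <- sample(.distractors, 1L)
      }
      narratives[i] <- paste(sample(sentences), collapse = " ")
    }

    events <- tibble::tibble(event_id = event_id, event_date = event_date,
                             poi_id = poi_id, victim_id = victim_id,
                             relationship_flag = relationship,
                             narrative = narratives)
    hospital <- if (hi > 0) dplyr::bind_rows(hosp_rows) else
      tibble::tibble(person_id = character(0), source = character(0),
                     start_date = as.Date(character(0)),
                     end_date = as.Date(character(0)),
                     raw_code = character(0), scheme = character(0))
    gold <- if (gi > 0) dplyr::bind_rows(gold_rows) else
      tibble::tibble(event_id = character(0), role = character(0),
                     level1_group = character(0), planted_phrase = character(0),
                     expected_concordant_at = character(0))
    structure(list(events = events, hospital = hospital, gold = gold,
                   config = config),
              class = "dv_cohort")
  })
}

#' Tables expected under perfect extraction
#'
#' Computes, directly from the gold labels and the generated hospital
#' table (bypassing text extraction entirely), the summary tables the
#' pipeline should produce if every planted mention were recovered. Used
#' as the parameter-recovery oracle: on a noiseless cohort the end-to-end
#' pipeline must reproduce these tables cell for cell.
#'
#' @param cohort A `dv_cohort`.
#' @param window A `dv_window`.
#' @param crosswalk A `dv_crosswalk` for harmonizing the hospital side.
#' @param semantics Month-window semantics (see [in_window()]).
#' @return A `dv_tables`.
#' @export
expected_tables <- function(cohort, window, crosswalk = load_crosswalk(),
                            semantics = "overlap") {
  gold_mentions <- cohort$gold[, c("event_id", "role", "level1_group")]
  harmonized <- harmonize_records(cohort$hospital, crosswalk)
  links <- link_events(cohort$events, harmonized, window, semantics)
  tabulate_concordance(classify_events(cohort$events, gold_mentions, links))
}

#' Write a cohort to delimited files
#'
#' Writes `events.csv`, `hospital.csv` and `gold.csv` in the formats the
#' extraction and linkage stages read.
#'
#' @param cohort A `dv_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$events, file.path(dir, "events.csv"))
  readr::write_csv(cohort$hospital, file.path(dir, "hospital.csv"))
  readr::write_csv(cohort$gold, file.path(dir, "gold.csv"))
  invisible(dir)
}
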