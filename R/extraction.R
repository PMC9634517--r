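# Rule-based extraction of role-attributed mental-illness mentions from
# free-text event narratives: sentence segmentation, semantic role anchors,
# trigger patterns, gazetteer term match, nearest-anchor attribution.

#' Construct the extraction pattern grammar
#'
#' The grammar is the pattern inventory used to recognise role-attributed
#' mention phrases: a set of role anchors for the person of interest and
#' the victim, and a set of trigger phrases that connect an anchor to a
#' dictionary term (e.g. "the POI *is suffering from* dementia", "the
#' victim *takes* Valium"). A mention is emitted when an anchor, a trigger
#' and a lexicon term occur in that order within one sentence.
#'
#' @param poi_anchors,victim_anchors Character vectors of anchor phrases
#'   (matched case-insensitively on word boundaries). The two sets must be
#'   disjoint.
#' @param triggers Character vector of trigger phrases.
#' @return A list of class `dv_grammar`.
#' @export
dv_grammar <- function(poi_anchors = c("poi", "person of interest", "defendant", "accused"),
                       victim_anchors = c("vic", "victim", "pinop",
                                          "person in need of protection"),
                       triggers = c("is suffering from", "suffering from", "suffers from",
                                    "was diagnosed with", "diagnosed with",
                                    "has a history of", "history of",
                                    "is on", "takes", "is taking", "has")) {
  poi_anchors <- tolower(poi_anchors)
  victim_anchors <- tolower(victim_anchors)
  if (length(intersect(poi_anchors, victim_anchors)) > 0) {
    stop("anchor sets must be disjoint", call. = FALSE)
  }
  structure(list(poi_anchors = poi_anchors,
                 victim_anchors = victim_anchors,
                 triggers = tolower(triggers)),
            class = "dv_grammar")
}

.rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Word-bounded alternation, longest alternative first so that e.g.
# "paranoid schizophrenia" wins over the embedded "schizophrenia".
.phrase_regex <- function(phrases) {
  phrases <- phrases[order(-nchar(phrases))]
  paste0("\\b(?:", paste(.rx_escape(phrases), collapse = "|"), ")\\b")
}

#' Normalize a narrative for offset-stable matching
#'
#' Collapses runs of whitespace to single spaces and trims the ends. All
#' mention character spans refer to this normalized text.
#'
#' @param x Character vector of narratives.
#' @return Character vector of normalized narratives.
#' @export
normalize_narrative <- function(x) stringr::str_squish(x)

# Sentence segmentation: split after sentence-final punctuation followed by
# whitespace. Returns start offsets (0-based) and texts.
.split_sentences <- function(text) {
  if (nchar(text) == 0) {
    return(list(start = integer(0), text = character(0)))
  }
  bounds <- stringr::str_locate_all(text, "[.!?]+\\s+")[[1]]
  starts <- c(0L, bounds[, "end"])
  ends <- c(bounds[, "end"], nchar(text))
  keep <- ends > starts
  list(start = as.integer(starts[keep]),
       text = substring(text, starts[keep] + 1L, ends[keep]))
}

.locate_phrases <- function(lower_sentence, regex) {
  loc <- stringr::str_locate_all(lower_sentence, stringr::regex(regex))[[1]]
  if (nrow(loc) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0), text = character(0)))
  }
  tibble::tibble(start = as.integer(loc[, "start"]) - 1L,  # 0-based
                 end = as.integer(loc[, "end"]),           # half-open
                 text = substring(lower_sentence, loc[, "start"], loc[, "end"]))
}

#' Extract role-attributed mental-illness mentions from one event
#'
#' Applies the rule grammar sentence by sentence: within each sentence it
#' locates role anchors, lexicon terms, and trigger phrases; each term is
#' attributed to the nearest anchor by character distance (ties break to
#' the anchor preceding the term) and emitted only when a trigger lies
#' between that anchor and the term. Matches are case-insensitive on the
#' whitespace-normalized narrative; spans are 0-based half-open offsets
#' into that normalized text. Results are deduplicated to one mention per
#' (role, first-level group), keeping the earliest, in sentence order.
#' Negated statements are not handled: "no history of depression" still
#' yields a mention (a documented limitation).
#'
#' @param event A one-row event tibble (see [read_events()]), or a list
#'   with `event_id` and `narrative`.
#' @param lexicon A `dv_lexicon`.
#' @param grammar A `dv_grammar`; defaults to [dv_grammar()].
#' @return A tibble with columns `event_id, role, level1_group, surface,
#'   anchor, trigger, start, end`.
#' @examples
#' lex <- load_lexicon()
#' ev <- list(event_id = "E1", narrative = "The POI is suffering from dementia.")
#' extract_mentions(ev, lex)
#' @export
extract_mentions <- function(event, lexicon, grammar = dv_grammar()) {
  narrative <- event$narrative
  if (is.na(narrative) || !validUTF8(narrative)) {
    stop("narrative for event ", event$event_id, " is not valid text", call. = FALSE)
  }
  empty <- tibble::tibble(event_id = character(0), role = character(0),
                          level1_group = character(0), surface = character(0),
                          anchor = character(0), trigger = character(0),
                          start = integer(0), end = integer(0))
  text <- normalize_narrative(narrative)
  if (nchar(text) == 0) {
    warning("empty narrative for event ", event$event_id, call. = FALSE)
    return(empty)
  }
  if (nrow(lexicon) == 0) return(empty)

  term_rx <- .phrase_regex(lexicon$surface_form)
  anchor_rx <- .phrase_regex(c(grammar$poi_anchors, grammar$victim_anchors))
  trigger_rx <- .phrase_regex(grammar$triggers)

  sentences <- .split_sentences(text)
  out <- vector("list", length(sentences$text))
  for (i in seq_along(sentences$text)) {
    lower <- tolower(sentences$text[[i]])
    terms <- .locate_phrases(lower, term_rx)
    if (nrow(terms) == 0) next
    anchors <- .locate_phrases(lower, anchor_rx)
    if (nrow(anchors) == 0) next
    triggers <- .locate_phrases(lower, trigger_rx)
    anchors$role <- ifelse(anchors$text %in% grammar$poi_anchors, "POI", "VICTIM")

    hits <- vector("list", nrow(terms))
    for (j in seq_len(nrow(terms))) {
      t_start <- terms$start[j]
      t_end <- terms$end[j]
      gap <- ifelse(anchors$end <= t_start, t_start - anchors$end,
             ifelse(anchors$start >= t_end, anchors$start - t_end, 0L))
      preceding <- anchors$end <= t_start
      # nearest anchor; ties break to the anchor preceding the term
      ord <- order(gap, !preceding)
      a <- anchors[ord[1], ]
      if (a$end > t_start) next  # grammar is anchor-first
      trig <- triggers[triggers$start >= a$end & triggers$end <= t_start, , drop = FALSE]
      if (nrow(trig) == 0) next
      off <- sentences$start[[i]]
      hits[[j]] <- tibble::tibble(
        event_id = event$event_id, role = a$role,
        level1_group = NA_character_,
        surface = substring(text, off + t_start + 1L, off + t_end),
        anchor = a$text,
        trigger = trig$text[nrow(trig)],  # trigger closest to the term
        start = off + t_start, end = off + t_end)
    }
    out[[i]] <- dplyr::bind_rows(hits)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty)
  res$level1_group <- lexicon$level1[match(tolower(res$surface), lexicon$surface_form)]
  res <- res[!is.na(res$level1_group), , drop = FALSE]
  res <- res[!duplicated(res[, c("role", "level1_group")]), , drop = FALSE]
  res
}

#' Extract mentions over a corpus of events
#'
#' Concatenates per-event extraction and reports how many events carry at
#' least one unique mention, overall and by role. Deterministic given
#' identical inputs.
#'
#' @param events Event tibble (one row per event; unique `event_id`).
#' @param lexicon A `dv_lexicon`.
#' @param grammar A `dv_grammar`.
#' @return A list with `mentions` (tibble) and `summary` (tibble with
#'   `n_events`, `n_events_with_mention`, `n_events_poi_mention`,
#'   `n_events_victim_mention`).
#' @export
extract_corpus <- function(events, lexicon, grammar = dv_grammar()) {
  if (anyDuplicated(events$event_id)) {
    stop("duplicate event_id(s): ",
         paste(unique(events$event_id[duplicated(events$event_id)]), collapse = ", "),
         call. = FALSE)
  }
  mentions <- dplyr::bind_rows(lapply(seq_len(nrow(events)), function(i) {
    extract_mentions(events[i, ], lexicon, grammar)
  }))
  if (nrow(mentions) == 0) {
    mentions <- tibble::tibble(event_id = character(0), role = character(0),
                               level1_group = character(0), surface = character(0),
                               anchor = character(0), trigger = character(0),
                               start = integer(0), end = integer(0))
  }
  summary <- tibble::tibble(
    n_events = nrow(events),
    n_events_with_mention = dplyr::n_distinct(mentions$event_id),
    n_events_poi_mention = dplyr::n_distinct(mentions$event_id[mentions$role == "POI"]),
    n_events_victim_mention = dplyr::n_distinct(mentions$event_id[mentions$role == "VICTIM"]))
  list(mentions = mentions, summary = summary)
}

#' Score extracted mentions against gold annotations
#'
#' Mentions are keyed by the unique triple (event, role, first-level
#' group); a true positive is an exact key match. Precision, recall and the
#' F1 score (harmonic mean) are reported per role and micro-averaged
#' overall. An undefined precision (no predictions) or recall (empty gold)
#' is reported as `NaN` with a warning.
#'
#' @param predicted,gold Tibbles with columns `event_id, role,
#'   level1_group`.
#' @return A tibble with one row per role plus `overall`: `tp, fp, fn,
#'   precision, recall, f1`.
#' @export
score_extraction <- function(predicted, gold) {
  key <- function(x) unique(paste(x$event_id, x$role, x$level1_group, sep = "\r"))
  strata <- list(POI = "POI", VICTIM = "VICTIM", overall = c("POI", "VICTIM"))
  rows <- lapply(names(strata), function(nm) {
    p <- key(predicted[predicted$role %in% strata[[nm]], , drop = FALSE])
    g <- key(gold[gold$role %in% strata[[nm]], , drop = FALSE])
    tp <- length(intersect(p, g))
    fp <- length(setdiff(p, g))
    fn <- length(setdiff(g, p))
    precision <- if (tp + fp == 0) NaN else tp / (tp + fp)
    recall <- if (tp + fn == 0) NaN else tp / (tp + fn)
    f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0) {
      NaN
    } else {
      2 * precision * recall / (precision + recall)
    }
    tibble::tibble(role = nm, tp = tp, fp = fp, fn = fn,
                   precision = precision, recall = recall, f1 = f1)
  })
  res <- dplyr::bind_rows(rows)
  if (any(is.nan(res$precision))) {
    warning("precision undefined (no predictions) for: ",
            paste(res$role[is.nan(res$precision)], collapse = ", "), call. = FALSE)
  }
  if (any(is.nan(res$recall))) {
    warning("recall undefined (empty gold) for: ",
            paste(res$role[is.nan(res$recall)], collapse = ", "), call. = FALSE)
  }
  res
}

#' Read an event table
#'
#' Expects comma-delimited text with header
#' `event_id,event_date,poi_id,victim_id,relationship_flag,narrative`,
#' ISO-8601 dates. Validates the single-POI/single-victim design: person
#' IDs must differ within an event and event IDs must be unique. Rows whose
#' POI and victim IDs coincide are rejected rather than silently processed.
#'
#' @param path Path to the event file.
#' @return Event tibble.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  ev <- readr::read_csv(path, col_types = readr::cols(
    event_id = readr::col_character(),
    event_date = readr::col_date(),
    poi_id = readr::col_character(),
    victim_id = readr::col_character(),
    relationship_flag = readr::col_character(),
    narrative = readr::col_character()))
  if (any(is.na(ev$event_date))) {
    stop("unparseable event_date in ", path, call. = FALSE)
  }
  if (anyDuplicated(ev$event_id)) {
    stop("duplicate event_id(s) in ", path, call. = FALSE)
  }
  same <- ev$poi_id == ev$victim_id
  if (any(same)) {
    stop("poi_id equals victim_id for event(s): ",
         paste(ev$event_id[same], collapse = ", "), call. = FALSE)
  }
  ev
}

#' Write extracted mentions to delimited text
#' @param mentions Mention tibble from [extract_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mentions <- function(mentions, path) {
  readr::write_csv(mentions[, c("event_id", "role", "level1_group", "surface",
                                "start", "end", "trigger")], path)
  invisible(path)
}
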