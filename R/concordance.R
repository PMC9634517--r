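# Event-level concordance between text-mined mentions and hospital
# diagnoses: per-role group sets, 2x2 cross-tabulation over events, and
# per-group concordance/discordance profiles.

.dv_cells <- c("BOTH", "MENTION_ONLY", "HOSPITAL_ONLY", "NEITHER")

.cell_of <- function(has_mention, has_hospital) {
  dplyr::case_when(
    has_mention & has_hospital ~ "BOTH",
    has_mention & !has_hospital ~ "MENTION_ONLY",
    !has_mention & has_hospital ~ "HOSPITAL_ONLY",
    TRUE ~ "NEITHER")
}

#' Classify events into concordance cells
#'
#' For every event and role, builds the set of first-level groups mentioned
#' in the narrative and the set carried by linked hospital records, and
#' intersects them. Agreement for a role means the intersection is
#' nonempty: the two record systems name the same first-level group for
#' the same individual, irrespective of how many other diagnoses that
#' individual carries. The event-level cell takes an OR over roles (an
#' event is "mention yes" if either party has a mention), so events where
#' the mention belongs to one party and the hospital record to the other
#' land in the BOTH cell without any role-level agreement.
#'
#' @param events Event tibble.
#' @param mentions Mention tibble (`event_id, role, level1_group`).
#' @param links Linked-record tibble from [link_events()].
#' @return A tibble with one row per event x role: `event_id, role,
#'   mention_groups, hospital_groups` (list columns), `cell`, `agreement`,
#'   `matched_groups` (list column), `event_cell` (the OR-over-roles cell,
#'   repeated on both rows of an event).
#' @export
classify_events <- function(events, mentions, links) {
  grid <- tidyr::expand_grid(event_id = events$event_id, role = dv_roles())

  gather <- function(x) {
    if (nrow(x) == 0) {
      return(tibble::tibble(event_id = character(0), role = character(0),
                            groups = list()))
    }
    x |>
      dplyr::distinct(.data$event_id, .data$role, .data$level1_group) |>
      dplyr::group_by(.data$event_id, .data$role) |>
      dplyr::summarise(groups = list(sort(.data$level1_group)), .groups = "drop")
  }
  m <- gather(mentions)
  h <- gather(links)

  res <- grid |>
    dplyr::left_join(dplyr::rename(m, mention_groups = "groups"),
                     by = c("event_id", "role")) |>
    dplyr::left_join(dplyr::rename(h, hospital_groups = "groups"),
                     by = c("event_id", "role"))
  fill0 <- function(lst) lapply(lst, function(g) if (is.null(g)) character(0) else g)
  res$mention_groups <- fill0(res$mention_groups)
  res$hospital_groups <- fill0(res$hospital_groups)
  res$matched_groups <- Map(intersect, res$mention_groups, res$hospital_groups)
  has_m <- lengths(res$mention_groups) > 0
  has_h <- lengths(res$hospital_groups) > 0
  res$cell <- .cell_of(has_m, has_h)
  res$agreement <- lengths(res$matched_groups) > 0

  ev <- res |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(event_cell = .cell_of(any(lengths(.data$mention_groups) > 0),
                                           any(lengths(.data$hospital_groups) > 0)),
                     .groups = "drop")
  dplyr::left_join(res, ev, by = "event_id")
}

#' Percentage with half-up rounding
#'
#' Computes `100 * numerator / denominator` rounded half-up to two decimal
#' places, the convention used in all reported tables. A zero denominator
#' is flagged with a warning and rendered as 0.
#'
#' @param numerator,denominator Integer vectors (recycled).
#' @return Numeric vector of percentages.
#' @examples
#' rate(382, 2395)  # 15.95
#' @export
rate <- function(numerator, denominator) {
  n <- max(length(numerator), length(denominator))
  numerator <- rep_len(numerator, n)
  denominator <- rep_len(denominator, n)
  zero <- denominator == 0
  if (any(zero)) {
    warning("rate with zero denominator rendered as 0", call. = FALSE)
  }
  pct <- ifelse(zero, 0, 100 * numerator / denominator)
  # round half-up to 2 dp; the epsilon guards against binary representation
  # of values sitting exactly on the .xx5 boundary
  floor(pct * 100 + 0.5 + 1e-9) / 100
}

#' Tabulate concordance summaries over a classified cohort
#'
#' Produces the full set of reporting tables from per-event
#' classifications:
#' \describe{
#'   \item{two_by_two}{event counts by mention-yes/no x hospital-yes/no
#'     (OR over roles); cells sum to the event count.}
#'   \item{per_role}{per role: events in the BOTH cell and events with
#'     agreement (same group, same individual), with the agreement share.}
#'   \item{per_group_concordance}{per role and first-level group: events
#'     with a mention of that group (the denominator), events with
#'     agreement on that group, and the concordance rate. Groups with a
#'     zero denominator are listed with rate 0 and flagged.}
#'   \item{mention_only_profile}{within events whose event-level cell is
#'     MENTION_ONLY: per role and group, mention counts with percentages
#'     of that role's stratum denominator (events in the stratum with a
#'     mention for the role).}
#'   \item{hospital_only_profile}{the same profile for events with a
#'     hospital record and no mention.}
#' }
#'
#' @param conc Classification tibble from [classify_events()].
#' @return A list of class `dv_tables` with the five tibbles plus
#'   `n_events`.
#' @export
tabulate_concordance <- function(conc) {
  per_event <- conc[!duplicated(conc$event_id), c("event_id", "event_cell")]
  n_events <- nrow(per_event)
  two_by_two <- tibble::tibble(cell = .dv_cells) |>
    dplyr::left_join(dplyr::count(per_event, cell = .data$event_cell), by = "cell") |>
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n))

  per_role <- conc |>
    dplyr::group_by(.data$role) |>
    dplyr::summarise(n_both = sum(.data$cell == "BOTH"),
                     n_agreement = sum(.data$agreement), .groups = "drop") |>
    dplyr::mutate(agreement_rate = suppressWarnings(rate(.data$n_agreement,
                                                         .data$n_both)))

  groups <- level1_groups()
  grid <- tidyr::expand_grid(role = dv_roles(), level1_group = groups)
  # flatten list-columns by hand so empty cohorts keep character typing
  flatten_groups <- function(rows, side) {
    lst <- rows[[side]]
    tibble::tibble(role = rep(rows$role, lengths(lst)),
                   level1_group = as.character(unlist(lst, use.names = FALSE)))
  }
  mention_long <- flatten_groups(conc, "mention_groups")
  matched_long <- flatten_groups(conc, "matched_groups")
  per_group <- grid |>
    dplyr::left_join(dplyr::count(mention_long, .data$role, .data$level1_group,
                                  name = "n_total"),
                     by = c("role", "level1_group")) |>
    dplyr::left_join(dplyr::count(matched_long, .data$role, .data$level1_group,
                                  name = "n_concordant"),
                     by = c("role", "level1_group")) |>
    dplyr::mutate(n_total = ifelse(is.na(.data$n_total), 0L, .data$n_total),
                  n_concordant = ifelse(is.na(.data$n_concordant), 0L, .data$n_concordant),
                  zero_denominator = .data$n_total == 0,
                  concordance_rate = suppressWarnings(rate(.data$n_concordant,
                                                           .data$n_total)))

  profile <- function(stratum_cell, side) {
    rows <- conc[conc$event_cell == stratum_cell, , drop = FALSE]
    side_groups <- rows[[side]]
    denom <- rows |>
      dplyr::mutate(has = lengths(side_groups) > 0) |>
      dplyr::group_by(.data$role) |>
      dplyr::summarise(n_role = sum(.data$has), .groups = "drop")
    counts <- flatten_groups(rows, side) |>
      dplyr::count(.data$role, .data$level1_group, name = "n")
    grid |>
      dplyr::left_join(counts, by = c("role", "level1_group")) |>
      dplyr::left_join(denom, by = "role") |>
      dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
                    n_role = ifelse(is.na(.data$n_role), 0L, .data$n_role),
                    pct = suppressWarnings(rate(.data$n, .data$n_role)))
  }
  mention_only_profile <- profile("MENTION_ONLY", "mention_groups")
  hospital_only_profile <- profile("HOSPITAL_ONLY", "hospital_groups")

  structure(list(n_events = n_events,
                 two_by_two = two_by_two,
                 per_role = per_role,
                 per_group_concordance = per_group,
                 mention_only_profile = mention_only_profile,
                 hospital_only_profile = hospital_only_profile),
            class = "dv_tables")
}

#' Write summary tables to delimited files
#'
#' Writes `table_2x2.csv`, `table_concordance_by_group.csv`,
#' `table_mention_only.csv` and `table_hospital_only.csv` into a
#' directory.
#'
#' @param tables A `dv_tables` from [tabulate_concordance()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tables$two_by_two, file.path(dir, "table_2x2.csv"))
  readr::write_csv(tables$per_group_concordance,
                   file.path(dir, "table_concordance_by_group.csv"))
  readr::write_csv(tables$mention_only_profile,
                   file.path(dir, "table_mention_only.csv"))
  readr::write_csv(tables$hospital_only_profile,
                   file.path(dir, "table_hospital_only.csv"))
  readr::write_csv(tables$per_role, file.path(dir, "table_per_role.csv"))
  invisible(dir)
}
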