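# Temporal window-period linkage between police events and hospital
# records, joined on exact person identifiers (identity resolution is
# assumed already done upstream by the linkage authority).

#' Construct a window specification
#'
#' Month windows are symmetric calendar-month intervals around the event
#' date (the analyses use 1, 3, 6 and 12 months before and after); the
#' hour window supports the forward-looking 48-hour sub-analysis; `none`
#' lifts the temporal restriction entirely.
#'
#' @param kind One of `"none"`, `"months"`, `"hours"`.
#' @param before,after Nonnegative integers. For `months` the window is
#'   symmetric (`before == after`, one of 1, 3, 6, 12); for `hours` only
#'   `after` is used (forward-looking) and `before` must be 0.
#' @return A list of class `dv_window`.
#' @export
window_spec <- function(kind = c("none", "months", "hours"), before = 0L, after = before) {
  kind <- match.arg(kind)
  before <- as.integer(before); after <- as.integer(after)
  if (kind == "months") {
    if (before != after || !before %in% c(1L, 3L, 6L, 12L)) {
      stop("month windows are symmetric with width 1, 3, 6 or 12 months", call. = FALSE)
    }
  }
  if (kind == "hours" && (before != 0L || after < 0L)) {
    stop("hour windows are forward-looking: before must be 0", call. = FALSE)
  }
  structure(list(kind = kind, before = before, after = after),
            class = "dv_window")
}

#' Parse a compact window label
#'
#' Accepts `"none"`, `"<n>m"` (months) and `"<n>h"` (hours), e.g. `"12m"`,
#' `"48h"`.
#'
#' @param label Character scalar.
#' @return A `dv_window`.
#' @export
parse_window <- function(label) {
  label <- tolower(trimws(label))
  if (label == "none") return(window_spec("none"))
  if (grepl("^[0-9]+m$", label)) {
    return(window_spec("months", as.integer(sub("m$", "", label))))
  }
  if (grepl("^[0-9]+h$", label)) {
    return(window_spec("hours", before = 0L, after = as.integer(sub("h$", "", label))))
  }
  stop("cannot parse window label: ", label, call. = FALSE)
}

#' Format a window specification as a compact label
#' @param window A `dv_window`.
#' @return Character scalar, e.g. `"12m"`, `"48h"`, `"none"`.
#' @export
window_label <- function(window) {
  switch(window$kind,
         none = "none",
         months = paste0(window$after, "m"),
         hours = paste0(window$after, "h"))
}

#' Test whether an admission falls inside a window period
#'
#' For month windows the default semantics are interval overlap with
#' closed endpoints: the admission interval `[start_date, end_date]` must
#' intersect `[event_date - before months, event_date + after months]`,
#' where month arithmetic is calendar-based with the day of month clamped
#' to the month end (31 January minus 1 month is 31 December). The
#' alternative `"start"` semantics test the admission start date only.
#' Hour windows are forward-looking from the event-date midnight and test
#' the admission start only: the start must lie within `after` hours of
#' the event date (closed endpoints). A `none` window is always `TRUE`.
#'
#' @param event_date Event date(s) (`Date`).
#' @param start_date,end_date Admission interval (`Date`), recycled
#'   against `event_date`.
#' @param window A `dv_window`.
#' @param semantics `"overlap"` (default) or `"start"` for month windows.
#' @return Logical vector.
#' @examples
#' in_window(as.Date("2010-06-15"), as.Date("2010-06-20"),
#'           as.Date("2010-06-21"), window_spec("months", 12))
#' @export
in_window <- function(event_date, start_date, end_date = start_date,
                      window, semantics = c("overlap", "start")) {
  semantics <- match.arg(semantics)
  stopifnot(inherits(window, "dv_window"))
  n <- max(length(event_date), length(start_date), length(end_date))
  event_date <- rep_len(event_date, n)
  start_date <- rep_len(start_date, n)
  end_date <- rep_len(end_date, n)
  switch(window$kind,
    none = rep(TRUE, n),
    months = {
      # calendar-month shift with day-of-month clamped to the month end
      # (31 Jan minus 1 month -> 31 Dec)
      lo <- lubridate::add_with_rollback(
        event_date, lubridate::period(month = -window$before))
      hi <- lubridate::add_with_rollback(
        event_date, lubridate::period(month = window$after))
      if (semantics == "overlap") {
        start_date <= hi & end_date >= lo
      } else {
        start_date >= lo & start_date <= hi
      }
    },
    hours = {
      elapsed <- as.numeric(difftime(start_date, event_date, units = "hours"))
      elapsed >= 0 & elapsed <= window$after
    })
}

#' Read a hospital-record table
#'
#' Expects comma-delimited text with header
#' `person_id,source,start_date,end_date,raw_code,scheme`, ISO-8601 dates.
#' Validates that admission intervals are ordered, that `source` is APDC
#' or EDDC, and that APDC rows carry ICD-10 codes only (the admitted
#' patient collection is ICD-10 coded; only the emergency collection mixes
#' schemes).
#'
#' @param path Path to the hospital file.
#' @return Hospital-record tibble.
#' @export
read_hospital <- function(path) {
  if (!file.exists(path)) stop("hospital file not found: ", path, call. = FALSE)
  hosp <- readr::read_csv(path, col_types = readr::cols(
    person_id = readr::col_character(),
    source = readr::col_character(),
    start_date = readr::col_date(),
    end_date = readr::col_date(),
    raw_code = readr::col_character(),
    scheme = readr::col_character()))
  validate_hospital(hosp)
  hosp
}

validate_hospital <- function(hosp) {
  if (any(hosp$end_date < hosp$start_date)) {
    stop("hospital record(s) with end_date before start_date", call. = FALSE)
  }
  bad_src <- setdiff(unique(hosp$source), c("APDC", "EDDC"))
  if (length(bad_src) > 0) {
    stop("unknown hospital source(s): ", paste(bad_src, collapse = ", "), call. = FALSE)
  }
  if (any(hosp$source == "APDC" & hosp$scheme != "ICD10")) {
    stop("APDC records must be ICD-10 coded", call. = FALSE)
  }
  invisible(hosp)
}

#' Harmonize hospital diagnosis codes to first-level ICD-10 groups
#'
#' Converts ICD-9 and SNOMED-CT codes to ICD-10 through the crosswalk and
#' rolls every code up to its first-level group. Records whose codes cannot
#' be mapped are flagged `unmappable`; they are excluded from linkage and
#' counted in the run report.
#'
#' @param records Hospital-record tibble (see [read_hospital()]).
#' @param crosswalk A `dv_crosswalk`.
#' @return The tibble with added columns `icd10_code`, `level1_group`,
#'   `unmappable` and a stable `record_index`.
#' @export
harmonize_records <- function(records, crosswalk) {
  validate_hospital(records)
  records$record_index <- seq_len(nrow(records))
  records$icd10_code <- convert_code(crosswalk, records$raw_code, records$scheme)
  records$level1_group <- roll_up(records$icd10_code)
  records$unmappable <- is.na(records$level1_group)
  records
}

#' Link events to hospital records by person and window
#'
#' For each event and role, the linked set contains the harmonized,
#' mappable hospital records whose person ID equals that role's person ID
#' (exact string match) and whose admission falls inside the window. The
#' number of unmappable records excluded is attached as the
#' `n_unmappable` attribute.
#'
#' @param events Event tibble.
#' @param records Harmonized hospital tibble from [harmonize_records()].
#' @param window A `dv_window`.
#' @param semantics Month-window semantics passed to [in_window()].
#' @return Long tibble `event_id, role, person_id, record_index,
#'   level1_group, start_date`.
#' @export
link_events <- function(events, records, window, semantics = "overlap") {
  if (!"level1_group" %in% names(records)) {
    stop("records must be harmonized first (see harmonize_records)", call. = FALSE)
  }
  n_unmappable <- sum(records$unmappable)
  usable <- records[!records$unmappable,
                    c("person_id", "record_index", "level1_group",
                      "start_date", "end_date")]
  parties <- dplyr::bind_rows(
    tibble::tibble(event_id = events$event_id, event_date = events$event_date,
                   role = "POI", person_id = events$poi_id),
    tibble::tibble(event_id = events$event_id, event_date = events$event_date,
                   role = "VICTIM", person_id = events$victim_id))
  cand <- dplyr::inner_join(parties, usable, by = "person_id",
                            relationship = "many-to-many")
  if (nrow(cand) > 0) {
    keep <- in_window(cand$event_date, cand$start_date, cand$end_date,
                      window, semantics)
    cand <- cand[keep, , drop = FALSE]
  }
  out <- cand[order(match(cand$event_id, events$event_id),
                    cand$role, cand$record_index),
              c("event_id", "role", "person_id", "record_index",
                "level1_group", "start_date")]
  attr(out, "n_unmappable") <- n_unmappable
  out
}
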