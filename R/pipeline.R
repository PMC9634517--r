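# Orchestration: generate -> extract -> harmonize -> link -> concord ->
# report, driven by a structured config, with a JSON run manifest.

#' Read a pipeline run configuration
#'
#' Reads a YAML configuration with the fields accepted by
#' [run_pipeline()]. Paths are resolved relative to the configuration
#' file's directory.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (field in c("events", "hospital", "lexicon", "crosswalk", "out_dir")) {
    if (!is.null(cfg[[field]]) && !grepl("^/", cfg[[field]])) {
      cfg[[field]] <- file.path(base, cfg[[field]])
    }
  }
  cfg
}

#' Run the full concordance pipeline
#'
#' Stages: load (or synthesize) the cohort, extract role-attributed
#' mentions from the narratives, harmonize hospital codes to first-level
#' ICD-10 groups, link events to records for each requested window
#' period, classify and tabulate concordance, and write one table set per
#' window plus a JSON run manifest (package version, seed, configuration
#' echo, exclusion counts).
#'
#' @param config A named list (or path to a YAML file, see
#'   [read_run_config()]) with fields:
#'   \describe{
#'     \item{events, hospital}{input file paths; omit both to generate a
#'       synthetic cohort instead.}
#'     \item{generate}{list of [cohort_config()] arguments used when no
#'       input files are given.}
#'     \item{windows}{character vector of window labels, e.g.
#'       `c("1m","3m","6m","12m","none")`; must be nonempty.}
#'     \item{lexicon, crosswalk}{optional paths; default to the packaged
#'       files.}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{integer seed used for any generation step.}
#'     \item{window_semantics}{`"overlap"` (default) or `"start"`.}
#'   }
#' @return Invisibly, a named list of `dv_tables`, one per window label,
#'   with the manifest attached as attribute `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  windows <- config$windows %||% c("1m", "3m", "6m", "12m", "none")
  if (length(windows) == 0) stop("window list must be nonempty", call. = FALSE)
  out_dir <- config$out_dir %||% stop("config needs an out_dir", call. = FALSE)
  semantics <- config$window_semantics %||% "overlap"
  seed <- as.integer(config$seed %||% 1L)

  lexicon <- load_lexicon(config$lexicon %||% dv_lexicon_path())
  crosswalk <- load_crosswalk(config$crosswalk %||% dv_crosswalk_path())
  grammar <- dv_grammar()

  generated <- is.null(config$events) && is.null(config$hospital)
  if (generated) {
    gen_args <- config$generate %||% list()
    gen_args$seed <- seed
    if (!is.null(gen_args$date_range)) gen_args$date_range <- as.Date(gen_args$date_range)
    cohort <- generate_cohort(do.call(cohort_config, gen_args),
                              lexicon, crosswalk, grammar)
    events <- cohort$events
    hospital <- cohort$hospital
  } else {
    if (is.null(config$events) || !file.exists(config$events)) {
      stop("event file not found: ", config$events %||% "<missing>", call. = FALSE)
    }
    if (is.null(config$hospital) || !file.exists(config$hospital)) {
      stop("hospital file not found: ", config$hospital %||% "<missing>", call. = FALSE)
    }
    events <- read_events(config$events)
    hospital <- read_hospital(config$hospital)
  }

  extraction <- extract_corpus(events, lexicon, grammar)
  harmonized <- harmonize_records(hospital, crosswalk)
  n_unmappable <- sum(harmonized$unmappable)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mentions(extraction$mentions, file.path(out_dir, "mentions.csv"))

  results <- list()
  for (label in windows) {
    window <- parse_window(label)
    links <- link_events(events, harmonized, window, semantics)
    tables <- tabulate_concordance(
      classify_events(events, extraction$mentions, links))
    write_tables(tables, file.path(out_dir, paste0("window_", label)))
    results[[label]] <- tables
  }

  manifest <- list(
    package = "dvconcord",
    version = as.character(utils::packageVersion("dvconcord")),
    seed = seed,
    generated_inputs = generated,
    windows = as.list(windows),
    window_semantics = semantics,
    n_events = nrow(events),
    n_hospital_records = nrow(hospital),
    n_unmappable_records = n_unmappable,
    extraction_summary = as.list(extraction$summary),
    config = config[setdiff(names(config), "generate")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(results, "manifest") <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
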