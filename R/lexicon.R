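# Mental-illness term dictionary, code crosswalks, and the first-level
# roll-up of the ICD-10 Mental and Behavioural Disorders chapter.

# Closed set of first-level reporting groups. The F-chapter blocks carry
# their chapter labels; categories without an ICD-10 chapter-V home
# (medication groups, unspecified substance abuse, drug-induced disorders,
# prescription abuse) are reserved tokens with their own first-level labels,
# as are the injury / self-harm / nervous-system groups that police
# narratives mention but chapter V does not cover.
.dv_groups <- c(
  physiological = "Mental disorders due to known physiological conditions",
  substance_use = "Mental and behavioral disorders due to psychoactive substance use",
  schizophrenia = "Schizophrenia, schizotypal, delusional, and other nonmood psychotic disorders",
  mood          = "Mood (affective) disorders",
  anxiety       = "Anxiety, dissociative, stress related, somatoform, and other nonpsychotic mental disorders",
  behavioural_syndromes = "Behavioral syndromes associated with physiological disturbances and physical factors",
  personality   = "Disorders of adult personality and behavior",
  intellectual  = "Intellectual disability",
  developmental = "Pervasive and specific developmental disorders",
  childhood     = "Behavioral and emotional disorders with onset usually occurring in childhood and adolescence",
  unspecified   = "Unspecified mental disorder",
  self_harm     = "Intentional self-harm",
  symptoms      = "Symptoms and signs involving cognition, perception, emotional state, and behavior",
  substance_abuse = "Substance abuse",
  drug_induced  = "Unspecified drug-induced disorders",
  rx_abuse      = "Drug prescription abuse",
  tbi           = "Traumatic brain injury",
  injury        = "Injury of unspecified body region",
  degenerative  = "Other degenerative diseases of the nervous system",
  atrophies     = "Systematic atrophies primarily affecting the central nervous system",
  nervous       = "Diseases of the nervous system",
  chromosomal   = "Chromosomal abnormalities, not elsewhere classified",
  med_antidepressant = "Medications: antidepressants",
  med_antipsychotic  = "Medications (antipsychotics)",
  med_anxiolytic     = "Medications for anxiety",
  med_neuroleptic    = "Medications (neuroleptics)"
)

# Reserved token -> first-level group
.dv_special_tokens <- c(
  UNSPECIFIED_MI     = "Unspecified mental disorder",
  SUBSTANCE_ABUSE    = "Substance abuse",
  DRUG_INDUCED       = "Unspecified drug-induced disorders",
  RX_ABUSE           = "Drug prescription abuse",
  MED_ANTIDEPRESSANT = "Medications: antidepressants",
  MED_ANTIPSYCHOTIC  = "Medications (antipsychotics)",
  MED_ANXIOLYTIC     = "Medications for anxiety",
  MED_NEUROLEPTIC    = "Medications (neuroleptics)"
)

#' First-level mental-illness reporting groups
#'
#' The closed set of first-level group labels used throughout the pipeline:
#' the top-tier blocks of the ICD-10 Mental and Behavioural Disorders
#' chapter, the adjacent nervous-system / injury / self-harm / symptom
#' groups that appear in narrative mentions and hospital codes, and the
#' reserved medication and unspecified-illness categories that have no
#' chapter-V code of their own.
#'
#' @return Character vector of group labels.
#' @export
level1_groups <- function() unname(.dv_groups)

#' Map an ICD-10 code (or reserved token) to its first-level group
#'
#' Deterministic many-to-one roll-up used as the unit of agreement in the
#' concordance analysis: all F30--F39 codes become "Mood (affective)
#' disorders", all F20--F29 codes the schizophrenia-spectrum group, and so
#' on. Reserved tokens (e.g. `UNSPECIFIED_MI`, the medication categories)
#' map to their own first-level labels. Unknown codes yield `NA`, which
#' downstream stages treat as an unmappable record.
#'
#' @param icd10_code Character vector of ICD-10 codes (e.g. `"F31.1"`) or
#'   reserved category tokens.
#' @return Character vector of first-level group labels, `NA` where the
#'   code falls outside the supported blocks.
#' @examples
#' roll_up(c("F31.1", "F20.0", "UNSPECIFIED_MI", "B99"))
#' @export
roll_up <- function(icd10_code) {
  code <- toupper(trimws(as.character(icd10_code)))
  out <- rep(NA_character_, length(code))

  tok <- .dv_special_tokens[code]
  out[!is.na(tok)] <- tok[!is.na(tok)]

  numeric_part <- suppressWarnings(as.integer(substr(code, 2L, 3L)))
  letter <- substr(code, 1L, 1L)
  valid <- is.na(out) & grepl("^[A-Z][0-9]{2}", code) & !is.na(numeric_part)

  block <- function(ltr, lo, hi, group) {
    hit <- valid & letter == ltr & numeric_part >= lo & numeric_part <= hi
    out[hit] <<- .dv_groups[[group]]
    valid[hit] <<- FALSE
  }
  block("F", 0L, 9L, "physiological")
  block("F", 10L, 19L, "substance_use")
  block("F", 20L, 29L, "schizophrenia")
  block("F", 30L, 39L, "mood")
  block("F", 40L, 48L, "anxiety")
  block("F", 50L, 59L, "behavioural_syndromes")
  block("F", 60L, 69L, "personality")
  block("F", 70L, 79L, "intellectual")
  block("F", 80L, 89L, "developmental")
  block("F", 90L, 98L, "childhood")
  block("F", 99L, 99L, "unspecified")
  block("G", 10L, 14L, "atrophies")
  block("G", 30L, 32L, "degenerative")
  block("G", 0L, 99L, "nervous")
  block("Q", 90L, 99L, "chromosomal")
  block("R", 40L, 46L, "symptoms")
  block("S", 0L, 9L, "tbi")
  block("T", 14L, 14L, "injury")
  block("X", 60L, 84L, "self_harm")
  out
}

#' Load the mental-illness term lexicon
#'
#' Reads a comma-delimited gazetteer with columns
#' `surface_form,canonical,icd10_code,level1,level2,level3`. Surface forms
#' are case-folded and must be unique; every `level1` label must belong to
#' the closed group set ([level1_groups()]); every `icd10_code` must roll up
#' to the `level1` label it is filed under, so each code maps to exactly one
#' first-level group. The packaged lexicon (the default) is a curated,
#' user-replaceable dictionary covering every first-level group.
#'
#' @param path Path to the lexicon file. Defaults to the packaged lexicon.
#' @return A tibble of class `dv_lexicon`, one row per surface form.
#' @export
load_lexicon <- function(path = dv_lexicon_path()) {
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  lex <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("surface_form", "canonical", "icd10_code", "level1", "level2", "level3")
  missing <- setdiff(required, names(lex))
  if (length(missing) > 0) {
    stop("lexicon is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(lex) == 0) {
    warning("lexicon file is empty: ", path, call. = FALSE)
    lex$surface_form <- character(0)
    return(structure(lex, class = c("dv_lexicon", class(lex))))
  }
  lex$surface_form <- stringr::str_squish(tolower(lex$surface_form))
  dup <- lex$surface_form[duplicated(lex$surface_form)]
  if (length(dup) > 0) {
    stop("duplicate surface form(s) in lexicon: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(lex$level1), level1_groups())
  if (length(bad_group) > 0) {
    stop("unknown level1 group(s) in lexicon: ", paste(bad_group, collapse = "; "),
         call. = FALSE)
  }
  rolled <- roll_up(lex$icd10_code)
  off <- which(is.na(rolled) | rolled != lex$level1)
  if (length(off) > 0) {
    stop("icd10_code does not roll up to its stated level1 group for surface form(s): ",
         paste(lex$surface_form[off], collapse = ", "), call. = FALSE)
  }
  message("loaded lexicon with ", nrow(lex), " surface forms")
  structure(lex, class = c("dv_lexicon", class(lex)))
}

#' Path to the packaged lexicon file
#' @return File path of the lexicon shipped with the package.
#' @export
dv_lexicon_path <- function() {
  system.file("extdata", "mi_lexicon.csv", package = "dvconcord", mustWork = TRUE)
}

#' Path to the packaged code crosswalk file
#' @return File path of the ICD-9/SNOMED-CT to ICD-10 crosswalk shipped
#'   with the package.
#' @export
dv_crosswalk_path <- function() {
  system.file("extdata", "code_crosswalk.csv", package = "dvconcord", mustWork = TRUE)
}

#' Look up a surface form in the lexicon
#'
#' Case-insensitive exact phrase match (no stemming, no fuzzing), mirroring
#' a gazetteer lookup.
#'
#' @param lexicon A `dv_lexicon` from [load_lexicon()].
#' @param surface A single surface string.
#' @return A one-row tibble, or `NULL` when the term is absent.
#' @export
lookup_term <- function(lexicon, surface) {
  stopifnot(length(surface) == 1L)
  key <- stringr::str_squish(tolower(surface))
  hit <- lexicon[lexicon$surface_form == key, , drop = FALSE]
  if (nrow(hit) == 0) NULL else hit
}

#' Load the diagnosis-code crosswalk
#'
#' Reads a comma-delimited table `raw_code,scheme,icd10_code` mapping ICD-9
#' and SNOMED-CT diagnosis codes to a single equivalent ICD-10 code. Codes
#' with several plausible ICD-10 targets are resolved to one authoritative
#' row in the file (no runtime disambiguation), so the mapping is
#' deterministic. ICD-10-scheme rows, if present, must be identities.
#'
#' @param path Path to the crosswalk file. Defaults to the packaged table.
#' @return A tibble of class `dv_crosswalk`.
#' @export
load_crosswalk <- function(path = dv_crosswalk_path()) {
  if (!file.exists(path)) {
    stop("crosswalk file not found: ", path, call. = FALSE)
  }
  cw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("raw_code", "scheme", "icd10_code")
  missing <- setdiff(required, names(cw))
  if (length(missing) > 0) {
    stop("crosswalk is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_scheme <- setdiff(unique(cw$scheme), c("ICD10", "ICD9", "SNOMED"))
  if (length(bad_scheme) > 0) {
    stop("unknown scheme(s) in crosswalk: ", paste(bad_scheme, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(cw$raw_code, cw$scheme)
  if (anyDuplicated(key)) {
    stop("crosswalk has multiple rows for: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  id_rows <- cw$scheme == "ICD10" & cw$raw_code != cw$icd10_code
  if (any(id_rows)) {
    stop("ICD10 crosswalk rows must be identity mappings", call. = FALSE)
  }
  structure(cw, class = c("dv_crosswalk", class(cw)))
}

#' Convert a raw diagnosis code to ICD-10
#'
#' ICD-10 inputs pass through unchanged; ICD-9 and SNOMED-CT codes are
#' resolved through the crosswalk. Unmapped codes yield `NA` and are flagged
#' unmappable (and excluded, with a count) by downstream stages.
#'
#' @param crosswalk A `dv_crosswalk` from [load_crosswalk()].
#' @param raw_code Character vector of raw codes.
#' @param scheme Character vector (recycled) in `ICD10`, `ICD9`, `SNOMED`.
#' @return Character vector of ICD-10 codes with `NA` for unmapped input.
#' @export
convert_code <- function(crosswalk, raw_code, scheme) {
  raw_code <- as.character(raw_code)
  scheme <- rep_len(as.character(scheme), length(raw_code))
  bad <- setdiff(unique(scheme), c("ICD10", "ICD9", "SNOMED"))
  if (length(bad) > 0) {
    stop("unknown code scheme(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_character_, length(raw_code))
  out[scheme == "ICD10"] <- raw_code[scheme == "ICD10"]
  need <- scheme != "ICD10"
  if (any(need)) {
    idx <- match(paste(raw_code[need], scheme[need]),
                 paste(crosswalk$raw_code, crosswalk$scheme))
    out[need] <- crosswalk$icd10_code[idx]
  }
  out
}
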