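#' Drug synonym dictionaries
#'
#' A drug dictionary maps verbatim drug strings, as typed into
#' spontaneous-report forms (brand names, generics, salt forms, doses,
#' arbitrary capitalisation), to canonical ingredient names. Lookup keys
#' are normalised with [normalize_drug_key()], so `"OZEMPIC 0.5 mg"` and
#' `"ozempic"` hit the same entry. Verbatim names with no entry fall into
#' a single other-drug bucket (see [other_bucket()]); those reports are
#' retained because they form the comparator ("all other drugs")
#' denominator of the screen.
#'
#' @param entries A data frame with columns `synonym` and `ingredient`.
#' @return An object of class `drug_dictionary`.
#' @seealso [normalize_drug()], [default_drug_dictionary()]
#' @export
drug_dictionary <- function(entries) {
  entries <- tibble::as_tibble(entries)
  if (!all(c("synonym", "ingredient") %in% names(entries))) {
    abort_config("drug dictionary needs columns 'synonym' and 'ingredient'")
  }
  entries$key <- normalize_drug_key(entries$synonym)
  entries <- entries[entries$key != "", , drop = FALSE]
  clash <- tapply(entries$ingredient, entries$key,
                  function(x) length(unique(x)))
  if (any(clash > 1)) {
    abort_config("drug dictionary key(s) map to more than one ingredient: ",
                 paste(names(clash)[clash > 1], collapse = ", "))
  }
  entries <- entries[!duplicated(entries$key), c("key", "ingredient")]
  structure(list(entries = entries), class = "drug_dictionary")
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat("<drug_dictionary> ", nrow(x$entries), " keys -> ",
      length(unique(x$entries$ingredient)), " ingredients\n", sep = "")
  invisible(x)
}

#' Read a drug dictionary from CSV
#'
#' @param path CSV file with columns `synonym`, `ingredient`.
#' @return A [drug_dictionary()].
#' @export
read_drug_dictionary <- function(path) {
  if (!file.exists(path)) abort_config("drug dictionary file not found: ", path)
  drug_dictionary(readr::read_csv(path, col_types = readr::cols(
    synonym = readr::col_character(), ingredient = readr::col_character())))
}

#' Packaged default drug dictionary
#'
#' Covers the drugs of the thyroid-cancer screen — GLP-1 receptor
#' agonists (semaglutide, dulaglutide, liraglutide), the dual GIP/GLP-1
#' agonist tirzepatide, SGLT-2 inhibitors, DPP-4 inhibitors,
#' weight-neutral comparators (metformin, insulin glargine,
#' rosuvastatin, glyburide) and other weight-loss drugs (orlistat,
#' bupropion, topiramate, phentermine, naltrexone) — each with brand and
#' generic keys. Editable: copy the CSV, extend it, and load with
#' [read_drug_dictionary()].
#'
#' @return A [drug_dictionary()].
#' @export
default_drug_dictionary <- function() {
  read_drug_dictionary(system.file("extdata", "drug_dictionary.csv",
                                   package = "rorscreen", mustWork = TRUE))
}

# dose/salt noise words stripped from verbatim drug strings
.drug_noise_tokens <- c(
  "HCL", "HYDROCHLORIDE", "SODIUM", "CALCIUM", "MALEATE", "TARTRATE",
  "BESYLATE", "MESYLATE", "SUCCINATE", "FUMARATE", "PHOSPHATE", "ACETATE",
  "MG", "MCG", "G", "ML", "TABLET", "TABLETS", "TAB", "TABS", "CAPSULE",
  "CAPSULES", "CAP", "CAPS", "INJECTION", "INJ", "PEN", "SOLUTION", "ORAL",
  "XR", "ER", "SR", "UNKNOWN")

#' Normalise a verbatim drug string to a lookup key
#'
#' Upper-cases, replaces punctuation with spaces, and drops numeric and
#' dose/salt tokens ("HCL", "500", "MG", "TABLET", ...). Deterministic and
#' idempotent; this is the key space in which dictionary lookup happens.
#'
#' @param x Character vector of verbatim drug names.
#' @return Character vector of normalised keys.
#' @export
#' @examples
#' normalize_drug_key("Metformin HCl 500mg")
normalize_drug_key <- function(x) {
  x <- toupper(enc2utf8(as.character(x)))
  x <- gsub("[^A-Z0-9]+", " ", x)
  # strip pure numbers and number+unit fragments like 500MG / 0 5
  x <- gsub("\\b[0-9]+(\\.[0-9]+)?(MG|MCG|G|ML)?\\b", " ", x)
  toks <- strsplit(trimws(gsub(" +", " ", x)), " ", fixed = TRUE)
  vapply(toks, function(t) paste(t[!(t %in% .drug_noise_tokens)],
                                 collapse = " "), character(1))
}

#' Token for the other-drug comparator bucket
#'
#' Canonical name under which all unmapped verbatim drug names are kept.
#' They stay in the database so that every report contributes to the
#' comparator cells of the 2x2 tables.
#'
#' @return A single string.
#' @export
other_bucket <- function() "(other)"

#' Map verbatim drug names to canonical ingredients
#'
#' @param verbatim Character vector of drug names as reported.
#' @param dict A [drug_dictionary()].
#' @return Character vector of canonical ingredients; unmapped names
#'   become [other_bucket()].
#' @export
#' @examples
#' normalize_drug(c("OZEMPIC", "Metformin HCl 500mg", "XYZZY-DRUG"),
#'                default_drug_dictionary())
normalize_drug <- function(verbatim, dict) {
  stopifnot(inherits(dict, "drug_dictionary"))
  key <- normalize_drug_key(verbatim)
  out <- dict$entries$ingredient[match(key, dict$entries$key)]
  out[is.na(out)] <- other_bucket()
  out
}

#' Composite-event term sets
#'
#' An event term set defines the composite adverse event of a screen as a
#' set of MedDRA preferred terms (PTs), each labelled with a histological
#' subtype used by [subtype_breakdown()]. Membership testing is
#' case-insensitive on the exact PT string.
#'
#' @param terms Data frame with columns `term` and `subtype`. Subtypes
#'   must come from `c("papillary", "medullary", "follicular",
#'   "anaplastic", "metastatic", "recurrent", "generic")`.
#' @return An object of class `event_term_set`.
#' @export
event_term_set <- function(terms) {
  terms <- tibble::as_tibble(terms)
  if (!all(c("term", "subtype") %in% names(terms))) {
    abort_config("event term set needs columns 'term' and 'subtype'")
  }
  ok <- c("papillary", "medullary", "follicular", "anaplastic",
          "metastatic", "recurrent", "generic")
  if (!all(terms$subtype %in% ok)) {
    abort_config("unknown subtype label(s): ",
                 paste(setdiff(terms$subtype, ok), collapse = ", "))
  }
  terms$term_lc <- tolower(trimws(terms$term))
  if (anyDuplicated(terms$term_lc)) {
    abort_config("duplicate event term(s) in term set")
  }
  structure(list(terms = terms[, c("term", "term_lc", "subtype")]),
            class = "event_term_set")
}

#' @export
print.event_term_set <- function(x, ...) {
  cat("<event_term_set> ", nrow(x$terms), " preferred terms\n", sep = "")
  invisible(x)
}

#' Read an event term set from CSV
#' @param path CSV file with columns `term`, `subtype`.
#' @return An [event_term_set()].
#' @export
read_event_terms <- function(path) {
  if (!file.exists(path)) abort_config("event term file not found: ", path)
  event_term_set(readr::read_csv(path, col_types = readr::cols(
    term = readr::col_character(), subtype = readr::col_character())))
}

#' Packaged thyroid-cancer composite event
#'
#' The seven thyroid-cancer preferred terms of the screen (thyroid
#' cancer, thyroid neoplasm, recurrent/papillary/follicular/medullary/
#' anaplastic thyroid cancer) plus "Thyroid cancer metastatic", which
#' backs the metastatic category of the subtype breakdown.
#'
#' @return An [event_term_set()].
#' @export
default_event_terms <- function() {
  read_event_terms(system.file("extdata", "event_terms.csv",
                               package = "rorscreen", mustWork = TRUE))
}

#' Classify preferred terms against a composite event
#'
#' Pure, vectorised and case-insensitive: the same PT always yields the
#' same answer.
#'
#' @param pt Character vector of preferred terms.
#' @param terms An [event_term_set()].
#' @return A tibble with columns `pt`, `is_composite`, `subtype`
#'   (`NA` for non-composite terms).
#' @export
#' @examples
#' classify_event(c("Papillary thyroid cancer", "Nausea"),
#'                default_event_terms())
classify_event <- function(pt, terms) {
  stopifnot(inherits(terms, "event_term_set"))
  i <- match(tolower(trimws(pt)), terms$terms$term_lc)
  tibble::tibble(pt = pt,
                 is_composite = !is.na(i),
                 subtype = terms$terms$subtype[i])
}

# Collapse composite-event terms into a reporting scheme.
# "histology": four categories; generic, follicular, anaplastic and
#   recurrent mentions fold into "other" (unspecified pathology etc.).
# "classification": the report-classification view, where the two generic
#   PTs ("thyroid cancer", "thyroid neoplasm") keep their own classes and
#   anaplastic/metastatic/recurrent fold into "other".
event_class <- function(term_lc, subtype,
                        scheme = c("histology", "classification")) {
  scheme <- match.arg(scheme)
  if (scheme == "histology") {
    ifelse(subtype %in% c("medullary", "papillary", "metastatic"),
           subtype, "other")
  } else {
    ifelse(subtype %in% c("papillary", "medullary", "follicular"), subtype,
           ifelse(subtype == "generic", term_lc, "other"))
  }
}

subtype_levels <- function(scheme = c("histology", "classification")) {
  scheme <- match.arg(scheme)
  if (scheme == "histology") {
    c("medullary", "papillary", "metastatic", "other")
  } else {
    c("thyroid cancer", "thyroid neoplasm", "papillary", "medullary",
      "follicular", "other")
  }
}
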