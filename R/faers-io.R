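#' FAERS quarterly ASCII dialect
#'
#' Describes the flat-file layout of a FAERS-style quarter: delimiter
#' (`"$"` in the public files), text encoding (the legacy archives are
#' not clean UTF-8, so input is read as Latin-1), and the column names
#' expected in the DEMO, DRUG and REAC files. The first line of each
#' file is a header.
#'
#' @param delim Field delimiter.
#' @param encoding Input encoding.
#' @param id_col Name of the case-version identifier column shared by the
#'   three files (`"primaryid"` in modern quarters; legacy quarters used
#'   `"isr"`).
#' @return An object of class `faers_dialect`.
#' @export
faers_dialect <- function(delim = "$", encoding = "latin1",
                          id_col = "primaryid") {
  structure(list(delim = delim, encoding = encoding, id_col = id_col,
                 demo_cols = c(id_col, "caseid", "caseversion", "age",
                               "age_cod", "sex", "event_dt", "fda_dt",
                               "reporter_country"),
                 drug_cols = c(id_col, "drug_seq", "drugname", "role_cod"),
                 reac_cols = c(id_col, "pt")),
            class = "faers_dialect")
}

# Line-wise "$"-split parser. FAERS ASCII has no quoting or escaping, so a
# record is valid iff it splits into exactly the header's field count;
# anything else is counted and skipped, never silently dropped.
parse_dollar_file <- function(path, dialect, required_cols, what) {
  if (!file.exists(path)) abort_config(what, " file not found: ", path)
  lines <- readLines(path, encoding = dialect$encoding, warn = FALSE)
  lines <- iconv(lines, from = dialect$encoding, to = "UTF-8", sub = "?")
  if (length(lines) == 0) abort_config(what, " file is empty: ", path)
  header <- tolower(strsplit(lines[1], dialect$delim, fixed = TRUE)[[1]])
  if (!all(required_cols %in% header)) {
    abort_config(what, " header lacks required column(s): ",
                 paste(setdiff(required_cols, header), collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, dialect$delim, fixed = TRUE)
  # strsplit drops a trailing empty field; restore it where the line
  # really ends with the delimiter (a truncated line stays short)
  nf <- lengths(fields)
  pad <- nf == length(header) - 1 & endsWith(body, dialect$delim)
  fields[pad] <- lapply(fields[pad], function(f) c(f, ""))
  nf <- lengths(fields)
  bad <- nf != length(header)
  if (any(bad)) {
    warning(sum(bad), " malformed line(s) skipped in ", basename(path),
            call. = FALSE)
  }
  mat <- do.call(rbind, fields[!bad])
  df <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                          .name_repair = "minimal")
  if (nrow(df) == 0) df <- tibble::as_tibble(
    stats::setNames(rep(list(character()), length(header)), header))
  names(df) <- header
  attr(df, "n_skipped") <- sum(bad)
  df
}

#' Read one FAERS-style quarter
#'
#' Parses the DEMO, DRUG and REAC files of a quarter into a `raw_quarter`
#' object. Malformed data lines are counted, reported as a warning and
#' skipped; missing files and unusable headers are fatal.
#'
#' @param demo_path,drug_path,reac_path Paths to the three files.
#' @param dialect A [faers_dialect()].
#' @return A `raw_quarter`: list with tibbles `demo`, `drug`, `reac` and
#'   an integer vector `skipped` of per-file skip counts.
#' @export
read_faers_quarter <- function(demo_path, drug_path, reac_path,
                               dialect = faers_dialect()) {
  stopifnot(inherits(dialect, "faers_dialect"))
  id <- dialect$id_col
  demo <- parse_dollar_file(demo_path, dialect,
                            c(id, "caseid", "sex"), "DEMO")
  drug <- parse_dollar_file(drug_path, dialect,
                            c(id, "drugname"), "DRUG")
  reac <- parse_dollar_file(reac_path, dialect, c(id, "pt"), "REAC")
  structure(list(demo = demo, drug = drug, reac = reac,
                 skipped = c(demo = attr(demo, "n_skipped"),
                             drug = attr(drug, "n_skipped"),
                             reac = attr(reac, "n_skipped")),
                 dialect = dialect),
            class = "raw_quarter")
}

#' @export
print.raw_quarter <- function(x, ...) {
  cat("<raw_quarter> demo:", nrow(x$demo), " drug:", nrow(x$drug),
      " reac:", nrow(x$reac), " (skipped:", sum(x$skipped), ")\n")
  invisible(x)
}

#' Assemble raw quarters into safety reports
#'
#' Turns one or more parsed quarters into a pre-deduplication
#' [report_set()]: one report per case version, verbatim drug names
#' normalised through the dictionary (unmapped names are kept under
#' [other_bucket()] so comparator denominators stay complete), ages
#' banded with [age_to_band()], and all drug role codes retained — no
#' entry is ever dropped by role. Case versions that lack any drug or
#' any reaction row are dropped with a warning.
#'
#' @param quarters A `raw_quarter` or list of them.
#' @param drug_dict A [drug_dictionary()].
#' @param term_set Optional [event_term_set()]; only used to precompute
#'   the `is_composite` flag on event rows.
#' @param year_source Which date field defines a report's year:
#'   `"event"` (the adverse event's date, falling back to the receipt
#'   date when absent) or `"receipt"` (FDA receipt date only).
#' @return A [report_set()] (not yet deduplicated).
#' @export
assemble_reports <- function(quarters, drug_dict, term_set = NULL,
                             year_source = c("event", "receipt")) {
  year_source <- match.arg(year_source)
  if (inherits(quarters, "raw_quarter")) quarters <- list(quarters)
  if (length(quarters) == 0) {
    warning("no quarters supplied; returning empty report list",
            call. = FALSE)
    return(empty_report_set())
  }
  stopifnot(all(vapply(quarters, inherits, logical(1), "raw_quarter")))
  id <- quarters[[1]]$dialect$id_col
  demo <- dplyr::bind_rows(lapply(quarters, `[[`, "demo"))
  drug <- dplyr::bind_rows(lapply(quarters, `[[`, "drug"))
  reac <- dplyr::bind_rows(lapply(quarters, `[[`, "reac"))
  if (nrow(demo) == 0) {
    warning("no demographic records; returning empty report list",
            call. = FALSE)
    return(empty_report_set())
  }

  year_of <- function(x) {
    y <- suppressWarnings(as.integer(substr(trimws(x), 1, 4)))
    ifelse(!is.na(y) & y >= 1900 & y <= 2100, y, NA_integer_)
  }
  col <- function(df, nm) if (nm %in% names(df)) df[[nm]] else
    rep(NA_character_, nrow(df))
  ev_year <- year_of(col(demo, "event_dt"))
  rc_year <- year_of(col(demo, "fda_dt"))
  year <- if (year_source == "event") {
    ifelse(is.na(ev_year), rc_year, ev_year)
  } else rc_year

  sex_raw <- toupper(trimws(col(demo, "sex")))
  sex <- ifelse(sex_raw == "F", "female",
                ifelse(sex_raw == "M", "male", "unspecified"))
  country <- trimws(col(demo, "reporter_country"))
  country[is.na(country) | country == ""] <- "unspecified"
  version <- suppressWarnings(as.integer(col(demo, "caseversion")))
  version[is.na(version)] <- 1L

  reports <- tibble::tibble(
    report_id = trimws(demo[[id]]),
    case_id = trimws(col(demo, "caseid")),
    version = version,
    sex = sex,
    age_band = age_to_band(col(demo, "age"), col(demo, "age_cod")),
    year = year,
    country = country)
  reports$case_id[reports$case_id == "" | is.na(reports$case_id)] <-
    reports$report_id[reports$case_id == "" | is.na(reports$case_id)]

  role_raw <- toupper(trimws(col(drug, "role_cod")))
  drugs <- tibble::tibble(
    report_id = trimws(drug[[id]]),
    drug = normalize_drug(drug$drugname, drug_dict),
    role = ifelse(role_raw %in% c("PS", "SS", "C", "I"), role_raw,
                  NA_character_))
  events <- tibble::tibble(report_id = trimws(reac[[id]]),
                           pt = trimws(reac$pt))
  drugs <- drugs[drugs$report_id %in% reports$report_id, , drop = FALSE]
  events <- events[events$report_id %in% reports$report_id, , drop = FALSE]
  if (!is.null(term_set)) {
    events$is_composite <- classify_event(events$pt, term_set)$is_composite
  }

  complete <- reports$report_id %in% drugs$report_id &
    reports$report_id %in% events$report_id
  if (any(!complete)) {
    warning(sum(!complete),
            " case version(s) without drug or reaction rows dropped",
            call. = FALSE)
  }
  reports <- reports[complete, , drop = FALSE]
  drugs <- drugs[drugs$report_id %in% reports$report_id, , drop = FALSE]
  events <- events[events$report_id %in% reports$report_id, , drop = FALSE]
  report_set(reports, drugs, events)
}

empty_report_set <- function() {
  report_set(
    tibble::tibble(report_id = character(), case_id = character(),
                   version = integer(), sex = character(),
                   age_band = character(), year = integer(),
                   country = character()),
    tibble::tibble(report_id = character(), drug = character(),
                   role = character()),
    tibble::tibble(report_id = character(), pt = character()))
}

# ---- internal flat format -------------------------------------------------

report_cols <- readr::cols(
  report_id = readr::col_character(), case_id = readr::col_character(),
  version = readr::col_integer(), sex = readr::col_character(),
  age_band = readr::col_character(), year = readr::col_integer(),
  country = readr::col_character())
drug_cols <- readr::cols(report_id = readr::col_character(),
                         drug = readr::col_character(),
                         role = readr::col_character())
event_cols <- readr::cols(report_id = readr::col_character(),
                          pt = readr::col_character())

#' Write / read the internal flat format
#'
#' The internal format is three CSVs (`reports.csv`, `report_drugs.csv`,
#' `report_events.csv`) plus a `manifest.json` with row counts and the
#' format version. Column order and types are fixed, and
#' `read_report_set(write_report_set(x))` reproduces `x` exactly.
#'
#' @param x A [report_set()].
#' @param dir Directory to write into / read from (created if needed).
#' @return `write_report_set()` returns `dir` invisibly;
#'   `read_report_set()` returns a [report_set()].
#' @export
write_report_set <- function(x, dir) {
  stopifnot(inherits(x, "report_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x$reports, file.path(dir, "reports.csv"), na = "")
  readr::write_csv(x$drugs[, c("report_id", "drug", "role")],
                   file.path(dir, "report_drugs.csv"), na = "")
  readr::write_csv(x$events[, c("report_id", "pt")],
                   file.path(dir, "report_events.csv"), na = "")
  jsonlite::write_json(
    list(format = "rorscreen-flat", format_version = 1L,
         n_reports = nrow(x$reports), n_drug_rows = nrow(x$drugs),
         n_event_rows = nrow(x$events)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_report_set
#' @export
read_report_set <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    abort_config("not an internal report directory (no manifest.json): ", dir)
  }
  man <- jsonlite::read_json(man_path)
  if (!identical(man$format, "rorscreen-flat")) {
    abort_config("unrecognised internal format: ", man$format)
  }
  rd <- function(f, ct) readr::read_csv(file.path(dir, f), col_types = ct,
                                        na = "", progress = FALSE)
  reports <- rd("reports.csv", report_cols)
  drugs <- rd("report_drugs.csv", drug_cols)
  events <- rd("report_events.csv", event_cols)
  report_set(reports, drugs, events)
}
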