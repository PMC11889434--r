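#' Deduplicatable sets of safety reports
#'
#' A `report_set` is the internal relational model of a spontaneous-report
#' database: three linked tibbles keyed by `report_id` (one row of
#' `reports` per case *version* before deduplication).
#'
#' * `reports`: `report_id`, `case_id`, `version` (integer, higher =
#'   later), `sex` (`"female"`, `"male"`, `"unspecified"`), `age_band`
#'   (see [age_bands()]), `year` (integer or `NA`), `country`.
#' * `drugs`: `report_id`, `drug` (canonical ingredient or
#'   [other_bucket()]), `role` (`"PS"`, `"SS"`, `"C"`, `"I"` or `NA`).
#'   Role codes are carried but never used to drop a drug entry.
#' * `events`: `report_id`, `pt` (verbatim MedDRA preferred term).
#'
#' Every `report_id` in `drugs`/`events` must exist in `reports`; every
#' report must name at least one drug and one event.
#'
#' @param reports,drugs,events Tibbles as described above.
#' @return An object of class `report_set`.
#' @export
report_set <- function(reports, drugs, events) {
  reports <- tibble::as_tibble(reports)
  drugs <- tibble::as_tibble(drugs)
  events <- tibble::as_tibble(events)
  need <- function(df, cols, what) {
    if (!all(cols %in% names(df))) {
      abort_config(what, " must have columns: ", paste(cols, collapse = ", "))
    }
  }
  need(reports, c("report_id", "case_id", "version", "sex", "age_band",
                  "year", "country"), "reports")
  need(drugs, c("report_id", "drug", "role"), "drugs")
  need(events, c("report_id", "pt"), "events")
  if (anyDuplicated(reports$report_id)) {
    abort_config("duplicated report_id in reports table")
  }
  if (!all(reports$sex %in% c("female", "male", "unspecified"))) {
    abort_config("sex must be female/male/unspecified")
  }
  if (!all(reports$age_band %in% age_bands())) {
    abort_config("age_band outside ", paste(age_bands(), collapse = "/"))
  }
  bad_role <- !(drugs$role %in% c("PS", "SS", "C", "I") | is.na(drugs$role))
  if (any(bad_role)) abort_config("role codes must be PS/SS/C/I or NA")
  if (!all(drugs$report_id %in% reports$report_id)) {
    abort_config("drug rows reference unknown report_id")
  }
  if (!all(events$report_id %in% reports$report_id)) {
    abort_config("event rows reference unknown report_id")
  }
  has_drug <- reports$report_id %in% drugs$report_id
  has_event <- reports$report_id %in% events$report_id
  if (!all(has_drug & has_event)) {
    abort_config(sum(!(has_drug & has_event)),
                 " report(s) lack a drug or an event entry")
  }
  reports$version <- as.integer(reports$version)
  reports$year <- as.integer(reports$year)
  structure(list(reports = reports, drugs = drugs, events = events),
            class = "report_set")
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", nrow(x$reports), " reports (",
      length(unique(x$reports$case_id)), " distinct cases), ",
      nrow(x$drugs), " drug rows, ", nrow(x$events), " event rows\n",
      sep = "")
  invisible(x)
}

#' @rdname report_set
#' @param x A `report_set`.
#' @export
n_reports <- function(x) nrow(x$reports)

#' @rdname report_set
#' @export
report_info <- function(x) x$reports

#' @rdname report_set
#' @export
report_drugs <- function(x) x$drugs

#' @rdname report_set
#' @export
report_events <- function(x) x$events

# keep only the given report ids, preserving their order in `reports`
filter_reports <- function(x, keep_ids) {
  report_set(x$reports[x$reports$report_id %in% keep_ids, , drop = FALSE],
             x$drugs[x$drugs$report_id %in% keep_ids, , drop = FALSE],
             x$events[x$events$report_id %in% keep_ids, , drop = FALSE])
}

#' Age bands of the demographic summaries
#'
#' The five bands used throughout: 0-11, 12-17, 18-64 and 65-85 years,
#' plus `"unspecified"` for missing ages and ages above 85 (no band is
#' defined beyond 85).
#'
#' @return Character vector of band labels.
#' @export
age_bands <- function() c("0-11", "12-17", "18-64", "65-85", "unspecified")

#' Band an age given its reporting unit
#'
#' FAERS ages come with a unit code: `YR` (years), `DEC` (decades),
#' `MON` (months), `WK` (weeks), `DY` (days), `HR` (hours). The age is
#' converted to years and banded deterministically; missing,
#' unparseable or out-of-band ages (negative or > 85) become
#' `"unspecified"`.
#'
#' @param age Numeric or character vector of age values.
#' @param unit Character vector of unit codes (recycled if length 1).
#' @return Character vector of band labels.
#' @export
#' @examples
#' age_to_band(c(70, 840, 5), c("YR", "MON", "DEC"))
age_to_band <- function(age, unit = "YR") {
  age <- suppressWarnings(as.numeric(age))
  unit <- toupper(ifelse(is.na(unit) | unit == "", "YR", unit))
  if (length(unit) == 1) unit <- rep(unit, length(age))
  fac <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1775,
           DY = 1 / 365.25, HR = 1 / 8766)
  yrs <- age * unname(fac[match(unit, names(fac))])
  band <- rep("unspecified", length(age))
  ok <- !is.na(yrs)
  band[ok & yrs >= 0 & yrs < 12] <- "0-11"
  band[ok & yrs >= 12 & yrs < 18] <- "12-17"
  band[ok & yrs >= 18 & yrs < 65] <- "18-64"
  band[ok & yrs >= 65 & yrs < 86] <- "65-85"
  band
}
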