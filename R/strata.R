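#' Demographic summary of composite-event reports
#'
#' Percentages of the event reports by sex, age band, report
#' classification and reporting country — the "characteristics" table
#' of a screen. Optionally restricted to reports naming at least one
#' drug of a class (e.g. the GLP-1 receptor agonists), which yields the
#' class-user column of such tables.
#'
#' Sex, age and country percentages are over all event reports and each
#' axis sums to 100. Classification counts one mention per distinct
#' class per report; reports naming several composite terms of
#' different classes are counted in each, so that axis can exceed 100
#' in the presence of multi-term reports.
#'
#' @param x A deduplicated [report_set()].
#' @param term_set An [event_term_set()].
#' @param drug_class Optional character vector of canonical ingredients;
#'   restrict to event reports naming at least one of them.
#' @param scheme Category scheme for the classification axis:
#'   `"classification"` (generic terms keep their own classes) or
#'   `"histology"` (four-category subtype scheme).
#' @return Tibble `characteristic`, `level`, `n`, `pct`.
#' @export
demographics_summary <- function(x, term_set, drug_class = NULL,
                                 scheme = c("classification", "histology")) {
  stopifnot(inherits(x, "report_set"))
  scheme <- match.arg(scheme)
  ids <- composite_report_ids(x, term_set)
  if (!is.null(drug_class)) {
    in_class <- unique(x$drugs$report_id[x$drugs$drug %in% drug_class])
    ids <- ids[ids %in% in_class]
  }
  if (length(ids) == 0) abort_config("no composite-event reports to summarise")
  ev <- filter_reports(x, ids)
  n_total <- nrow(ev$reports)

  axis <- function(values, levels, characteristic) {
    cnt <- as.integer(table(factor(values, levels = levels)))
    tibble::tibble(characteristic = characteristic, level = levels,
                   n = cnt, pct = 100 * cnt / n_total)
  }
  sexes <- axis(ev$reports$sex, c("female", "male", "unspecified"), "sex")
  ages <- axis(ev$reports$age_band, age_bands(), "age_band")
  countries <- {
    cn <- ev$reports$country
    top <- names(sort(table(cn[cn != "unspecified"]), decreasing = TRUE))
    axis(cn, unique(c(top, "unspecified")), "country")
  }
  cls <- classify_event(ev$events$pt, term_set)
  comp <- ev$events[cls$is_composite, , drop = FALSE]
  comp_cls <- event_class(tolower(trimws(comp$pt)),
                          cls$subtype[cls$is_composite], scheme)
  mentions <- unique(data.frame(report_id = comp$report_id,
                                class = comp_cls))
  classification <- {
    cnt <- as.integer(table(factor(mentions$class,
                                   levels = subtype_levels(scheme))))
    tibble::tibble(characteristic = "classification",
                   level = subtype_levels(scheme), n = cnt,
                   pct = 100 * cnt / n_total)
  }
  dplyr::bind_rows(sexes, ages, classification, countries)
}

#' Stratum specification and stratified screening
#'
#' Runs [ror_screen()] on the subset of reports with the given level on
#' one demographic axis; database totals are recomputed within the
#' stratum. An empty stratum returns a zero-row screen flagged with
#' `attr(, "empty_stratum")` rather than an error.
#'
#' @param x A deduplicated [report_set()].
#' @param axis One of `"sex"`, `"age_band"`, `"year"`.
#' @param level Level on that axis (e.g. `"female"`, `"18-64"`, `2021`).
#' @inheritParams ror_screen
#' @return A `signal_screen` tibble (see [ror_screen()]).
#' @export
stratified_screen <- function(x, axis = c("sex", "age_band", "year"),
                              level, drug_list, term_set, k = 5,
                              alpha = 0.05,
                              comparator = c("exclude-drug", "all-reports"),
                              correction = FALSE) {
  stopifnot(inherits(x, "report_set"))
  axis <- match.arg(axis)
  comparator <- match.arg(comparator)
  vals <- x$reports[[axis]]
  if (axis == "year") {
    sel <- if (identical(level, "unspecified")) is.na(vals)
    else !is.na(vals) & vals == as.integer(level)
  } else {
    sel <- vals == level
  }
  ids <- x$reports$report_id[sel]
  if (length(ids) == 0) {
    empty <- new_signal_screen(
      tibble::tibble(drug = character(), a = integer(), b = integer(),
                     c = integer(), d = integer(), ror = numeric(),
                     ci_low = numeric(), ci_high = numeric(),
                     p_value = numeric(), excluded = logical(),
                     reason = character()),
      total_event = 0L, total_other = 0L, k = k, alpha = alpha,
      comparator = comparator)
    attr(empty, "empty_stratum") <- TRUE
    return(empty)
  }
  ror_screen(filter_reports(x, ids), drug_list, term_set, k = k,
             alpha = alpha, comparator = comparator,
             correction = correction)
}

#' Yearly trend of composite-event reports for a drug class
#'
#' Counts composite-event reports naming at least one drug of the class
#' per calendar year. Years inside the observed range with no reports
#' appear with count 0; reports without a year are tallied under
#' `"unspecified"`.
#'
#' @param x A deduplicated [report_set()].
#' @param drug_class Character vector of canonical ingredients.
#' @param term_set An [event_term_set()].
#' @return Tibble `year` (character; calendar years then possibly
#'   `"unspecified"`), `n`.
#' @export
yearly_trend <- function(x, drug_class, term_set) {
  stopifnot(inherits(x, "report_set"))
  ids <- composite_report_ids(x, term_set)
  in_class <- unique(x$drugs$report_id[x$drugs$drug %in% drug_class])
  ids <- ids[ids %in% in_class]
  yrs <- x$reports$year[match(ids, x$reports$report_id)]
  if (length(ids) == 0) {
    return(tibble::tibble(year = character(), n = integer()))
  }
  known <- yrs[!is.na(yrs)]
  out <- if (length(known) > 0) {
    rng <- seq(min(known), max(known))
    counts <- table(factor(known, levels = rng))
    tibble::tibble(year = as.character(rng), n = as.integer(counts))
  } else {
    tibble::tibble(year = character(), n = integer())
  }
  if (any(is.na(yrs))) {
    out <- dplyr::bind_rows(out, tibble::tibble(year = "unspecified",
                                                n = sum(is.na(yrs))))
  }
  out
}

#' Histological subtype breakdown for one drug
#'
#' Proportions of the drug's composite-event reports over the
#' histological categories (default scheme: medullary, papillary,
#' metastatic, other — where "other" aggregates the generic terms,
#' follicular, anaplastic, recurrent and any unspecified pathology). A
#' report naming composite terms of several subtypes contributes one
#' mention to each distinct subtype, and the denominator is the total
#' number of mentions, so proportions always sum to 1.
#'
#' @param x A deduplicated [report_set()].
#' @param drug Canonical ingredient.
#' @param term_set An [event_term_set()].
#' @param scheme `"histology"` (default) or `"classification"`.
#' @return Tibble `subtype`, `n`, `proportion`, with the drug name as
#'   attribute `drug`.
#' @export
subtype_breakdown <- function(x, drug, term_set,
                              scheme = c("histology", "classification")) {
  stopifnot(inherits(x, "report_set"))
  scheme <- match.arg(scheme)
  ids <- composite_report_ids(x, term_set)
  drug_ids <- unique(x$drugs$report_id[x$drugs$drug == drug])
  ids <- ids[ids %in% drug_ids]
  if (length(ids) == 0) {
    abort_config("no composite-event reports for drug: ", drug)
  }
  ev <- x$events[x$events$report_id %in% ids, , drop = FALSE]
  cls <- classify_event(ev$pt, term_set)
  comp <- ev[cls$is_composite, , drop = FALSE]
  lab <- event_class(tolower(trimws(comp$pt)), cls$subtype[cls$is_composite],
                     scheme)
  mentions <- unique(data.frame(report_id = comp$report_id, class = lab))
  counts <- table(factor(mentions$class, levels = subtype_levels(scheme)))
  out <- tibble::tibble(subtype = names(counts), n = as.integer(counts),
                        proportion = as.integer(counts) / nrow(mentions))
  attr(out, "drug") <- drug
  out
}
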