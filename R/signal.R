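#' 2x2 contingency tables for drug-event disproportionality
#'
#' The unit of counting is the deduplicated report. For a drug of
#' interest and a composite event:
#' \describe{
#'   \item{a}{reports naming the drug (any role) with >= 1 composite-event
#'     preferred term}
#'   \item{b}{reports naming the drug, with other events only}
#'   \item{c}{reports not naming the drug, with the composite event}
#'   \item{d}{reports not naming the drug, other events only}
#' }
#' Every report falls in exactly one cell.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    abort_config("contingency cells must be non-negative integers")
  }
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "no drug"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

#' Build the 2x2 table for one drug
#'
#' Counts deduplicated reports. A report is in the drug rows if the
#' canonical ingredient appears among its drugs in any role; it is in
#' the event column if at least one of its preferred terms belongs to
#' the composite event. With the default `"exclude-drug"` comparator the
#' drug's own reports are removed from the comparator row
#' (`c = total event reports - a`, `d = total other reports - b`), the
#' standard reporting-odds-ratio convention; `"all-reports"` leaves them
#' in.
#'
#' @param x A deduplicated [report_set()].
#' @param drug Canonical ingredient name.
#' @param term_set An [event_term_set()].
#' @param comparator Comparator convention, see Details.
#' @return A [contingency_table()].
#' @export
build_contingency <- function(x, drug, term_set,
                              comparator = c("exclude-drug", "all-reports")) {
  stopifnot(inherits(x, "report_set"))
  comparator <- match.arg(comparator)
  ev_ids <- composite_report_ids(x, term_set)
  n <- nrow(x$reports)
  n_event <- length(ev_ids)
  drug_ids <- unique(x$drugs$report_id[x$drugs$drug == drug])
  a <- sum(drug_ids %in% ev_ids)
  b <- length(drug_ids) - a
  if (comparator == "exclude-drug") {
    contingency_table(a, b, n_event - a, (n - n_event) - b)
  } else {
    contingency_table(a, b, n_event, n - n_event)
  }
}

# report ids with at least one composite-event PT
composite_report_ids <- function(x, term_set) {
  stopifnot(inherits(term_set, "event_term_set"))
  hit <- tolower(trimws(x$events$pt)) %in% term_set$terms$term_lc
  unique(x$events$report_id[hit])
}

check_cells <- function(tab, correction) {
  stopifnot(inherits(tab, "contingency_table"))
  cells <- as.numeric(c(tab$a, tab$b, tab$c, tab$d))
  if (correction) return(cells + 0.5)
  if (any(cells == 0)) {
    abort_config("degenerate 2x2 table (zero cell); ",
                 "use correction = TRUE for a Haldane-Anscombe +0.5 fix")
  }
  cells
}

#' Reporting odds ratio
#'
#' `ROR = (a/b) / (c/d) = (a d)/(b c)`: the odds of the composite event
#' among the drug's reports relative to the odds among all other
#' reports. A relative-reporting measure, not a risk estimate.
#'
#' @param tab A [contingency_table()].
#' @param correction Apply the Haldane-Anscombe +0.5 continuity
#'   correction to every cell (needed when a cell is zero; off by
#'   default).
#' @return The ROR (positive scalar).
#' @export
ror <- function(tab, correction = FALSE) {
  k <- check_cells(tab, correction)
  (k[1] * k[4]) / (k[2] * k[3])
}

#' Woolf confidence interval for the ROR
#'
#' Based on the asymptotic normality of `log(ROR)` with standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`:
#' `exp(log(ROR) -/+ z_(1-alpha/2) * SE)`.
#'
#' @inheritParams ror
#' @param alpha Two-sided error rate (0.05 gives a 95% CI).
#' @return Named numeric vector `c(low, high)`.
#' @export
woolf_ci <- function(tab, alpha = 0.05, correction = FALSE) {
  if (alpha <= 0 || alpha > 1) abort_config("alpha must be in (0, 1]")
  k <- check_cells(tab, correction)
  lr <- log(k[1]) + log(k[4]) - log(k[2]) - log(k[3])
  se <- sqrt(sum(1 / k))
  z <- stats::qnorm(1 - alpha / 2)
  c(low = exp(lr - z * se), high = exp(lr + z * se))
}

#' Two-sided z-test p-value for log(ROR) = 0
#'
#' `p = 2 * Phi(-|log(ROR)| / SE)` with the Woolf standard error; by
#' construction `p < alpha` exactly when 1 lies outside the
#' `(1 - alpha)` Woolf interval.
#'
#' @inheritParams ror
#' @return p-value in (0, 1].
#' @export
ror_p_value <- function(tab, correction = FALSE) {
  k <- check_cells(tab, correction)
  lr <- log(k[1]) + log(k[4]) - log(k[2]) - log(k[3])
  se <- sqrt(sum(1 / k))
  2 * stats::pnorm(-abs(lr) / se)
}

#' Flag drugs below the minimum report count
#'
#' Drugs with fewer than `k` event reports (`a < k`, default `k = 5`)
#' are excluded from the screen: with so few drug-event pairs the ROR is
#' unstable and prone to spurious signals. Excluded rows keep their
#' counts but carry no statistics.
#'
#' @param results A `signal_screen` tibble (from [ror_screen()] or
#'   [signal_from_counts()]).
#' @param k Minimum number of drug-event reports required.
#' @return `results` with `excluded`/`reason` updated and statistics
#'   blanked on excluded rows.
#' @export
apply_min_count_filter <- function(results, k = 5) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort_config("k must be a single number >= 1")
  }
  out <- results
  excl <- out$a < k
  out$excluded <- excl
  out$reason <- ifelse(excl, "below-min-count", NA_character_)
  for (col in c("ror", "ci_low", "ci_high", "p_value")) {
    out[[col]][excl] <- NA_real_
  }
  out
}

new_signal_screen <- function(df, total_event, total_other, k, alpha,
                              comparator) {
  structure(df, class = c("signal_screen", class(tibble::tibble())),
            total_event = total_event, total_other = total_other,
            k = k, alpha = alpha, comparator = comparator)
}

screen_from_cells <- function(drug, a, b, total_event, total_other, k,
                              alpha, comparator, correction) {
  if (comparator == "exclude-drug") {
    cc <- total_event - a
    dd <- total_other - b
  } else {
    cc <- rep(total_event, length(a))
    dd <- rep(total_other, length(a))
  }
  res <- tibble::tibble(
    drug = drug, a = as.integer(a), b = as.integer(b),
    c = as.integer(cc), d = as.integer(dd),
    ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p_value = NA_real_, excluded = FALSE, reason = NA_character_)
  res <- apply_min_count_filter(res, k)
  if (!correction) {
    # a zero comparator/non-event cell (tiny strata) makes the table
    # degenerate; flag the row instead of aborting the whole screen
    degen <- !res$excluded &
      (res$a == 0 | res$b == 0 | res$c == 0 | res$d == 0)
    res$excluded[degen] <- TRUE
    res$reason[degen] <- "degenerate-table"
  }
  for (i in which(!res$excluded)) {
    tab <- contingency_table(res$a[i], res$b[i], res$c[i], res$d[i])
    res$ror[i] <- ror(tab, correction)
    ci <- woolf_ci(tab, alpha, correction)
    res$ci_low[i] <- ci[["low"]]
    res$ci_high[i] <- ci[["high"]]
    res$p_value[i] <- ror_p_value(tab, correction)
  }
  new_signal_screen(res, total_event, total_other, k, alpha, comparator)
}

#' Screen a drug list for disproportionate reporting
#'
#' Runs the full disproportionality screen: for each drug in
#' `drug_list` (in the given order) a 2x2 table against the whole
#' remaining database, the minimum-count exclusion, and for retained
#' drugs the ROR, Woolf `(1 - alpha)` CI and z-test p-value.
#'
#' @param x A deduplicated [report_set()].
#' @param drug_list Character vector of canonical ingredients.
#' @param term_set An [event_term_set()].
#' @param k Minimum drug-event report count (see
#'   [apply_min_count_filter()]).
#' @param alpha Two-sided error rate for the CI.
#' @param comparator See [build_contingency()].
#' @param correction Haldane-Anscombe +0.5 correction for zero cells.
#' @return A `signal_screen` tibble: `drug`, cells `a`-`d`, `ror`,
#'   `ci_low`, `ci_high`, `p_value`, `excluded`, `reason`; totals and
#'   settings as attributes. Rows failing the count threshold are
#'   excluded with reason `"below-min-count"`; rows whose table has a
#'   zero cell (possible in tiny strata with `correction = FALSE`) with
#'   reason `"degenerate-table"`.
#' @export
ror_screen <- function(x, drug_list, term_set, k = 5, alpha = 0.05,
                       comparator = c("exclude-drug", "all-reports"),
                       correction = FALSE) {
  stopifnot(inherits(x, "report_set"))
  comparator <- match.arg(comparator)
  if (nrow(x$reports) == 0) abort_config("empty report set")
  ev_ids <- composite_report_ids(x, term_set)
  n <- nrow(x$reports)
  n_event <- length(ev_ids)
  cells <- vapply(drug_list, function(d) {
    ids <- unique(x$drugs$report_id[x$drugs$drug == d])
    a <- sum(ids %in% ev_ids)
    c(a, length(ids) - a)
  }, numeric(2))
  screen_from_cells(drug_list, cells[1, ], cells[2, ],
                    total_event = n_event, total_other = n - n_event,
                    k = k, alpha = alpha, comparator = comparator,
                    correction = correction)
}

#' Screen from published counts
#'
#' Computes the same results as [ror_screen()] directly from per-drug
#' counts — `a` (reports with the drug and the event) and `b` (reports
#' with the drug, other events) — plus the database totals, skipping
#' ingestion entirely. This is how a published screen's count table is
#' re-analysed without the underlying archive.
#'
#' @param counts Data frame with columns `drug`, `a`, `b`.
#' @param total_event,total_other Database-wide number of composite-event
#'   and other reports (the screen's "all drugs" row).
#' @inheritParams ror_screen
#' @return A `signal_screen` tibble (see [ror_screen()]).
#' @export
signal_from_counts <- function(counts, total_event, total_other, k = 5,
                               alpha = 0.05,
                               comparator = c("exclude-drug", "all-reports"),
                               correction = FALSE) {
  comparator <- match.arg(comparator)
  counts <- tibble::as_tibble(counts)
  if (!all(c("drug", "a", "b") %in% names(counts))) {
    abort_config("counts needs columns drug, a, b")
  }
  screen_from_cells(counts$drug, counts$a, counts$b, total_event,
                    total_other, k, alpha, comparator, correction)
}

#' Round screen statistics for display
#'
#' Returns the screen with `ror`, `ci_low`, `ci_high` rounded half-up to
#' `digits` decimals (the convention of published screens); internal
#' values stay at full precision in the input object.
#'
#' @param screen A `signal_screen`.
#' @param digits Decimal places.
#' @return A tibble.
#' @export
format_screen <- function(screen, digits = 2) {
  out <- tibble::as_tibble(screen)
  for (col in c("ror", "ci_low", "ci_high")) {
    out[[col]] <- round_half_up(out[[col]], digits)
  }
  out
}

#' Forest-plot data from a screen
#'
#' @param screen A `signal_screen`.
#' @return Tibble `drug`, `point`, `low`, `high` for retained drugs, in
#'   screen order; ready for any plotting layer.
#' @export
forest_data <- function(screen) {
  s <- tibble::as_tibble(screen)[!screen$excluded, , drop = FALSE]
  tibble::tibble(drug = s$drug, point = s$ror, low = s$ci_low,
                 high = s$ci_high)
}

#' Reference thyroid-cancer screen counts
#'
#' The per-drug report counts of a published FAERS thyroid-cancer
#' disproportionality screen (2004 through 2024 Q1): for each drug the
#' number of reports with thyroid cancer as an event (`a`) and with
#' other events (`b`), plus the database totals (14,370 event reports;
#' 25,925,016 others). Shipped as plain CSV in
#' `inst/extdata/thyroid_faers_counts.csv`.
#'
#' @return List with `counts` (tibble `drug`, `drug_class`, `a`, `b`),
#'   `total_event`, `total_other`.
#' @export
reference_screen_counts <- function() {
  path <- system.file("extdata", "thyroid_faers_counts.csv",
                      package = "rorscreen", mustWork = TRUE)
  df <- readr::read_csv(path, col_types = readr::cols(
    drug = readr::col_character(), drug_class = readr::col_character(),
    n_event = readr::col_double(), n_other = readr::col_double()))
  tot <- df[df$drug == "all drugs", , drop = FALSE]
  df <- df[df$drug != "all drugs", , drop = FALSE]
  list(counts = tibble::tibble(drug = df$drug, drug_class = df$drug_class,
                               a = df$n_event, b = df$n_other),
       total_event = tot$n_event, total_other = tot$n_other)
}
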