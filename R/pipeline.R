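#' Run the full screening pipeline
#'
#' End-to-end driver: ingest (FAERS ASCII files or the internal flat
#' format), assemble, deduplicate, screen, optionally stratify, and
#' write results, forest-plot data and a run manifest (record counts at
#' every stage plus the settings used, so a run is reproducible from its
#' output directory).
#'
#' @param input Either a directory containing `DEMO.txt`/`DRUG.txt`/
#'   `REAC.txt` in the FAERS dialect, a directory in the internal flat
#'   format (detected via its `manifest.json`), or a [report_set()].
#' @param drug_list Drugs to screen; defaults to every ingredient in the
#'   dictionary.
#' @param out_dir Output directory (created).
#' @param drug_dict,term_set Vocabularies; packaged defaults when `NULL`.
#' @param strata Optional list of `list(axis =, level =)` stratum
#'   requests.
#' @param year_source Passed to [assemble_reports()].
#' @inheritParams ror_screen
#' @return The `signal_screen`, invisibly; side effect: `results.csv`,
#'   `forest.csv`, `manifest.json` (and `strata_<axis>_<level>.csv`)
#'   under `out_dir`.
#' @export
run_screen <- function(input, out_dir, drug_list = NULL, drug_dict = NULL,
                       term_set = NULL, k = 5, alpha = 0.05,
                       comparator = c("exclude-drug", "all-reports"),
                       correction = FALSE, strata = NULL,
                       year_source = c("event", "receipt")) {
  comparator <- match.arg(comparator)
  year_source <- match.arg(year_source)
  drug_dict <- drug_dict %||% default_drug_dictionary()
  term_set <- term_set %||% default_event_terms()
  drug_list <- drug_list %||%
    setdiff(sort(unique(drug_dict$entries$ingredient)), other_bucket())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  counts <- list()
  if (inherits(input, "report_set")) {
    raw <- input
    counts$ingested <- n_reports(raw)
  } else if (file.exists(file.path(input, "manifest.json"))) {
    raw <- read_report_set(input)
    counts$ingested <- n_reports(raw)
  } else {
    q <- read_faers_quarter(file.path(input, "DEMO.txt"),
                            file.path(input, "DRUG.txt"),
                            file.path(input, "REAC.txt"))
    counts$parsed_demo <- nrow(q$demo)
    counts$parse_skipped <- sum(q$skipped)
    raw <- assemble_reports(q, drug_dict, term_set,
                            year_source = year_source)
    counts$ingested <- n_reports(raw)
  }
  dedup <- deduplicate_reports(raw, quiet = TRUE)
  counts$deduplicated <- n_reports(dedup)
  screen <- ror_screen(dedup, drug_list, term_set, k = k, alpha = alpha,
                       comparator = comparator, correction = correction)
  counts$screened <- nrow(screen)
  counts$retained <- sum(!screen$excluded)

  readr::write_csv(tibble::as_tibble(screen),
                   file.path(out_dir, "results.csv"), na = "")
  readr::write_csv(forest_data(screen), file.path(out_dir, "forest.csv"),
                   na = "")
  for (s in strata %||% list()) {
    ss <- stratified_screen(dedup, axis = s$axis, level = s$level,
                            drug_list = drug_list, term_set = term_set,
                            k = k, alpha = alpha, comparator = comparator,
                            correction = correction)
    readr::write_csv(tibble::as_tibble(ss),
                     file.path(out_dir, sprintf("strata_%s_%s.csv",
                                                s$axis, s$level)),
                     na = "")
  }
  jsonlite::write_json(
    list(stage_counts = counts,
         settings = list(k = k, alpha = alpha, comparator = comparator,
                         correction = correction,
                         year_source = year_source,
                         drug_list = drug_list)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(screen)
}

#' Screen published counts from a CSV
#'
#' The from-counts entry point: reads a CSV of per-drug counts
#' (`drug`, `a`, `b`) and runs [signal_from_counts()] against the given
#' totals.
#'
#' @param counts_path CSV path.
#' @param total_event,total_other Database totals.
#' @inheritParams ror_screen
#' @param out_path Optional CSV to write the (full-precision) results to.
#' @return A `signal_screen` tibble.
#' @export
run_from_counts <- function(counts_path, total_event, total_other, k = 5,
                            alpha = 0.05,
                            comparator = c("exclude-drug", "all-reports"),
                            correction = FALSE, out_path = NULL) {
  comparator <- match.arg(comparator)
  if (!file.exists(counts_path)) {
    abort_config("counts file not found: ", counts_path)
  }
  counts <- readr::read_csv(counts_path, col_types = readr::cols(
    drug = readr::col_character(), a = readr::col_double(),
    b = readr::col_double(), .default = readr::col_guess()))
  screen <- signal_from_counts(counts, total_event, total_other, k = k,
                               alpha = alpha, comparator = comparator,
                               correction = correction)
  if (!is.null(out_path)) {
    readr::write_csv(tibble::as_tibble(screen), out_path, na = "")
  }
  screen
}

#' Simulate a synthetic database to disk
#'
#' Generates a database from a [synthetic_config()] and writes it in the
#' internal flat format, in the FAERS ASCII dialect, or both, together
#' with the ground truth (as JSON, kept separate from the report
#' records).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory.
#' @param format `"internal"`, `"faers"` or `"both"`.
#' @return The generated list (`reports`, `ground_truth`), invisibly.
#' @export
run_simulate <- function(config, out_dir,
                         format = c("internal", "faers", "both")) {
  format <- match.arg(format)
  gen <- generate_reports(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (format %in% c("internal", "both")) {
    write_report_set(gen$reports, file.path(out_dir, "internal"))
  }
  if (format %in% c("faers", "both")) {
    write_faers_quarter(gen$reports, file.path(out_dir, "faers"),
                        seed = config$seed)
  }
  gt <- gen$ground_truth
  jsonlite::write_json(
    list(multipliers = gt$multipliers, n_cases = gt$n_cases, p0 = gt$p0,
         seed = config$seed),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
    digits = NA)
  write_synthetic_config(config, file.path(out_dir, "config.yaml"))
  invisible(gen)
}
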