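#' Configuration of the synthetic report generator
#'
#' Fully specifies a synthetic spontaneous-report database with known
#' ground truth. Demographics are drawn independently per report from
#' the mixtures; each catalogue drug enters a report independently with
#' its `marginal` probability; reports with no catalogue drug receive a
#' background co-medication instead (and catalogue-drug reports gain one
#' with probability `comedication_rate`). The composite event is drawn
#' per report with odds `m * p0 / (1 - p0)`, where `m` is the largest
#' `multiplier` among the report's drugs (background drugs have
#' `m = 1`), so for a drug taken alone the population reporting odds
#' ratio equals its multiplier up to co-medication contamination. Event
#' reports receive one preferred term drawn from `subtype_mix`;
#' non-event reports one background term. A fraction `duplication_rate`
#' of cases gains 1-3 superseded earlier versions, which never changes
#' the distinct-case count.
#'
#' Default mixtures follow the demographic marginals of the reference
#' thyroid-cancer screen: 63% female / 23.6% male / 13.4% unspecified;
#' age bands 0.4 / 0.6 / 42.8 / 11.1 / 44.9%; country led by the US at
#' 44.85%; reporting years 2004-2024 with volume concentrated in recent
#' years.
#'
#' @param seed Integer; fully determines the output.
#' @param n_reports Number of distinct cases to generate.
#' @param drugs Data frame `drug`, `marginal`, `multiplier`.
#' @param p0 Baseline composite-event probability for multiplier-1
#'   reports.
#' @param sex_mix,age_mix,country_mix,year_mix Named numeric mixtures
#'   summing to 1.
#' @param subtype_mix Named numeric mixture over composite preferred
#'   terms, summing to 1.
#' @param duplication_rate Fraction of cases that gain superseded
#'   versions.
#' @param comedication_rate Probability that a catalogue-drug report
#'   also names a background drug.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_reports = 10000L,
                             drugs = tibble::tibble(
                               drug = c("drug_a", "drug_b", "drug_c"),
                               marginal = c(0.02, 0.02, 0.02),
                               multiplier = c(1, 1, 1)),
                             p0 = 0.01,
                             sex_mix = c(female = 0.63, male = 0.236,
                                         unspecified = 0.134),
                             age_mix = c("0-11" = 0.004, "12-17" = 0.006,
                                         "18-64" = 0.428, "65-85" = 0.111,
                                         unspecified = 0.451),
                             country_mix = c(US = 0.4485, CA = 0.034,
                                             JP = 0.011, DE = 0.0081,
                                             FR = 0.0076, IT = 0.007,
                                             other = 0.4838),
                             year_mix = NULL,
                             subtype_mix = c(
                               "Thyroid cancer" = 0.77,
                               "Thyroid neoplasm" = 0.11,
                               "Papillary thyroid cancer" = 0.091,
                               "Medullary thyroid cancer" = 0.015,
                               "Follicular thyroid cancer" = 0.008,
                               "Anaplastic thyroid cancer" = 0.003,
                               "Thyroid cancer metastatic" = 0.003),
                             duplication_rate = 0.05,
                             comedication_rate = 0.3) {
  if (is.null(year_mix)) {
    # volume grows roughly linearly over 2004-2024, like report inflow
    w <- seq_len(21)
    year_mix <- stats::setNames(w / sum(w), as.character(2004:2024))
  }
  cfg <- structure(list(seed = as.integer(seed),
                        n_reports = as.integer(n_reports),
                        drugs = tibble::as_tibble(drugs), p0 = p0,
                        sex_mix = sex_mix, age_mix = age_mix,
                        country_mix = country_mix, year_mix = year_mix,
                        subtype_mix = subtype_mix,
                        duplication_rate = duplication_rate,
                        comedication_rate = comedication_rate),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  chk_mix <- function(m, what) {
    if (any(m < 0) || abs(sum(m) - 1) > 1e-8) {
      abort_config(what, " must be non-negative and sum to 1")
    }
  }
  chk_mix(cfg$sex_mix, "sex_mix")
  chk_mix(cfg$age_mix, "age_mix")
  chk_mix(cfg$country_mix, "country_mix")
  chk_mix(cfg$year_mix, "year_mix")
  chk_mix(cfg$subtype_mix, "subtype_mix")
  if (!all(names(cfg$sex_mix) %in% c("female", "male", "unspecified"))) {
    abort_config("sex_mix levels must be female/male/unspecified")
  }
  if (!all(names(cfg$age_mix) %in% age_bands())) {
    abort_config("age_mix levels must be the standard age bands")
  }
  if (cfg$p0 <= 0 || cfg$p0 >= 1) abort_config("p0 must be in (0, 1)")
  d <- cfg$drugs
  if (!all(c("drug", "marginal", "multiplier") %in% names(d))) {
    abort_config("drugs needs columns drug, marginal, multiplier")
  }
  if (any(d$marginal <= 0 | d$marginal >= 1)) {
    abort_config("drug marginals must be in (0, 1)")
  }
  if (any(d$multiplier <= 0)) abort_config("multipliers must be > 0")
  if (cfg$duplication_rate < 0 || cfg$duplication_rate >= 1) {
    abort_config("duplication_rate must be in [0, 1)")
  }
  if (cfg$comedication_rate < 0 || cfg$comedication_rate > 1) {
    abort_config("comedication_rate must be in [0, 1]")
  }
  if (cfg$n_reports < 1) abort_config("n_reports must be >= 1")
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> seed ", x$seed, ", ", x$n_reports, " cases, ",
      nrow(x$drugs), " catalogue drugs, p0 = ", x$p0, "\n", sep = "")
  invisible(x)
}

.background_drugs <- c("aspirin", "lisinopril", "atorvastatin",
                       "omeprazole", "levothyroxine", "amlodipine",
                       "ibuprofen", "paracetamol")
.background_pts <- c("Nausea", "Headache", "Diarrhoea", "Fatigue",
                     "Dizziness", "Vomiting", "Rash", "Arthralgia")

#' Generate a synthetic report database
#'
#' Draws a database from a [synthetic_config()]; the same seed always
#' yields the identical database. Returns the reports *before*
#' deduplication (with any injected superseded versions) together with
#' the ground truth needed to validate the pipeline.
#'
#' @param config A [synthetic_config()].
#' @return List with `reports` (a [report_set()], pre-deduplication) and
#'   `ground_truth` (list: `multipliers` tibble, `n_cases`, `p0`,
#'   `config`).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  withr::local_seed(config$seed)
  n <- config$n_reports

  draw <- function(mix, n) {
    names(mix)[sample.int(length(mix), n, replace = TRUE, prob = mix)]
  }
  sex <- draw(config$sex_mix, n)
  age_band <- draw(config$age_mix, n)
  country <- draw(config$country_mix, n)
  year <- as.integer(draw(config$year_mix, n))

  # per-drug exposure indicators; multiplier per report = max over drugs
  nd <- nrow(config$drugs)
  m_report <- rep(1, n)
  drug_rows_id <- vector("list", nd + 2L)
  drug_rows_nm <- vector("list", nd + 2L)
  any_study <- rep(FALSE, n)
  for (j in seq_len(nd)) {
    on <- stats::runif(n) < config$drugs$marginal[j]
    idx <- which(on)
    m_report[idx] <- pmax(m_report[idx], config$drugs$multiplier[j])
    any_study[idx] <- TRUE
    drug_rows_id[[j]] <- idx
    drug_rows_nm[[j]] <- rep(config$drugs$drug[j], length(idx))
  }
  # background co-medication: always for drug-free reports, with
  # probability comedication_rate otherwise
  bg <- !any_study | stats::runif(n) < config$comedication_rate
  bg_idx <- which(bg)
  drug_rows_id[[nd + 1L]] <- bg_idx
  drug_rows_nm[[nd + 1L]] <- rep(other_bucket(), length(bg_idx))
  idx_all <- unlist(drug_rows_id)
  nm_all <- unlist(drug_rows_nm)

  odds <- m_report * config$p0 / (1 - config$p0)
  event <- stats::runif(n) < odds / (1 + odds)
  pt <- character(n)
  pt[event] <- draw(config$subtype_mix, sum(event))
  pt[!event] <- sample(.background_pts, sum(!event), replace = TRUE)

  case_id <- paste0("C", 10000000L + seq_len(n))  # fixed width, sortable
  report_id <- paste0(case_id, "-1")
  reports <- tibble::tibble(report_id = report_id, case_id = case_id,
                            version = 1L, sex = sex, age_band = age_band,
                            year = year, country = country)
  drugs <- tibble::tibble(
    report_id = report_id[idx_all],
    drug = nm_all,
    role = sample(c("PS", "SS", "C", "I"), length(idx_all),
                  replace = TRUE, prob = c(0.5, 0.2, 0.25, 0.05)))
  events <- tibble::tibble(report_id = report_id, pt = pt)

  # inject superseded earlier versions for a fraction of cases; the final
  # (highest) version is the canonical record, so dedup recovers exactly
  # the n generated cases
  n_dup <- floor(config$duplication_rate * n)
  if (n_dup > 0) {
    which_dup <- sample.int(n, n_dup)
    n_extra <- sample(1:3, n_dup, replace = TRUE)
    di <- rep(which_dup, n_extra)
    # superseded versions numbered 0, -1, -2 below the canonical version 1
    ver <- 1L - unlist(lapply(n_extra, seq_len), use.names = FALSE)
    dup_rid <- paste0(case_id[di], "-x", 1L - ver)
    extra_reports <- tibble::tibble(
      report_id = dup_rid, case_id = case_id[di], version = as.integer(ver),
      sex = sex[di], age_band = age_band[di], year = year[di],
      country = country[di])
    # replicate each duplicated case's drug and event rows per extra version
    dup_tbl <- tibble::tibble(case = case_id[di], rid = dup_rid)
    base_drugs <- drugs[drugs$report_id %in% report_id[which_dup], ,
                        drop = FALSE]
    base_drugs$case <- sub("-1$", "", base_drugs$report_id)
    ed <- dplyr::inner_join(dup_tbl, base_drugs, by = "case",
                            relationship = "many-to-many")
    extra_drugs <- tibble::tibble(report_id = ed$rid, drug = ed$drug,
                                  role = ed$role)
    base_events <- events[events$report_id %in% report_id[which_dup], ,
                          drop = FALSE]
    base_events$case <- sub("-1$", "", base_events$report_id)
    ee <- dplyr::inner_join(dup_tbl, base_events, by = "case",
                            relationship = "many-to-many")
    extra_events <- tibble::tibble(report_id = ee$rid, pt = ee$pt)
    reports <- dplyr::bind_rows(reports, extra_reports)
    drugs <- dplyr::bind_rows(drugs, extra_drugs)
    events <- dplyr::bind_rows(events, extra_events)
  }

  list(reports = report_set(reports, drugs, events),
       ground_truth = list(
         multipliers = tibble::tibble(drug = config$drugs$drug,
                                      multiplier = config$drugs$multiplier),
         n_cases = n, p0 = config$p0, config = config))
}

#' Analytic expected contingency cells for a config
#'
#' First-order expected `a` and `b` counts per catalogue drug, treating
#' the drug's multiplier as dominant for its exposed reports (exact for
#' single-drug reports; co-medication between catalogue drugs perturbs
#' this only at second order).
#'
#' @param config A [synthetic_config()].
#' @return Tibble `drug`, `exp_a`, `exp_b`.
#' @export
expected_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  p_event <- function(m) {
    o <- m * config$p0 / (1 - config$p0)
    o / (1 + o)
  }
  n_exposed <- config$n_reports * config$drugs$marginal
  pe <- p_event(config$drugs$multiplier)
  tibble::tibble(drug = config$drugs$drug,
                 exp_a = n_exposed * pe,
                 exp_b = n_exposed * (1 - pe))
}

#' Synthetic config shaped like the reference screen
#'
#' Builds a [synthetic_config()] whose catalogue mirrors the reference
#' thyroid-cancer screen counts ([reference_screen_counts()]) at reduced
#' scale: each drug's multiplier is the ROR recomputed from its counts
#' (Haldane-corrected where a count is zero), and marginals and the
#' baseline event rate are inflated (`marginal_scale`, default 5x, and
#' `p0 = 0.01` against the archive's ~5.5e-4) so that a database of
#' `n_reports` cases — rather than 26 million — still produces countable
#' contingency cells with the same relative magnitudes.
#'
#' @param n_reports Database size.
#' @param seed Seed.
#' @param marginal_scale Inflation factor on per-drug report marginals.
#' @param p0 Baseline event probability.
#' @return A [synthetic_config()].
#' @export
reference_screen_config <- function(n_reports = 200000L, seed = 1L,
                                    marginal_scale = 5, p0 = 0.01) {
  ref <- reference_screen_counts()
  cnt <- ref$counts
  n_db <- ref$total_event + ref$total_other
  cc <- ref$total_event - cnt$a
  dd <- ref$total_other - cnt$b
  mult <- ifelse(cnt$a > 0,
                 (cnt$a * dd) / (cnt$b * cc),
                 ((cnt$a + 0.5) * (dd + 0.5)) /
                   ((cnt$b + 0.5) * (cc + 0.5)))
  synthetic_config(
    seed = seed, n_reports = n_reports,
    drugs = tibble::tibble(drug = cnt$drug,
                           marginal = marginal_scale * (cnt$a + cnt$b) / n_db,
                           multiplier = mult),
    p0 = p0)
}

#' Write a synthetic database in the FAERS ASCII dialect
#'
#' Materialises a [report_set()] as `$`-delimited DEMO/DRUG/REAC files,
#' so the ingestion path can be exercised end-to-end. Canonical drug
#' names are roughened into verbatim variants (brand names from the
#' dictionary, random upper-casing, occasional dose suffixes); ages are
#' sampled uniformly inside each band, so re-ingestion re-derives the
#' same bands.
#'
#' @param x A [report_set()].
#' @param dir Output directory; `DEMO.txt`, `DRUG.txt`, `REAC.txt` are
#'   created there.
#' @param dict A [drug_dictionary()] used to pick brand-name variants.
#' @param dialect A [faers_dialect()].
#' @param seed Seed for the name/age roughening.
#' @return `dir`, invisibly.
#' @export
write_faers_quarter <- function(x, dir, dict = default_drug_dictionary(),
                                dialect = faers_dialect(), seed = 1L) {
  stopifnot(inherits(x, "report_set"))
  withr::local_seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- x$reports
  band_age <- function(band) {
    lo <- c("0-11" = 0, "12-17" = 12, "18-64" = 18, "65-85" = 65)
    hi <- c("0-11" = 11, "12-17" = 17, "18-64" = 64, "65-85" = 85)
    out <- rep("", length(band))
    sel <- band != "unspecified"
    out[sel] <- as.character(floor(stats::runif(sum(sel), lo[band[sel]],
                                                hi[band[sel]] + 1)))
    out
  }
  sex_code <- c(female = "F", male = "M", unspecified = "")[r$sex]
  demo <- data.frame(
    primaryid = r$report_id, caseid = r$case_id,
    caseversion = r$version,
    age = band_age(r$age_band),
    age_cod = ifelse(r$age_band == "unspecified", "", "YR"),
    sex = sex_code,
    event_dt = ifelse(is.na(r$year), "", paste0(r$year, "0101")),
    fda_dt = ifelse(is.na(r$year), "", paste0(r$year, "0301")),
    reporter_country = ifelse(r$country == "unspecified", "", r$country))

  # verbatim roughening: brand synonym when available, random case, and
  # occasional dose suffix; all collapse back under normalisation
  syn <- split(dict$entries$key, dict$entries$ingredient)
  verbatim <- vapply(x$drugs$drug, function(dn) {
    if (dn == other_bucket()) return(sample(.background_drugs, 1))
    keys <- syn[[dn]]
    if (is.null(keys)) dn else sample(keys, 1)
  }, character(1))
  flip <- stats::runif(nrow(x$drugs))
  verbatim <- ifelse(flip < 0.4, toupper(verbatim), tolower(verbatim))
  dosed <- stats::runif(nrow(x$drugs)) < 0.15
  verbatim[dosed] <- paste(verbatim[dosed], "10 MG")
  drug <- data.frame(primaryid = x$drugs$report_id,
                     drug_seq = stats::ave(seq_len(nrow(x$drugs)),
                                           x$drugs$report_id,
                                           FUN = seq_along),
                     drugname = verbatim,
                     role_cod = ifelse(is.na(x$drugs$role), "",
                                       x$drugs$role))
  reac <- data.frame(primaryid = x$events$report_id, pt = x$events$pt)

  wr <- function(df, cols, file) {
    df <- df[, cols, drop = FALSE]
    lines <- c(paste(cols, collapse = dialect$delim),
               do.call(paste, c(unname(as.list(df)), sep = dialect$delim)))
    writeLines(lines, file.path(dir, file))
  }
  wr(demo, dialect$demo_cols, "DEMO.txt")
  wr(drug, dialect$drug_cols, "DRUG.txt")
  wr(reac, dialect$reac_cols, "REAC.txt")
  invisible(dir)
}

#' Read/write synthetic configs as YAML
#'
#' @param config A [synthetic_config()].
#' @param path File path.
#' @return `write_synthetic_config()` returns `path` invisibly;
#'   `read_synthetic_config()` a [synthetic_config()].
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  obj <- unclass(config)
  obj$drugs <- lapply(seq_len(nrow(config$drugs)), function(i)
    as.list(config$drugs[i, ]))
  # named vectors must become maps, or yaml drops the level names
  for (nm in c("sex_mix", "age_mix", "country_mix", "year_mix",
               "subtype_mix")) {
    obj[[nm]] <- as.list(obj[[nm]])
  }
  writeLines(yaml::as.yaml(obj, precision = 15), path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  if (!file.exists(path)) abort_config("config file not found: ", path)
  obj <- yaml::read_yaml(path)
  obj$drugs <- dplyr::bind_rows(lapply(obj$drugs, tibble::as_tibble))
  for (nm in c("sex_mix", "age_mix", "country_mix", "year_mix",
               "subtype_mix")) {
    obj[[nm]] <- unlist(obj[[nm]])
  }
  do.call(synthetic_config, obj)
}
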