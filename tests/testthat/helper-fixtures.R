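# Shared fixtures, built in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Six deduplicated reports: two name drug "dx" (one of them with the
# composite event), four do not (one with the event).
# Exhaustive enumeration gives (a, b, c, d) = (1, 1, 1, 3).
toy_report_set <- function() {
  reports <- tibble::tibble(
    report_id = paste0("R", 1:6),
    case_id = paste0("K", 1:6),
    version = 1L,
    sex = c("female", "male", "female", "unspecified", "male", "female"),
    age_band = c("18-64", "65-85", "18-64", "unspecified", "12-17", "18-64"),
    year = c(2020L, 2021L, 2021L, NA, 2022L, 2023L),
    country = c("US", "US", "CA", "unspecified", "JP", "US"))
  drugs <- tibble::tibble(
    report_id = c("R1", "R1", "R2", "R3", "R4", "R5", "R6"),
    drug = c("dx", "(other)", "dx", "(other)", "(other)", "(other)",
             "(other)"),
    role = c("PS", "C", "C", "PS", "SS", "I", NA))
  events <- tibble::tibble(
    report_id = c("R1", "R2", "R3", "R4", "R5", "R6"),
    pt = c("Thyroid cancer", "Nausea", "Papillary thyroid cancer",
           "Headache", "Rash", "Fatigue"))
  report_set(reports, drugs, events)
}

# FAERS-dialect toy quarter: 2 cases, 3 drug rows, 2 reaction rows.
write_toy_quarter <- function(dir, extra_drug_lines = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(
    "primaryid$caseid$caseversion$age$age_cod$sex$event_dt$fda_dt$reporter_country",
    "1001$C1$1$70$YR$F$20210315$20210401$US",
    "1002$C2$1$$$M$$20220101$CA"),
    file.path(dir, "DEMO.txt"))
  writeLines(c(
    "primaryid$drug_seq$drugname$role_cod",
    "1001$1$OZEMPIC$C",
    "1001$2$Metformin HCl 500mg$PS",
    "1002$1$XYZZY-DRUG$SS",
    extra_drug_lines),
    file.path(dir, "DRUG.txt"))
  writeLines(c(
    "primaryid$pt",
    "1001$Thyroid cancer",
    "1002$Nausea"),
    file.path(dir, "REAC.txt"))
  dir
}

# Independent oracle: enumerates every report one by one and inspects
# that report's own drug and event rows, instead of the implementation's
# global set operations.
brute_contingency <- function(x, drug, term_set,
                              comparator = "exclude-drug") {
  terms <- tolower(term_set$terms$term)
  drugs_by <- split(x$drugs$drug, x$drugs$report_id)
  events_by <- split(tolower(trimws(x$events$pt)), x$events$report_id)
  di <- match(x$reports$report_id, names(drugs_by))
  ei <- match(x$reports$report_id, names(events_by))
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(x$reports))) {
    has_drug <- drug %in% drugs_by[[di[i]]]
    has_event <- any(events_by[[ei[i]]] %in% terms)
    if (has_drug && has_event) a <- a + 1L
    else if (has_drug) b <- b + 1L
    else if (has_event) cc <- cc + 1L
    else d <- d + 1L
  }
  if (comparator == "all-reports") {
    cc <- cc + a
    d <- d + b
  }
  contingency_table(a, b, cc, d)
}

# small random database for property tests
random_report_set <- function(seed, n = 200) {
  cfg <- synthetic_config(
    seed = seed, n_reports = n,
    drugs = tibble::tibble(drug = c("dx", "dy", "dz"),
                           marginal = c(0.1, 0.05, 0.2),
                           multiplier = c(3, 1, 0.5)),
    p0 = 0.05, duplication_rate = 0.1)
  generate_reports(cfg)
}
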