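terms <- default_event_terms()

test_that("demographic percentages behave on degenerate and toy input", {
  rs <- toy_report_set()
  s <- demographics_summary(rs, terms)
  # two event reports (R1 female US 2020, R3 female CA 2021)
  sex <- s[s$characteristic == "sex", ]
  expect_equal(sex$pct[sex$level == "female"], 100)
  expect_equal(sum(sex$pct), 100)
  expect_equal(sum(s$pct[s$characteristic == "age_band"]), 100)
  expect_equal(sum(s$pct[s$characteristic == "country"]), 100)
  # single-report input
  one <- report_set(rs$reports[rs$reports$report_id == "R1", ],
                    rs$drugs[rs$drugs$report_id == "R1", ],
                    rs$events[rs$events$report_id == "R1", ])
  s1 <- demographics_summary(one, terms)
  expect_equal(s1$pct[s1$characteristic == "sex" & s1$level == "female"],
               100)
  expect_error(demographics_summary(one, terms, drug_class = "absent"),
               "no composite-event reports")
})

test_that("summary recovers the generator's configured mixtures", {
  cfg <- synthetic_config(seed = 31, n_reports = 10000,
                          p0 = 0.2, duplication_rate = 0)
  gen <- generate_reports(cfg)
  s <- demographics_summary(gen$reports, terms)
  n_event <- sum(s$n[s$characteristic == "sex"])
  for (lvl in names(cfg$sex_mix)) {
    p <- cfg$sex_mix[[lvl]]
    se3 <- 3 * sqrt(p * (1 - p) / n_event)
    got <- s$pct[s$characteristic == "sex" & s$level == lvl] / 100
    expect_lt(abs(got - p), se3)
  }
  # female share specifically lands near the configured 63%
  got_f <- s$pct[s$characteristic == "sex" & s$level == "female"]
  expect_equal(got_f, 63, tolerance = 0.05)
  for (lvl in names(cfg$age_mix)) {
    p <- cfg$age_mix[[lvl]]
    se3 <- 3 * sqrt(p * (1 - p) / n_event) + 1e-9
    got <- s$pct[s$characteristic == "age_band" & s$level == lvl] / 100
    expect_lt(abs(got - p), se3)
  }
})

test_that("stratified a-cells over a partition sum to the pooled a-cell", {
  gen <- random_report_set(41, n = 800)
  rs <- suppressMessages(deduplicate_reports(gen$reports))
  pooled <- ror_screen(rs, c("dx", "dy"), terms, k = 1)
  for (axis in c("sex", "age_band")) {
    levels <- unique(rs$reports[[axis]])
    parts <- lapply(levels, function(lv)
      stratified_screen(rs, axis = axis, level = lv,
                        drug_list = c("dx", "dy"), term_set = terms, k = 1))
    expect_equal(Reduce(`+`, lapply(parts, function(p) p$a)), pooled$a)
    expect_equal(Reduce(`+`, lapply(parts, function(p) p$a + p$b + p$c + p$d)),
                 rep(n_reports(rs), 2))
  }
})

test_that("a stratum holding every report reproduces the plain screen", {
  gen <- random_report_set(43, n = 400)
  rs <- suppressMessages(deduplicate_reports(gen$reports))
  rs$reports$sex <- "female"  # degenerate axis: single level
  pooled <- ror_screen(rs, c("dx", "dy"), terms, k = 1)
  strat <- stratified_screen(rs, axis = "sex", level = "female",
                             drug_list = c("dx", "dy"), term_set = terms,
                             k = 1)
  expect_equal(tibble::as_tibble(strat), tibble::as_tibble(pooled))
})

test_that("empty strata are flagged, small strata all-excluded", {
  rs <- toy_report_set()
  s <- stratified_screen(rs, axis = "sex", level = "male",
                         drug_list = "dx", term_set = terms)
  # one male report, no dx-event pair: everything below threshold
  expect_true(all(s$excluded))
  s0 <- stratified_screen(rs, axis = "year", level = 1999,
                          drug_list = "dx", term_set = terms)
  expect_equal(nrow(s0), 0)
  expect_true(isTRUE(attr(s0, "empty_stratum")))
})

test_that("yearly trend conserves totals and fills gaps with zeros", {
  rs <- toy_report_set()
  # dx is on R1 and R2; only R1 carries a composite event (year 2020)
  tr <- yearly_trend(rs, "dx", terms)
  expect_equal(tr, tibble::tibble(year = "2020", n = 1L))
  # widening the class to the other-bucket drugs picks up R3 (2021)
  tr2 <- yearly_trend(rs, c("dx", other_bucket()), terms)
  expect_equal(tr2$n, c(1L, 1L))
  expect_equal(tr2$year, c("2020", "2021"))
  gen <- random_report_set(47, n = 600)
  rs2 <- suppressMessages(deduplicate_reports(gen$reports))
  tr2 <- yearly_trend(rs2, c("dx", "dy"), terms)
  ids <- intersect(
    unique(rs2$drugs$report_id[rs2$drugs$drug %in% c("dx", "dy")]),
    unique(rs2$events$report_id[
      tolower(rs2$events$pt) %in% terms$terms$term_lc]))
  expect_equal(sum(tr2$n), length(ids))
  yrs <- suppressWarnings(as.integer(tr2$year[tr2$year != "unspecified"]))
  expect_equal(yrs, seq(min(yrs), max(yrs)))  # contiguous, gaps as zeros
  expect_equal(nrow(yearly_trend(rs2, "no-such-drug", terms)), 0)
})

test_that("a configured surge year shows up in the trend", {
  w <- stats::setNames(c(rep(0.02, 19), 0.31, 0.31),
                       as.character(2004:2024))
  cfg <- synthetic_config(seed = 53, n_reports = 5000, p0 = 0.3,
                          year_mix = w, duplication_rate = 0)
  gen <- generate_reports(cfg)
  tr <- yearly_trend(gen$reports, c("drug_a", "drug_b", "drug_c"), terms)
  n23 <- tr$n[tr$year == "2023"]
  before <- mean(tr$n[tr$year %in% as.character(2004:2022)])
  expect_gt(n23, 5 * before)
})

test_that("subtype proportions count mentions and sum to one", {
  reports <- tibble::tibble(report_id = paste0("R", 1:4),
                            case_id = paste0("K", 1:4), version = 1L,
                            sex = "female", age_band = "18-64",
                            year = 2022L, country = "US")
  drugs <- tibble::tibble(report_id = paste0("R", 1:4), drug = "dx",
                          role = "PS")
  events <- tibble::tibble(
    report_id = paste0("R", 1:4),
    pt = c("Papillary thyroid cancer", "Medullary thyroid cancer",
           "Thyroid cancer", "Thyroid neoplasm"))
  rs <- report_set(reports, drugs, events)
  b <- subtype_breakdown(rs, "dx", terms)
  expect_equal(b$proportion[b$subtype == "papillary"], 0.25)
  expect_equal(b$proportion[b$subtype == "medullary"], 0.25)
  expect_equal(b$proportion[b$subtype == "metastatic"], 0)
  expect_equal(b$proportion[b$subtype == "other"], 0.5)
  expect_equal(sum(b$proportion), 1)
  # all-generic reports: 100% "other"
  events2 <- tibble::tibble(report_id = paste0("R", 1:4),
                            pt = "Thyroid cancer")
  rs2 <- report_set(reports, drugs, events2)
  b2 <- subtype_breakdown(rs2, "dx", terms)
  expect_equal(b2$proportion[b2$subtype == "other"], 1)
  # a report with terms of two subtypes contributes one mention to each
  events3 <- rbind(events, tibble::tibble(
    report_id = "R1", pt = "Medullary thyroid cancer"))
  rs3 <- report_set(reports, drugs, events3)
  b3 <- subtype_breakdown(rs3, "dx", terms)
  expect_equal(sum(b3$proportion), 1)
  expect_equal(b3$n[b3$subtype == "medullary"], 2)
  expect_error(subtype_breakdown(rs, "absent", terms), "no composite")
})

test_that("the classification scheme separates the two generic terms", {
  reports <- tibble::tibble(report_id = c("R1", "R2"),
                            case_id = c("K1", "K2"), version = 1L,
                            sex = "female", age_band = "18-64",
                            year = 2022L, country = "US")
  drugs <- tibble::tibble(report_id = c("R1", "R2"), drug = "dx",
                          role = "PS")
  events <- tibble::tibble(report_id = c("R1", "R2"),
                           pt = c("Thyroid cancer", "Thyroid neoplasm"))
  rs <- report_set(reports, drugs, events)
  b <- subtype_breakdown(rs, "dx", terms, scheme = "classification")
  expect_equal(b$proportion[b$subtype == "thyroid cancer"], 0.5)
  expect_equal(b$proportion[b$subtype == "thyroid neoplasm"], 0.5)
})
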