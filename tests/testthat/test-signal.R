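ref <- reference_screen_counts()

test_that("hand-enumerated toy database gives (1, 1, 1, 3)", {
  tab <- build_contingency(toy_report_set(), "dx", default_event_terms())
  expect_equal(unclass(tab)[c("a", "b", "c", "d")],
               list(a = 1, b = 1, c = 1, d = 3))
  # all-reports comparator leaves the drug's reports in the comparator
  tab2 <- build_contingency(toy_report_set(), "dx", default_event_terms(),
                            comparator = "all-reports")
  expect_equal(tab2$c, 2)
  expect_equal(tab2$d, 4)
  # a drug absent everywhere is a zero row, not an error
  tab0 <- build_contingency(toy_report_set(), "nope",
                            default_event_terms())
  expect_equal(tab0$a + tab0$b, 0)
})

test_that("build_contingency matches exhaustive enumeration", {
  terms <- default_event_terms()
  for (seed in c(5, 6)) {
    gen <- random_report_set(seed, n = 300)
    rs <- suppressMessages(deduplicate_reports(gen$reports))
    for (d in c("dx", "dy", "dz", other_bucket())) {
      expect_equal(build_contingency(rs, d, terms),
                   brute_contingency(rs, d, terms))
    }
  }
})

test_that("ROR reproduces archive-scale published values", {
  # cells from the reference screen counts, comparator by subtraction
  tir <- contingency_table(37, 31928, 14370 - 37, 25925016 - 31928)
  expect_equal(round_half_up(ror(tir), 2), 2.09)
  met <- contingency_table(17, 53172, 14370 - 17, 25925016 - 53172)
  expect_equal(round_half_up(ror(met), 2), 0.58)
  # balanced odds give exactly 1
  expect_equal(ror(contingency_table(5, 50, 10, 100)), 1)
})

test_that("Woolf CI reproduces published intervals and collapses at alpha 1", {
  met <- contingency_table(17, 53172, 14370 - 17, 25925016 - 53172)
  expect_equal(unname(round_half_up(woolf_ci(met), 2)), c(0.36, 0.93))
  top <- contingency_table(14, 34652, 14370 - 14, 25925016 - 34652)
  expect_equal(unname(round_half_up(woolf_ci(top), 2)), c(0.43, 1.23))
  ci1 <- woolf_ci(met, alpha = 1)
  expect_equal(unname(ci1), rep(ror(met), 2))
})

test_that("z-test p-value matches the published value and the CI", {
  met <- contingency_table(17, 53172, 14370 - 17, 25925016 - 53172)
  expect_equal(round_half_up(ror_p_value(met), 2), 0.02)
  expect_equal(ror_p_value(contingency_table(5, 50, 10, 100)), 1)
})

test_that("p < alpha exactly when 1 is outside the Woolf interval", {
  set.seed(101)
  for (i in 1:200) {
    tab <- contingency_table(sample(1:50, 1), sample(1:5000, 1),
                             sample(1:500, 1), sample(1:50000, 1))
    for (alpha in c(0.01, 0.05, 0.2)) {
      ci <- woolf_ci(tab, alpha)
      expect_equal(ror_p_value(tab) < alpha,
                   ci[["low"]] > 1 || ci[["high"]] < 1)
    }
  }
})

test_that("odds-ratio route agrees with an independent logistic fit", {
  # saturated logistic regression on the 2x2 recovers the sample OR
  tab <- contingency_table(37, 31928, 14333, 25893088)
  fit <- stats::glm(cbind(ev, no) ~ drug,
                    data = data.frame(drug = c(1, 0), ev = c(37, 14333),
                                      no = c(31928, 25893088)),
                    family = stats::binomial())
  expect_equal(ror(tab), unname(exp(stats::coef(fit)["drug"])),
               tolerance = 1e-8)
  se_glm <- sqrt(diag(stats::vcov(fit)))["drug"]
  ci <- woolf_ci(tab)
  expect_equal(unname(log(ci[["high"]]) - log(ror(tab))),
               unname(stats::qnorm(0.975) * se_glm), tolerance = 1e-6)
})

test_that("swapping table rows inverts the ROR and its CI", {
  set.seed(77)
  for (i in 1:50) {
    k <- sample(1:1000, 4, replace = TRUE)
    tab <- contingency_table(k[1], k[2], k[3], k[4])
    swp <- contingency_table(k[3], k[4], k[1], k[2])
    expect_equal(ror(swp), 1 / ror(tab), tolerance = 1e-12)
    expect_equal(unname(woolf_ci(swp)),
                 unname(rev(1 / woolf_ci(tab))), tolerance = 1e-12)
    expect_equal(ror_p_value(swp), ror_p_value(tab), tolerance = 1e-12)
  }
})

test_that("ROR is monotone in a; SE shrinks as any cell grows", {
  base <- contingency_table(10, 100, 50, 5000)
  se <- function(tab) sqrt(1 / tab$a + 1 / tab$b + 1 / tab$c + 1 / tab$d)
  expect_true(ror(contingency_table(11, 100, 50, 5000)) > ror(base))
  for (cell in c("a", "b", "c", "d")) {
    cells <- unclass(base)
    cells[[cell]] <- cells[[cell]] + 10
    expect_lt(se(do.call(contingency_table, cells)), se(base))
  }
})

test_that("zero cells error without, and compute with, the correction", {
  z <- contingency_table(0, 100, 50, 5000)
  expect_error(ror(z), "degenerate")
  expect_error(woolf_ci(z), "degenerate")
  expect_gt(ror(z, correction = TRUE), 0)
})

test_that("the minimum-count filter excludes a < k and keeps a >= k", {
  counts <- tibble::tibble(drug = c("low0", "low4", "edge5", "kept7",
                                    "kept14"),
                           a = c(0, 4, 5, 7, 14),
                           b = c(1000, 23841, 5000, 12714, 34652))
  s <- signal_from_counts(counts, ref$total_event, ref$total_other, k = 5)
  expect_equal(s$excluded, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(s$reason[1:2], rep("below-min-count", 2))
  expect_true(all(is.na(s$ror[s$excluded])))
  expect_true(all(!is.na(s$ror[!s$excluded])))
  expect_error(apply_min_count_filter(s, k = 0), "k must be")
})

test_that("screen preserves drug order and matches per-drug tables", {
  terms <- default_event_terms()
  gen <- random_report_set(13, n = 400)
  rs <- suppressMessages(deduplicate_reports(gen$reports))
  drugs <- c("dz", "dx", "dy")
  s <- ror_screen(rs, drugs, terms, k = 1)
  expect_equal(s$drug, drugs)
  for (i in seq_along(drugs)) {
    tab <- build_contingency(rs, drugs[i], terms)
    expect_equal(s$a[i], tab$a)
    if (!s$excluded[i]) expect_equal(s$ror[i], ror(tab))
  }
  empty <- report_set(rs$reports[0, ], rs$drugs[0, ], rs$events[0, ])
  expect_error(ror_screen(empty, "dx", terms), "empty report set")
})

test_that("from-counts and report-level screens agree on the same database", {
  terms <- default_event_terms()
  gen <- random_report_set(17, n = 500)
  rs <- suppressMessages(deduplicate_reports(gen$reports))
  s1 <- ror_screen(rs, c("dx", "dy"), terms, k = 1)
  s2 <- signal_from_counts(
    tibble::tibble(drug = c("dx", "dy"), a = s1$a, b = s1$b),
    total_event = attr(s1, "total_event"),
    total_other = attr(s1, "total_other"), k = 1)
  expect_equal(tibble::as_tibble(s2), tibble::as_tibble(s1))
})
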