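# rorscreen

Disproportionality screening of spontaneous adverse-event reports:
a reusable pipeline from raw FAERS-style quarterly files to per-drug
reporting odds ratios for a composite thyroid-cancer event, built for
the pharmacovigilance question of whether weight-loss drugs — above all
the GLP-1 receptor agonists — are disproportionately reported with
thyroid cancer.

Spontaneous-reporting databases have no exposure denominator, so risk
cannot be estimated; what can be computed is whether an event is
reported more often with a drug than with the rest of the database.
For each drug, deduplicated reports are cross-classified into a 2x2
table — `a` (drug + composite event), `b` (drug, other events),
`c`/`d` (the same for all other drugs) — and screened with the
reporting odds ratio

    ROR = (a/b) / (c/d),

its Woolf 95% confidence interval
`exp(ln ROR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`, and the matching
z-test p-value. Drugs with fewer than five event reports are excluded
as unstable. A drug appears in a report's exposure set whatever its
role code (primary/secondary suspect, concomitant, interacting), and
unmapped drug names are retained in the comparator so denominators stay
honest.

The package covers the full workflow:

* **Ingestion** — `$`-delimited DEMO/DRUG/REAC quarter files
  (`read_faers_quarter()`, `assemble_reports()`), with malformed-line
  accounting, a synonym dictionary for verbatim drug names, exact
  PT-level matching of the composite event terms, and a bit-exact
  internal CSV format (`write_report_set()`).
* **Deduplication** — latest-version-wins per case
  (`deduplicate_reports()`).
* **Screening** — `ror_screen()`, `signal_from_counts()` (re-analyse a
  published count table without the archive), threshold filtering,
  forest-plot data export.
* **Strata and trends** — `stratified_screen()`,
  `demographics_summary()`, `yearly_trend()`, `subtype_breakdown()`.
* **Synthetic data** — a seeded generator with known ground truth
  (`synthetic_config()`, `generate_reports()`), which is how the
  pipeline is validated without a 26-million-report download.
* **CLI** — `inst/cli/rorscreen.R` exposes screen / simulate /
  from-counts / strata / trend / subtypes subcommands.

## Worked example

Screen the packaged count table of a published FAERS thyroid-cancer
screen (2004–2024 Q1; 14,370 composite-event reports against
25,925,016 others):

```r
library(rorscreen)

ref <- reference_screen_counts()
s   <- signal_from_counts(ref$counts, ref$total_event, ref$total_other)
format_screen(s)[c(4, 7, 11), c("drug", "a", "b", "ror", "ci_low", "ci_high")]
#> # A tibble: 3 × 6
#>   drug            a     b   ror ci_low ci_high
#>   <chr>       <int> <int> <dbl>  <dbl>   <dbl>
#> 1 tirzepatide    37 31928  2.09   1.52    2.89
#> 2 metformin      17 53172  0.58   0.36    0.93
#> 3 topiramate     14 34652  0.73   0.43    1.23
```

Tirzepatide's reports carry 2.09 times the thyroid-cancer reporting
odds of the rest of the database, with a confidence interval excluding
1 — a signal worth investigation, not a causal claim. Metformin is
reported *less* often than expected (inverse association), and
topiramate's interval straddles 1 (no signal). Sparse drugs (for
example orlistat with 4 event reports) come back flagged
`excluded = "below-min-count"` with no statistics.

The same numbers arise end-to-end from raw files: simulate a database,
write it in the FAERS dialect, and run the full pipeline:

```r
cfg <- reference_screen_config(n_reports = 50000, seed = 1)
sim <- run_simulate(cfg, "sim", format = "faers")
scr <- run_screen("sim/faers", "out",
                  drug_list = c("liraglutide", "metformin", "orlistat"))
```

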