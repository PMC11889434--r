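---
title: "Disproportionality screening of spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorscreen)
```

## The problem

Spontaneous-reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect voluntarily submitted case reports of suspected
adverse drug reactions. They have no exposure denominator — nobody knows
how many patients took a drug without filing a report — so incidence
cannot be estimated. What *can* be estimated is disproportionality:
whether an event is reported more often with a given drug than with the
rest of the database. rorscreen implements this for a composite
thyroid-cancer event screened against weight-loss and anti-diabetic
drugs (GLP-1 receptor agonists and comparators), from raw quarterly
files to publication-style outputs.

## The statistic

For one drug and the composite event, deduplicated reports are
cross-classified into a 2x2 table:

|              | composite event | other events |
|--------------|-----------------|--------------|
| drug         | a               | b            |
| all others   | c               | d            |

The reporting odds ratio is

$$\mathrm{ROR} = \frac{a/b}{c/d} = \frac{ad}{bc},$$

with Woolf (log-normal) confidence interval
$\exp\{\ln \mathrm{ROR} \pm z_{1-\alpha/2}\sqrt{1/a + 1/b + 1/c + 1/d}\}$
and the matching two-sided z-test
$p = 2\Phi(-|\ln \mathrm{ROR}|/\mathrm{SE})$. The three are consistent
by construction: $p < \alpha$ exactly when 1 falls outside the
$(1-\alpha)$ interval — a property the test suite checks over random
tables. A ROR is a reporting signal, not a risk estimate: it warrants
investigation, never establishes causation.

### Counting conventions

These choices matter more than the formula and are worth stating
precisely.

* **Unit of counting.** One deduplicated report, never a report-drug
  pair: a report listing a drug twice counts once, and a report with
  several composite terms still contributes a single count to `a`.
* **Role-agnostic exposure.** A report is "exposed" if the drug appears
  in *any* role — primary suspect, secondary suspect, concomitant or
  interacting. Concomitant mentions carry signal in a database where
  suspicion assignment is informal; role codes are carried through the
  model but never used to drop an entry.
* **Comparator.** By default the drug's own reports are subtracted from
  the comparator row (`c = total event reports − a`,
  `d = total other reports − b`), the standard ROR convention. A
  `comparator = "all-reports"` switch leaves them in; with millions of
  reports the difference is negligible, but the subtraction convention
  is what reproduces published thyroid-cancer screen statistics to the
  printed 2 decimals.
* **Minimum count.** Drugs with `a < 5` event reports are excluded
  (`k` configurable). Below that the ROR is dominated by Poisson noise
  and a single report can manufacture a "signal". The boundary sits at
  *fewer than* five: `a = 5` is retained.
* **Zero cells.** With the threshold in place, a retained drug cannot
  have `a = 0`, and comparator cells are never zero in any realistic
  database, so the default is to refuse degenerate tables loudly. An
  optional Haldane–Anscombe +0.5 correction supports exploratory use.
* **Display rounding.** Statistics are printed half-up at 2 decimals
  (`round_half_up()`), matching publication convention; base R's
  round-half-even disagrees on exact ties. Internal values stay at full
  precision.

## Vocabularies

Verbatim drug strings are mapped to canonical ingredients through an
editable synonym dictionary. Lookup keys are upper-cased, stripped of
punctuation, numbers and dose/salt tokens, so "Metformin HCl 500mg"
and "GLUCOPHAGE" land on the same ingredient. Unmapped names are *kept*
under a single other-drug bucket: dropping them would shrink the
comparator cells and bias every ROR upward. The shipped dictionary
covers the screened drugs with brand and generic keys; it makes no
attempt at licensed MedDRA or RxNorm traversal.

The composite event is a set of MedDRA preferred terms matched exactly
(case-insensitively) at PT level: thyroid cancer, thyroid neoplasm, and
the recurrent, papillary, follicular, medullary and anaplastic forms.
"Thyroid cancer metastatic" is included as an eighth term so that the
metastatic category of subtype breakdowns is populated; verbatim
reaction text matching is deliberately out of scope.

Subtype breakdowns support two schemes: a four-category histology view
(medullary, papillary, metastatic, other — "other" absorbing the
generic terms, follicular, anaplastic, recurrent and unspecified
pathology) and a report-classification view in which the two generic
PTs keep their own classes. A report naming terms of several subtypes
contributes one mention to each, and proportions are over mentions, so
they always sum to 1.

## Deduplication

FAERS stores every submitted version of a case. The package keeps, per
`case_id`, the row with the greatest version key — latest-version-wins,
as in the FDA's own guidance — sorted deterministically, with exact
(case, version) duplicates resolved to the first seen plus a warning. A
flag can disable it for sensitivity analyses. Probabilistic record
linkage across manufacturers is out of scope.

## Ingestion details

* FAERS quarters are `$`-delimited with a header line and no quoting;
  records are parsed line-wise, and any line that does not split into
  the header's field count is counted, reported and skipped — never
  silently dropped. Input is treated as Latin-1 (legacy archives are
  not clean UTF-8) with unmappable bytes replaced.
* Ages arrive as value + unit code (`YR`, `DEC`, `MON`, `WK`, `DY`,
  `HR`) and are banded into 0–11, 12–17, 18–64, 65–85; anything
  missing, negative or above 85 is "unspecified", because no band above
  85 is defined in the summary scheme.
* The year of a report is taken from the event date, falling back to
  the FDA receipt date (`year_source = "receipt"` restricts to the
  latter); the choice is a config switch because archives are
  inconsistent about which date is populated.
* The internal flat format (three CSVs plus a manifest) round-trips
  bit-exactly and is the fast path for re-analysis.

## The synthetic generator

Real FAERS archives are tens of gigabytes; every pipeline stage here is
instead validated against a seeded generator whose ground truth is
known. Per report: demographics from configurable mixtures, each
catalogue drug present independently with its marginal probability,
background co-medication filling drug-free reports, and the composite
event drawn with odds `m·p0/(1−p0)` where `m` is the largest multiplier
among the report's drugs. Under this model the population ROR of a drug
taken alone equals its multiplier, which is what makes parameter
recovery a meaningful test. The max-multiplier rule (rather than a
product) keeps single-drug reports interpretable and bounds the
contamination that co-medication introduces into the comparator.

Default mixtures follow the demographic marginals reported for
thyroid-cancer reports in the screened archive — 63% female, 23.6%
male; age mass concentrated in 18–64 (42.8%) with 44.9% unspecified;
US-led country mix (44.85%); report volume growing roughly linearly
over 2004–2024, as spontaneous-report inflow does. The subtype mixture
puts 77% on the generic "Thyroid cancer" PT, 11% on "Thyroid
neoplasm", 9.1% papillary, 1.5% medullary and the remainder on
follicular/anaplastic/metastatic, mirroring how rarely pathology is
specified in practice. The duplication rate defaults to 5% of cases
gaining 1–3 superseded versions — FAERS-like in order of magnitude —
and the co-medication rate to 30%.

`reference_screen_config()` builds a catalogue whose multipliers are
the RORs recomputed from a published thyroid-cancer screen's count
table (Haldane-corrected where a printed count is zero). Because that
archive has ~26 million reports and a baseline event rate of ~5.5e-4,
a faithful miniature would leave every expected `a` cell near zero; the
config therefore inflates drug marginals 5x and sets `p0 = 0.01`, a
deliberate rescaling that preserves the *relative* magnitudes (which
analogue outranks which, who falls under the count threshold) rather
than the absolute counts.

What the generator does *not* emulate: correlated co-prescription
networks, reporting waves after media coverage, country-specific
reporting cultures, free-text drug-name noise beyond case/salt/dose
variants, and partially duplicated cases that evade exact case-id
matching. Passing tests therefore demonstrate correctness of the
machinery under a clean generative model, not robustness to every
pathology of real pharmacovigilance data.

## Validation design

The test suite validates along four independent routes:

1. **Published statistics.** Feeding the packaged count table of a
   published thyroid-cancer screen through the engine reproduces the
   printed ROR/CI/p values (tirzepatide 2.09, CI upper 2.89; metformin
   0.58, 0.36–0.93, p = 0.02; topiramate 0.73, upper 1.23;
   dapagliflozin 0.99, upper 2.08; rosuvastatin 1.56) at 2-decimal
   half-up rounding. A handful of that screen's other printed values
   (semaglutide, dulaglutide, liraglutide, empagliflozin, and
   rosuvastatin's lower bound) are internally inconsistent with their
   own printed counts at the last digit — recomputation under either
   comparator convention gives nearby but different 2-dp values — so
   they are documented here rather than asserted.
2. **Exhaustive enumeration.** On 100 random synthetic databases of up
   to 1,000 reports, `build_contingency()` must equal a per-report
   brute-force oracle for every drug.
3. **Parameter recovery.** With an embedded multiplier of 4
   (200,000 reports, drug marginal 0.01, baseline event probability
   0.001, 500 replicates) the Woolf 95% CI must cover 4 in at least
   93% of replicates; with all multipliers 1 the CI excludes 1 in
   5% ± 2% of drug-replicates. The null design (n = 50,000, marginal
   0.02, p0 = 0.01, four drugs x 250 replicates) was chosen so the
   expected `a` cell is ~20, adequate for the asymptotic z-test; both
   simulations run without duplicate injection, since version handling
   is exercised separately and has no bearing on the estimator.
4. **Structural properties.** Row-swap inversion symmetry of
   ROR/CI/p, p/CI threshold consistency, stratified `a` cells summing
   to the pooled `a` over any demographic partition, deduplication
   idempotence, and byte-identical regeneration from a fixed seed.

An independent cross-check ties the estimator to standard software: on
a single 2x2 table, a saturated binomial GLM's exponentiated
coefficient and its Wald interval coincide with the ROR and Woolf CI.

## Limitations

Beyond the generator's idealisations listed above: no PRR/IC/EBGM
metrics or Bayesian shrinkage, no multiple-testing adjustment (screens
of this style historically apply none — interpret wide screens
accordingly), no adjustment for confounding by indication (diabetes
itself raises thyroid-cancer detection), and exact-PT event matching
only. Stratified screens recompute totals within stratum but the
package offers no formal across-stratum homogeneity test.
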