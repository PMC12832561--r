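---
title: "Disproportionality signal detection with pvsignal: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection with pvsignal: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
library(dplyr)
```

## The problem

Spontaneous-report databases such as FAERS (FDA) and the Canada Vigilance
database collect unsolicited reports of suspected adverse drug events. They
have no denominator: we observe how often an event is *reported* with a
drug, never how often it *occurs* among users. Signal detection therefore
compares the reporting frequency of each drug–event pair against the rest
of the database. pvsignal implements the full path from raw quarterly
ASCII extracts to a classified signal table: ingestion and normalization,
case-version deduplication, term-level cleaning, 2×2 contingency
construction, four disproportionality statistics, onset-time modeling,
subgroup contrasts with FDR control, and a co-medication sensitivity
reanalysis — plus a synthetic-report generator so that every stage can be
validated against known ground truth without access to the regulatory
extracts.

A signal here is always an association of reporting, not a causal claim.

## Report model and cleaning rules

Each report is normalized to a relational store (`report_store`): one row
per report version with demographics and dates, child tables for drug
entries, event preferred terms (PT), and indication terms. Conventions
that matter downstream:

* **Counting unit.** A report contributes at most once per PT and once per
  system organ class (SOC), however many of its terms repeat or share a
  class. All contingency counts are report counts.
* **Dates.** FAERS dates arrive as `YYYY`, `YYYYMM`, or `YYYYMMDD`; they
  are stored as digit strings with their precision and compared in
  zero-padded numeric form. Partial dates are never silently completed.
* **Deduplication.** Databases carry every follow-up version of a case.
  Per case identifier we keep the latest receipt date, breaking ties by
  the numerically largest report key. The operation is idempotent, and the
  synthetic generator's duplicate manifest verifies exact recovery.
* **Unit conversion.** Ages convert to years from their unit codes
  (decades ×10 through hours /8760); implausible results (>120 years)
  become missing rather than propagate. Weights convert to kilograms
  (pounds × 0.45359237).
* **Term exclusions.** Indication terms recorded as reactions (the treated
  disease itself) and administration-noise terms (off-label use,
  medication error, …) are stripped from event lists before analysis;
  reports left without events are dropped with logged counts.
* **Drug matching.** Queries match case-insensitive substrings of both the
  verbatim product name and the active-ingredient field, so combination
  products containing a queried ingredient are caught — the same rule the
  sensitivity stage uses to exclude co-medication reports.

## The four statistics

For each event, with `a` target-drug reports with the event, `b` without,
`c`/`d` the same cells for all other drugs, and `N = a+b+c+d`:

* **ROR** `= ad/bc`, interval `exp(log ROR ± 1.96·√(1/a+1/b+1/c+1/d))`
  (Woolf). Any zero cell triggers the Haldane–Anscombe +0.5 correction on
  all four cells, flagged in the output.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with the Yates-corrected
  `χ² = N(|ad−bc|−N/2)² / [(a+b)(c+d)(a+c)(b+d)]`, floored at zero for
  small deviations. `c = 0` yields an infinite PRR, reported as such with
  a flag rather than corrected away.
* **BCPNN IC**: the information component `log2` of the shrunk
  observed-to-expected co-reporting ratio, using the standard closed-form
  posterior expectation and variance with pseudo-counts
  (α₁ = β₁ = γ₁₁ = 1, α = β = 2); `IC025 = E(IC) − 2√V(IC)`. The closed
  form is validated in tests against hand evaluation and its structural
  limits (zero co-reports give negative IC; exact independence at large
  N gives IC ≈ 0).
* **MGPS EBGM**: the observed `a` is modeled as Poisson with rate `λE`,
  `E = (a+b)(a+c)/N`, and `λ` drawn from a two-component gamma mixture.
  Hyperparameters are fitted by marginal maximum likelihood (the implied
  negative-binomial mixture) over the database's whole event universe,
  with multi-start bounded quasi-Newton optimization, deterministic given
  a seed. `EBGM = 2^{E[log2 λ | a]}` — the posterior geometric mean, which
  is what the "EBGM05" naming convention presumes — and EBGM05 is the 5th
  posterior percentile found by bisection on the mixture CDF (tolerance
  1e-8). The closed-form posterior is tested against numerical integration
  of the posterior density to three decimals.

The shrinkage estimators are deliberately unstratified by default:
stratified expected counts change the question being asked, and the
package validates its default threshold behaviour against a published
SOC-level marker pattern that an unstratified analysis reproduces exactly.

### Positivity criteria

The default thresholds are the standard set used with these four
algorithms:

| algorithm | criterion |
|---|---|
| ROR | a ≥ 3 and CI lower bound > 1 |
| PRR | a ≥ 3, PRR ≥ 2, χ² ≥ 4 |
| BCPNN | IC025 > 0 |
| MGPS | a ≥ 3 and EBGM05 > 2 |

`positive_any` (at least one criterion) is the usual screening definition;
`positive_all` is the conservative intersection. Applied to a published
26-row SOC table shipped as a fixture, these thresholds reproduce the
printed positivity markers exactly — five ROR-positive classes, two
PRR-positive, one MGPS-positive, five BCPNN-positive, and exactly one
class positive on all four — which is the discriminating check among the
threshold variants in circulation.

## Time-to-onset model

Onset is the event date minus the earliest day-precision start date of a
matching drug entry. Records with partial or missing dates, non-positive
intervals, or intervals above a 3,650-day cap (a guard against date-entry
errors) are excluded with logged reasons; on real extracts only a minority
of reports carry complete dates, and the generator defaults emulate that
(16.7%).

Quantiles use one convention throughout: the inverse empirical CDF
(type 1), so the median and IQR are always observed values. This choice is
stated explicitly because published onset summaries rarely name their
percentile rule; with small samples the conventions differ, and exact
replication of any published median/IQR on other software is not claimed.

The Weibull model is fitted by maximum likelihood (via `fitdistrplus`),
with 95% intervals from the normal approximation on the log-parameter
scale. The shape β classifies the hazard: **early failure** when β < 1
with the whole interval below 1 (risk concentrated at treatment start),
**wear-out** when β > 1 with the interval above 1, **random** when the
interval contains 1. Because only reports with an observed event enter a
spontaneous-report store, there is no censoring and the
cumulative-incidence curve is the empirical CDF of observed onsets.

## Subgroups and sensitivity

Subgroup contrasts are computed within the target drug's reports: for each
of the K most frequent events (default 50), a 2×2 of event vs all-other
events crossed with target vs control stratum (female vs male, ≥65 vs
18–64, oral vs topical; reports missing the stratum are excluded). The
estimate is the crude stratified ROR with a Woolf interval — published
"adjusted ROR" outputs of this design are fully determined by the crude
table plus FDR adjustment, so no covariate model is imposed — and the
p-value comes from the Yates χ² test, falling back to Fisher's exact test
when any expected cell is below 5. Benjamini–Hochberg adjustment is
applied across the tested events (`fdr_adjust()`, verified against the
quadratic-time step-up definition).

The sensitivity stage re-runs the whole contingency + statistics path
after dropping every report that mentions a co-medication in any role;
the default list covers long-acting β₂-agonist mono-, dual- and
triple-therapy products and their components.

## The synthetic generator

`generate_reports()` draws reports independently: a multinomial drug
assignment (mild power-law popularity), event lists of truncated-Poisson
size (mean 2.9, minimum 1) sampled with replacement from the background
distribution and uniquified — matching the report-level counting unit —
with planted drug–event pairs getting their background probability
multiplied by the configured relative risk before renormalization.
Demographic marginals default to a profile typical of an oral respiratory
drug: gender 45.7/41.2/13.1% (male/female/missing), age missing 51.6%,
weight missing 73%, route 89.5/7.7/2.8% (oral/topical/other). Onset
intervals are Weibull(scale 27 days, shape 0.8) — an early-failure regime
whose median sits near two and a half weeks — rounded up to whole days,
attached to the 16.7% of reports carrying complete dates. A configurable
fraction of cases (default 10%) is emitted twice with an incremented
receipt date and a new report key, and a manifest records every planted
pair and duplicate.

What the generator does **not** emulate: reporting-volume dynamics over a
product's lifecycle (the Weber pattern), correlated event co-occurrence
within reports, drug–drug interaction signals, free-text name variants,
or conflicting-field duplicates (duplicates are exact clones apart from
key and date, since the deduplication rule resolves only on those
fields). Passing the generator-based tests therefore demonstrates the
correctness of the bookkeeping and the statistical machinery under a
clean generative model, not robustness to the full messiness of real
extracts.

## Problem sizes and numerical choices

The validation battery runs at the following scales, chosen to give the
binomial checks enough resolution while staying lightweight: null
calibration with 200 events × 100,000 reports × 100 generator seeds
(observed all-four false-positive rate ≈ 0); planted-signal recovery at
relative risk 5, background probability 0.01, 50,000 reports × 100 seeds
(recovery ≥ 95% required, 100% observed); Weibull shape recovery at
n = 1,000 × 20 seeds (mean estimate within ±0.1 of 0.8). Optimizer starts
for the gamma-mixture fit combine three fixed heuristics with seeded
jitter; ties and degenerate inputs are handled explicitly (empty strata
raise classed errors, infinite PRR and corrected ROR are flagged, events
with fewer than `min_count` target cases are dropped before fitting).
Rounding for report output is decimal half-up, matching published tables,
and never used internally.

## Known limitations

* The package reads the modern FAERS column set with a legacy-alias map;
  exotic historical dialects may need pre-mapping.
* MedDRA is licensed, so only a small fixture vocabulary ships; real
  analyses must supply their own PT→SOC table and label dictionaries.
* Label matching is exact after an explicit synonym map — no fuzzy
  matching; the medical-evaluation step of labeledness assessment cannot
  be automated responsibly.
* No interval-censored onset models and no covariate-adjusted
  (regression) disproportionality; both are out of scope by design.
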