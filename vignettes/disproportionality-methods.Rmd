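---
title: "Disproportionality analysis of spontaneous reports: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of spontaneous reports: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
unsolicited reports of suspected drug reactions. They have no denominator:
we never observe how many patients took a drug without an event, only how
often each (drug, event) combination was *reported*. Disproportionality
analysis works around this by asking whether an event is reported more
often with the study drug than the reporting pattern of the rest of the
database would predict. `faersignal` implements the standard four-method
workflow over FAERS-style quarterly ASCII extracts, plus a Weibull model
of onset timing, subgroup and sensitivity re-analyses, and a synthetic
report generator used to validate every stage against known ground truth.

## From raw tables to one 2×2 table per event

**Deduplication.** FAERS publishes every version of a case. Following the
FDA's recommended rule, we keep one row per `caseid`: the version with the
latest FDA receipt date, ties broken by the numerically highest
`primaryid`. If any version of a case carries an unparseable date the whole
case falls back to the primaryid-only comparison (with a warning) rather
than mixing a date comparison with missing values. The operation is
idempotent and is tested against a brute-force per-case argmax.

**Cohort.** A report enters the study cohort iff at least one drug record
has role `PS` (primary suspect) and a name matching the user dictionary
after uppercasing, trimming and whitespace collapsing. Matching is exact by
design — fuzzy matching would trade reproducibility for recall and make
the comparator set depend on a similarity threshold. All remaining reports
form the comparator ("rest of database").

**Counting unit.** Cells count unique (report, event-term) pairs: a report
listing the same PT twice counts once, and at SOC level a report counts
once per distinct SOC. This makes the database-wide total
`N = a + b + c + d` identical for every term and keeps the margins
additive, which is what all four statistics implicitly assume. Counting
reports instead of pairs would make `b` ill-defined for multi-event
reports. Every PT must map to exactly one primary SOC; an incomplete map
is a hard error listing the unmapped terms, never a silent drop.

## The four statistics

Writing `a, b, c, d` for the cells and `E = (a+b)(a+c)/N` for the expected
count under independence:

- **ROR** `= ad/(bc)`, CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`.
- **PRR** `= [a/(a+b)]/[c/(c+d)]`,
  `χ² = N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))` without Yates correction.
- **BCPNN information component**: closed-form posterior moments of
  `IC = log₂ p₁₁/(p₁. p.₁)` under Beta priors `α₁ = β₁ = 1`,
  `α = β = 2`, `γ₁₁ = 1`, with the joint prior parameter tied to the
  margins so independence gives IC = 0; `IC025 = E(IC) − 1.96·√V(IC)`.
- **MGPS/EBGM**: λ ~ mixture of Gamma(α₁, β₁) and Gamma(α₂, β₂) with
  weight P; observed count ~ Poisson(λE). The posterior is again a
  two-component gamma mixture; `EBGM = exp(E[ln λ])` and EBGM05 is the
  posterior 5th percentile, located by bisection on the mixture CDF to
  `|ΔCDF| < 10⁻⁹`.

Signal thresholds are the field-standard quartet: ROR needs `a ≥ 3` and CI
lower bound > 1; PRR needs `a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`; BCPNN needs
`IC025 > 0`; MGPS needs `EBGM05 > 2`. A term is a potential signal when at
least one method fires — the methods deliberately differ in conservatism,
with EBGM05 shrinking hardest at small counts. No multiple-testing
adjustment is applied: flags are per-method screening thresholds, not
hypothesis tests, and the downstream use is triage.

### Numerical choices

- **Zero cells.** ROR and PRR are undefined when a cell is zero. We apply
  the Haldane–Anscombe correction (+0.5 to *every* cell) whenever *any*
  cell is zero, for both statistics uniformly, and flag the row
  `corrected`. One uniform rule is easier to audit than per-statistic
  special cases; corrected rows are marked so a reviewer can discount
  them.
- **EBGM posterior weights** are computed from negative-binomial log
  masses with a log-sum-exp guard, so extreme counts cannot overflow.
- **IC** uses the closed-form (moment) formulation throughout; tests
  verify it against Monte-Carlo sampling of the Beta posteriors to
  < 0.05 bits for `a ≥ 5`.

### Fitting the MGPS prior

The five hyperparameters `(α₁, β₁, α₂, β₂, P)` are fitted by maximizing
the marginal likelihood over database-wide (drug, PT) cells — marginally
each count is a mixture of two negative binomials. Optimization runs on
log/logit-transformed parameters (Nelder–Mead, then BFGS polish) from the
conventional start `(0.2, 0.1, 2, 4, 1/3)`. Two regimes are supported:

- `include_zeros = FALSE` (default): only cells with `a ≥ 1` enter, and
  the likelihood is **zero-truncated** accordingly. Fitting observed-only
  cells with an untruncated likelihood would be mis-specified — at the
  conventional prior roughly 60% of unit-expectation cells are zeros.
- `include_zeros = TRUE`: all supplied cells enter with the plain mixture
  likelihood. This is the right estimator when the cell set genuinely
  contains the zeros (as in simulation studies), and is markedly better
  identified: in our recovery experiments (50,000 cells simulated from
  the start values, `E` log-normal) all five hyperparameters return
  within 10% of truth, whereas the truncated fit's MLE — verifiably the
  maximizer of its own likelihood — can sit ~40% away on the
  first-component shape at the same sample size.

The two-component prior is weakly identified when the data are truly
one-component; in that regime the fit reaches likelihood parity with the
generating values (tested) and the two components may merge — the EBGM
values, which depend on the prior only through the implied posterior, are
insensitive to this.

## Weibull time-to-onset

TTO = event onset date − earliest primary-suspect therapy start date, in
days. Only day-precision dates are used; partial dates (YYYYMM, YYYY) are
excluded rather than imputed, and non-positive gaps are dropped (the
log-likelihood is undefined at t = 0 for shape < 1). The attrition is
reported, mirroring the large drop from reported cases to TTO-eligible
cases seen in real extracts. Event onset (not report receipt) anchors the
gap; the DEMO `event_dt` field supplies it.

The two-parameter Weibull `f(t) = (β/α)(t/α)^{β−1} e^{−(t/α)^β}` is fitted
by MLE on `(ln α, ln β)` with 95% CIs from the observed Fisher
information on the log scale (positivity for free, better normal
approximation than the natural scale; likelihood-ratio CIs are out of
scope). Classification reads the shape CI: entirely below 1 →
*early failure* (decreasing hazard — onset risk front-loaded after
initiation), containing 1 → *random failure*, entirely above 1 →
*wear-out*. At the design size of the motivating analyses (n = 683,
scale ≈ 199 d, shape ≈ 0.63), 100-replicate recovery experiments classify
early failure in every replicate and cover both parameters at ≥ 94/100.

## Subgroups and sensitivity

Subgroup analyses restrict cohort *and* comparator to one stratum (sex,
age group, reporter type) before rebuilding tables, so `N` is recomputed
within stratum; stratified cells are additive over a partition (tested).
Two age-bin presets ship: `baseline` (`<18, 18–65, 65–85, >85`) matching
published baseline tables, and `subgroup` (`<18, 18–65, >65`) matching
published subgroup analyses; the boundary value 65 falls in the middle bin
in both. The sensitivity analysis removes any report listing a specified
co-medication in *any* drug role — suspect or concomitant — since
confounding-by-indication operates regardless of role assignment, and
reports retained case and (case, PT) pair counts.

## The synthetic generator

`simulate_faers()` emits a complete six-table database plus a ground-truth
manifest. It emulates the features the pipeline's correctness depends on:

- a study drug holding a configurable share (default 5%) of
  primary-suspect reports, comparator drugs Zipf-weighted;
- per-PT background reporting probabilities, default `0.3/√rank` so a
  report carries ~3 event terms on average (spontaneous reporting is
  heavy-tailed; reports list a handful of PTs);
- planted (drug, PT, rr) associations multiplying the background rate for
  the target cohort — the manifest records them, and empirical
  reporting-rate ratios recover the planted rr within sampling error;
- every report carries ≥ 1 reaction; the rare fallback draw uses the
  case's *own* probability vector (planting included) so conditioning
  does not dilute planted ratios;
- demographic marginals shaped like a published study-drug cohort
  (38% missing sex, 78% missing age, 85% US, 52% consumer-reported);
- onset gaps Weibull(198.63 d, 0.63) and a configurable fraction
  (default 10%) of month-precision therapy dates;
- duplicate case versions (default 10% of cases) perturbing *only*
  `fda_dt`/`primaryid`, so the dedup rule's correct answer is computable
  a priori and stored in the manifest.

What it does **not** emulate: drug-name misspellings, true FAERS volume
(11.6 M reports), correlated event co-reporting beyond shared SOC labels,
secular reporting trends, or masking/competition between signals. Passing
tests therefore demonstrate algorithmic correctness under the assumed
reporting model, not robustness to real-world coding noise.

`table1_fixture()` is deterministic: 9,090 cases whose marginal counts
equal a published cohort's baseline table exactly (the joint structure is
arbitrary), used to verify the summary layer reproduces printed
percentages after half-up rounding to one decimal — note base R's
`round()` rounds half to even, so the package carries its own
`round_half_up()`.

## Problem sizes used in validation

The shipped validation suite uses: 1,000-table random sweeps for the
closed-form statistics (tolerance 10⁻¹²); the grid `a ∈ 0..50 ×
E ∈ {0.1, 1, 10}` against an independent composite-Simpson quadrature of
the EBGM posterior (10⁻⁶); 50 random tables against a 10⁵-draw
Monte-Carlo IC oracle (0.05 bits); 50,000-cell MGPS recovery; 100 × 683
Weibull replicates; and a 10⁵-case planted-signal simulation with
`rr = 10` at expected `a ≈ 50`, flagged by all four methods. Null
(no-signal) simulations across five seeds report per-method flag rates as
a calibration table in the test log.

## Known limitations

- The comparator is the full remaining database; restricted comparators
  (same-class drugs) are not implemented.
- One primary SOC per PT; MedDRA's multiaxial linkage and HLT/HLGT levels
  are out of scope.
- No censoring-aware survival modelling: reports without an observed
  event never enter a spontaneous database, so TTO fits describe the
  onset distribution *among reported events* only.
- Signal thresholds and prior constants are conventions, not inferences;
  all are exposed as arguments (`signal_thresholds()`, `mgps_prior()`)
  so variant formulations can be swapped behind the same interface.
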