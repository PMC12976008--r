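# faersignal

Disproportionality signal detection for spontaneous adverse-event report
databases in the style of the FDA Adverse Event Reporting System (FAERS).

Pharmacovigilance teams mine spontaneous-report databases for drug safety
signals: adverse events reported disproportionately often with a drug of
interest relative to the rest of the database. `faersignal` implements that
workflow end to end for FAERS-style quarterly ASCII extracts — reading the
`$`-delimited DEMO/DRUG/REAC/THER/INDI/OUTC tables, deduplicating case
versions by the FDA rule, extracting the primary-suspect cohort, building
2×2 contingency tables at MedDRA preferred-term (PT) and system-organ-class
(SOC) level, computing four disproportionality statistics, modelling
time-to-onset with a Weibull distribution, and re-running everything in
demographic subgroups and under concomitant-drug exclusions. A synthetic
spontaneous-reporting generator with a full ground-truth manifest makes
every stage testable without the multi-gigabyte FAERS download.

## The statistics

For each (drug, event) pair the database reduces to a 2×2 table of unique
(report, event-term) pairs — `a` cohort reports with the event, `b` cohort
reports with other events, `c`/`d` the same for the comparator,
`N = a+b+c+d`:

- **ROR** — reporting odds ratio `ad/(bc)` with Wald 95% CI
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`; signal when `a ≥ 3` and the CI
  lower bound exceeds 1.
- **PRR** — proportional reporting ratio `[a/(a+b)]/[c/(c+d)]` with the
  Pearson statistic `χ² = N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))`; signal when
  `a ≥ 3`, `PRR ≥ 2` and `χ² ≥ 4`.
- **BCPNN IC** — Bayesian confidence propagation neural network
  information component `IC = log₂ p₁₁/(p₁.p.₁)` with closed-form
  posterior moments under the standard Beta priors; signal when the lower
  bound `IC025 > 0`.
- **MGPS EBGM** — multi-item gamma-Poisson shrinker: a two-component gamma
  mixture prior on the relative reporting rate λ (observed count
  ~ Poisson(λE), `E = (a+b)(a+c)/N`), fitted by maximum likelihood over
  all database cells; `EBGM = exp(E[ln λ])` is the shrunken
  observed-to-expected ratio and EBGM05 its posterior 5th percentile;
  signal when `EBGM05 > 2`.

An event is a *potential signal* when at least one method exceeds its
threshold. Time-to-onset (therapy start → event onset, days) is fitted by
a two-parameter Weibull MLE; a shape-parameter CI entirely below 1 marks
an **early-failure** hazard (risk concentrated after initiation).

## Worked example

```r
library(faersignal)

# synthetic database: 20,000 cases, study drug on 5% of reports,
# one planted association (pt_25, relative reporting ratio 6)
cfg <- sim_config(n_cases = 20000,
                  planted_signals = data.frame(drug = "STUDYDRUG",
                                               pt = "pt_25", rr = 6),
                  seed = 7)
sim <- simulate_faers(cfg)

db  <- apply_dedup(sim$data)                          # FDA dedup rule
sp  <- select_primary_suspect(db, drug_dictionary("STUDYDRUG"))
ct  <- count_pairs(sp$cohort, sp$comparator, level = "pt")
cells <- mgps_cells(db)                               # database-wide (a, E)
prior <- fit_mgps_prior(cells$a, cells$E)
sig <- detect_signals(ct, prior)
head(sig[order(-sig$ebgm), ], 3)
#>     term   a  ror ror_lo ror_hi  prr    chi2    ic   ic025  ebgm ebgm05 any_signal
#> 1  pt_25 371 6.01  5.321   6.80 5.43 1050.59 2.116  1.9468 4.351  3.993       TRUE
#> 10 pt_19  99 1.31  1.067   1.62 1.30    6.64 0.353  0.0566 0.999  0.997       TRUE
#> 11 pt_16  97 1.19  0.964   1.46 1.18    2.61 0.223 -0.0751 0.997  0.997      FALSE
```

The planted term tops the table: 371 cohort reports against ~85 expected,
ROR 6.0 (CI 5.3–6.8) close to the planted ratio, and all four methods
flag it. EBGM (4.35) sits below the raw ratio — the empirical-Bayes
shrinkage toward the database prior that stabilizes small counts.

```r
tto <- compute_tto(sp$cohort, drug_dictionary("STUDYDRUG"))
onset_summary(tto)
#>     n median    q1  q3
#> 1 920    104 24.75 314
fit_weibull_tto(tto)
#> Weibull time-to-onset fit (n = 920)
#>   scale alpha = 193.94 days (95% CI 174.39-215.68)
#>   shape beta  = 0.642      (95% CI 0.610-0.675)
#>   pattern: early_failure
```

The generator draws onset gaps from Weibull(scale 198.63 d, shape 0.63);
the fit recovers both parameters and classifies the hazard as early
failure (shape CI entirely below 1): onset risk is front-loaded after
therapy start. 920 of the 1,002 cohort reports had day-precision dates;
the rest are excluded, not imputed.

`run_pipeline()` chains all stages (baseline table, PT/SOC signal tables,
TTO, subgroups, sensitivity exclusion, attrition log) into one output
directory; `inst/cli/faersignal.R` exposes `simulate` and `report`
subcommands for shell use.

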