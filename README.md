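# mitomotor

Analysis toolkit for studies linking the gut microbiome, α-synuclein
pathology and brain mitochondrial function in mouse models of
Parkinson's disease. It is written for experimenters who collect four
kinds of tabular data — timed motor-test trials, enzymatic-activity
plates, qPCR triplicates, and Seahorse oxygen-consumption traces — and
need the bespoke statistics those data require, plus seeded synthetic
generators so every stage is testable without animal data.

## What it computes

**Motor latency.** Latency-to-complete data from beam-crossing and
pole-descent tests are censored at a 60-s ceiling: mice that fail are
scored 60 s. mitomotor models the latency as a right-censored lognormal
mixture,

    y' ~ ω·LogNormal(μ, σ) + (1 − ω)·δ_60,   y = min(y', 60),

where ω is the probability of completing the task. The likelihood has
two branches — ω·f(y) for uncensored trials, ω·(1 − F(60)) + (1 − ω)
for trials at the ceiling — and is maximized by multi-start BFGS with
an analytic gradient (`fit_mle()`). Confidence intervals come from a
parametric bootstrap (`parametric_bootstrap()`), model fit is assessed
with predictive-ECDF bands and Q-Q plots
(`predictive_ecdf_envelope()`), and group comparisons use per-animal
median latencies (`median_summary()`) with Kruskal–Wallis plus
Conover's or Dunn's post-hoc tests under Benjamini–Hochberg adjustment
(`kruskal_wallis()`, `conover_posthoc()`, `dunn_posthoc()`,
`bh_adjust()`), all implemented from the defining formulas with
mid-rank tie corrections.

**Mitochondrial bioenergetics.** From duplicate enzymatic assays
(Complexes I, II, IV and citrate synthase) and triplicate qPCR
(mitochondrial COX1 vs nuclear B2M), the package computes specific
activities, plate normalization against reference samples, cohort
mean-centering, mtDNA copy number (2^ΔCt × 2) and density, and the
composite indices

    MHI = (CI + CII + CIV) / (CS + mtDNA density + 1) × 100
    MRC = mean(√CI + √CII + √CIV) / mean(∛mtDNA density + ∛CS) × 100

on mean-centered features, so an animal at the cohort average scores
MHI = 100 exactly (`mito_features()`, `mhi()`, `mrc()`).

**Respirometry.** Injection-phased OCR traces (substrate → ADP →
oligomycin → FCCP → rotenone+antimycin A) become States 2/3/4o/3u after
non-mitochondrial subtraction and protein normalization, with
RCR = State 3 / State 4o, averaged over each mouse's quintuplicate
wells (`ocr_states()`). Group effects are tested with the 2×2 factorial
model `value ~ Genotype * Microbiome` and BH-adjusted pairwise
contrasts (`fit_two_factor()`, `pairwise_contrasts()`).

## Worked example

```r
library(mitomotor)

cfg    <- sim_config(seed = 42)          # 4 groups x 10 mice, 2 tests
trials <- simulate_trials(cfg)

aso <- subset(trials, genotype == "ASO" & condition == "SPF" & test == "pole")
fit <- fit_mle(aso)
fit
#> Right-censored lognormal mixture fit
#>   n = 24 trials (14 censored at 60 s)
#>   omega = 0.4172   mu = 2.7949   sigma = 0.4289
#>   logLik = -49.882   converged = TRUE   boundary = none

parametric_bootstrap(fit, n_replicates = 2000, seed = 42)
#>   parameter estimate lower upper level n_replicates n_failed seed
#> 1     omega    0.417 0.208 0.625  0.95         2000        0   42
#> 2        mu    2.795 2.522 3.081  0.95         2000        0   42
#> 3     sigma    0.429 0.204 0.614  0.95         2000        0   42
```

Only 42% of this group's pole trials end in completion (ω̂ = 0.42,
95% CI 0.21–0.63), and completers take exp(2.79) ≈ 16 s on a log-scale
spread of 0.43. Group comparison on per-animal medians:

```r
med <- median_summary(subset(trials, test == "pole"))
grp <- paste(med$genotype, med$condition, sep = ".")
kw  <- kruskal_wallis(med$median_latency_s, grp)   # H = 24.03, p = 2.5e-05
conover_posthoc(med$median_latency_s, grp, kw)
#>   group_a group_b statistic    p_raw     p_bh
#> 1  ASO.GF ASO.SPF     -4.43 8.51e-05 1.70e-04
#> 4 ASO.SPF   WT.GF      7.04 2.89e-08 1.73e-07
#> 5 ASO.SPF  WT.SPF      6.00 6.90e-07 2.07e-06
#> ...
```

The conventionally colonized (SPF) ASO group is slower than every other
group after BH adjustment, while germ-free ASO mice sit near wild type —
the synthetic generator's built-in effect direction. The bioenergetics
identity is immediate:

```r
mhi(1, 1, 1, 1, 1)   # all-average animal
#> [1] 100
```

## Analysis workflow

Numbered drivers under `analysis/` chain the package end to end on
synthetic data and write their tables under `results/`:

| script | output |
|---|---|
| `analysis/01_simulate.R` | `results/data/{trials,enzymes,qpcr,ocr}.csv` |
| `analysis/02_fit_latency.R` | per-group mixture fits + bootstrap CIs |
| `analysis/03_rank_tests.R` | medians, Kruskal–Wallis + Conover tables |
| `analysis/04_mito_index.R` | MHI/MRC features and factorial contrasts |
| `analysis/05_respirometry.R` | respiration states, RCR, contrasts |
| `analysis/06_run_all.R` | one-shot `run_pipeline()` with manifest |

`run_pipeline()` also accepts real CSV inputs in place of the
simulators; stages whose inputs are absent are skipped and recorded in
the JSON manifest.

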