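---
title: "Models and methods in mitomotor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mitomotor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomotor)
```

mitomotor bundles the quantitative analyses of a gut-microbiome x
alpha-synuclein mouse experiment: motor-latency modelling, rank-based group
inference, mitochondrial bioenergetics indices, and respirometry state
extraction, together with seeded generators that emulate each input. This
vignette documents the models, the numerical choices, and what the
synthetic data can and cannot show.

## The censored lognormal mixture for motor latencies

Timed motor tests (beam crossing, pole descent) are scored with a 60-s
ceiling: a mouse that does not finish is assigned 60 s. Averaging such
data conflates two different outcomes — failing outright and completing
slowly — so the latency is modelled as a two-component mixture,

$$y' \sim \omega\,\mathrm{LogNormal}(\mu, \sigma) +
  (1-\omega)\,\delta_{y_{60}}, \qquad y = \min(y', 60),$$

where $\omega$ is the probability that the mouse completes the task,
$(\mu, \sigma)$ are the log-scale location and scale of the completion
time, and $\delta_{y_{60}}$ is a point mass at the ceiling. An uncensored
trial contributes $\omega f_{LN}(y)$ to the likelihood; a trial recorded
at 60 contributes $\omega(1 - F_{LN}(60)) + (1-\omega)$. The model does
not — and cannot — distinguish a completion time beyond 60 s from an
outright failure; both are absorbed by the censored branch.

Key assumptions: trials are independent given the group (no per-animal
random effect), the completion-time distribution is lognormal, and the
mixture is defined at the trial level. Group fits therefore pool trials
across a group's animals by default; per-animal medians remain available
through `median_summary()` for the rank-based comparisons, which is also
how group differences are tested.

### Estimation

`fit_mle()` maximizes the likelihood over the unconstrained
reparameterization $(\mathrm{logit}\,\omega, \mu, \log\sigma)$ with BFGS
and a hand-derived analytic gradient. Because mixture likelihoods can be
multimodal, five deterministic starts are used — $\omega_0 \in \{0.25,
0.5, 0.9\}$ at $\sigma_0 = s$ plus $\omega_0 \in \{0.5, 0.9\}$ at
$\sigma_0 = 2s$, where $\mu_0$ is the log of the uncensored median and
$s$ the standard deviation of the uncensored log-latencies — and the best
negative log-likelihood wins. Two regimes bypass the optimizer because
the MLE is analytic: with zero censored trials the likelihood increases
monotonically in $\omega$, so $\hat\omega = 1$ (reported as a boundary)
and $(\hat\mu, \hat\sigma)$ are the closed-form lognormal MLE; with zero
uncensored trials $(\mu, \sigma)$ are unidentifiable and the fit is
declared degenerate instead of returning arbitrary values. An interior
optimum with $|\mathrm{logit}\,\omega| > 12$ is reported as the
corresponding boundary, exposing boundary cases rather than disguising
them as spurious interior estimates.

### Bootstrap intervals

`parametric_bootstrap()` simulates replicate datasets of the original
size from the fitted parameters, refits each, and takes percentile
intervals of the replicate MLEs — the simplest defensible interval when
the construction is "intervals from bootstrap replicates" without further
qualification. Replicate refits start from the parent estimate (the
replicates are drawn from that very model, so the parent MLE lies in the
refit's basin of attraction; the multi-start schedule is the fallback if
the warm start fails), which is what makes coverage simulations with
hundreds of thousands of refits tractable. All-censored replicates cannot
be refit; they are dropped and counted in `n_failed`. Each replicate
derives its own RNG stream from the master seed by a counter-based
scheme, so results do not depend on replicate order. At the study scale
the interval uses 10,000 replicates; the package's own validation
simulations use 500 replicates across 200 datasets of 300 trials, which
is sufficient to measure percentile-interval coverage to a few percent.

### Model assessment

`predictive_ecdf_envelope()` draws datasets from the fitted model and
returns a pointwise predictive band for the ECDF on the observed latency
grid, plus Q-Q points. Censored observations carry no quantile
information beyond their count, so the Q-Q plot pairs only the uncensored
order statistics with quantiles of the fitted completion distribution
truncated at 60 ($q_{LN}(p \cdot F_{LN}(60))$).

## Rank-based inference

`kruskal_wallis()`, `conover_posthoc()` and `dunn_posthoc()` are written
from the defining formulas with mid-ranks for ties throughout.
The Kruskal-Wallis H statistic is divided by the tie-correction factor
$1 - \sum(t^3 - t)/(N^3 - N)$; when every observation is identical this
factor vanishes and the test reports $H = 0$, $p = 1$ by convention.
Conover's pairwise t statistics use the pooled rank variance
$S^2 = (\sum R_i^2 - N(N+1)^2/4)/(N-1)$ and the factor $(N-1-H)/(N-k)$
with the tie-corrected H — the correction is used everywhere, so it is
used here too. Dunn's z statistics use the tie-corrected null variance
$N(N+1)/12 - \sum(t^3-t)/(12(N-1))$. All post-hoc p-values are two-sided
and adjusted by the step-up Benjamini-Hochberg rule (`bh_adjust()`),
with the family defined as all pairwise comparisons of one endpoint —
the conservative, reproducible reading when the family is not otherwise
specified. Conover's test follows a significant omnibus test on motor
endpoints; Dunn's variant is intended for endpoints with fewer than six
animals per group.

## Bioenergetics indices

Specific activity is the duplicate mean minus the non-specific control.
Negative specific activities are retained and flagged, never clamped:
clamping would bias the cohort mean that all downstream centering divides
by. Plate (batch) normalization multiplies each sample by
(grand reference mean)/(plate reference mean), computed per assay from
the five reference samples carried on every plate; the construction
equalizes cross-plate reference means exactly and is idempotent. The
exact form of the "derived normalization factor" is a design choice of
this package: a ratio of reference means is the simplest estimator that
removes a multiplicative plate effect.

Each of the five features (CI, CII, CIV, CS, mtDNA density) is
mean-centered by dividing by the cohort mean — the cohort being every
animal in the analysis run, not a single group, since the point of
centering is "relative to all other animals". The Mitochondrial Health
Index is then

$$\mathrm{MHI} = \frac{CI + CII + CIV}{CS + \text{mtDNA density} + 1}
  \times 100,$$

with the constant 1 a balancing third denominator term that is never
centered; an animal at the cohort average on all five features scores
exactly 100. The Mitochondrial Respiratory Capacity applies square roots
to the respiratory-chain terms (surface-area scaling of cristae-bound
complexes) and cube roots to the content markers (volume scaling):

$$\mathrm{MRC} = \frac{mean(\sqrt{CI}+\sqrt{CII}+\sqrt{CIV})}
  {mean(\sqrt[3]{\text{mtDNA density}}+\sqrt[3]{CS})} \times 100 .$$

The roots are applied to the mean-centered features, consistent with the
MHI; the cohort form averages before the ratio, and a per-animal variant
applies the ratio animal-wise — both are reported because the summary
level is a genuine choice.

mtDNA copy number is $2^{\Delta Ct} \times 2$ with $\Delta Ct$ the mean
nuclear Ct minus the mean mitochondrial Ct and the factor 2 accounting
for the diploid nuclear genome. Triplicate QC drops a single replicate
deviating more than 1 Ct from the replicate median (a standard qPCR
rule); at least two valid replicates are required and a post-QC spread
above 1 Ct raises a flag. mtDNA density is implemented exactly as the
index defines it, $2^{Ct} \times 10^{-12}$. That direction increases
with Ct while template abundance decreases with Ct; rather than silently
"fixing" the definition, the as-printed form is the default and
`direction = "inverse"` exposes the reciprocal reading
$2^{-Ct} \times 10^{12}$.

## Respirometry states

Isolated-mitochondria plates follow the injection order substrate →
ADP → oligomycin → FCCP → rotenone + antimycin A. Each phase is
summarized by the mean of its measurement cycles (quintuplicate wells
are averaged anyway, and a mean is robust on plateau-shaped traces,
whereas a last-cycle rule would discard most of the signal). The
rotenone + antimycin A residual is the non-mitochondrial rate; it is
subtracted from each phase by default — the standard treatment for
isolated mitochondria, exposed as a switch because subtraction is a
choice, not a law — and the corrected rates divided by the well's
protein mass give State 2 (substrate), State 3 (ADP), State 4o
(oligomycin) and State 3u (FCCP) in pmol O2/min/µg. Negative corrected
states are clamped to 0 with a flag: negative respiration is physically
meaningless, but the flag preserves auditability. RCR = State 3 /
State 4o is computed per well and then averaged across the mouse's
wells (the per-well ratio respects within-well pairing); the
ratio-of-averages alternative is available through `rcr_method`.

## Factorial analysis

Bioenergetic endpoints are analysed with ordinary least squares,
`value ~ Genotype + Microbiome + Genotype:Microbiome`, treatment-coded
with WT and SPF (or vehicle) as references; the saturated 2x2 model
reproduces cell means exactly. Pairwise contrasts are differences of
cell means with standard errors from the single pooled residual
variance — one homoscedastic model, no Welch variant — tested two-sided
on the residual degrees of freedom and BH-adjusted within the requested
family. The family must be named explicitly (`pairwise_contrasts()`
takes the pair list), because which of the six possible pairs belongs to
an endpoint's family is an analysis decision, not a package default.

## Synthetic data: what it emulates, and what it does not

`sim_config()` encodes the study design: four groups (WT/ASO x SPF/GF),
10 animals per group, 1–3 trials per mouse on two motor tests censored
at 60 s, duplicate enzyme wells with a non-specific control and five
reference samples on each of two plates, triplicate qPCR wells for a
mitochondrial and a nuclear amplicon, and five Seahorse wells per mouse
with 3 cycles per injection phase and 3–5 µg protein. Default effect
directions are qualitative: ASO.SPF mice have the lowest completion
probability ($\omega = 0.6$ vs 0.95 in WT) and the highest
ADP-stimulated and uncoupled respiration (about 1.3x WT), with ASO.GF
near WT — mirroring the direction, not the magnitude, of the biology
the analyses were designed for, since the magnitudes are properties of
animals, not of printed parameters.

The generators reproduce the statistical structure the analyses assume:
mixture latencies with exact 60-s censoring, multiplicative plate
effects uniform within plate, iid Ct noise around a generative
$\Delta Ct = \log_2(M/2)$, and phase-plateau OCR traces with iid cycle
noise. They deliberately omit features of real data — per-animal random
effects and learning across trials, heteroscedastic or drifting plate
noise, qPCR efficiency below 100%, Seahorse cycle-to-cycle drift and
edge-well artefacts. Passing tests on synthetic data therefore
demonstrate that the estimators recover the generative structure they
assume, not that real data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Optimizer: BFGS, `reltol = 1e-12`, analytic gradient; five
  deterministic starts (above); best NLL wins.
* Boundary convention: $|\mathrm{logit}\,\omega| > 12$ reports the
  boundary value.
* Likelihood: log-space accumulation with log-sum-exp in the censored
  branch; $\omega = 0$ with an uncensored trial yields $+\infty$, not an
  error.
* Identification: fewer than two distinct uncensored latencies is an
  error (with censored data present, $(\mu, \sigma)$ are not
  identifiable from one distinct value).
* Validation problem sizes: parameter recovery uses 200 datasets of 300
  trials at $(\omega, \mu, \sigma) = (0.7, \log 20, 0.4)$ with
  500-replicate bootstrap intervals; the rank tests are checked against
  independent direct-formula evaluations on 50 small instances to
  $10^{-9}$; the null rejection rate is measured over 2,000 draws.
* All randomness flows from one master seed expanded by fixed offsets
  (`seed_stream`), so every generator and every bootstrap replicate has
  an independent, reproducible stream and identical seeds give
  byte-identical CSV outputs.

## Known limitations

* No per-animal random effects: trials are pooled within group, so an
  animal contributing three trials weighs more than one contributing
  one. The median summary sidesteps this for the rank tests.
* Percentile bootstrap intervals can undercover near the $\omega = 1$
  boundary, where the replicate distribution piles up at 1.
* The Conover scaling factor $(N-1-H)/(N-k)$ can turn negative when H
  approaches its maximum; the statistics are then undefined (NaN), which
  the package propagates rather than masks.
* The MHI/MRC denominators assume positive centered features; cohorts
  containing flagged negative specific activities can make the indices
  undefined, and the flags say which animals to inspect.
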