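---
title: "Pleiotropy-robust Mendelian randomisation across clustered metabolite outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pleiotropy-robust Mendelian randomisation across clustered metabolite outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Observational associations between adiposity and blood metabolite
concentrations are confounded: diet, lifestyle and unmeasured physiology
drive both. Mendelian randomisation (MR) uses genetic variants associated
with the exposure as instrumental variables. Because genotypes are fixed at
conception, an instrument Z that (a) is associated with the exposure X,
(b) is independent of the confounders U, and (c) affects the outcome Y only
through X, identifies the causal effect of X on Y from purely observational
data.

`mrmetab` implements a complete individual-level MR pipeline for one
exposure (log body-mass index) against many correlated outcomes (log
metabolite concentrations): instrument quality control and selection,
several causal-effect estimators with different robustness properties,
hierarchical clustering of the outcomes, and cluster-level enrichment of
significant causal effects. Because suitable individual-level cohort data
are rarely redistributable, the package also contains a first-class
synthetic-cohort generator with full ground truth, and every stage of the
pipeline is validated against it.

## Structural model

All inference assumes linear, normal, additive structure. Writing Z_j for
the dosage (0/1/2 copies of the minor allele) of instrument j, the
generator — and, implicitly, the estimators — use

$$X = \mu_x + \textstyle\sum_j \gamma_j Z_j + \kappa_x U + a_x\,\mathrm{age} + s_x\,\mathrm{sex} + \varepsilon_x$$
$$Y_m = \mu_m + \beta_m X + \textstyle\sum_j \alpha_{jm} Z_j + \kappa_{y,m} U + a_y\,\mathrm{age} + s_y\,\mathrm{sex} + s_m\big(\sqrt{\rho_b} F_b + \sqrt{1-\rho_b}\, e_m\big)$$

with U a latent standard-normal confounder shared by exposure and all
outcomes, and F_b a latent factor shared by the outcomes of block b, which
produces the block-correlation structure that metabolite panels show
(lipoprotein subclasses move together). An instrument with any
$\alpha_{jm} \neq 0$ is *invalid* (violates condition (c)); $\beta_m$ is
the causal effect of interest, in log-concentration units per log-BMI unit.

## Estimators

Per instrument, age- and sex-adjusted least-squares slopes
$\hat\beta_{Xj}$ (exposure on Z_j) and $\hat\beta_{Yj}$ (outcome on Z_j)
are computed on complete cases; the per-instrument ratio
$\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates $\beta$ when instrument j is
valid.

* **IVW** — weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
  through the origin with weights $1/\mathrm{se}(\hat\beta_{Yj})^2$;
  algebraically the inverse-variance-weighted mean of the ratios.
  Consistent only when *all* instruments are valid.
* **Egger regression** — the same regression with a free intercept, after
  orienting every instrument so $\hat\beta_{Xj} \ge 0$. The slope is
  consistent for $\beta$ even when every instrument is pleiotropic,
  provided the direct effects are uncorrelated with instrument strength
  (InSIDE); the intercept estimates the mean directional pleiotropic
  effect, and its Wald test is the standard pleiotropy check.
* **Weighted median (WME)** — the interpolated median of the ratio
  estimates under weights $\hat\beta_{Xj}^2/\mathrm{se}(\hat\beta_{Yj})^2$,
  with cumulative-weight coordinates $p_j = (S_j - w_j/2)/S_\mathrm{tot}$.
  Consistent while valid instruments carry more than half of the weight.
  Its standard error comes from an individual-level bootstrap: subjects are
  resampled with replacement and all per-instrument regressions and the
  median are recomputed per replicate.
* **Invalid-instrument count** — an L1-penalised reformulation: after
  residualising on covariates and projecting onto the instrument space, the
  direct effects $\alpha$ are lasso-penalised with the causal effect
  profiled out, the penalty chosen by 10-fold cross-validation on the
  projected residual (conservative one-standard-error rule). The number of
  nonzero $\alpha_j$ estimates how many instruments violate condition (c),
  and the share of WME weight they carry is reported because the WME
  consistency condition is stated in terms of that share.

Numerical conventions, fixed for reproducibility: the residual variance in
the IVW/Egger weighted regressions is floored at 1 (overdispersion is
allowed, underdispersion is not); Egger p-values use a t reference with
J − 2 degrees of freedom by default (a normal reference is available via
`reference = "normal"`), while confidence intervals use normal quantiles,
the common convention in MR software; bootstrap-WME p-values use the
normal reference. Instruments with exactly zero exposure slope have no
defined ratio and are dropped from ratio/WME with a warning but retained in
IVW/Egger, where nothing is undefined. Bootstrap replicates in which an
instrument has zero dosage variance are redrawn up to ten times, then
skipped and counted.

## Instrument QC and selection

Filters run in a fixed, audited order with the conventional thresholds:
SNP call rate ≥ 0.95; subject call rate ≥ 0.95 (over the surviving SNPs);
orientation to the minor allele (dosage → 2 − dosage wherever the counted
allele frequency exceeds 0.5, frequency exactly 0.5 untouched); minor
allele frequency > 0.01; |signed Hardy-Weinberg statistic| < 4, where the
statistic is the signed square root of the 1-df goodness-of-fit chi-square
(positive for heterozygote excess); age/sex-adjusted exposure association
p ≤ 1e-5; and greedy LD pruning at pairwise dosage r² ≤ 0.05, visiting
survivors by ascending association p with lexicographic tie-break. Each
exclusion is recorded with its filter and value. The SNP call-rate filter
runs before the subject filter so that a single low-call SNP in a small
panel is attributed to the SNP, not to the subjects carrying its missing
calls; with genome-scale panels the order is immaterial.

Missing data are handled by complete-case analysis within each regression
and pairwise-complete correlations; the generator produces missingness
completely at random, which is the regime in which these simple choices
are unbiased. Chained-equation multiple imputation is deliberately out of
scope.

## Clustering and enrichment

Outcomes are clustered on the correlation distance
$D_{jk} = \sqrt{1 - R_{jk}^2}$ (sample Pearson correlation of
log concentrations, sign-blind so that strongly anti-correlated
metabolites are "close"), with Ward linkage in its squared-update
(`ward.D2`) form, cut at a user-chosen k — choosing k automatically is a
non-goal, since cluster counts in metabolomics are conventionally read off
a heatmap. A manual-override hook reassigns single named outcomes after
the cut, mirroring the occasional curation of a metabolite whose
correlation pattern straddles clusters.

Per outcome, the selected method's result (default WME) is summarised as a
signed score $\mathrm{sign}(\hat\beta)\,(-\log_{10} p)$ with a two-sided
significance flag at α = 0.05, deliberately unadjusted: the outcomes are
strongly correlated and the per-cluster aggregation below is the
inferential unit. Each cluster's 2×2 table (significant/not ×
inside/outside) is tested by one-sided hypergeometric tails — identical to
one-sided Fisher tests with fixed margins — for enrichment
(P(X ≥ a)) and depletion (P(X ≤ a)); Benjamini-Hochberg adjustment is
applied across clusters separately within each direction (the two
directions answer different questions; a pooled 2k family would mix them).

## Generator defaults and what they emulate

The defaults describe a biobank-style cohort analysed the way such studies
are: n = 2000 subjects, 18 instrument SNPs with minor-allele frequencies
spanning 0.02–0.50, 30 outcomes in 3 correlated blocks
(within-block residual correlation 0.6), sd(log BMI) = 0.15 around a mean
BMI of 26.5, outcome residual sd 0.3, a confounder explaining 9% of the
exposure and of each outcome, age ~ uniform(25, 74) and sex ~
Bernoulli(1/2) with small nonzero coefficients so the adjustment path is
always exercised.

Per-SNP instrument effects deserve a note. Instruments enter a study of
this design only by passing the p ≤ 1e-5 selection scan *in the analysis
cohort itself*, so their apparent strength is at least threshold-level by
construction — selection at that threshold in a cohort of a few hundred to
a few thousand subjects implies large apparent per-SNP effects (winner's
curse makes genome-wide-selected panels look strong in-sample even when
true effects are modest). The default effects are therefore
power-calibrated: each SNP has 90% power to pass the selection filter at a
reference size `power_n` (default 2000), accounting for the contribution
of the other instruments to the residual exposure variance. This single
choice makes the end-to-end pipeline self-consistent (the selection stage
retains the panel it is given) and puts the estimators in the regime where
their advertised asymptotic properties are visible at the simulated sample
sizes. A deliberately weak panel (instruments jointly explaining a few
percent of exposure variance, allocated inversely to heterozygosity) is
available through `instrument_r2` for studying weak-instrument behaviour;
with it, one-sample weak-instrument attenuation of Egger regression and
finite-sample spread of the ratio estimates become visible, which is
precisely why it is not the default test-bed.

Scenario presets fix the pleiotropy regime: `valid` (all α = 0),
`balanced_pleiotropy` (zero-mean α, sd 0.02), `directional_inside`
(α ~ N(0.05, 0.01), independent of γ so InSIDE holds),
`directional_violating_inside` (α correlated with γ), and `null_effect`
(β = 0). The pleiotropy sd values are chosen so that directional
pleiotropy dominates the per-SNP causal signal (mean α ≈ 2.5 × the typical
γβ) while the instrument-to-instrument scatter it adds to the Egger
regression stays small against the instrument-strength spread.

What the generator does *not* emulate: linkage disequilibrium between the
simulated instruments (the estimators assume independent instruments; the
LD-pruning code path is exercised on duplicated and derived columns
instead), non-normal or skewed concentration distributions, genotyping
batch structure, and informative missingness. Passing tests therefore
certify the statistical machinery under the model the methods themselves
assume, not robustness to violations of that model.

## Validation design and problem sizes

Every operation is tested against an independent oracle: explicit
normal-equations solves for the adjusted and weighted regressions, a
fine-grid CDF search for the weighted-median interpolant, allele-count and
hand-computed chi-square values for the QC statistics, exhaustive
combinatorial enumeration for every hypergeometric table with N ≤ 25, and
ground-truth recovery on simulated cohorts. Sampling-property checks use
200 replicate cohorts of n = 5000 (parameter recovery and interval
coverage), 200 × n = 20000 (Egger under directional pleiotropy),
200 × n = 10000 (weighted-median robustness with 7 of 18 instruments
invalid), 500 × n = 2000 (test size under the null, bootstrap B = 200),
100 × n = 2000 (bootstrap-SE calibration against the Monte-Carlo spread,
B = 500), and 20 seeds × n = 5000 (invalid-instrument recovery with three
planted direct effects of 0.1, about ten times their standard-error
scale). These sizes keep the full suite comfortably within a coffee break
on one CPU while leaving Monte-Carlo noise well inside the asserted
tolerance bands.

In the invalid-instrument robustness test the seven invalid instruments
are given one third of the default strength: weak-but-pleiotropic
instruments carry a small share of the weighted-median weight (the regime
in which the estimator's ≥50%-valid-weight condition is comfortably met)
while the IVW estimator, which weights pleiotropic displacement by
instrument strength regardless of validity, is visibly biased. With
invalid instruments carrying weight equal to the valid ones, no estimator
of this family stays within a ±0.05 band at these sample sizes — the
weighted median's breakdown is a weight condition, not a count condition,
and the test is designed to respect that.

## Known limitations

* One-sample MR: both regressions are computed on the same subjects, so
  weak-instrument bias pulls estimates towards the confounded
  observational slope rather than towards zero, and the Egger standard
  error is mildly conservative (the error in the two slope estimates is
  positively correlated, which the textbook variance formula ignores, and
  the residual-variance floor cannot shrink below 1). With the
  default selectable panel these effects are small; with `instrument_r2`
  panels they are the object of study.
* The bootstrap standard error of the weighted median runs some 10–20%
  above the true Monte-Carlo spread at n around 2000 (the usual behaviour
  of the nonparametric bootstrap for non-smooth, median-type statistics),
  so the normal-reference test built on it is conservative: its size at
  nominal 0.05 is nearer 0.02–0.03. Confidence intervals err on the wide
  side; no correction is applied because the plain bootstrap SD is the
  estimator this package documents.
* The hypergeometric enrichment null treats outcomes as exchangeable;
  correlated outcomes make it anti-conservative in principle. The package
  reports both directions with within-direction BH adjustment and leaves
  correlation-aware nulls out of scope.
* The invalid-instrument count inherits lasso behaviour: with the
  conservative CV rule it rarely over-selects, but weak direct effects
  (below the noise scale) are not detectable and are not counted.
* `power_n` below roughly 560 cannot calibrate 18 mutually-adjusting
  selectable instruments (the required per-SNP variance diverges); the
  generator refuses and points to `instrument_r2`.
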