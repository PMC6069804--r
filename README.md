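# mrmetab

Pleiotropy-robust Mendelian randomisation of one exposure (log body-mass
index) against many correlated outcomes (log metabolite concentrations),
from individual-level data.

Observational BMI-metabolite associations are confounded. Mendelian
randomisation (MR) sidesteps the confounding by using genetic variants as
instrumental variables: a variant Z associated with the exposure X,
independent of the confounders, and affecting the outcome Y only through X
identifies the causal effect of X on Y. With many instruments, each SNP j
contributes a ratio estimate β̂_Yj / β̂_Xj of the causal effect β, where
β̂_Xj and β̂_Yj are age- and sex-adjusted regression slopes of log BMI and
the log metabolite concentration on the SNP's 0/1/2 minor-allele dosage.
`mrmetab` implements the estimators built on those ratios:

* **IVW** — inverse-variance-weighted regression of β̂_Yj on β̂_Xj through
  the origin (consistent only if every instrument is valid);
* **Egger regression** — the same regression with a free intercept: the
  slope stays consistent under directional pleiotropy satisfying the
  InSIDE condition, and the intercept estimates the mean pleiotropic
  effect (its Wald test is the standard pleiotropy check);
* **Weighted median (WME)** — the interpolated weighted median of the
  ratios, consistent while valid instruments carry > 50 % of the weight,
  with a standard error from an individual-level bootstrap (subjects
  resampled with replacement, all regressions recomputed);
* an L1-penalised **invalid-instrument count** (lasso on the per-SNP
  direct effects with the causal effect profiled out, penalty chosen by
  10-fold cross-validation on the projected residual).

Around the estimators sit the standard stages of such an analysis:
instrument QC and selection (call rate ≥ 0.95, MAF > 0.01, |signed HWE
statistic| < 4, exposure association p ≤ 1e-5, greedy LD pruning at
r² ≤ 0.05, all audited), Ward clustering of the outcomes on the
correlation distance D = √(1 − R²), per-outcome signed significance scores
sign(β̂)·(−log10 p), and one-sided hypergeometric enrichment/depletion of
significant causal effects per cluster with Benjamini-Hochberg adjustment.
A synthetic-cohort generator with full ground truth (linear-additive
structural model with a latent confounder, block-correlated outcomes, and
preset validity scenarios) makes every stage testable end to end.

## Worked example

```r
library(mrmetab)

cfg <- mr_scenario("valid", n_subjects = 2000, n_outcomes = 30, seed = 42)
sim <- simulate_cohort(cfg)                       # genotypes + cohort + truth

inst <- select_instruments(sim$genotypes, sim$cohort)
inst
#> Instrument set: 18 SNPs retained, 0 excluded, 2000 subjects

ph <- sim$cohort
ex <- snp_summary_stats(inst$genotypes, log(ph$bmi), ph$age, ph$sex)
oy <- snp_summary_stats(inst$genotypes, log(ph$M001), ph$age, ph$sex)

egger_estimate(ex, oy)
#> MR egger estimate: 0.4442 (se 0.1819, p 0.0266) from 18 instruments
#>   intercept: -0.001664 (se 0.008224, p 0.842)

bootstrap_wme(inst$genotypes, ph, inst, "M001", B = 1000, seed = 1)
#> MR wme estimate: 0.4119 (se 0.09819, p 2.74e-05) from 18 instruments
```

The cohort was generated with a true causal effect of 0.3 on every
outcome: the Egger slope (0.44 ± 0.18) and weighted median (0.41 ± 0.10)
both cover it, and the Egger intercept (−0.0017, p = 0.84) shows no
evidence of directional pleiotropy — as it should, since this scenario has
none.

The whole pipeline (selection → per-outcome estimators → clustering →
enrichment, all tables plus a JSON manifest written to `out/`) is one
call:

```r
res <- run_analysis(analysis_config(sim$genotypes, sim$cohort,
                                    cluster_k = 3, seed = 7,
                                    output_dir = "out"))
head(res$enrichment)
```

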