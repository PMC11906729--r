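# gabaipdma

Pooling cortical GABA measurements across the lifespan, and modeling GABA
stability in the oldest-old.

## What this package is for

Edited magnetic resonance spectroscopy (MEGA-PRESS) quantifies cortical
GABA+ in units that differ by reference method (creatine vs water),
scanner and site, so participant-level measurements from different cohorts
cannot be pooled directly. `gabaipdma` implements an
individual-participant-data meta-analysis that harmonizes and models such
data jointly, plus the companion analyses used for cohorts of
cognitively-intact adults aged 85-99. It is aimed at researchers running
multi-site MRS aging studies who need a tested, reproducible pipeline from
raw participant tables to posterior trajectory summaries and predictive
model comparisons.

## The model at its core

For observation $i$ in dataset $d(i)$ with age $a_i$ and reported GABA
level $y_i$:

$$F_{d(i)}\,y_i \sim \mathrm{Normal}\Big(\textstyle\sum_{k=1}^{21}
\beta_k B_k(a_i),\ \sigma\Big),\qquad F_d = e^{\phi_d} > 0,$$

a penalized cubic B-spline on 19 evenly spaced knots
($\Delta^2\beta_k \sim \mathrm{Normal}(0,\tau)$, half-Normal priors on
$\tau,\sigma$, weak $\mathrm{Normal}(0, 0.5)$ penalty on $\phi_d$). The
feature scaling factor $F_d$ is the per-dataset multiplier bringing each
cohort into standardized units; after MCMC, draws are renormalized so the
scaled observations have geometric mean 1. The first derivative
$\sum_k \beta_k B_k'(a)$ is the velocity of GABA change with age. All
parameters are estimated simultaneously by a collapsed Gibbs/slice
sampler with rank-normalized split-$\widehat{R}$ and bulk/tail ESS
convergence gates.

For the oldest-old analyses the package fits Bayesian linear mixed models
(`GABA ~ age + fGM`, `GABA ~ age * sex + fGM`,
`MoCA ~ GABA + age + education`, alpha-corrected `GABA_w ~ age + fGM`)
with site random intercepts and slopes, and compares model variants with a
self-contained PSIS-LOO implementation (Pareto-smoothed importance
sampling leave-one-out cross-validation, with Pareto-$k$ reliability
diagnostics and the small-sample caveat surfaced as a flag).

Because the registry data behind the original analyses are not public,
the package ships a seeded synthetic generator whose defaults emulate the
study conditions (12 overlapping cohorts across ages 8-99; 4-site
oldest-old cohorts, N = 100, with the published demographic marginals);
every statistical claim in the test suite is a parameter-recovery or
oracle-equivalence statement on that generator.

## Worked example

```r
library(gabaipdma)

# 12 synthetic cohorts, known truth; fit, normalize, summarize
sim <- generate_lifespan_datasets(lifespan_truth(), seed = 101)
cfg <- run_config(n_chains = 4, n_iter = 2000, n_burnin = 1000, seed = 42)
fit <- normalize_draws(fit_lifespan_model(sim$data, cfg))

head(scaling_factor_summary(fit), 3)
#>        dataset_id log_fs_mean log_fs_lower_95 log_fs_upper_95   fs_mean
#> phi[1]        D01  -0.3699820      -0.4130092      -0.3264677 0.6909104
#> phi[2]        D02   0.2767894       0.2388579       0.3158385 1.3191504
#> phi[3]        D03  -0.3138586      -0.3497829      -0.2788914 0.7307434

dv <- summarize_curve(fit, kind = "derivative")
dv[dv$age %in% c(70, 85), ]
#>    age posterior_mean    lower_95      upper_95       kind
#> 11  70   -0.013977314 -0.02099260 -0.0076408407 derivative
#> 26  85   -0.007287639 -0.01429922 -0.0009703971 derivative
```

The log scaling factors separate by reference method (creatine-referenced
cohorts recover lower `log_fs_mean` than water-referenced ones, matching
how they were generated), and the posterior-mean velocity at age 85 is
about half that at age 70: the fitted trajectory flattens past the
generator's plateau onset at 80, with the uncertainty of the derivative
quantified by its credible band.

```r
# oldest-old cohort: recruitment manifest -> QC cascade -> mixed model
cohort <- generate_oldestold_cohort(seed = 11,
  extras = list(not_acquired = 42, qc_fail = 39, low_moca = 24, outlier = 1))
qc <- apply_exclusion_cascade(cohort$records, run_config())
nrow(qc$retained)
#> [1] 100

rec <- standardize_within_site(qc$retained, c("age", "gaba_cr", "fgm"))
fit_sex <- fit_lme(rec, oldestold_model_spec("age_sex"),
                   run_config(seed = 43))
subset(lme_summary(fit_sex), parameter == "b[age:sex_male]")
#>         parameter  estimate est_error lower_95  upper_95      rhat ess_bulk ess_tail
#> 5 b[age:sex_male] 0.5857531 0.1870768 0.220256 0.9521826 0.9999056 19226.85 18818.38
```

The cascade reduces the 206-row recruitment manifest to exactly 100
retained participants (42 never scanned, 39 visual-QC failures, 24 MoCA
at or below 22, 1 site-mean outlier, 0 fit-error exclusions), and the
mixed model recovers a positive age-by-sex interaction whose 95% credible
interval covers the generating value 0.58, with all convergence gates
(split-R-hat at most 1.05, bulk ESS at least 1000) passing at 4 chains x
10000 iterations.

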