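---
title: "Modeling cortical GABA across the lifespan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cortical GABA across the lifespan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabaipdma)
```

## The scientific problem

Magnetic resonance spectroscopy (MRS) quantifies cortical GABA+ in
*institutional units* that are not comparable across studies: a
creatine-referenced ratio is a number near 0.1, a water-referenced
concentration a number near 2-3, and scanner, sequence and voxel placement
add further multiplicative offsets. Pooling participant-level measurements
from many cross-sectional cohorts into one lifespan trajectory therefore
requires harmonization to a common scale, estimated jointly with the
trajectory itself so that uncertainty propagates. This package implements
that joint model, its derivative summaries, and the companion analyses for
oldest-old (85+) cohorts: Bayesian linear mixed-effects models with site
random effects, leave-one-out predictive comparison, and the
participant-retention pipeline that precedes them.

## The lifespan meta-analysis model

Observation $i$ with age $a_i$ belongs to dataset $d(i)$. With $y_i$ the
reported GABA+ level in that dataset's native units, the model is

$$F_{d(i)}\, y_i \sim \mathrm{Normal}\!\Big(\sum_{k=1}^K \beta_k
B_k(a_i),\; \sigma\Big), \qquad F_d = e^{\phi_d},$$

where $B_k$ is a cubic B-spline basis on 19 evenly spaced knots spanning
the pooled age range (boundary knots repeated, $K = 19 + 3 - 1 = 21$),
$\sigma$ is a single global error term on the harmonized scale, and $F_d$
is the dataset's *feature scaling factor* — the multiplier that brings its
institutional units onto the common scale. Smoothness is imposed by a
second-order random-walk (P-spline) penalty
$\Delta^2\beta_k \sim \mathrm{Normal}(0, \tau)$ with a diffuse
$\mathrm{Normal}(0, 10)$ anchor on the first two coefficients; the penalty
scale $\tau$ and the error $\sigma$ carry half-Normal(0, 1) priors, and the
log scales carry a weak $\mathrm{Normal}(0, 0.5)$ penalty that discourages
extreme scaling factors while guaranteeing $F_d > 0$ smoothly (rather than
through a hard truncation bound).

The model assumes that measurements within one dataset are mutually
comparable, that all datasets reflect a common underlying age trajectory,
and that the datasets' age ranges overlap — the readers and generators
enforce the overlap precondition, because a dataset with no age overlap
with any other has no information tying its scale to the rest.

### Likelihood placement of the scaling factors

Only the product "scaled data $\approx$ spline" is fixed by the model
idea; whether $F_d$ multiplies the data or divides the mean is a
convention. We use the proper change-of-variables form — equivalently
$y_i \sim \mathrm{Normal}(\mu_i / F_d,\, \sigma / F_d)$, i.e. the
scaled-data Normal plus the $\log F_d$ Jacobian. This choice matters: the
bare scaled-data likelihood without the Jacobian acquires a spurious drift
$-n \log c$ along the joint rescaling
$(F, \beta, \sigma) \to (cF, c\beta, c\sigma)$, which at realistic sample
sizes drags the posterior many orders of magnitude down in scale before
the weak $\phi$ prior stops it. With the Jacobian the rescaling ray is
*exactly* likelihood-flat: the data identify the curve's shape and the
datasets' relative scales, while the overall level is pinned only softly
by the $\phi$ prior and fixed by convention at reporting time (below).
`log_posterior(..., jacobian = FALSE)` exposes the bare form so the gap
itself is testable.

### Normalization convention

The harmonized scale is defined by the convention that the scaled
observations have geometric mean 1. `normalize_draws()` enforces it per
draw: compute $\log g = \overline{\phi_{d(i)} + \log y_i}$ over all
observations, subtract $\log g$ from every $\phi_d$, and divide $\beta$,
$\sigma$ and $\tau$ by $g$. Because the rescaling ray is likelihood-flat,
this is a pure relabeling — curve shape, credible intervals and scale
*ratios* are untouched. An alternative reading (constraining the geometric
mean of the $F_d$ themselves rather than of the scaled data) differs only
by a constant; we constrain the scaled data because that is the scale on
which the curve is drawn, and the truth mapping used by the recovery tests
applies the identical convention to the generating parameters.

### Sampler

The posterior is explored by a collapsed Gibbs scheme, written for this
package: $(\phi_1,\dots,\phi_D, \log\tau, \log\sigma)$ are updated one at
a time by Neal's stepping-out slice sampler under the marginal posterior
with $\beta$ integrated out analytically (the $\beta$ conditional is
Gaussian, so the marginal is available from two Cholesky factorizations),
after which $\beta$ is drawn exactly from that conditional. One additional
move per sweep — a Haar-measure group update that shifts all $\phi_d$
jointly while rescaling $\tau$ and $\sigma$ — traverses the
likelihood-flat ray at the prior scale; without it the overall level mixes
by a slow random walk and raw-parameter diagnostics fail even though
normalized summaries are already stable. Chains run sequentially from a
single seed, so fits are exactly reproducible. Any sampler meeting the
convergence gates would be conformant; this one is used because it is
deterministic, tuning-free, and fast for this model's structure.

Convergence is gated, not assumed: rank-normalized split-$\widehat R$ and
bulk effective sample size are computed for every parameter after
sampling, and the fit errors (listing the offending parameters) if any
exceeds $\widehat R \le 1.05$ or falls below the configured minimum ESS
(1000 by default).

### Curve and velocity summaries

`summarize_curve()` evaluates $\sum_k \beta_k B_k(a)$ — or its analytic
derivative $\sum_k \beta_k B_k'(a)$, the *velocity* of GABA change in
standardized units per year — on an age grid for every draw and reports the
pointwise posterior mean with equal-tailed 95% credible bounds. The
derivative summary defaults to a 1-year grid over ages 60-100 (clipped to
the knot range), the region where trajectory flattening is scientifically
at issue. Extrapolation beyond the knot range is refused rather than
returned.

## The oldest-old mixed-effects suite

Within a narrow age band (85-99) a linear model is deliberately preferred
to the spline: the constrained age range gives the nonparametric model
little to estimate and much to overfit. The models are Gaussian
mixed-effects regressions of GABA+/Cr (or alpha-corrected GABA+/H2O, or
MoCA) on standardized predictors, with a site random intercept and site
random slopes for the continuous predictors:

$$y_i \sim \mathrm{Normal}(X_i\beta + Z_i u_{s(i)},\ \sigma), \qquad
u_s \sim \mathrm{MultiNormal}(0,\ \mathrm{diag}(s)\, R\,
\mathrm{diag}(s)).$$

All continuous variables (outcome included) are centered and scaled within
site first — `standardize_within_site()` records the location/scale table
for exact back-transformation — and sex enters as an unstandardized 0/1
male indicator, so an age-by-sex coefficient reads as the male-specific
increment to the standardized age slope. Standardizing the outcome as well
as the predictors is one admissible reading of "all continuous variables";
it is the default here and can be avoided simply by passing unstandardized
columns.

Priors: fixed effects and residual SD are weakly informative,
$\beta \sim \mathrm{Normal}(0,1)$ and $\sigma \sim$ half-Normal(0, 1), on
the standardized scale. The random-effect SD and correlation priors are
a design choice of this package (the corresponding reference analyses do
not publish theirs): half-Normal(0, 1) SDs and an LKJ(2) shape prior on
$R$, weakly favoring identity. All four scales are exposed via
`model_spec(priors = ...)`.

The sampler again collapses aggressively: SDs, correlations and $\sigma$
are slice-sampled under the likelihood with $u$ integrated out (a
block-diagonal Woodbury identity makes each evaluation a single small
Cholesky), which sidesteps the funnel geometry that plagues
few-group hierarchical models; $\beta$ is drawn from its exact Gaussian
conditional with $u$ marginalized; $u$ is then drawn conditionally, and the
pointwise log-likelihood matrix is recorded *conditional on the sampled
site effects* — so the downstream LOO criterion is a conditional-on-site
criterion, the convention of the reference tooling for such models. An
integrated (marginal-over-site) LOO is out of scope.

`bayes_r2()` reports the per-draw ratio
$\mathrm{Var}(\text{fitted})/(\mathrm{Var}(\text{fitted}) + \sigma^2)$
with fitted values including the site effects; `conditional_effects_age_sex()`
returns population-level age-by-sex prediction bands with the gray matter
fraction held at its standardized mean.

## Model comparison and diagnostics

`psis_loo()` implements Pareto-smoothed importance sampling leave-one-out
cross-validation from first principles: per observation, importance ratios
proportional to the inverse likelihood; the largest 20% of ratios replaced
by expected order statistics of a generalized Pareto distribution fitted
to them by the Zhang-Stephens profile method (with the customary weak
regularization of the shape toward 0.5); weights truncated at the raw
maximum and self-normalized. Shape diagnostics above $k = 0.7$ attach a
warning. `compare_models()` reports
$\mathrm{elpd}_{\mathrm{diff}} = \sum_i (\mathrm{elpd}^a_i -
\mathrm{elpd}^b_i)$ with
$\mathrm{SE}_{\mathrm{diff}} = \sqrt{n\,\mathrm{Var}(\text{pointwise
diff})}$ — a normal approximation that is unreliable below $n = 100$
observations, so a small-sample warning flag is part of the result rather
than an afterthought.

`split_rhat()` and `ess()` follow the rank-normalized split formulation:
chains halved, fractional ranks mapped through the Normal quantile
function, potential scale reduction and Geyer-truncated
autocorrelation ESS computed on the transformed chains; tail ESS is the
minimum over indicator chains at the 5% and 95% quantiles. Constant chains
are reported as converged-but-degenerate via a `constant` flag instead of
`NaN`s.

## Quality control and tissue correction

`apply_exclusion_cascade()` fixes the retention pipeline's order:
not-acquired, visual QC failure, MoCA at or below 22 (retention requires
23+, the recommended cutoff for minimizing false-positive amnestic MCI
screens), site-mean GABA outliers, then spectral fit error. Decisions the
source narrative leaves open are resolved as explicit defaults: the
outlier rule is $|z| > 4$ SD (the narrative reports a single exclusion at
4.78 SD but states no rule; the threshold is configurable and the z-score
is logged), the z-score includes the candidate row (indistinguishable from
leave-one-out at realistic site sizes and matching the "from the site
mean" reading), and the fit-error rule is strictly greater than 15% (a row
at exactly the threshold is kept; the boundary is unobserved in the
source, which reports zero exclusions at this stage). Sites with fewer
than three eligible records skip the outlier test with a warning — their
SD estimate would be noise.

`alpha_correct()` applies the group-normalized tissue-composition
correction for water-referenced GABA,
$$\mathrm{corrected} = \mathrm{GABA_w} \cdot
\frac{\bar f_{GM} + \alpha \bar f_{WM}}{f_{GM} + \alpha f_{WM}},$$
with $\alpha = 0.5$ by default — the conventional gray:white GABA
visibility ratio, configurable because the source value is not printed.
The group-normalized form makes the cohort-average correction factor 1, so
corrected water-referenced values stay scale-comparable with uncorrected
ones. Whether a CSF term belonged in the original variant is unknowable
from the text; the implemented form uses the GM/WM fractions only.

## The synthetic test bed

The registry and legacy cohort data are not public, so the package's
evidence is parameter recovery on a generator whose defaults *are* the
study conditions:

* **Lifespan**: 12 cross-sectional datasets with overlapping age windows
  spanning ages 8-99, four of them oldest-old cohorts on 85-99, 60
  observations each; seven Cr-referenced datasets clustered at lower log
  scale than the five water-referenced ones (so the recovered
  $\log F_s$ reproduce the reference-method clustering); noise SD 0.12 on
  a curve of magnitude ~1 (a realistic 10-15% coefficient of variation for
  edited MRS GABA). The true curve is a smooth double-logistic — rise to
  an early-adult peak near 27, monotone decline, flattening after a
  plateau-onset parameter at 80. The family is a free choice (only the
  fitted curve's qualitative shape is documented anywhere); a
  double-logistic is the simplest smooth family containing all three
  features, and it is deliberately *not* in the spline span, so curve
  recovery is tested under realistic approximation error. Noise is added
  on the standardized scale and then divided by $F^*_d$, keeping
  $\sigma$ interpretable as the model's global error term; positivity is
  enforced by resampling the noise.
* **Oldest-old cohort**: four sites with retained-quality counts
  34/18/28/20 (N = 100), age uniform on 85-99, voxel gray matter fraction
  Normal(0.42, 0.05), 41% male, MoCA a rounded Normal(25.5, 1.9) floored
  at 23 for retained records, and a standardized GABA outcome with fixed
  effects matching the reported oldest-old magnitudes (age -0.18, fGM
  0.14, sex 0.25, age-by-sex 0.58), site SDs ~0.2-0.3, residual SD 0.96.
  The MoCA-GABA slope defaults to 0 — the null association is the
  generator's reference condition — but is configurable for power studies.
  A cascade-exercise mode appends records engineered to fail each QC
  stage, reproducing the published recruitment arithmetic
  (206 recruited = 42 never scanned + 39 QC failures + 24 low MoCA + 1
  site outlier + 100 retained).

What the generator does *not* emulate: spectral physics (fit errors are
drawn from a plausible distribution, not simulated from spectra),
item-level MoCA structure, covariate-dependent missingness, and
dataset-specific age distributions beyond uniform windows. Passing
recovery tests therefore demonstrates correctness of the estimation
machinery under the stated model, not robustness to every way real
multi-site data can deviate from it.

### Nested predictive comparisons

"Including age as a predictor" is read as the population-level (fixed)
effect: the reduced model in each LOO comparison drops only the fixed
term and keeps the random-effects structure identical (a random slope
without its fixed counterpart is a legal and standard mixed-model
specification). Comparing models that differ simultaneously in fixed and
random structure would conflate two questions — and, concretely, the
extra unidentified site slopes in the fuller model carry a systematic
conditional-LOO overfitting penalty of one to two elpd units with a small
standard error, which would make even a true null look decisively
"resolved". With the random structure shared, the null comparison behaves
like its reference: elpd differences of a few tenths with comparable
standard errors. The "no age effect" generator scenario zeroes exactly
the age terms (the fixed age effect and the age-by-sex interaction) and
leaves every other study condition — the sex effect, which the age/fGM
models do not adjust for, and the site random slopes — at its default.
Zeroing more than that produces an unrealistically sterile null: with no
residual heterogeneity beyond pure noise, the pointwise elpd differences
of the nested pair become almost deterministic, their standard error
collapses, and the systematic one-parameter overfitting penalty
(~0.5-1 elpd) dominates any interval test, which is a statement about the
scenario rather than about the comparison machinery.

## Numerical and scale choices

* Problem sizes: the full-scale recovery fits use 12 x 60 lifespan
  observations with 4 chains x 2000 iterations (half burn-in), and the
  N = 100 cohort with 4 chains x 10000/5000 — the latter being the
  published MCMC settings. Replicate-based properties (interval coverage,
  null-comparison rates) run on reduced fits (2 chains, a few hundred
  retained draws, smaller cohorts) chosen so the whole suite completes on
  a single CPU in minutes while the Monte Carlo error stays well inside
  the asserted margins.
* Slice sampling uses stepping-out widths of 0.05-0.6 on the scale of each
  parameter; widths affect efficiency only, not the stationary
  distribution.
* The smoothing scale has a numerical floor of $\tau \ge 10^{-3}$ (in
  standardized GABA units): below it the penalty precision
  $D^\top D/\tau^2$ is conditioned beyond Cholesky range, and for data on
  a curve of magnitude ~1 any smaller value is already an
  effectively-flat-curve fit, so the floor is statistically inert. It
  binds only in degenerate scenarios such as an exactly constant true
  curve.
* Degenerate inputs fail loudly and early: nonpositive ages or GABA,
  disjoint age windows, zero within-site SDs, constant design columns,
  extrapolation beyond the knot range, double normalization, non-finite
  log-likelihood matrices.
* Ties in the rank normalization are averaged; constant chains short-cut
  to flagged values rather than dividing by zero.
* The exclusion cascade is single-pass by construction; re-running it on
  its own output excludes nobody under the generator's conditions, and
  count conservation (input = retained + logged exclusions) is asserted
  inside the function.

## Known limitations

* MoCA is modeled as a continuous Gaussian outcome despite integer
  support and a hard screening floor; this matches the linear-model
  convention for the cognition analyses but is a recognized
  simplification.
* LOO is conditional on sampled site effects; predictive statements are
  about observations from the *observed* sites.
* The spline model estimates one global $\sigma$; heteroscedasticity
  across datasets is absorbed into, not separated from, the scaling
  factors' posteriors.
* With only 4 sites, random-effect SDs and especially correlations are
  prior-dominated; their posteriors should be read as regularized
  summaries, not as estimates of between-site variance components.

## A worked example

```{r example, eval = FALSE}
library(gabaipdma)

# lifespan meta-analysis on synthetic multi-site data
sim <- generate_lifespan_datasets(lifespan_truth(), seed = 101)
cfg <- run_config(n_chains = 4, n_iter = 2000, n_burnin = 1000, seed = 42)
fit <- normalize_draws(fit_lifespan_model(sim$data, cfg))
summarize_curve(fit, kind = "derivative")
scaling_factor_summary(fit)

# oldest-old cohort: QC, standardization, mixed model, LOO comparison
cohort <- generate_oldestold_cohort(seed = 11,
  extras = list(not_acquired = 42, qc_fail = 39, low_moca = 24, outlier = 1))
qc <- apply_exclusion_cascade(cohort$records, run_config())
rec <- standardize_within_site(qc$retained, c("age", "gaba_cr", "fgm"))
fit_sex <- fit_lme(rec, oldestold_model_spec("age_sex"),
                   run_config(seed = 43))
lme_summary(fit_sex)
bayes_r2(fit_sex)
```
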