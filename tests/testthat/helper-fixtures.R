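# Shared fixtures, built in code. Expensive fits are cached per test run so
# several test blocks can interrogate the same posterior.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, build(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# A small 5-dataset lifespan problem and its fitted, normalized posterior.
small_lifespan_truth <- function(sizes = rep(30L, 5L)) {
  lifespan_truth(
    dataset_sizes = sizes,
    dataset_age_ranges = list(c(8, 40), c(30, 60), c(50, 80),
                              c(70, 95), c(85, 99)),
    reference_method = c("Cr", "water", "Cr", "water", "Cr"))
}

small_lifespan_sim <- function(seed = 2) {
  cached(paste0("lifespan_sim_", seed),
         function() generate_lifespan_datasets(small_lifespan_truth(), seed))
}

small_spline_cfg <- function(seed = 3) {
  run_config(n_chains = 2, n_iter = 500, n_burnin = 250, seed = seed,
             ess_min = 50, rhat_max = 1.2)
}

small_spline_fit <- function(seed = 3) {
  cached(paste0("spline_fit_", seed), function() {
    sim <- small_lifespan_sim()
    normalize_draws(fit_lifespan_model(sim$data, small_spline_cfg(seed),
                                       on_gate_failure = "warn"))
  })
}

# Truth targets for log F_s in the model's reporting convention (scaled
# observations have geometric mean 1): log F* minus the log geometric mean
# of the realized standardized signal.
lifespan_targets <- function(sim) {
  d_idx <- match(sim$data$dataset_id, sort(unique(sim$data$dataset_id)))
  log_g0 <- mean(log(sim$data$gaba) + sim$truth$log_scales[d_idx])
  list(log_fs = sim$truth$log_scales - log_g0, log_g0 = log_g0)
}

# A small standardized oldest-old cohort and a quick mixed-model fit.
small_cohort <- function(seed = 5, truth = cohort_truth()) {
  generate_oldestold_cohort(truth, seed = seed)
}

standardized_cohort <- function(seed = 5, truth = cohort_truth()) {
  sim <- small_cohort(seed, truth)
  standardize_within_site(sim$records, c("age", "gaba_cr", "fgm"))
}

small_lme_cfg <- function(seed = 7, n_iter = 800, n_burnin = 300) {
  run_config(n_chains = 2, n_iter = n_iter, n_burnin = n_burnin, seed = seed,
             ess_min = 50, rhat_max = 1.2)
}

small_lme_fit <- function() {
  cached("lme_fit_small", function() {
    fit_lme(standardized_cohort(), oldestold_model_spec("age_sex"),
            small_lme_cfg(), on_gate_failure = "warn")
  })
}

# Conjugate Normal toy model (y_i ~ N(mu, 1), mu ~ N(0, 1)): posterior
# draws, pointwise log-likelihood, and the exact leave-one-out elpd by n
# closed-form refits -- the independent oracle for PSIS-LOO.
normal_toy <- function(n = 30, n_draws = 4000, seed = 1) {
  set.seed(seed)
  y <- stats::rnorm(n, 0.3, 1)
  post_prec <- n + 1
  mu <- stats::rnorm(n_draws, sum(y) / post_prec, 1 / sqrt(post_prec))
  loglik <- vapply(y, function(yi) stats::dnorm(yi, mu, 1, log = TRUE),
                   numeric(n_draws))
  exact <- sum(vapply(seq_len(n), function(i) {
    prec_i <- n                     # refit without observation i
    stats::dnorm(y[i], sum(y[-i]) / prec_i, sqrt(1 + 1 / prec_i), log = TRUE)
  }, numeric(1)))
  list(y = y, loglik = loglik, exact_loo = exact)
}

# Participant records where every row passes all QC stages.
clean_records <- function(n = 10, site = "Site1") {
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)), site = site,
    age = seq(86, 95, length.out = n), sex = rep(c("male", "female"),
                                                 length.out = n),
    gaba_cr = 0.10 + 0.01 * sin(seq_len(n)), gaba_w = 2.5,
    fgm = 0.42, fwm = 0.38, fcsf = 0.20, moca = 26,
    education_years = 16, fit_error_pct = 6,
    qc_visual_pass = TRUE, acquired = TRUE, stringsAsFactors = FALSE)
}
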