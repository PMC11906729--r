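test_that("model specs enforce their structural invariants", {
  # a random slope without a fixed counterpart is allowed (nested
  # comparisons keep the random structure), but its column must exist
  ok <- model_spec("gaba_cr", "fgm", random_slopes = c("age", "fgm"))
  expect_s3_class(ok, "lme_spec")
  bad_col <- model_spec("gaba_cr", "fgm", random_slopes = "not_a_column")
  expect_error(fit_lme(standardized_cohort(), bad_col, small_lme_cfg()),
               "not_a_column")
  spec <- oldestold_model_spec("age_sex")
  expect_equal(spec$outcome, "gaba_cr")
  expect_true("sex" %in% spec$fixed)
  rec <- standardized_cohort()
  rec$constant_col <- 1.5
  bad <- model_spec("gaba_cr", c("age", "constant_col"))
  expect_error(fit_lme(rec, bad, small_lme_cfg()), "constant")
  one_site <- rec[rec$site == "Site1", ]
  expect_error(fit_lme(one_site, oldestold_model_spec("age_fgm"),
                       small_lme_cfg()), "2 sites")
})

test_that("the generating age-by-sex interaction is recovered within its
           own credible interval", {
  fit <- small_lme_fit()
  s <- lme_summary(fit)
  row <- s[s$parameter == "b[age:sex_male]", ]
  expect_gt(row$upper_95, 0.58 - 1e-9)
  expect_lt(row$lower_95, 0.58 + 1e-9)
  expect_gt(row$estimate, 0)         # direction is identified
  # monitored layout mirrors the reporting tables
  expect_true(all(c("sd[Intercept]", "sd[age]", "sd[fgm]",
                    "cor[age,fgm]", "sigma") %in% s$parameter))
  expect_true(all(abs(s$estimate[grep("^cor\\[", s$parameter)]) <= 1))
  expect_true(all(s$estimate[grep("^sd\\[", s$parameter)] >= 0))
})

test_that("an empty likelihood returns the prior", {
  cfg <- run_config(n_chains = 2, n_iter = 1300, n_burnin = 300, seed = 61,
                    ess_min = 50, rhat_max = 1.2)
  fit <- fit_lme(standardized_cohort(), oldestold_model_spec("age_fgm"),
                 cfg, on_gate_failure = "none", prior_only = TRUE)
  flat <- gabaipdma:::draws_matrix(fit)
  for (b in grep("^b\\[", colnames(flat), value = TRUE)) {
    ks <- stats::ks.test(flat[, b], "pnorm")
    expect_lt(unname(ks$statistic), 0.05)
  }
  ks_sig <- stats::ks.test(flat[, "sigma"],
                           function(q) 2 * stats::pnorm(q) - 1)
  expect_lt(unname(ks_sig$statistic), 0.05)
})

test_that("shifting a predictor before within-site standardization leaves
           the fit unchanged", {
  sim <- small_cohort()
  shifted <- sim$records
  shifted$age <- shifted$age + 7
  rec1 <- standardize_within_site(sim$records, c("age", "gaba_cr", "fgm"))
  rec2 <- standardize_within_site(shifted, c("age", "gaba_cr", "fgm"))
  expect_equal(rec1$age, rec2$age, tolerance = 1e-12)
  f1 <- fit_lme(rec1, oldestold_model_spec("age_fgm"),
                small_lme_cfg(62, 300, 100), on_gate_failure = "none")
  f2 <- fit_lme(rec2, oldestold_model_spec("age_fgm"),
                small_lme_cfg(62, 300, 100), on_gate_failure = "none")
  expect_equal(f1$draws, f2$draws, tolerance = 1e-9)
})

test_that("duplicating every record shrinks fixed-effect posteriors", {
  rec <- standardized_cohort()
  doubled <- rbind(rec, rec)
  cfg <- small_lme_cfg(63, 500, 200)
  f1 <- fit_lme(rec, oldestold_model_spec("age_fgm"), cfg,
                on_gate_failure = "none")
  f2 <- fit_lme(doubled, oldestold_model_spec("age_fgm"), cfg,
                on_gate_failure = "none")
  s1 <- lme_summary(f1); s2 <- lme_summary(f2)
  for (b in c("b[age]", "b[fgm]")) {
    expect_lt(s2$est_error[s2$parameter == b],
              s1$est_error[s1$parameter == b])
  }
})

test_that("stored pointwise log-likelihoods are consistent with the draws", {
  fit <- small_lme_fit()
  flat <- gabaipdma:::draws_matrix(fit)
  uflat <- gabaipdma:::draws_matrix(list(draws = fit$u_draws))
  des <- fit$design
  q <- ncol(des$Z); S <- nlevels(des$site)
  site_idx <- as.integer(des$site)
  for (dr in c(1L, nrow(flat) %/% 2L, nrow(flat))) {
    beta <- flat[dr, grep("^b\\[", colnames(flat))]
    u <- matrix(uflat[dr, ], S, q, byrow = TRUE)
    fitted <- as.vector(des$X %*% beta) +
      rowSums(des$Z * u[site_idx, , drop = FALSE])
    ll <- stats::dnorm(des$y, fitted, flat[dr, "sigma"], log = TRUE)
    expect_equal(unname(fit$loglik[dr, ]), unname(ll), tolerance = 1e-10)
  }
  expect_true(all(is.finite(fit$loglik)))
})

test_that("Bayesian R-squared matches its degenerate limits and a known
           variance split", {
  fit <- small_lme_fit()
  # degenerate copies: zero residual SD => R2 = 1; constant fit => R2 = 0
  zero_sig <- fit
  zero_sig$draws[, , "sigma"] <- 1e-12
  expect_equal(bayes_r2(zero_sig)$mean, 1, tolerance = 1e-6)
  flatfit <- fit
  flatfit$draws[, , grep("^b\\[", dimnames(fit$draws)[[3]])] <- 0
  flatfit$u_draws[] <- 0
  expect_equal(bayes_r2(flatfit)$mean, 0, tolerance = 1e-12)

  # generator with variance split 0.2 / 0.8 at large n
  tr <- cohort_truth(beta_age = 0.5, beta_fgm = 0, beta_sex = 0,
                     beta_age_sex = 0, site_sd_intercept = 0,
                     site_sd_age = 0, site_sd_fgm = 0, sigma_resid = 1)
  sim <- generate_oldestold_cohort(tr, n_per_site = rep(500L, 4L), seed = 64)
  rec <- standardize_within_site(sim$records, c("age", "gaba_cr", "fgm"))
  f <- fit_lme(rec, oldestold_model_spec("age_fgm"),
               small_lme_cfg(65, 400, 150), on_gate_failure = "none")
  r2 <- bayes_r2(f)
  expect_equal(r2$mean, 0.5^2 / (0.5^2 + 1), tolerance = 0.05)
})

test_that("conditional age-by-sex effects follow the printed-coefficient
           arithmetic", {
  fit <- small_lme_fit()
  inj <- fit
  inj$draws[, , "b[(Intercept)]"] <- 0
  inj$draws[, , "b[age]"] <- -0.18
  inj$draws[, , "b[sex_male]"] <- 0.25
  inj$draws[, , "b[age:sex_male]"] <- 0.58
  ce <- conditional_effects_age_sex(inj, n_grid = 11)
  male <- ce[ce$sex == "male", ]; female <- ce[ce$sex == "female", ]
  slope_m <- diff(male$posterior_mean[c(1, 11)]) / diff(male$age[c(1, 11)])
  slope_f <- diff(female$posterior_mean[c(1, 11)]) /
    diff(female$age[c(1, 11)])
  expect_equal(slope_m, -0.18 + 0.58, tolerance = 1e-9)  # male slope 0.40
  expect_equal(slope_f, -0.18, tolerance = 1e-9)
  # zero interaction: parallel lines
  inj$draws[, , "b[age:sex_male]"] <- 0
  ce0 <- conditional_effects_age_sex(inj, n_grid = 11)
  gap <- ce0$posterior_mean[ce0$sex == "male"] -
    ce0$posterior_mean[ce0$sex == "female"]
  expect_lt(max(gap) - min(gap), 1e-9)
  # real fit: bands widen at the age extremes relative to the center
  ce_real <- conditional_effects_age_sex(fit, n_grid = 11)
  m <- ce_real[ce_real$sex == "female", ]
  width <- m$upper_95 - m$lower_95
  expect_gt(width[1], width[6])
  expect_gt(width[11], width[6])
  f_noint <- fit_lme(standardized_cohort(), oldestold_model_spec("age_fgm"),
                     small_lme_cfg(66, 300, 100), on_gate_failure = "none")
  expect_error(conditional_effects_age_sex(f_noint), "interaction")
})

test_that("fixed-effect credible intervals attain nominal coverage across
           null replicates", {
  tr <- cohort_truth(beta_age = 0, beta_fgm = 0, beta_sex = 0,
                     beta_age_sex = 0)
  covered <- matrix(NA, 8, 2)
  for (i in 1:8) {
    sim <- generate_oldestold_cohort(tr, seed = 800 + i)
    rec <- standardize_within_site(sim$records, c("age", "gaba_cr", "fgm"))
    f <- fit_lme(rec, oldestold_model_spec("age_fgm"),
                 small_lme_cfg(900 + i, 400, 150), on_gate_failure = "none")
    s <- lme_summary(f)
    for (j in seq_along(c("b[age]", "b[fgm]"))) {
      b <- c("b[age]", "b[fgm]")[j]
      covered[i, j] <- s$lower_95[s$parameter == b] <= 0 &&
        s$upper_95[s$parameter == b] >= 0
    }
  }
  expect_gte(sum(covered), 13)   # ~95% nominal over 16 intervals
})
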