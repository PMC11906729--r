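#' Ground truth for the synthetic oldest-old cohort
#'
#' Fixed effects are on the standardized scale (continuous covariates
#' z-scored, sex a 0/1 male indicator), matching how the mixed models are
#' reported. Defaults mirror the magnitudes of the oldest-old age-by-sex
#' model: a male-specific positive age slope with a small negative female
#' slope, modest site heterogeneity, and residual SD near 1.
#'
#' @param beta_age,beta_fgm,beta_sex,beta_age_sex Standardized fixed effects
#'   on the GABA outcome.
#' @param site_sd_intercept,site_sd_age,site_sd_fgm Between-site SDs of the
#'   random intercept and slopes.
#' @param re_corr 3x3 correlation matrix of the site effects
#'   (intercept, age, fGM); must be symmetric positive-definite with unit
#'   diagonal.
#' @param sigma_resid Residual SD on the standardized scale.
#' @param moca_gaba_slope Points of MoCA per standardized unit of GABA
#'   (default 0: no GABA-cognition association in the generator).
#' @return An object of class `cohort_truth`.
#' @export
cohort_truth <- function(beta_age = -0.18, beta_fgm = 0.14, beta_sex = 0.25,
                         beta_age_sex = 0.58,
                         site_sd_intercept = 0.18, site_sd_age = 0.27,
                         site_sd_fgm = 0.19, re_corr = diag(3),
                         sigma_resid = 0.96, moca_gaba_slope = 0) {
  re_corr <- as.matrix(re_corr)
  stopifnot(nrow(re_corr) == 3, ncol(re_corr) == 3,
            max(abs(re_corr - t(re_corr))) < 1e-12,
            max(abs(diag(re_corr) - 1)) < 1e-12,
            site_sd_intercept >= 0, site_sd_age >= 0, site_sd_fgm >= 0,
            sigma_resid >= 0)
  ev <- eigen(re_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("re_corr must be positive-definite")
  truth <- list(beta_age = beta_age, beta_fgm = beta_fgm, beta_sex = beta_sex,
                beta_age_sex = beta_age_sex,
                site_sd_intercept = site_sd_intercept,
                site_sd_age = site_sd_age, site_sd_fgm = site_sd_fgm,
                re_corr = re_corr, sigma_resid = sigma_resid,
                moca_gaba_slope = moca_gaba_slope)
  class(truth) <- "cohort_truth"
  truth
}

#' Generate a synthetic 4-site oldest-old cohort
#'
#' Retained-quality records are drawn as: age uniform on 85-99, voxel gray
#' matter fraction Normal(0.42, 0.05) truncated to (0, 1), sex male with
#' probability 0.41, and a standardized GABA outcome
#' `g = X beta + u_site . (1, z_age, z_fgm) + Normal(0, sigma_resid)` with
#' site effects `u_site ~ MultiNormal(0, Sigma)` from the truth. `g` is then
#' mapped to institutional units (`gaba_cr = 0.10 + 0.012 g`, and for ~85%
#' of rows a water-referenced `gaba_w = 2.5 + 0.30 g` plus independent
#' measurement noise). MoCA is a rounded Normal(25.5, 1.9) plus
#' `moca_gaba_slope * g`, clipped to 0-30 and floored at `moca_floor` for
#' retained records (the cohort is screened for intact cognition).
#'
#' `extras` appends records engineered to exercise each stage of the
#' exclusion cascade: scans never acquired, visual-QC failures, low-MoCA
#' participants, site-mean GABA outliers, and fit-error failures.
#'
#' @param truth A [cohort_truth()] object.
#' @param n_per_site Retained-quality records per site (default
#'   `c(34, 18, 28, 20)`).
#' @param seed Integer seed.
#' @param extras Named counts
#'   `list(not_acquired=, qc_fail=, low_moca=, outlier=, fit_error=)`.
#' @param moca_floor Minimum MoCA of retained-quality records (default 23).
#' @return A list with `records` (participant data frame, retained-quality
#'   rows first), `truth`, `latent` (per-row standardized covariates and
#'   outcome `g` for retained-quality rows), and `site_effects` (the drawn
#'   `u_site` matrix).
#' @export
generate_oldestold_cohort <- function(truth = cohort_truth(),
                                      n_per_site = c(34L, 18L, 28L, 20L),
                                      seed = 1L,
                                      extras = list(),
                                      moca_floor = 23L) {
  stopifnot(inherits(truth, "cohort_truth"), length(n_per_site) >= 1)
  has_slopes <- truth$site_sd_age > 0 || truth$site_sd_fgm > 0 ||
    truth$site_sd_intercept > 0
  if (any(n_per_site <= 0) && has_slopes) {
    stop("n_per_site must be positive at every site when site random ",
         "effects are requested")
  }
  ex <- list(not_acquired = 0L, qc_fail = 0L, low_moca = 0L,
             outlier = 0L, fit_error = 0L)
  ex[names(extras)] <- lapply(extras, as.integer)
  set.seed(seed)

  n_sites <- length(n_per_site)
  sites <- sprintf("Site%d", seq_len(n_sites))
  sds <- c(truth$site_sd_intercept, truth$site_sd_age, truth$site_sd_fgm)
  Sigma <- diag(sds) %*% truth$re_corr %*% diag(sds)
  L <- t(chol(Sigma + diag(1e-12, 3)))
  u <- t(L %*% matrix(stats::rnorm(3 * n_sites), 3, n_sites))
  rownames(u) <- sites
  colnames(u) <- c("intercept", "age", "fgm")

  age_sd <- 14 / sqrt(12)   # SD of uniform(85, 99)
  draw_rows <- function(n, site, kind) {
    site <- rep_len(site, n)
    age <- stats::runif(n, 85, 99)
    fgm <- stats::rnorm(n, 0.42, 0.05)
    while (any(fgm <= 0 | fgm >= 1)) {
      bad <- fgm <= 0 | fgm >= 1
      fgm[bad] <- stats::rnorm(sum(bad), 0.42, 0.05)
    }
    male <- stats::rbinom(n, 1, 0.41)
    z_age <- (age - 92) / age_sd
    z_fgm <- (fgm - 0.42) / 0.05
    us <- u[site, , drop = FALSE]
    g <- truth$beta_age * z_age + truth$beta_fgm * z_fgm +
      truth$beta_sex * male + truth$beta_age_sex * z_age * male +
      us[, 1] + us[, 2] * z_age + us[, 3] * z_fgm +
      stats::rnorm(n, 0, truth$sigma_resid)
    fwm <- stats::rnorm(n, 0.37, 0.03)
    fwm <- pmin(pmax(fwm, 0.2), 1 - fgm - 0.02)
    moca_base <- round(stats::rnorm(n, 25.5, 1.9) + truth$moca_gaba_slope * g)
    moca <- pmin(pmax(moca_base, moca_floor), 30)
    has_w <- stats::runif(n) < 0.85
    rec <- data.frame(
      participant_id = NA_character_, site = site,
      age = age, sex = ifelse(male == 1, "male", "female"),
      gaba_cr = pmax(0.10 + 0.012 * g, 0.005),
      gaba_w = ifelse(has_w,
                      pmax(2.5 + 0.30 * g + stats::rnorm(n, 0, 0.10), 0.05),
                      NA_real_),
      fgm = fgm, fwm = fwm, fcsf = 1 - fgm - fwm,
      moca = as.numeric(moca),
      education_years = pmax(round(stats::rnorm(n, 16.2, 3.0)), 6),
      fit_error_pct = pmin(pmax(stats::rnorm(n, 6, 2.5), 1), 14.5),
      qc_visual_pass = TRUE, acquired = TRUE,
      stringsAsFactors = FALSE)
    attr(rec, "latent") <- data.frame(z_age = z_age, z_fgm = z_fgm,
                                      male = male, g = g, kind = kind)
    rec
  }

  retained <- vector("list", n_sites)
  latent <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    retained[[s]] <- draw_rows(n_per_site[s], sites[s], "retained")
    latent[[s]] <- attr(retained[[s]], "latent")
  }
  records <- do.call(rbind, retained)
  latent <- do.call(rbind, latent)

  # cascade-exercise extras, spread over sites round-robin
  extra_site <- function(k) sites[((seq_len(k) - 1L) %% n_sites) + 1L]
  add <- list()
  if (ex$qc_fail > 0) {
    rows <- draw_rows(ex$qc_fail, extra_site(ex$qc_fail), "qc_fail")
    rows$qc_visual_pass <- FALSE
    rows$gaba_cr <- NA_real_; rows$gaba_w <- NA_real_
    rows$fit_error_pct <- NA_real_
    add <- c(add, list(rows))
  }
  if (ex$low_moca > 0) {
    rows <- draw_rows(ex$low_moca, extra_site(ex$low_moca), "low_moca")
    rows$moca <- as.numeric(sample(12:22, ex$low_moca, replace = TRUE))
    add <- c(add, list(rows))
  }
  if (ex$outlier > 0) {
    rows <- draw_rows(ex$outlier, extra_site(ex$outlier), "outlier")
    # far beyond any plausible site spread: flagged at cascade stage 4
    rows$gaba_cr <- 0.10 + 0.012 * (12 + seq_len(ex$outlier))
    add <- c(add, list(rows))
  }
  if (ex$fit_error > 0) {
    rows <- draw_rows(ex$fit_error, extra_site(ex$fit_error), "fit_error")
    rows$fit_error_pct <- stats::runif(ex$fit_error, 15.5, 30)
    add <- c(add, list(rows))
  }
  if (ex$not_acquired > 0) {
    n0 <- ex$not_acquired
    rows <- data.frame(
      participant_id = NA_character_, site = extra_site(n0),
      age = stats::runif(n0, 85, 99),
      sex = ifelse(stats::rbinom(n0, 1, 0.41) == 1, "male", "female"),
      gaba_cr = NA_real_, gaba_w = NA_real_,
      fgm = NA_real_, fwm = NA_real_, fcsf = NA_real_,
      moca = as.numeric(pmin(pmax(round(stats::rnorm(n0, 25.5, 1.9)), 0), 30)),
      education_years = pmax(round(stats::rnorm(n0, 16.2, 3.0)), 6),
      fit_error_pct = NA_real_, qc_visual_pass = NA, acquired = FALSE,
      stringsAsFactors = FALSE)
    add <- c(add, list(rows))
  }
  if (length(add)) records <- rbind(records, do.call(rbind, add))
  records$participant_id <- sprintf("P%03d", seq_len(nrow(records)))
  rownames(records) <- NULL
  validate_participants(records)
  list(records = records, truth = truth, latent = latent, site_effects = u)
}
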