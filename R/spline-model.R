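#' Joint log-posterior of the lifespan spline meta-analysis model
#'
#' The model: observation `i` of dataset `d` has
#' `F_d * y_i ~ Normal(sum_k beta_k B_k(age_i), sigma)` with `F_d =
#' exp(phi_d)` the dataset's multiplicative scaling factor. The spline
#' coefficients carry an order-2 random-walk penalty
#' `diff(beta, differences = 2) ~ Normal(0, tau)` with a diffuse
#' `Normal(0, anchor_sd)` anchor on the first two coefficients; the log
#' scales have a weak `Normal(0, phi_sd)` penalty; `tau` and `sigma` have
#' half-Normal(0, 1) priors.
#'
#' With `jacobian = TRUE` (default) the likelihood includes the
#' change-of-variables term `sum_i phi_d(i)`, i.e. it is the proper density
#' of the raw observations `y_i ~ Normal(mu_i / F_d, sigma / F_d)`. Under
#' this form the joint rescaling `(F, beta, sigma) -> (cF, c beta, c sigma)`
#' leaves the likelihood exactly invariant, so the overall level of the
#' curve and of the scaling factors is identified only softly by the phi
#' prior; [normalize_draws()] resolves it at the reporting stage.
#' `jacobian = FALSE` gives the bare Normal log-likelihood of the scaled
#' observations (no change-of-variables term), useful for documenting that
#' structural identifiability gap.
#'
#' @param beta Spline coefficient vector (length K).
#' @param phi Per-dataset log scaling factors (length = number of datasets).
#' @param tau Penalty (smoothing) scale; nonpositive values return `-Inf`.
#' @param sigma Global error SD; nonpositive values return `-Inf`.
#' @param data Lifespan observation data frame (see [read_lifespan()]).
#' @param basis A [build_basis()] object evaluated at `data$age`.
#' @param priors Named list: `phi_sd` (default 0.5), `anchor_sd` (10),
#'   `tau_sd` (1), `sigma_sd` (1).
#' @param jacobian Include the log|F| change-of-variables term (default
#'   `TRUE`).
#' @return The unnormalized joint log-posterior (scalar).
#' @export
log_posterior <- function(beta, phi, tau, sigma, data, basis,
                          priors = list(), jacobian = TRUE) {
  pr <- spline_priors(priors)
  if (!is.finite(tau) || tau <= 0 || !is.finite(sigma) || sigma <= 0) {
    return(-Inf)
  }
  d_idx <- match(data$dataset_id, sort(unique(data$dataset_id)))
  stopifnot(length(phi) == max(d_idx),
            length(beta) == ncol(basis$design_matrix),
            nrow(basis$design_matrix) == nrow(data))
  mu <- as.vector(basis$design_matrix %*% beta)
  z <- exp(phi[d_idx]) * data$gaba
  ll <- sum(stats::dnorm(z, mu, sigma, log = TRUE))
  if (jacobian) ll <- ll + sum(phi[d_idx])
  K <- length(beta)
  pen <- sum(stats::dnorm(diff(beta, differences = 2), 0, tau, log = TRUE)) +
    sum(stats::dnorm(beta[1:2], 0, pr$anchor_sd, log = TRUE))
  ll + pen +
    sum(stats::dnorm(phi, 0, pr$phi_sd, log = TRUE)) +
    half_normal_lpdf(tau, pr$tau_sd) +
    half_normal_lpdf(sigma, pr$sigma_sd)
}

half_normal_lpdf <- function(x, sd = 1) {
  if (x < 0) return(-Inf)
  log(2) + stats::dnorm(x, 0, sd, log = TRUE)
}

spline_priors <- function(priors = list()) {
  pr <- list(phi_sd = 0.5, anchor_sd = 10, tau_sd = 1, sigma_sd = 1)
  pr[names(priors)] <- priors
  pr
}

# Precomputed sufficient statistics for the collapsed sampler.
spline_suffstats <- function(data, basis) {
  ids <- sort(unique(data$dataset_id))
  d_idx <- match(data$dataset_id, ids)
  D <- length(ids)
  B <- basis$design_matrix
  K <- ncol(B)
  v <- matrix(0, K, D)          # per-dataset B' y
  sy2 <- numeric(D)
  n_d <- numeric(D)
  for (d in seq_len(D)) {
    rows <- d_idx == d
    v[, d] <- crossprod(B[rows, , drop = FALSE], data$gaba[rows])
    sy2[d] <- sum(data$gaba[rows]^2)
    n_d[d] <- sum(rows)
  }
  list(ids = ids, d_idx = d_idx, D = D, K = K, n = nrow(data),
       B = B, BtB = crossprod(B), v = v, sy2 = sy2, n_d = n_d,
       D2 = difference_matrix(K, 2L))
}

# Marginal log-posterior of (phi, tau, sigma) with beta integrated out
# analytically (the beta conditional is Gaussian). Returns also the
# Cholesky pieces needed to draw beta.
spline_marginal <- function(phi, tau, sigma, ss, pr, keep = FALSE) {
  if (tau <= 0 || sigma <= 0) return(list(lp = -Inf))
  F_d <- exp(phi)
  P <- crossprod(ss$D2) / tau^2
  P[1, 1] <- P[1, 1] + 1 / pr$anchor_sd^2
  P[2, 2] <- P[2, 2] + 1 / pr$anchor_sd^2
  cP <- tryCatch(chol(P), error = function(e) NULL)
  if (is.null(cP)) return(list(lp = -Inf))
  A <- ss$BtB / sigma^2 + P
  cA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cA)) return(list(lp = -Inf))
  b <- as.vector(ss$v %*% F_d) / sigma^2       # B' z / sigma^2
  ztz <- sum(F_d^2 * ss$sy2)
  w <- backsolve(cA, b, transpose = TRUE)      # b' A^-1 b = |w|^2
  lp <- -0.5 * ss$n * log(2 * pi) - ss$n * log(sigma) +
    sum(log(diag(cP))) - sum(log(diag(cA))) -
    0.5 * (ztz / sigma^2 - sum(w * w)) +
    sum(ss$n_d * phi) +                        # change-of-variables term
    sum(stats::dnorm(phi, 0, pr$phi_sd, log = TRUE)) +
    half_normal_lpdf(tau, pr$tau_sd) +
    half_normal_lpdf(sigma, pr$sigma_sd)
  if (keep) {
    list(lp = lp, mean = backsolve(cA, w), chol = cA)
  } else {
    list(lp = lp)
  }
}

#' Fit the lifespan spline meta-analysis model by MCMC
#'
#' Runs a collapsed Gibbs sampler: the log scaling factors, the smoothing
#' scale and the global error SD are updated one at a time by slice sampling
#' under the marginal posterior with the spline coefficients integrated out
#' (their conditional is Gaussian), and the coefficients are then drawn
#' exactly from that conditional. Chains run sequentially from
#' `cfg$seed`, so the fit is fully deterministic.
#'
#' After sampling, rank-normalized split R-hat and bulk ESS are computed for
#' every parameter; the fit fails (or warns, per `on_gate_failure`) if any
#' monitored parameter violates `cfg$rhat_max` or `cfg$ess_min`.
#'
#' @param data Lifespan observation data frame ([read_lifespan()] /
#'   [generate_lifespan_datasets()]).
#' @param cfg A [run_config()]; uses `n_chains`, `n_iter`, `n_burnin`,
#'   `seed`, `n_knots`, `spline_degree`, `phi_prior_sd` and the convergence
#'   gates.
#' @param priors Prior overrides, see [log_posterior()].
#' @param on_gate_failure `"error"` (default), `"warn"`, or `"none"`.
#' @return An object of class `spline_posterior`: `draws` (iterations x
#'   chains x parameters array; parameters `beta[k]`, `phi[d]`, `tau`,
#'   `sigma`), `basis`, `dataset_ids`, `normalized = FALSE`, `diagnostics`
#'   (per-parameter R-hat / ESS), `data`, `priors`.
#' @export
fit_lifespan_model <- function(data, cfg = run_config(),
                               priors = list(),
                               on_gate_failure = c("error", "warn", "none")) {
  on_gate_failure <- match.arg(on_gate_failure)
  validate_lifespan(data)
  validate_config(cfg)
  pr <- spline_priors(c(priors, if (is.null(priors$phi_sd))
    list(phi_sd = cfg$phi_prior_sd)))
  basis <- build_basis(data$age, n_knots = cfg$n_knots,
                       degree = cfg$spline_degree)
  ss <- spline_suffstats(data, basis)
  n_keep <- cfg$n_iter - cfg$n_burnin
  pars <- c(sprintf("beta[%d]", seq_len(ss$K)),
            sprintf("phi[%d]", seq_len(ss$D)), "tau", "sigma")
  draws <- array(NA_real_, dim = c(n_keep, cfg$n_chains, length(pars)),
                 dimnames = list(NULL, NULL, pars))

  set.seed(cfg$seed)
  for (ch in seq_len(cfg$n_chains)) {
    phi <- stats::rnorm(ss$D, 0, 0.05)
    # rough residual scale from an unscaled ridge fit for initialization
    A0 <- ss$BtB + diag(1e-6, ss$K)
    b0 <- as.vector(ss$v %*% rep(1, ss$D))
    beta0 <- solve(A0, b0)
    resid0 <- data$gaba - as.vector(ss$B %*% beta0)
    sigma <- stats::sd(resid0) * exp(stats::rnorm(1, 0, 0.2))
    tau <- max(0.3 * exp(stats::rnorm(1, 0, 0.3)), 2e-3)
    for (it in seq_len(cfg$n_iter)) {
      for (d in seq_len(ss$D)) {
        phi[d] <- slice_sample1(phi[d], function(x) {
          p2 <- phi; p2[d] <- x
          spline_marginal(p2, tau, sigma, ss, pr)$lp
        }, w = 0.05)
      }
      # numerical floor on tau: below ~1e-3 the penalty precision D'D/tau^2
      # is conditioned past Cholesky range, and any smaller value is
      # already an effectively-flat-curve fit
      ltau <- slice_sample1(log(tau), function(x)
        spline_marginal(phi, exp(x), sigma, ss, pr)$lp + x, w = 0.5,
        lower = log(1e-3))
      tau <- exp(ltau)
      lsig <- slice_sample1(log(sigma), function(x)
        spline_marginal(phi, tau, exp(x), ss, pr)$lp + x, w = 0.2)
      sigma <- exp(lsig)
      # group (Haar-measure) move along the likelihood-flat rescaling ray:
      # phi -> phi + delta, tau -> tau e^delta, sigma -> sigma e^delta.
      # Single-site updates cross this ray only by a slow random walk; the
      # joint move makes the overall level mix at the prior scale.
      delta <- slice_sample1(0, function(d) {
        if (tau * exp(d) < 1e-3) return(-Inf)
        spline_marginal(phi + d, tau * exp(d), sigma * exp(d),
                        ss, pr)$lp + 2 * d
      }, w = 0.3)
      phi <- phi + delta
      tau <- tau * exp(delta)
      sigma <- sigma * exp(delta)
      if (it > cfg$n_burnin) {
        cond <- spline_marginal(phi, tau, sigma, ss, pr, keep = TRUE)
        beta <- cond$mean +
          backsolve(cond$chol, stats::rnorm(ss$K))
        draws[it - cfg$n_burnin, ch, ] <- c(beta, phi, tau, sigma)
      }
    }
  }

  fit <- structure(list(draws = draws, basis = basis,
                        dataset_ids = ss$ids, normalized = FALSE,
                        data = data, priors = pr,
                        diagnostics = NULL),
                   class = "spline_posterior")
  fit$diagnostics <- diagnose_draws(draws)
  check_gates(fit$diagnostics, cfg, on_gate_failure)
  fit
}

# Shared convergence-gate check; diag is the data frame from diagnose_draws.
check_gates <- function(diagnostics, cfg, on_gate_failure) {
  bad <- diagnostics[!diagnostics$constant &
                       (diagnostics$rhat > cfg$rhat_max |
                          diagnostics$ess_bulk < cfg$ess_min), , drop = FALSE]
  if (nrow(bad) == 0 || on_gate_failure == "none") return(invisible(NULL))
  msg <- paste0(
    "convergence gates violated (rhat_max = ", cfg$rhat_max,
    ", ess_min = ", cfg$ess_min, ") by: ",
    paste(sprintf("%s (rhat=%.3f, ess_bulk=%.0f)", bad$parameter,
                  bad$rhat, bad$ess_bulk), collapse = "; "))
  if (on_gate_failure == "error") stop(msg) else warning(msg)
  invisible(NULL)
}

#' Normalize spline posterior draws to the geometric-mean-1 convention
#'
#' The harmonized scale of the model is fixed by convention, not by the
#' likelihood: per draw, the geometric mean `g` of the scaled observations
#' `exp(phi_d(i)) * y_i` is computed, `log g` is subtracted from every
#' `phi_d`, and `beta`, `sigma` and `tau` are divided by `g`. After
#' normalization the scaled data have geometric mean exactly 1 in every
#' draw and the likelihood value is unchanged (the rescaling ray is
#' likelihood-flat).
#'
#' @param posterior A non-normalized `spline_posterior`.
#' @param data Lifespan observations the model was fit to (defaults to the
#'   data stored in the fit).
#' @return The normalized `spline_posterior`.
#' @export
normalize_draws <- function(posterior, data = posterior$data) {
  stopifnot(inherits(posterior, "spline_posterior"))
  if (isTRUE(posterior$normalized)) {
    stop("posterior is already normalized")
  }
  d_idx <- match(data$dataset_id, posterior$dataset_ids)
  stopifnot(!anyNA(d_idx))
  mean_logy <- mean(log(data$gaba))
  w_d <- tabulate(d_idx, nbins = length(posterior$dataset_ids)) / length(d_idx)
  a <- posterior$draws
  pars <- dimnames(a)[[3]]
  phi_ix <- grep("^phi\\[", pars)
  beta_ix <- grep("^beta\\[", pars)
  scale_ix <- match(c("tau", "sigma"), pars)
  d <- dim(a)
  flat <- matrix(a, nrow = d[1] * d[2], ncol = d[3])
  log_g <- as.vector(flat[, phi_ix, drop = FALSE] %*% w_d) + mean_logy
  flat[, phi_ix] <- flat[, phi_ix] - log_g
  flat[, beta_ix] <- flat[, beta_ix] / exp(log_g)
  flat[, scale_ix] <- flat[, scale_ix] / exp(log_g)
  posterior$draws <- array(flat, dim = d, dimnames = dimnames(a))
  posterior$normalized <- TRUE
  posterior
}

#' Posterior summary of the fitted curve or its derivative
#'
#' Evaluates `sum_k beta_k B_k(age)` (kind `"curve"`) or
#' `sum_k beta_k B'_k(age)` (kind `"derivative"`, the velocity of GABA
#' change in standardized units per year) over an age grid for every draw
#' and returns the pointwise posterior mean with equal-tailed 95% credible
#' bounds.
#'
#' @param posterior A normalized `spline_posterior`.
#' @param age_grid Evaluation ages; must lie inside the knot range. Default:
#'   a 1-year grid over the knot range for curves, and 60-100 (clipped to
#'   the knot range) for derivatives.
#' @param kind `"curve"` or `"derivative"`.
#' @return A `data.frame` (class `curve_summary`) with columns `age`,
#'   `posterior_mean`, `lower_95`, `upper_95`, `kind`.
#' @export
summarize_curve <- function(posterior, age_grid = NULL,
                            kind = c("curve", "derivative")) {
  kind <- match.arg(kind)
  stopifnot(inherits(posterior, "spline_posterior"))
  if (!isTRUE(posterior$normalized)) {
    stop("summarize_curve requires a normalized posterior; ",
         "call normalize_draws() first")
  }
  rng <- range(posterior$basis$inner_knots)
  if (is.null(age_grid)) {
    age_grid <- if (kind == "derivative") {
      seq(max(60, ceiling(rng[1])), min(100, floor(rng[2])), by = 1)
    } else {
      seq(ceiling(rng[1]), floor(rng[2]), by = 1)
    }
  }
  Bg <- eval_basis(posterior$basis, age_grid,
                   derivs = if (kind == "derivative") 1L else 0L)
  flat <- draws_matrix(posterior)
  beta <- flat[, grep("^beta\\[", colnames(flat)), drop = FALSE]
  vals <- beta %*% t(Bg)                      # draws x grid
  qs <- apply(vals, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  out <- data.frame(age = age_grid,
                    posterior_mean = colMeans(vals),
                    lower_95 = qs[1, ], upper_95 = qs[2, ],
                    kind = kind, stringsAsFactors = FALSE)
  class(out) <- c("curve_summary", "data.frame")
  out
}

#' Posterior summary of the per-dataset scaling factors
#'
#' @param posterior A `spline_posterior` (normalized or not).
#' @return Data frame with `dataset_id`, posterior mean/2.5%/97.5% of
#'   `log F_s`, and the posterior-mean `F_s`.
#' @export
scaling_factor_summary <- function(posterior) {
  stopifnot(inherits(posterior, "spline_posterior"))
  flat <- draws_matrix(posterior)
  phi <- flat[, grep("^phi\\[", colnames(flat)), drop = FALSE]
  qs <- apply(phi, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(dataset_id = posterior$dataset_ids,
             log_fs_mean = colMeans(phi),
             log_fs_lower_95 = qs[1, ], log_fs_upper_95 = qs[2, ],
             fs_mean = colMeans(exp(phi)),
             stringsAsFactors = FALSE)
}
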