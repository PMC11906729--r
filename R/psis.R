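# Generalized Pareto fit by the Zhang & Stephens (2009) profile
# quasi-posterior method: given exceedances x > 0 (sorted or not), returns
# shape k and scale sigma. This is the standard estimator for smoothing
# importance-ratio tails.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) stop("need at least 5 exceedances to fit the tail")
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  q1 <- x[max(1, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_bs * q1)
  prof <- vapply(bs, function(b) {
    xi <- mean(log1p(-b * x))          # profile MLE of the shape given b
    n * (log(-b / xi) - xi - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(j)
    sum(exp(prof - prof[j])), numeric(1))
  b <- sum(bs * w)
  xi <- mean(log1p(-b * x))
  sigma <- -xi / b
  # weakly-informative regularization of the shape toward 0.5
  k <- (n * xi + 10 * 0.5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Pareto-smooth one vector of log importance ratios: replace the largest
# 20% by expected order statistics of the fitted generalized Pareto tail,
# truncate at the raw maximum, return list(log_weights, k).
psis_smooth <- function(lr) {
  lr <- lr - max(lr)                         # shift-invariant; avoids overflow
  S <- length(lr)
  M <- ceiling(0.2 * S)
  if (M < 5 || max(lr) - min(lr) < 1e-12) {
    # too few draws to smooth, or degenerate (equal) ratios
    return(list(log_weights = lr - log_sum_exp(lr), k = 0))
  }
  ord <- order(lr)
  tail_ix <- ord[(S - M + 1):S]
  cut <- lr[ord[S - M]]                      # largest non-tail log ratio
  exceed <- exp(lr[tail_ix] - cut) - 1       # scaled exceedances over cut
  exceed <- exceed * exp(cut)                # back to ratio scale
  if (max(exceed) <= 0) {
    return(list(log_weights = lr - log_sum_exp(lr), k = 0))
  }
  fit <- tryCatch(gpd_fit(exceed), error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$k)) {
    p <- (seq_len(M) - 0.5) / M
    smoothed <- log(exp(cut) + qgpd(p, fit$k, fit$sigma))
    lr[tail_ix[order(lr[tail_ix])]] <- smoothed
    k <- fit$k
  } else {
    k <- Inf
  }
  lr <- pmin(lr, max(lr))                    # truncate at the raw maximum
  list(log_weights = lr - log_sum_exp(lr), k = k)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Computes the expected log pointwise predictive density under
#' leave-one-out (elpd_loo) from a pointwise log-likelihood matrix. For
#' each observation the importance ratios are proportional to the inverse
#' likelihood; the largest 20% of ratios are replaced by quantiles of a
#' generalized Pareto distribution fit to them (profile-likelihood method),
#' truncated at the raw maximum and self-normalized. The fitted Pareto
#' shape `k` diagnoses reliability: observations with `k > 0.7` trigger a
#' warning.
#'
#' @param loglik Draws x observations matrix of pointwise log-likelihoods
#'   (finite; at least 100 draws for stable tail smoothing), or a fit with
#'   `$loglik`.
#' @return Object of class `psis_loo`: list with `elpd_loo`, `pointwise`
#'   (per-observation elpd), `pareto_k`, `se_elpd`, `n`, `n_draws`,
#'   `warnings` (character vector, possibly empty).
#' @export
psis_loo <- function(loglik) {
  if (is.list(loglik) && !is.null(loglik$loglik)) loglik <- loglik$loglik
  loglik <- as.matrix(loglik)
  if (!all(is.finite(loglik))) stop("loglik matrix must be finite")
  S <- nrow(loglik); n <- ncol(loglik)
  if (S < 100) stop("need at least 100 draws for stable tail smoothing")
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-loglik[, i])
    pointwise[i] <- log_sum_exp(sm$log_weights + loglik[, i])
    pareto_k[i] <- sm$k
  }
  warnings <- character(0)
  n_bad <- sum(pareto_k > 0.7)
  if (n_bad > 0) {
    warnings <- c(warnings, paste0(
      n_bad, " observation(s) with Pareto k > 0.7; their elpd ",
      "contributions are unreliable"))
  }
  out <- list(elpd_loo = sum(pointwise), pointwise = pointwise,
              pareto_k = pareto_k,
              se_elpd = sqrt(n * stats::var(pointwise)),
              n = n, n_draws = S, warnings = warnings)
  class(out) <- "psis_loo"
  for (w in warnings) warning(w)
  out
}

#' Compare two models by PSIS-LOO
#'
#' Pointwise elpd differences between two fits of the same observations in
#' the same order. The sign convention: `elpd_diff = elpd_a - elpd_b`, so a
#' negative value means the first-listed model (conventionally the reduced
#' one) predicts worse. `se_diff = sqrt(n * var(pointwise differences))`, a
#' normal approximation that is unreliable below n = 100 — a warning flag is
#' set in that case.
#'
#' @param fit_a,fit_b `lme_fit` objects (or raw loglik matrices /
#'   `psis_loo` results) over identical observations.
#' @return Object of class `loo_comparison`: `elpd_loo_a`, `elpd_loo_b`,
#'   `pointwise_diff`, `elpd_diff`, `se_diff`, `pareto_k_a`, `pareto_k_b`,
#'   `small_n_warning`.
#' @export
compare_models <- function(fit_a, fit_b) {
  loo_a <- if (inherits(fit_a, "psis_loo")) fit_a else psis_loo(fit_a)
  loo_b <- if (inherits(fit_b, "psis_loo")) fit_b else psis_loo(fit_b)
  if (loo_a$n != loo_b$n) {
    stop("fits cover different numbers of observations (", loo_a$n,
         " vs ", loo_b$n, ")")
  }
  pd <- loo_a$pointwise - loo_b$pointwise
  n <- loo_a$n
  out <- list(elpd_loo_a = loo_a$elpd_loo, elpd_loo_b = loo_b$elpd_loo,
              pointwise_diff = pd,
              elpd_diff = sum(pd),
              se_diff = sqrt(n * stats::var(pd)),
              pareto_k_a = loo_a$pareto_k, pareto_k_b = loo_b$pareto_k,
              small_n_warning = n < 100)
  class(out) <- "loo_comparison"
  if (out$small_n_warning) {
    warning("LOO comparison may be unreliable in small samples (n < 100)")
  }
  out
}
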