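# Rank-normalized split-chain MCMC diagnostics.
#
# All functions take draws as an iterations x chains matrix. The rank
# normalization (fractional ranks mapped through the Normal quantile
# function) makes the diagnostics invariant to monotone transformation of
# the parameter and robust to heavy tails.

split_chains <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) stop("need at least 4 iterations per chain")
  cbind(x[seq_len(half), , drop = FALSE],
        x[(n - half + 1):n, , drop = FALSE])
}

rank_normalize <- function(x) {
  d <- dim(x)
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  array(z, dim = d)
}

# Classic potential-scale-reduction on an iterations x chains matrix.
rhat_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  mu <- colMeans(x)
  s2 <- apply(x, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  vhat <- (n - 1) / n * W + B / n
  sqrt(vhat / W)
}

#' Rank-normalized split R-hat
#'
#' Each chain is split in half, all draws are rank-normalized jointly, and
#' the classic potential-scale-reduction factor is computed on the split,
#' transformed chains. Values near 1 indicate the chains agree; the
#' conventional acceptance gate is 1.05.
#'
#' @param x Draws, an iterations x chains matrix (>= 2 chains, >= 4
#'   iterations).
#' @return Scalar R-hat. Constant chains return 1 with attribute
#'   `constant = TRUE`.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("split_rhat needs at least 2 chains")
  if (nrow(x) < 4) stop("split_rhat needs at least 4 iterations")
  if (max(x) - min(x) == 0) {
    return(structure(1, constant = TRUE))
  }
  rhat_basic(rank_normalize(split_chains(x)))
}

# Effective sample size of an iterations x chains matrix (already
# transformed), via per-chain FFT autocovariances combined across chains
# and Geyer's initial positive + monotone sequence truncation.
ess_core <- function(x) {
  n <- nrow(x); m <- ncol(x)
  acov <- matrix(0, n, m)
  for (j in seq_len(m)) {
    y <- x[, j] - mean(x[, j])
    npad <- 2^ceiling(log2(2 * n))
    f <- stats::fft(c(y, rep(0, npad - n)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / npad
    acov[, j] <- ac / n          # biased autocovariance (divisor n)
  }
  chain_var <- acov[1, ] * n / (n - 1)
  mean_var <- mean(chain_var)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1) var_plus <- var_plus + stats::var(colMeans(x))
  if (var_plus == 0) return(structure(n * m, constant = TRUE))
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer initial positive sequence: sum adjacent-lag pairs
  # P_k = rho(2k) + rho(2k+1) while positive, then enforce monotone decrease
  paired <- numeric(0)
  t <- 0
  while (t + 2 <= n) {
    p <- rho[t + 1] + rho[t + 2]
    if (p <= 0) break
    paired <- c(paired, p)
    t <- t + 2
  }
  if (length(paired) > 1) paired <- cummin(paired)
  tau <- -1 + 2 * sum(paired)
  tau <- max(tau, 1 / log10(n * m + 10))   # guard against overshoot
  min(n * m / tau, n * m * log10(n * m))
}

#' Effective sample size (bulk or tail)
#'
#' Bulk ESS: chains are split in half, rank-normalized, and an
#' autocorrelation-based ESS is computed with Geyer's paired-sum
#' truncation. Tail ESS: the minimum of the ESS of the indicator chains
#' `I(x <= q05)` and `I(x >= q95)` at the 5% and 95% quantiles, measuring
#' how well the tails are resolved.
#'
#' @param x Draws, an iterations x chains matrix.
#' @param kind `"bulk"` (default) or `"tail"`.
#' @return Scalar ESS. Constant chains return the total draw count with
#'   attribute `constant = TRUE`.
#' @export
ess <- function(x, kind = c("bulk", "tail")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("ess needs at least 2 chains")
  if (nrow(x) < 4) stop("ess needs at least 4 iterations")
  if (max(x) - min(x) == 0) {
    return(structure(nrow(x) * ncol(x), constant = TRUE))
  }
  if (kind == "bulk") {
    ess_core(rank_normalize(split_chains(x)))
  } else {
    q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
    lo <- ess_core(rank_normalize(split_chains((x <= q[1]) * 1)))
    hi <- ess_core(rank_normalize(split_chains((x >= q[2]) * 1)))
    min(lo, hi)
  }
}

#' Convergence diagnostics for every parameter of a draws array
#'
#' @param draws An iterations x chains x parameters array (or a fit with
#'   `$draws`).
#' @return Data frame with `parameter`, `rhat`, `ess_bulk`, `ess_tail`,
#'   `constant`.
#' @export
diagnose_draws <- function(draws) {
  a <- draws_array(draws)
  pars <- dimnames(a)[[3]]
  out <- data.frame(parameter = pars, rhat = NA_real_,
                    ess_bulk = NA_real_, ess_tail = NA_real_,
                    constant = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(pars)) {
    x <- a[, , k]
    r <- split_rhat(x)
    out$rhat[k] <- as.numeric(r)
    out$constant[k] <- isTRUE(attr(r, "constant"))
    out$ess_bulk[k] <- as.numeric(ess(x, "bulk"))
    out$ess_tail[k] <- as.numeric(ess(x, "tail"))
  }
  out
}
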