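# Univariate slice sampler (stepping-out + shrinkage, Neal 2003).
# Robust, tuning-free updates for the non-conjugate scalars of the Gibbs
# samplers; `logf` need only be correct up to a constant. Returns the new
# point. `lower`/`upper` bound the support (density is -Inf outside).
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50,
                          lower = -Inf, upper = Inf, f0 = NULL) {
  if (is.null(f0)) f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at a zero-density point")
  logy <- f0 - stats::rexp(1)
  u <- stats::runif(1) * w
  L <- x0 - u
  R <- L + w
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && logf(L) > logy) {
    L <- L - w
    j <- j - 1
  }
  while (k > 0 && R < upper && logf(R) > logy) {
    R <- R + w
    k <- k - 1
  }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    f1 <- logf(x1)
    if (is.finite(f1) && f1 >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}
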