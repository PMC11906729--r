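#' Ground truth for the synthetic lifespan meta-analysis
#'
#' Defines the true age-to-GABA curve, the per-dataset multiplicative scale
#' offsets, the observation noise and the cohort layout that the lifespan
#' generator draws from. The defaults emulate the study conditions the
#' pipeline targets: 12 cross-sectional datasets with overlapping age
#' windows spanning ages 8-99, four of them oldest-old cohorts (85-99),
#' seven creatine-referenced and five water-referenced, with
#' reference-method-specific scale clusters (Cr-referenced datasets sit at
#' smaller log scale, so their raw values are larger) and a smooth curve
#' that rises to an early-adult peak, declines through mid/old age, and
#' flattens after a plateau onset at age 80.
#'
#' @param curve_params Named list of curve parameters; see
#'   [true_lifespan_curve()].
#' @param log_scales Per-dataset true log scaling factors `log F_s*`;
#'   recentred so their mean is exactly zero (geometric mean of `F_s*` is 1).
#' @param sigma_true Observation noise SD on the standardized scale.
#' @param dataset_sizes Integer vector of per-dataset sample sizes.
#' @param dataset_age_ranges List of `c(lo, hi)` age windows; every window
#'   must overlap at least one other.
#' @param reference_method Character vector (`"Cr"`/`"water"`) per dataset.
#' @return An object of class `lifespan_truth`.
#' @export
lifespan_truth <- function(curve_params = default_curve_params(),
                           log_scales = NULL,
                           sigma_true = 0.12,
                           dataset_sizes = rep(60L, 12L),
                           dataset_age_ranges = default_age_ranges(),
                           reference_method = default_reference_methods()) {
  d <- length(dataset_sizes)
  stopifnot(d >= 2, length(dataset_age_ranges) == d,
            length(reference_method) == d, sigma_true >= 0)
  if (is.null(log_scales)) {
    # method-specific clusters: Cr below zero, water above, spread within
    log_scales <- numeric(d)
    cr <- reference_method == "Cr"
    log_scales[cr] <- -0.25 + seq(-0.15, 0.15, length.out = sum(cr))
    log_scales[!cr] <- 0.35 + seq(-0.12, 0.12, length.out = sum(!cr))
  }
  stopifnot(length(log_scales) == d)
  log_scales <- log_scales - mean(log_scales)   # geometric mean of F_s* is 1
  truth <- list(curve_params = curve_params, log_scales = log_scales,
                sigma_true = sigma_true,
                dataset_sizes = as.integer(dataset_sizes),
                dataset_age_ranges = dataset_age_ranges,
                reference_method = reference_method)
  class(truth) <- "lifespan_truth"
  truth
}

#' @rdname lifespan_truth
#' @export
default_curve_params <- function() {
  list(level = 0.6, rise_amp = 0.9, rise_mid = 13, rise_scale = 4,
       fall_amp = 0.75, plateau_onset = 80)
}

#' @rdname lifespan_truth
#' @export
default_age_ranges <- function() {
  c(list(c(8, 35), c(15, 45), c(20, 55), c(30, 65), c(40, 75),
         c(50, 85), c(60, 92), c(65, 95)),
    rep(list(c(85, 99)), 4))
}

#' @rdname lifespan_truth
#' @export
default_reference_methods <- function() {
  # 3 legacy Cr, 5 legacy water, 4 oldest-old Cr
  c("Cr", "water", "Cr", "water", "water", "Cr", "water", "water",
    "Cr", "Cr", "Cr", "Cr")
}

#' True lifespan GABA curve of the synthetic generator
#'
#' A smooth double-logistic: `level + rise_amp * plogis((a - rise_mid) /
#' rise_scale) - fall_amp * plogis((a - fall_mid) / fall_scale)` with
#' `fall_mid = plateau_onset - 25` and `fall_scale = 11`, giving a rise to an
#' early-adult peak near age 27, a monotone decline through mid and old age,
#' and a decline slope whose magnitude shrinks after the plateau onset
#' (default 80). Positive on the whole supported age range.
#'
#' @param age Ages in years, each in `(0, 110]`.
#' @param curve_params Named list as from [default_curve_params()].
#' @return Standardized GABA level at each age.
#' @export
true_lifespan_curve <- function(age, curve_params = default_curve_params()) {
  if (any(!is.finite(age)) || any(age <= 0) || any(age > 110)) {
    stop("age must lie in (0, 110]")
  }
  p <- curve_params
  fall_mid <- p$plateau_onset - 25
  p$level +
    p$rise_amp * stats::plogis((age - p$rise_mid) / p$rise_scale) -
    p$fall_amp * stats::plogis((age - fall_mid) / 11)
}

#' @rdname true_lifespan_curve
#' @details `true_lifespan_velocity()` is the analytic first derivative of
#'   the same curve (standardized units per year).
#' @export
true_lifespan_velocity <- function(age, curve_params = default_curve_params()) {
  if (any(!is.finite(age)) || any(age <= 0) || any(age > 110)) {
    stop("age must lie in (0, 110]")
  }
  p <- curve_params
  fall_mid <- p$plateau_onset - 25
  dl <- function(x) stats::plogis(x) * (1 - stats::plogis(x))
  p$rise_amp / p$rise_scale * dl((age - p$rise_mid) / p$rise_scale) -
    p$fall_amp / 11 * dl((age - fall_mid) / 11)
}

#' Generate synthetic multi-dataset lifespan observations
#'
#' For observation `i` in dataset `d`: ages are uniform within the dataset's
#' window and `gaba_i = (f*(age_i) + eps_i) / F_s*[d]` with
#' `eps_i ~ Normal(0, sigma_true)` truncated so the standardized signal stays
#' positive. Noise is added on the standardized scale before down-scaling,
#' so `sigma_true` is directly the global error term the lifespan model
#' estimates.
#'
#' @param truth A [lifespan_truth()] object.
#' @param seed Integer seed; output is byte-identical for equal seed and
#'   truth.
#' @return A list with `data` (a validated lifespan observation data frame)
#'   and `truth` (the generating truth, echoed for recovery tests).
#' @export
generate_lifespan_datasets <- function(truth = lifespan_truth(), seed = 1L) {
  stopifnot(inherits(truth, "lifespan_truth"))
  d <- length(truth$dataset_sizes)
  lo <- vapply(truth$dataset_age_ranges, `[`, numeric(1), 1)
  hi <- vapply(truth$dataset_age_ranges, `[`, numeric(1), 2)
  stopifnot(all(hi > lo))
  for (i in seq_len(d)) {
    if (!any(lo[-i] <= hi[i] & hi[-i] >= lo[i])) {
      stop("dataset ", i, " has an age window disjoint from all others; ",
           "the shared-curve model assumption requires overlap")
    }
  }
  set.seed(seed)
  rows <- vector("list", d)
  for (j in seq_len(d)) {
    n <- truth$dataset_sizes[j]
    age <- stats::runif(n, lo[j], hi[j])
    f <- true_lifespan_curve(age, truth$curve_params)
    std <- f + stats::rnorm(n, 0, truth$sigma_true)
    bad <- which(std <= 0)
    guard <- 0
    while (length(bad)) {   # truncate to positive by resampling the noise
      std[bad] <- f[bad] + stats::rnorm(length(bad), 0, truth$sigma_true)
      bad <- bad[std[bad] <= 0]
      guard <- guard + 1
      if (guard > 1000) stop("positivity truncation failed to converge")
    }
    rows[[j]] <- data.frame(
      dataset_id = sprintf("D%02d", j),
      age = age,
      gaba = std / exp(truth$log_scales[j]),
      reference_method = truth$reference_method[j],
      stringsAsFactors = FALSE)
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  validate_lifespan(data)
  list(data = data, truth = truth)
}
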