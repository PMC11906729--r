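#' Run configuration
#'
#' Bundles every tunable of the analysis pipeline: MCMC settings, spline
#' construction, convergence gates, the tissue-correction alpha, and the
#' quality-control thresholds. All downstream randomness flows from `seed`.
#'
#' @param n_chains Number of MCMC chains.
#' @param n_iter Iterations per chain (including burn-in).
#' @param n_burnin Burn-in iterations discarded from each chain; must be
#'   strictly less than `n_iter`.
#' @param seed Integer seed; two runs with equal config and inputs produce
#'   identical draws.
#' @param n_knots Number of evenly spaced spline knot positions spanning the
#'   pooled age range (default 19).
#' @param spline_degree Polynomial degree of the B-spline basis (default 3,
#'   cubic).
#' @param penalty_order Order of the random-walk difference penalty on spline
#'   coefficients (default 2).
#' @param ess_min Convergence gate: minimum bulk effective sample size
#'   required of every monitored parameter (default 1000).
#' @param rhat_max Convergence gate: maximum rank-normalized split R-hat
#'   (default 1.05).
#' @param alpha_gm_wm GABA visibility ratio of white relative to gray matter
#'   used by [alpha_correct()] (default 0.5).
#' @param moca_exclude_max Participants scoring at or below this MoCA value
#'   are excluded (default 22, i.e. retention requires >= 23).
#' @param fit_error_max_pct Spectral fit-error threshold in percent; rows
#'   strictly above it are excluded (default 15).
#' @param outlier_sd_max Site-mean outlier threshold in standard deviations
#'   (default 4).
#' @param phi_prior_sd Prior standard deviation of the per-dataset log
#'   scaling factors (default 0.5; "weakly penalizing").
#'
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(n_chains = 4L, n_iter = 10000L, n_burnin = 5000L,
                       seed = 1L, n_knots = 19L, spline_degree = 3L,
                       penalty_order = 2L, ess_min = 1000L, rhat_max = 1.05,
                       alpha_gm_wm = 0.5, moca_exclude_max = 22L,
                       fit_error_max_pct = 15, outlier_sd_max = 4,
                       phi_prior_sd = 0.5) {
  cfg <- list(
    n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
    n_burnin = as.integer(n_burnin), seed = as.integer(seed),
    n_knots = as.integer(n_knots), spline_degree = as.integer(spline_degree),
    penalty_order = as.integer(penalty_order), ess_min = as.integer(ess_min),
    rhat_max = as.numeric(rhat_max), alpha_gm_wm = as.numeric(alpha_gm_wm),
    moca_exclude_max = as.integer(moca_exclude_max),
    fit_error_max_pct = as.numeric(fit_error_max_pct),
    outlier_sd_max = as.numeric(outlier_sd_max),
    phi_prior_sd = as.numeric(phi_prior_sd)
  )
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$n_burnin >= cfg$n_iter) {
    stop("run_config: n_burnin (", cfg$n_burnin,
         ") must be strictly less than n_iter (", cfg$n_iter, ")")
  }
  pos <- c("n_chains", "n_iter", "n_knots", "ess_min", "rhat_max",
           "alpha_gm_wm", "fit_error_max_pct", "outlier_sd_max",
           "phi_prior_sd")
  for (fld in pos) {
    if (!is.finite(cfg[[fld]]) || cfg[[fld]] <= 0) {
      stop("run_config: `", fld, "` must be positive")
    }
  }
  if (cfg$n_burnin < 0) stop("run_config: n_burnin must be nonnegative")
  if (cfg$spline_degree < 0) stop("run_config: spline_degree must be >= 0")
  invisible(cfg)
}

#' Load a run configuration from a JSON file
#'
#' Absent keys take the package defaults of [run_config()]; the assembled
#' configuration is validated before it is returned.
#'
#' @param path Path to a JSON object whose keys are `run_config()` argument
#'   names.
#' @return A `run_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) && is.null(names(raw))) {
    stop("config must be a JSON object with named keys")
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}
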