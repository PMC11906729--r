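#' Participant exclusion cascade
#'
#' Applies the retention pipeline in its fixed order, each participant
#' falling out at the first failing stage:
#' \enumerate{
#'   \item drop records whose scan was never acquired;
#'   \item drop records failing visual quality inspection;
#'   \item drop records with MoCA at or below `cfg$moca_exclude_max`
#'     (cognitive screening; retention requires MoCA >= threshold + 1);
#'   \item compute each site's mean and SD of `gaba_cr` over the survivors
#'     of stages 1-3 and drop rows whose |z| exceeds `cfg$outlier_sd_max`
#'     (the z-score uses the site mean and SD including the candidate row);
#'   \item drop rows with spectral fit error strictly above
#'     `cfg$fit_error_max_pct` (a row at exactly the threshold is kept).
#' }
#' Sites with fewer than 3 stage-4 survivors skip the outlier test with a
#' warning (their SD is unstable). The cascade is idempotent: re-running it
#' on its own retained output excludes nobody.
#'
#' @param records Participant data frame (see [read_participants()]).
#' @param cfg A [run_config()].
#' @return A list with `retained` (surviving records) and `log`, a data
#'   frame with columns `stage`, `participant_id`, `detail` (the z-score at
#'   stage 4), one row per excluded participant.
#' @export
apply_exclusion_cascade <- function(records, cfg = run_config()) {
  validate_participants(records)
  stopifnot(inherits(cfg, "run_config"))
  log_rows <- list()
  note <- function(stage, ids, detail = "") {
    if (length(ids)) {
      log_rows[[length(log_rows) + 1]] <<- data.frame(
        stage = stage, participant_id = ids,
        detail = rep_len(as.character(detail), length(ids)),
        stringsAsFactors = FALSE)
    }
  }

  drop <- !(records$acquired %in% TRUE)
  note("not_acquired", records$participant_id[drop])
  cur <- records[!drop, , drop = FALSE]

  drop <- !(cur$qc_visual_pass %in% TRUE)
  note("visual_qc", cur$participant_id[drop])
  cur <- cur[!drop, , drop = FALSE]

  drop <- !is.na(cur$moca) & cur$moca <= cfg$moca_exclude_max
  note("low_moca", cur$participant_id[drop],
       sprintf("MoCA=%g", cur$moca[drop]))
  cur <- cur[!drop, , drop = FALSE]

  # stage 4: site-mean outliers on gaba_cr over the survivors so far
  z <- rep(NA_real_, nrow(cur))
  for (s in unique(cur$site)) {
    idx <- which(cur$site == s & !is.na(cur$gaba_cr))
    if (length(idx) < 3) {
      warning("site ", s, " has fewer than 3 records at the outlier stage; ",
              "skipping the site-mean outlier test there")
      next
    }
    m <- mean(cur$gaba_cr[idx])
    sdev <- stats::sd(cur$gaba_cr[idx])
    if (sdev > 0) z[idx] <- (cur$gaba_cr[idx] - m) / sdev
  }
  drop <- !is.na(z) & abs(z) > cfg$outlier_sd_max
  note("site_outlier", cur$participant_id[drop],
       sprintf("z=%.2f", z[drop]))
  cur <- cur[!drop, , drop = FALSE]

  drop <- !is.na(cur$fit_error_pct) &
    cur$fit_error_pct > cfg$fit_error_max_pct
  note("fit_error", cur$participant_id[drop],
       sprintf("fit_error=%.1f%%", cur$fit_error_pct[drop]))
  cur <- cur[!drop, , drop = FALSE]

  log <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(stage = character(), participant_id = character(),
               detail = character(), stringsAsFactors = FALSE)
  }
  stopifnot(nrow(cur) + nrow(log) == nrow(records))   # count conservation
  rownames(cur) <- NULL
  list(retained = cur, log = log)
}

#' Tissue-composition (alpha) correction for water-referenced GABA
#'
#' GABA is less visible in white than gray matter; `alpha` is the WM:GM
#' visibility ratio. The group-normalized form rescales each measurement by
#' the ratio of the cohort-average effective brain fraction to the
#' individual's, so the cohort-average correction factor is 1 and corrected
#' values stay on the scale of the input units:
#' `corrected = gaba_w * (mean_fgm + alpha * mean_fwm) / (fgm + alpha * fwm)`.
#'
#' @param gaba_w Water-referenced GABA level(s).
#' @param fgm,fwm Individual voxel gray/white matter fractions.
#' @param group_mean_fgm,group_mean_fwm Cohort mean fractions.
#' @param alpha GM:WM GABA visibility ratio (default 0.5).
#' @return Corrected GABA level(s).
#' @export
alpha_correct <- function(gaba_w, fgm, fwm, group_mean_fgm, group_mean_fwm,
                          alpha = 0.5) {
  if (alpha <= 0) stop("alpha must be positive")
  denom <- fgm + alpha * fwm
  if (any(!is.na(denom) & denom <= 0)) {
    stop("fgm + alpha * fwm must be positive")
  }
  gaba_w * (group_mean_fgm + alpha * group_mean_fwm) / denom
}

#' Center and scale variables within site
#'
#' Z-scores each named variable within each site (denominator `n - 1`), the
#' standardization applied to all continuous variables before mixed-model
#' fitting. The per-site location/scale table is attached as attribute
#' `"scaling"` and allows exact back-transformation.
#'
#' @param records Participant data frame with a `site` column.
#' @param variables Character vector of numeric column names to standardize.
#' @return The records with the named columns z-scored within site;
#'   `attr(, "scaling")` holds columns `site`, `variable`, `center`,
#'   `scale`.
#' @export
standardize_within_site <- function(records, variables) {
  stopifnot(is.data.frame(records), "site" %in% names(records),
            all(variables %in% names(records)))
  tab <- list()
  out <- records
  for (s in unique(records$site)) {
    idx <- which(records$site == s)
    for (v in variables) {
      x <- records[[v]][idx]
      ok <- !is.na(x)
      if (sum(ok) < 2) {
        stop("site ", s, ", variable `", v,
             "`: need at least 2 non-missing values to standardize")
      }
      m <- mean(x[ok])
      sdev <- stats::sd(x[ok])
      if (!is.finite(sdev) || sdev == 0) {
        stop("site ", s, ", variable `", v, "` has zero within-site SD")
      }
      out[[v]][idx] <- (x - m) / sdev
      tab[[length(tab) + 1]] <- data.frame(
        site = s, variable = v, center = m, scale = sdev,
        stringsAsFactors = FALSE)
    }
  }
  attr(out, "scaling") <- do.call(rbind, tab)
  out
}

#' Undo [standardize_within_site()]
#'
#' @param records Output of [standardize_within_site()] (or any data frame
#'   with the same standardized columns), plus the `scaling` table.
#' @param scaling The `attr(, "scaling")` table; defaults to the one
#'   attached to `records`.
#' @return Records on the original scale.
#' @export
unstandardize_within_site <- function(records, scaling = attr(records, "scaling")) {
  if (is.null(scaling)) stop("no scaling table supplied or attached")
  out <- records
  for (k in seq_len(nrow(scaling))) {
    idx <- which(records$site == scaling$site[k])
    v <- scaling$variable[k]
    out[[v]][idx] <- records[[v]][idx] * scaling$scale[k] + scaling$center[k]
  }
  attr(out, "scaling") <- NULL
  out
}
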