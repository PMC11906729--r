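#' Specify a Bayesian linear mixed-effects model
#'
#' Gaussian outcome with population-level (fixed) effects, a site random
#' intercept, and site random slopes, the model family used for the
#' oldest-old cohort analyses. Continuous variables are expected to be
#' standardized within site before fitting ([standardize_within_site()]);
#' `sex` enters as an unstandardized 0/1 male indicator.
#'
#' @param outcome Name of the outcome column.
#' @param fixed Character vector of fixed-effect columns (`"sex"` is
#'   expanded to the male indicator).
#' @param interactions List of 2-vectors of column names whose products
#'   enter as fixed effects.
#' @param random_slopes Character vector of columns with site random
#'   slopes. A random slope need not have a matching fixed effect, so
#'   nested model comparisons can drop a population-level term while
#'   keeping the random-effects structure identical.
#' @param grouping Grouping column (default `"site"`).
#' @param priors Named list of prior scales: `beta_sd` (fixed effects, 1),
#'   `sigma_sd` (residual SD half-Normal scale, 1), `re_sd` (random-effect
#'   SD half-Normal scale, 1), `lkj_eta` (correlation-matrix shape, 2).
#' @return An object of class `lme_spec`.
#' @export
model_spec <- function(outcome, fixed, interactions = list(),
                       random_slopes = character(), grouping = "site",
                       priors = list()) {
  stopifnot(is.character(outcome), length(outcome) == 1,
            is.character(fixed), length(fixed) >= 1,
            is.character(random_slopes))
  pr <- list(beta_sd = 1, sigma_sd = 1, re_sd = 1, lkj_eta = 2)
  pr[names(priors)] <- priors
  spec <- list(outcome = outcome, fixed = fixed,
               interactions = interactions,
               random_slopes = random_slopes, grouping = grouping,
               priors = pr)
  class(spec) <- "lme_spec"
  spec
}

#' Model specifications of the oldest-old analysis suite
#'
#' Named shortcuts for the cohort models: `"age_fgm"` (GABA+/Cr on age and
#' gray matter fraction), `"fgm_only"` (its reduction without the fixed age effect but with an
#' identical random-effects structure, used in the LOO comparison), `"age_sex"` (adds sex and the age-by-sex interaction),
#' `"moca"` (MoCA on GABA+/Cr, age and education) and `"moca_nogaba"` (its
#' GABA-free reduction), `"alpha_h2o"` (alpha-corrected water-referenced
#' GABA on age and fGM; compute the outcome with [alpha_correct()] into a
#' column `gaba_w_alpha` first). All carry a site random intercept and
#' random slopes for their continuous predictors.
#'
#' @param name One of the model names above.
#' @return An `lme_spec`.
#' @export
oldestold_model_spec <- function(name = c("age_fgm", "fgm_only", "age_sex",
                                          "moca", "moca_nogaba",
                                          "alpha_h2o")) {
  name <- match.arg(name)
  switch(name,
    age_fgm = model_spec("gaba_cr", c("age", "fgm"),
                         random_slopes = c("age", "fgm")),
    fgm_only = model_spec("gaba_cr", "fgm",
                          random_slopes = c("age", "fgm")),
    age_sex = model_spec("gaba_cr", c("age", "fgm", "sex"),
                         interactions = list(c("age", "sex")),
                         random_slopes = c("age", "fgm")),
    moca = model_spec("moca", c("gaba_cr", "age", "education_years"),
                      random_slopes = c("gaba_cr", "age", "education_years")),
    moca_nogaba = model_spec("moca", c("age", "education_years"),
                             random_slopes = c("gaba_cr", "age",
                                               "education_years")),
    alpha_h2o = model_spec("gaba_w_alpha", c("age", "fgm"),
                           random_slopes = c("age", "fgm")))
}

# Build the design pieces (X, Z, y, site index) from records + spec.
lme_design <- function(records, spec) {
  stopifnot(is.data.frame(records), inherits(spec, "lme_spec"))
  grab <- function(term) {
    if (term == "sex") {
      if (!all(records$sex %in% c("male", "female"))) {
        stop("sex must be \"male\"/\"female\"")
      }
      return(as.numeric(records$sex == "male"))
    }
    x <- records[[term]]
    if (is.null(x)) stop("records lack column `", term, "`")
    as.numeric(x)
  }
  y <- grab(spec$outcome)
  if (anyNA(y)) stop("outcome `", spec$outcome, "` has missing values")
  cols <- list("(Intercept)" = rep(1, nrow(records)))
  for (f in spec$fixed) {
    cols[[if (f == "sex") "sex_male" else f]] <- grab(f)
  }
  for (ia in spec$interactions) {
    nm <- paste(ifelse(ia == "sex", "sex_male", ia), collapse = ":")
    cols[[nm]] <- grab(ia[1]) * grab(ia[2])
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (anyNA(X)) stop("missing values in fixed-effect columns")
  const <- apply(X[, -1, drop = FALSE], 2, function(c) stats::sd(c) == 0)
  if (any(const)) {
    stop("unidentifiable constant fixed-effect column(s): ",
         paste(names(const)[const], collapse = ", "))
  }
  zcols <- list("(Intercept)" = rep(1, nrow(records)))
  for (f in spec$random_slopes) {
    zcols[[if (f == "sex") "sex_male" else f]] <- grab(f)
  }
  Z <- do.call(cbind, zcols)
  colnames(Z) <- names(zcols)
  zt <- names(zcols)
  site <- as.character(records[[spec$grouping]])
  if (length(unique(site)) < 2) stop("need at least 2 sites")
  list(y = y, X = X, Z = Z, site = factor(site),
       re_terms = sub("^\\(Intercept\\)$", "Intercept", zt))
}

# Site-stacked sufficient statistics for the collapsed sampler. Z blocks
# are stacked so every marginal-likelihood evaluation is a handful of
# dense operations on a (q*S) x (q*S) block-diagonal system rather than a
# loop over sites.
lme_suffstats <- function(des) {
  sites <- levels(des$site)
  S <- length(sites)
  q <- ncol(des$Z); p <- ncol(des$X)
  ZtZbd <- matrix(0, q * S, q * S)
  ZtX <- matrix(0, q * S, p)
  Zty <- numeric(q * S)
  n_s <- integer(S)
  for (s in seq_len(S)) {
    i <- des$site == sites[s]
    rows <- (s - 1L) * q + seq_len(q)
    Zs <- des$Z[i, , drop = FALSE]
    ZtZbd[rows, rows] <- crossprod(Zs)
    ZtX[rows, ] <- crossprod(Zs, des$X[i, , drop = FALSE])
    Zty[rows] <- crossprod(Zs, des$y[i])
    n_s[s] <- sum(i)
  }
  # index template to fill kronecker(diag(S), L) without rebuilding it
  kron_ix <- which(kronecker(diag(S), matrix(1, q, q)) == 1)
  diag_ix <- seq(1L, (q * S)^2, by = q * S + 1L)
  list(sites = sites, S = S, q = q, p = p, n = length(des$y),
       diag_ix = diag_ix,
       ZtZbd = ZtZbd, ZtX = ZtX, Zty = Zty, n_s = n_s,
       XtX = crossprod(des$X), Xty = as.vector(crossprod(des$X, des$y)),
       yty = sum(des$y^2), kron_ix = kron_ix,
       Lbig = matrix(0, q * S, q * S))
}

# Marginal (site effects integrated out) log-likelihood given beta and the
# covariance pieces, plus priors on sds / correlation / sigma. With
# Sigma = L L', the per-site Woodbury identities stack into one
# block-diagonal q*S system: M = I + L'Z'Z L / sigma^2.
lme_marg_ll <- function(beta, sds, cR, sigma, ss, pr, keep = FALSE) {
  if (sigma <= 0 || any(sds < 0)) return(list(lp = -Inf))
  L <- sds * t(cR)                             # Sigma = L L', cR = chol(R)
  Lbig <- ss$Lbig
  Lbig[ss$kron_ix] <- L
  sig2 <- sigma^2
  M <- crossprod(Lbig, ss$ZtZbd %*% Lbig) / sig2
  M[ss$diag_ix] <- M[ss$diag_ix] + 1
  cM <- chol(M)                      # M = I + PSD is always factorizable
  Ztr <- ss$Zty - as.vector(ss$ZtX %*% beta)
  rtr <- ss$yty - 2 * sum(beta * ss$Xty) + sum(beta * (ss$XtX %*% beta))
  h <- as.vector(crossprod(Lbig, Ztr))
  w <- backsolve(cM, h, transpose = TRUE)    # h' M^-1 h = |w|^2
  quad <- (rtr - sum(w * w) / sig2) / sig2
  lp <- -0.5 * ss$n * log(2 * pi * sig2) - sum(log(cM[ss$diag_ix])) -
    0.5 * quad +
    (length(sds) + 1) * (log(2) - 0.918938533204672669541) -
    0.5 * (sum((sds / pr$re_sd)^2) + (sigma / pr$sigma_sd)^2) -
    sum(log(pr$re_sd)) - log(pr$sigma_sd) +
    (pr$lkj_eta - 1) * 2 * sum(log(diag(cR)))  # LKJ(eta) on R
  if (keep) list(lp = lp, L = L, Lbig = Lbig, cM = cM, Ztr = Ztr) else
    list(lp = lp)
}

#' Fit a Bayesian linear mixed-effects model by MCMC
#'
#' Hierarchical Gaussian model `y_i ~ Normal(X_i beta + Z_i u_site(i),
#' sigma)` with `u_site ~ MultiNormal(0, diag(sd) R diag(sd))`. Priors:
#' `beta ~ Normal(0, 1)`, `sigma` and the random-effect SDs half-Normal(0,
#' 1), and an LKJ(2) shape prior on the correlation matrix `R` (weakly
#' favoring identity). The sampler is a collapsed Gibbs scheme: random-effect
#' SDs, correlations and `sigma` are slice-sampled under the likelihood with
#' the site effects integrated out (which avoids the small-number-of-groups
#' funnel), `beta` is drawn from its exact Gaussian conditional (also with
#' `u` marginalized), and `u` is then drawn conditionally for the pointwise
#' log-likelihood matrix.
#'
#' @param records Participant records, already through QC and
#'   [standardize_within_site()] for all continuous model variables.
#' @param spec An [model_spec()] / [oldestold_model_spec()] object.
#' @param cfg A [run_config()]; convergence gates as in
#'   [fit_lifespan_model()].
#' @param on_gate_failure `"error"` (default), `"warn"`, or `"none"`.
#' @param prior_only Drop the likelihood and sample from the prior
#'   (default `FALSE`); used for prior-predictive checks.
#' @return Object of class `lme_fit`: `draws` (iterations x chains x
#'   parameters; `b[...]` fixed effects, `sd[...]`, `cor[...,...]`,
#'   `sigma`), `loglik` (total draws x n pointwise log-likelihood matrix,
#'   conditional on the sampled site effects), `u_draws`, `design`, `spec`,
#'   `diagnostics`.
#' @export
fit_lme <- function(records, spec, cfg = run_config(),
                    on_gate_failure = c("error", "warn", "none"),
                    prior_only = FALSE) {
  on_gate_failure <- match.arg(on_gate_failure)
  validate_config(cfg)
  des <- lme_design(records, spec)
  ss <- lme_suffstats(des)
  if (prior_only) {
    # empty likelihood: all data sufficient statistics vanish, so every
    # update reduces to its prior
    ss$ZtZbd[] <- 0; ss$ZtX[] <- 0; ss$Zty[] <- 0
    ss$XtX[] <- 0; ss$Xty[] <- 0; ss$yty <- 0; ss$n <- 0L
  }
  pr <- spec$priors
  p <- ncol(des$X); q <- ncol(des$Z); S <- ss$S; n <- length(des$y)
  cor_pairs <- if (q > 1) utils::combn(q, 2) else matrix(0, 2, 0)
  site_idx <- as.integer(des$site)

  pars <- c(sprintf("b[%s]", colnames(des$X)),
            sprintf("sd[%s]", des$re_terms),
            if (ncol(cor_pairs)) sprintf("cor[%s,%s]",
                                         des$re_terms[cor_pairs[1, ]],
                                         des$re_terms[cor_pairs[2, ]]),
            "sigma")
  n_keep <- cfg$n_iter - cfg$n_burnin
  draws <- array(NA_real_, dim = c(n_keep, cfg$n_chains, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  loglik <- matrix(NA_real_, n_keep * cfg$n_chains, n)
  u_draws <- array(NA_real_,
                   dim = c(n_keep, cfg$n_chains, S * q),
                   dimnames = list(NULL, NULL,
                                   paste0("u[", rep(ss$sites, each = q), ",",
                                          rep(des$re_terms, S), "]")))

  set.seed(cfg$seed)
  XtX_all <- crossprod(des$X)
  Xty_all <- crossprod(des$X, des$y)
  for (ch in seq_len(cfg$n_chains)) {
    beta <- as.vector(solve(XtX_all + diag(p), Xty_all)) +
      stats::rnorm(p, 0, 0.05)
    sigma <- stats::sd(des$y - des$X %*% beta) * exp(stats::rnorm(1, 0, 0.1))
    sds <- abs(stats::rnorm(q, 0, 0.1)) + 0.05
    rho <- rep(0, ncol(cor_pairs))
    R_template <- diag(q)
    build_R <- function(rho) {
      R <- R_template
      if (length(rho)) {
        for (k in seq_along(rho)) {
          R[cor_pairs[1, k], cor_pairs[2, k]] <- rho[k]
          R[cor_pairs[2, k], cor_pairs[1, k]] <- rho[k]
        }
      }
      R
    }
    safe_chol <- function(R) tryCatch(chol(R), error = function(e) NULL)
    cR <- diag(q)
    for (it in seq_len(cfg$n_iter)) {
      # scale/correlation block, u marginalized (slice, one at a time)
      for (j in seq_len(q)) {
        lsd <- slice_sample1(log(sds[j]), function(x) {
          s2 <- sds; s2[j] <- exp(x)
          lme_marg_ll(beta, s2, cR, sigma, ss, pr)$lp + x
        }, w = 0.6)
        sds[j] <- exp(lsd)
      }
      if (length(rho)) {
        for (k in seq_along(rho)) {
          rho[k] <- slice_sample1(rho[k], function(x) {
            r2 <- rho; r2[k] <- x
            cR2 <- safe_chol(build_R(r2))
            if (is.null(cR2)) return(-Inf)
            lme_marg_ll(beta, sds, cR2, sigma, ss, pr)$lp
          }, w = 0.5, lower = -1, upper = 1)
        }
        cR <- chol(build_R(rho))
      }
      lsig <- slice_sample1(log(sigma), function(x)
        lme_marg_ll(beta, sds, cR, exp(x), ss, pr)$lp + x, w = 0.3)
      sigma <- exp(lsig)

      # beta | theta with u marginalized: Gaussian conditional.
      # X'V^-1 X = (XtX - G' M^-1 G / sig2) / sig2 with G = L' Z'X stacked.
      L <- sds * t(cR)
      Lbig <- ss$Lbig
      Lbig[ss$kron_ix] <- L
      sig2 <- sigma^2
      M <- crossprod(Lbig, ss$ZtZbd %*% Lbig) / sig2
      M[ss$diag_ix] <- M[ss$diag_ix] + 1
      cM <- chol(M)
      G <- crossprod(Lbig, ss$ZtX)             # (q*S) x p
      W <- backsolve(cM, backsolve(cM, G, transpose = TRUE))
      A <- diag(p) / pr$beta_sd^2 + (ss$XtX - crossprod(G, W) / sig2) / sig2
      wy <- backsolve(cM, backsolve(cM, crossprod(Lbig, ss$Zty),
                                    transpose = TRUE))
      bvec <- (ss$Xty - as.vector(crossprod(G, wy)) / sig2) / sig2
      cA <- chol(A)
      bmean <- backsolve(cA, backsolve(cA, bvec, transpose = TRUE))
      beta <- as.vector(bmean + backsolve(cA, stats::rnorm(p)))

      if (it > cfg$n_burnin) {
        # u | beta, theta (exact conditional), then pointwise loglik
        Sig <- L %*% t(L)
        Sinv <- chol2inv(chol(Sig + diag(1e-10, q)))
        prec <- ss$ZtZbd / sig2
        prec[ss$kron_ix] <- prec[ss$kron_ix] + rep(as.vector(Sinv), S)
        cp <- chol(prec)
        Ztr <- ss$Zty - as.vector(ss$ZtX %*% beta)
        um <- backsolve(cp, backsolve(cp, Ztr / sig2, transpose = TRUE))
        u_all <- um + backsolve(cp, stats::rnorm(q * S))
        u <- matrix(u_all, S, q, byrow = TRUE)
        fitted <- as.vector(des$X %*% beta) +
          rowSums(des$Z * u[site_idx, , drop = FALSE])
        row <- it - cfg$n_burnin
        flat_row <- (ch - 1L) * n_keep + row
        loglik[flat_row, ] <- stats::dnorm(des$y, fitted, sigma, log = TRUE)
        draws[row, ch, ] <- c(beta, sds, rho, sigma)
        u_draws[row, ch, ] <- as.vector(t(u))
      }
    }
  }

  fit <- structure(list(draws = draws, loglik = loglik, u_draws = u_draws,
                        design = des, spec = spec,
                        diagnostics = NULL),
                   class = "lme_fit")
  fit$diagnostics <- diagnose_draws(draws)
  check_gates(fit$diagnostics, cfg, on_gate_failure)
  fit
}

#' Summary table of a mixed-model fit
#'
#' One row per monitored parameter: posterior mean, posterior SD
#' (estimation error), equal-tailed 95% credible bounds, split R-hat, bulk
#' and tail ESS — the layout of the cohort result tables.
#'
#' @param fit An `lme_fit`.
#' @return A data frame.
#' @export
lme_summary <- function(fit) {
  stopifnot(inherits(fit, "lme_fit"))
  flat <- draws_matrix(fit)
  qs <- apply(flat, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  d <- fit$diagnostics
  data.frame(parameter = colnames(flat),
             estimate = colMeans(flat),
             est_error = apply(flat, 2, stats::sd),
             lower_95 = qs[1, ], upper_95 = qs[2, ],
             rhat = d$rhat[match(colnames(flat), d$parameter)],
             ess_bulk = d$ess_bulk[match(colnames(flat), d$parameter)],
             ess_tail = d$ess_tail[match(colnames(flat), d$parameter)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bayesian R-squared of a mixed-model fit
#'
#' Per draw, the variance of the fitted linear predictor (including the
#' sampled site effects) divided by itself plus the draw's residual
#' variance.
#'
#' @param fit An `lme_fit`.
#' @return List with `mean`, `lower_95`, `upper_95`, and the per-draw `r2`
#'   vector.
#' @export
bayes_r2 <- function(fit) {
  stopifnot(inherits(fit, "lme_fit"))
  flat <- draws_matrix(fit)
  des <- fit$design
  q <- ncol(des$Z); S <- nlevels(des$site)
  beta_ix <- grep("^b\\[", colnames(flat))
  sigma_ix <- match("sigma", colnames(flat))
  uflat <- draws_matrix(list(draws = fit$u_draws))
  site_idx <- as.integer(des$site)
  n_draws <- nrow(flat)
  r2 <- numeric(n_draws)
  Xt <- t(des$X)
  for (sdr in seq_len(n_draws)) {
    u <- matrix(uflat[sdr, ], S, q, byrow = TRUE)
    fitted <- as.vector(flat[sdr, beta_ix] %*% Xt) +
      rowSums(des$Z * u[site_idx, , drop = FALSE])
    vf <- stats::var(fitted)
    denom <- vf + flat[sdr, sigma_ix]^2
    r2[sdr] <- if (denom == 0) NA_real_ else vf / denom
  }
  if (anyNA(r2)) warning("degenerate draws with zero fitted and residual ",
                         "variance; R^2 undefined there")
  qs <- stats::quantile(r2, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(mean = mean(r2, na.rm = TRUE), lower_95 = qs[1], upper_95 = qs[2],
       r2 = r2)
}

#' Conditional effect of age by sex
#'
#' Population-level predictions (site effects at zero) over the observed
#' standardized age range for both sexes, with the gray matter fraction
#' held at its standardized mean of 0, and equal-tailed 95% credible bands.
#'
#' @param fit An `lme_fit` of a model containing the age-by-sex
#'   interaction.
#' @param n_grid Number of grid points (default 25).
#' @return Data frame with `age` (standardized), `sex`, `posterior_mean`,
#'   `lower_95`, `upper_95`.
#' @export
conditional_effects_age_sex <- function(fit, n_grid = 25) {
  stopifnot(inherits(fit, "lme_fit"))
  flat <- draws_matrix(fit)
  cn <- colnames(flat)
  need <- c("b[(Intercept)]", "b[age]", "b[sex_male]", "b[age:sex_male]")
  if (!all(need %in% cn)) {
    stop("model does not contain the age-by-sex interaction")
  }
  ages <- seq(min(fit$design$X[, "age"]), max(fit$design$X[, "age"]),
              length.out = n_grid)
  out <- list()
  for (sex in c("female", "male")) {
    m <- as.numeric(sex == "male")
    pred <- outer(flat[, "b[(Intercept)]"] + m * flat[, "b[sex_male]"],
                  rep(1, n_grid)) +
      outer(flat[, "b[age]"] + m * flat[, "b[age:sex_male]"], ages)
    qs <- apply(pred, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    out[[sex]] <- data.frame(age = ages, sex = sex,
                             posterior_mean = colMeans(pred),
                             lower_95 = qs[1, ], upper_95 = qs[2, ],
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
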