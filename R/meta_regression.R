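# Hierarchical precision-weighted meta-regression.
#
# Per-experiment effects y (raw or percentage change) are modeled as
#
#   y = X beta + b_study + eps,   b_study ~ N(0, tau^2)
#
# with marginal covariance V = tau^2 Z Z' + Sigma.  Sigma is diagonal
# with per-record variances sigma^2 / w (w = 1/Var(y), the meta-analytic
# precision weight), except that records sharing a control arm form a
# block with constant residual correlation rho (block compound symmetry):
#
#   Sigma[i,j] = rho * sigma^2 / sqrt(w_i w_j)   (same block, i != j).
#
# Estimation is maximum likelihood: beta is profiled out by generalized
# least squares at each variance-parameter point and (sigma^2, tau^2,
# rho) are optimized numerically on transformed scales with deterministic
# multi-start.  ML (rather than REML) keeps likelihood-ratio generalized
# R^2 between nested fixed-effect structures valid.

.glmm_covariates <- c("TIME", "BENZALDEHYDE", "TEMPERATURE", "VOLTAGE",
                      "AC_DC", "RH", "DRIVER", "LOBE_CATEGORY",
                      "CELL_COUNT")
.rho_max <- 0.99

#' Specify a meta-regression model
#'
#' @param response `"percent_change"` or `"raw_change"`.
#' @param covariates character vector drawn from `TIME`, `BENZALDEHYDE`,
#'   `TEMPERATURE`, `VOLTAGE`, `AC_DC`, `RH`, `DRIVER`, `LOBE_CATEGORY`,
#'   `CELL_COUNT` (may be empty: intercept-only model).
#' @param residual_structure `"block_compound_symmetry"` (shared-control
#'   blocks correlated by a common `rho`) or `"diagonal"`.
#' @param reml reserved switch; only maximum likelihood is implemented.
#' @return list of class `"mb_glmm_spec"`.
#' @export
glmm_spec <- function(response = c("percent_change", "raw_change"),
                      covariates = character(0),
                      residual_structure = c("block_compound_symmetry",
                                             "diagonal"),
                      reml = FALSE) {
  response <- match.arg(response)
  residual_structure <- match.arg(residual_structure)
  covariates <- as.character(covariates)
  bad <- setdiff(covariates, .glmm_covariates)
  if (length(bad) > 0)
    stop("unknown covariates: ", paste(bad, collapse = ", "), call. = FALSE)
  if (isTRUE(reml))
    stop("REML is not implemented; estimation is ML", call. = FALSE)
  structure(list(response = response, covariates = covariates,
                 residual_structure = residual_structure),
            class = "mb_glmm_spec")
}

#' Assemble the model frame for a meta-regression
#'
#' Computes per-record effects and precision weights, builds the design
#' matrix (numeric covariates are centered at their precision-weighted
#' means so the intercept is the covariate-adjusted mean effect), and
#' attaches study clusters and shared-control blocks.
#'
#' @param ds [mb_dataset()] with PI summaries.
#' @param spec a [glmm_spec()].
#' @param cellcounts optional data frame `driver`, `cell_count`; required
#'   when `CELL_COUNT` is a covariate.
#' @return list with `y`, `X`, `w`, `study`, `block`, `driver`, `centers`,
#'   `structure`.
#' @export
build_model_frame <- function(ds, spec, cellcounts = NULL) {
  stopifnot(inherits(spec, "mb_glmm_spec"))
  es <- compute_effects(ds, scale = if (spec$response == "percent_change")
                                      "percent" else "raw")
  w <- 1 / es$var
  if (any(!is.finite(w) | w <= 0))
    stop("precision weights must be positive and finite (zero-variance ",
         "records cannot be weighted)", call. = FALSE)
  n <- nrow(ds)
  cols <- list(`(Intercept)` = rep(1, n))
  centers <- c()
  num_cov <- function(name, x) {
    if (any(is.na(x)))
      stop("covariate ", name, " is missing for some records", call. = FALSE)
    ctr <- sum(w * x) / sum(w)
    centers[[name]] <<- ctr
    cols[[name]] <<- x - ctr
  }
  fac_cov <- function(name, x) {
    x <- as.factor(as.character(x))
    if (nlevels(x) > 1) {
      mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
      colnames(mm) <- paste0(name, levels(x)[-1])
      for (cn in colnames(mm)) cols[[cn]] <<- mm[, cn]
    }
  }
  for (cv in spec$covariates) {
    switch(cv,
      TIME = num_cov("TIME", ds$delay_min),
      BENZALDEHYDE = cols[["BENZALDEHYDE"]] <- as.numeric(ds$benzaldehyde),
      TEMPERATURE = num_cov("TEMPERATURE", ds$temperature_c),
      VOLTAGE = num_cov("VOLTAGE", ds$shock_v),
      RH = num_cov("RH", ds$rh_pct),
      AC_DC = fac_cov("AC_DC", ds$current_type),
      DRIVER = fac_cov("DRIVER", ds$driver),
      LOBE_CATEGORY = fac_cov("LOBE_CATEGORY", ds$lobe_category),
      CELL_COUNT = {
        if (is.null(cellcounts))
          stop("CELL_COUNT covariate needs a cellcounts table", call. = FALSE)
        cc <- cellcounts$cell_count[match(ds$driver, cellcounts$driver)]
        num_cov("CELL_COUNT", cc)
      })
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  block <- ds$shared_control_id
  if (spec$residual_structure == "block_compound_symmetry") {
    if (all(is.na(block) | !nzchar(block)))
      stop("block_compound_symmetry requires shared_control_id on at ",
           "least one record", call. = FALSE)
  }
  # records without a shared control are their own singleton blocks
  solo <- is.na(block) | !nzchar(block)
  block[solo] <- paste0(".solo", seq_len(n))[solo]
  list(y = es$estimate, X = X, w = w, study = as.character(ds$study_id),
       block = as.character(block), driver = as.character(ds$driver),
       centers = centers, structure = spec$residual_structure)
}

# Dense covariance evaluation is avoided: V is block-diagonal by study
# (shared-control blocks never span studies), so the likelihood is a sum
# of per-study chol factorizations.
.glmm_loglik_frame <- function(beta, tau2, rho, sigma2, fr) {
  if (sigma2 <= 0 || tau2 < 0 || rho < 0 || rho >= 1)
    stop("variance parameters out of domain", call. = FALSE)
  r <- fr$y - drop(fr$X %*% beta)
  ll <- 0
  for (idx in split(seq_along(fr$y), fr$study)) {
    m <- length(idx)
    Vi <- matrix(tau2, m, m)
    sd_i <- sqrt(sigma2 / fr$w[idx])
    if (fr$structure == "block_compound_symmetry" && rho > 0) {
      same <- outer(fr$block[idx], fr$block[idx], "==")
      R <- ifelse(same, rho, 0)
      diag(R) <- 1
      Vi <- Vi + outer(sd_i, sd_i) * R
    } else {
      Vi <- Vi + diag(sd_i^2, m)
    }
    ch <- tryCatch(chol(Vi), error = function(e)
      stop("residual covariance is not positive definite", call. = FALSE))
    z <- backsolve(ch, r[idx], transpose = TRUE)
    ll <- ll - sum(log(diag(ch))) - 0.5 * sum(z^2)
  }
  ll - 0.5 * length(fr$y) * log(2 * pi)
}

# GLS profile of beta and the resulting profiled log-likelihood.
.gls_profile <- function(tau2, rho, sigma2, fr) {
  n <- length(fr$y)
  XtVX <- matrix(0, ncol(fr$X), ncol(fr$X))
  XtVy <- numeric(ncol(fr$X))
  pieces <- list()
  for (idx in split(seq_len(n), fr$study)) {
    m <- length(idx)
    Vi <- matrix(tau2, m, m)
    sd_i <- sqrt(sigma2 / fr$w[idx])
    if (fr$structure == "block_compound_symmetry" && rho > 0) {
      same <- outer(fr$block[idx], fr$block[idx], "==")
      R <- ifelse(same, rho, 0)
      diag(R) <- 1
      Vi <- Vi + outer(sd_i, sd_i) * R
    } else {
      Vi <- Vi + diag(sd_i^2, m)
    }
    ch <- tryCatch(chol(Vi), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Xi <- backsolve(ch, fr$X[idx, , drop = FALSE], transpose = TRUE)
    yi <- backsolve(ch, fr$y[idx], transpose = TRUE)
    XtVX <- XtVX + crossprod(Xi)
    XtVy <- XtVy + crossprod(Xi, yi)
    pieces[[length(pieces) + 1L]] <- list(idx = idx, ch = ch)
  }
  beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  r <- fr$y - drop(fr$X %*% beta)
  quad <- 0; ldet <- 0
  for (p in pieces) {
    z <- backsolve(p$ch, r[p$idx], transpose = TRUE)
    quad <- quad + sum(z^2)
    ldet <- ldet + 2 * sum(log(diag(p$ch)))
  }
  ll <- -0.5 * (n * log(2 * pi) + ldet + quad)
  list(beta = drop(beta), vcov_beta = solve(XtVX), loglik = ll,
       residuals = r)
}

#' Gaussian log-likelihood of a meta-regression model
#'
#' Evaluates the marginal log-likelihood at a given parameter point.
#' Exposed mainly so the likelihood surface can be checked against a
#' dense multivariate-normal evaluation.
#'
#' @param params list with `beta` (coefficient vector in design-matrix
#'   order), `tau2`, `rho`, `sigma2`.
#' @param spec a [glmm_spec()].
#' @param ds [mb_dataset()] with PI summaries.
#' @param cellcounts optional driver/cell-count table (see
#'   [build_model_frame()]).
#' @return scalar log-likelihood.
#' @export
glmm_loglik <- function(params, spec, ds, cellcounts = NULL) {
  fr <- build_model_frame(ds, spec, cellcounts)
  if (length(params$beta) != ncol(fr$X))
    stop("beta has length ", length(params$beta), ", design has ",
         ncol(fr$X), " columns", call. = FALSE)
  .glmm_loglik_frame(params$beta, params$tau2, params$rho, params$sigma2,
                     fr)
}

.fit_glmm_frame <- function(fr, n_starts = 5, tol = 1e-8) {
  n <- length(fr$y)
  free_tau <- length(unique(fr$study)) >= 2
  free_rho <- fr$structure == "block_compound_symmetry" &&
    any(duplicated(fr$block))
  # WLS starting point
  wls <- stats::lm.wfit(fr$X, fr$y, fr$w)
  p <- ncol(fr$X)
  s2_0 <- sum(fr$w * wls$residuals^2) / max(1, n - p)
  if (s2_0 <= 0) s2_0 <- 1e-6
  tau_0 <- if (free_tau) {
    sm <- tapply(wls$residuals, fr$study, mean)
    max(stats::var(sm) * 0.5, s2_0 * 1e-3, na.rm = TRUE)
  } else 0
  # deterministic multistart: no RNG so caller seeds are untouched
  s2_mult <- c(1, 0.3, 3, 0.1, 10)
  tau_mult <- c(1, 3, 0.3, 10, 0.1)
  rho_0 <- c(0.2, 0.05, 0.5, 0.8, 0.35)
  unpack <- function(th) {
    k <- 1L
    sigma2 <- exp(th[k]); k <- k + 1L
    tau2 <- if (free_tau) exp(th[k]) else 0
    if (free_tau) k <- k + 1L
    rho <- if (free_rho) .rho_max * stats::plogis(th[k]) else 0
    list(sigma2 = sigma2, tau2 = tau2, rho = rho)
  }
  negll <- function(th) {
    pr <- unpack(th)
    out <- .gls_profile(pr$tau2, pr$rho, pr$sigma2, fr)
    if (is.null(out) || !is.finite(out$loglik)) return(1e10)
    -out$loglik
  }
  best <- NULL
  conv <- FALSE
  for (s in seq_len(min(n_starts, 5))) {
    th0 <- log(s2_0 * s2_mult[s])
    if (free_tau) th0 <- c(th0, log(max(tau_0 * tau_mult[s], 1e-8)))
    if (free_rho) th0 <- c(th0, stats::qlogis(rho_0[s] / .rho_max))
    opt <- tryCatch(
      stats::nlminb(th0, negll,
                    control = list(rel.tol = tol, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective - 1e-12) {
      best <- opt
      conv <- opt$convergence == 0
    }
  }
  if (is.null(best)) stop("meta-regression optimization failed entirely",
                          call. = FALSE)
  pr <- unpack(best$par)
  fit <- .gls_profile(pr$tau2, pr$rho, pr$sigma2, fr)
  structure(list(
    beta = stats::setNames(fit$beta, colnames(fr$X)),
    se_beta = stats::setNames(sqrt(diag(fit$vcov_beta)), colnames(fr$X)),
    vcov_beta = fit$vcov_beta,
    tau2 = pr$tau2, rho = pr$rho, sigma2 = pr$sigma2,
    loglik = fit$loglik, residuals = fit$residuals,
    fitted = fr$y - fit$residuals,
    n = n, converged = conv,
    free = c(tau2 = free_tau, rho = free_rho),
    frame = fr), class = "mb_glmm")
}

#' Fit a hierarchical precision-weighted meta-regression
#'
#' Maximum-likelihood fit of the mixed model described in the package
#' vignette: fixed covariate effects, a study-level random effect, and
#' (for shared-control designs) block compound-symmetric residual
#' correlation.  With fewer than 2 studies `tau^2` is fixed at 0; with no
#' multi-record shared-control block `rho` is fixed at 0 (each with a
#' warning).
#'
#' @param spec a [glmm_spec()].
#' @param ds [mb_dataset()] with PI summaries.
#' @param cellcounts optional driver/cell-count table.
#' @param n_starts number of deterministic multistart points (max 5).
#' @param tol relative convergence tolerance on the log-likelihood.
#' @return object of class `"mb_glmm"`; `converged = FALSE` flags a fit
#'   that did not meet the optimizer's criteria.
#' @export
fit_glmm <- function(spec, ds, cellcounts = NULL, n_starts = 5,
                     tol = 1e-8) {
  fr <- build_model_frame(ds, spec, cellcounts)
  if (length(unique(fr$study)) < 2)
    warning("fewer than 2 study clusters: tau^2 fixed at 0")
  if (fr$structure == "block_compound_symmetry" &&
      !any(duplicated(fr$block)))
    warning("no multi-record shared-control block: rho fixed at 0")
  fit <- .fit_glmm_frame(fr, n_starts = n_starts, tol = tol)
  fit$spec <- spec
  if (!fit$converged) warning("meta-regression fit did not converge")
  fit
}

#' @export
print.mb_glmm <- function(x, ...) {
  cat(sprintf("<mb_glmm> n = %d, logLik = %.3f%s\n", x$n, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  sigma^2 = %.4g, tau^2 = %.4g, rho = %.3f\n",
              x$sigma2, x$tau2, x$rho))
  coefs <- cbind(estimate = x$beta, se = x$se_beta)
  print(round(coefs, 4))
  invisible(x)
}

#' Likelihood-ratio generalized R-squared
#'
#' `R^2 = 1 - exp(-(2/n) * (logLik_full - logLik_null))` for two nested
#' ML fits on the same records.  An optional nonparametric bootstrap over
#' experiments gives a percentile confidence interval.
#'
#' @param full,null `"mb_glmm"` fits; the null's design columns must be a
#'   subset of the full's and both must use the same `n` records.
#' @param bootstrap number of bootstrap resamples (0 = point estimate
#'   only; default 0, use e.g. 2000 for reporting).
#' @param seed RNG seed for the bootstrap.
#' @param level confidence level.
#' @return list with `r2` and, when bootstrapped, `ci` and `boot`.
#' @export
generalized_r2 <- function(full, null, bootstrap = 0, seed = 1,
                           level = 0.95) {
  stopifnot(inherits(full, "mb_glmm"), inherits(null, "mb_glmm"))
  if (full$n != null$n)
    stop("fits use different numbers of records", call. = FALSE)
  if (!all(colnames(null$frame$X) %in% colnames(full$frame$X)))
    stop("null model is not nested in the full model", call. = FALSE)
  r2_of <- function(lf, ln, n) {
    max(0, min(1, 1 - exp(-(2 / n) * (lf - ln))))
  }
  r2 <- r2_of(full$loglik, null$loglik, full$n)
  if (bootstrap <= 0) return(list(r2 = r2, ci = NULL))
  subset_frame <- function(fr, idx) {
    list(y = fr$y[idx], X = fr$X[idx, , drop = FALSE], w = fr$w[idx],
         study = fr$study[idx], block = fr$block[idx],
         driver = fr$driver[idx], centers = fr$centers,
         structure = fr$structure)
  }
  n <- full$n
  boots <- numeric(bootstrap)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  for (b in seq_len(bootstrap)) {
    idx <- sample.int(n, n, replace = TRUE)
    ff <- tryCatch(.fit_glmm_frame(subset_frame(full$frame, idx),
                                   n_starts = 2),
                   error = function(e) NULL)
    nf <- tryCatch(.fit_glmm_frame(subset_frame(null$frame, idx),
                                   n_starts = 2),
                   error = function(e) NULL)
    boots[b] <- if (is.null(ff) || is.null(nf)) NA_real_
                else r2_of(ff$loglik, nf$loglik, n)
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(r2 = r2, ci = ci, boot = boots)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Residual learning effect per driver
#'
#' Summarizes the covariate-adjusted record values of a fitted
#' meta-regression by driver line, converts them to the learning scale,
#' and subtracts the no-intervention reference (40 for the rutabaga
#' mutant baseline, 83 for the heat-effect baseline).
#'
#' @param fit converged `"mb_glmm"` on the `percent_change` response.
#' @param reference learning-percent reference level to subtract.
#' @param variant `"fitted"` (default): per-record adjusted value is the
#'   model intercept plus the marginal residual, i.e. the observation
#'   stripped of centered-covariate contributions; `"residual"`: the
#'   residual about the overall fitted mean.
#' @param cellcounts optional data frame `driver`, `cell_count` merged
#'   into the result (drivers without counts get `NA`).
#' @param lobe_categories optional data frame `driver`, `lobe_category`.
#' @return data frame of class `"mb_driver_effects"`: `driver`, `effect`
#'   (%, reference-rescaled), `se`, `n_experiments`, `cell_count`,
#'   `per_cell_effect`, `lobe_category`.
#' @export
residual_driver_effects <- function(fit, reference,
                                    variant = c("fitted", "residual"),
                                    cellcounts = NULL,
                                    lobe_categories = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(fit, "mb_glmm"))
  if (!fit$converged)
    stop("fit did not converge; refusing to summarize residuals",
         call. = FALSE)
  fr <- fit$frame
  has_driver <- !is.na(fr$driver) & fr$driver != "NA"
  if (!any(has_driver))
    stop("no records with a driver label", call. = FALSE)
  base <- switch(variant,
    fitted = fit$beta[["(Intercept)"]] + fit$residuals,
    residual = sum(fr$w * fit$fitted) / sum(fr$w) + fit$residuals)
  adj <- 100 + base - reference
  out <- do.call(rbind, lapply(split(which(has_driver), fr$driver[has_driver]),
    function(idx) {
      wi <- fr$w[idx]
      a <- adj[idx]
      m <- sum(wi * a) / sum(wi)
      n_d <- length(idx)
      se <- if (n_d >= 2) {
        wn <- wi / sum(wi)
        sqrt(sum(wn * (a - m)^2) * n_d / (n_d - 1)) / sqrt(n_d)
      } else sqrt(fit$sigma2 / wi)
      data.frame(driver = fr$driver[idx[1]], effect = m, se = se,
                 n_experiments = n_d, stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out$cell_count <- if (is.null(cellcounts)) NA_real_ else
    cellcounts$cell_count[match(out$driver, cellcounts$driver)]
  out$per_cell_effect <- ifelse(!is.na(out$cell_count) & out$cell_count > 0,
                                out$effect / out$cell_count, NA_real_)
  out$lobe_category <- if (is.null(lobe_categories)) NA_character_ else
    lobe_categories$lobe_category[match(out$driver,
                                        lobe_categories$driver)]
  class(out) <- c("mb_driver_effects", "data.frame")
  out
}

#' Weighted driver cell-count regression
#'
#' Linear meta-regression of per-driver residual learning effects on
#' Kenyon-cell counts, weighted by the number of contributing experiments,
#' with t-distribution confidence intervals for the slope and a
#' likelihood-ratio generalized R-squared against the intercept-only
#' model.
#'
#' @param effects an `"mb_driver_effects"` data frame (needs >= 3 drivers
#'   with cell counts).
#' @param level confidence level for the slope interval.
#' @return list: `slope` (%/cell), `slope_se`, `ci` (length 2),
#'   `intercept`, `r2_generalized`, `p`, `n`, `excluded` (drivers without
#'   counts).
#' @export
cellcount_regression <- function(effects, level = 0.95) {
  stopifnot(inherits(effects, "data.frame"))
  keep <- !is.na(effects$cell_count)
  excluded <- effects$driver[!keep]
  eff <- effects[keep, , drop = FALSE]
  if (nrow(eff) < 3)
    stop("need at least 3 drivers with cell counts", call. = FALSE)
  if (length(unique(eff$cell_count)) < 2)
    stop("all cell counts are equal: slope is unidentifiable",
         call. = FALSE)
  w <- eff$n_experiments
  fit <- stats::lm(effect ~ cell_count, data = eff, weights = w)
  sm <- summary(fit)
  slope <- sm$coefficients["cell_count", "Estimate"]
  se <- sm$coefficients["cell_count", "Std. Error"]
  dfres <- fit$df.residual
  tcrit <- stats::qt(1 - (1 - level) / 2, dfres)
  p <- 2 * stats::pt(-abs(slope / se), dfres)
  n <- nrow(eff)
  ll_w <- function(r) {
    s2 <- max(sum(w * r^2) / n, 1e-12)
    -n / 2 * log(2 * pi * s2) + 0.5 * sum(log(w)) - n / 2 *
      (sum(w * r^2) / (n * s2))
  }
  r_full <- stats::residuals(fit)
  r_null <- eff$effect - sum(w * eff$effect) / sum(w)
  r2g <- max(0, min(1, 1 - exp(-(2 / n) * (ll_w(r_full) - ll_w(r_null)))))
  list(slope = slope, slope_se = se,
       ci = c(slope - tcrit * se, slope + tcrit * se),
       intercept = sm$coefficients["(Intercept)", "Estimate"],
       r2_generalized = r2g, p = p, n = n, excluded = excluded)
}

#' Per-cell lobe potency model
#'
#' Divides each driver's residual learning effect (and SE) by its cell
#' count and synthesizes the per-cell effects by lobe category with
#' inverse-variance weights, giving one estimate and CI per category plus
#' all pairwise category differences.
#'
#' @param effects `"mb_driver_effects"` with `cell_count` and
#'   `lobe_category` populated.
#' @param level confidence level.
#' @return list with `categories` (data frame: `lobe_category`,
#'   `estimate` %/cell, `se`, `ci_low`, `ci_high`, `k`) and `pairwise`
#'   (differences with CIs), plus `excluded` drivers (no or zero count).
#' @export
per_cell_model <- function(effects, level = 0.95) {
  keep <- !is.na(effects$cell_count) & effects$cell_count > 0 &
    !is.na(effects$lobe_category)
  excluded <- effects$driver[!keep]
  if (length(excluded) > 0)
    warning("excluded drivers without usable cell counts/categories: ",
            paste(excluded, collapse = ", "))
  eff <- effects[keep, , drop = FALSE]
  if (nrow(eff) == 0) stop("no usable drivers", call. = FALSE)
  pc <- eff$effect / eff$cell_count
  pc_se <- eff$se / eff$cell_count
  z <- stats::qnorm(1 - (1 - level) / 2)
  cats <- do.call(rbind, lapply(split(seq_len(nrow(eff)),
                                      eff$lobe_category), function(idx) {
    if (all(pc_se[idx] == 0)) {
      est <- mean(pc[idx]); se <- 0
    } else if (any(pc_se[idx] == 0)) {
      est <- mean(pc[idx][pc_se[idx] == 0]); se <- 0
    } else {
      wi <- 1 / pc_se[idx]^2
      est <- sum(wi * pc[idx]) / sum(wi)
      se <- 1 / sqrt(sum(wi))
    }
    data.frame(lobe_category = eff$lobe_category[idx[1]], estimate = est,
               se = se, ci_low = est - z * se, ci_high = est + z * se,
               k = length(idx), stringsAsFactors = FALSE)
  }))
  rownames(cats) <- NULL
  pairs <- NULL
  if (nrow(cats) >= 2) {
    cmb <- utils::combn(nrow(cats), 2)
    pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      d <- cats$estimate[i1] - cats$estimate[i2]
      se <- sqrt(cats$se[i1]^2 + cats$se[i2]^2)
      data.frame(a = cats$lobe_category[i1], b = cats$lobe_category[i2],
                 difference = d, se = se,
                 ci_low = d - z * se, ci_high = d + z * se,
                 stringsAsFactors = FALSE)
    }))
  }
  list(categories = cats, pairwise = pairs, excluded = excluded)
}
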