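# Inverse-variance random-effects pooling in the style of the Cochrane
# tooling the source analyses used: DerSimonian-Laird between-study
# variance, Q/I^2 heterogeneity from the fixed-effect weights, and
# subgroup analyses with their own tau^2 per subgroup.

#' DerSimonian-Laird between-study variance
#'
#' Moment estimator `tau^2 = max(0, (Q - df) / C)` with
#' `C = sum(w) - sum(w^2)/sum(w)` and fixed-effect weights `w = 1/var`.
#'
#' @param es `mb_effects` (or data frame with `estimate` and `var`).
#' @return Nonnegative scalar.
#' @export
dl_tau2 <- function(es) {
  y <- es$estimate
  v <- es$var
  if (length(y) < 2) stop("need at least 2 estimates", call. = FALSE)
  if (any(v <= 0)) stop("all variances must be positive", call. = FALSE)
  w <- 1 / v
  yb <- sum(w * y) / sum(w)
  q <- sum(w * (y - yb)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (length(y) - 1)) / cc)
}

.meta_core <- function(es, tau2 = NULL) {
  y <- es$estimate
  v <- es$var
  k <- length(y)
  scale <- unique(es$scale)[1]
  if (k == 1) {
    pooled <- .mk_effects(y, sqrt(v), scale,
                          n_exp = es$n_exp, n_ctrl = es$n_ctrl,
                          source = "pooled")
    return(list(pooled = pooled, tau2 = 0, q = 0, df = 0L, i2 = 0,
                k = 1L, weights = 1))
  }
  w_fe <- 1 / v
  yb <- sum(w_fe * y) / sum(w_fe)
  q <- sum(w_fe * (y - yb)^2)
  df <- k - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  if (is.null(tau2)) tau2 <- dl_tau2(es)
  w_re <- 1 / (v + tau2)
  est <- sum(w_re * y) / sum(w_re)
  se <- 1 / sqrt(sum(w_re))
  pooled <- .mk_effects(est, se, scale,
                        n_exp = sum(es$n_exp), n_ctrl = sum(es$n_ctrl),
                        source = "pooled")
  list(pooled = pooled, tau2 = tau2, q = q, df = df, i2 = i2, k = k,
       weights = w_re / sum(w_re))
}

#' Random-effects meta-analysis
#'
#' Pools effect sizes with inverse-variance random-effects weights
#' `1/(var + tau^2)`; heterogeneity (`Q`, `I^2`) is computed from the
#' fixed-effect weights.  A single estimate is passed through unchanged
#' with `tau^2 = 0`.
#'
#' @param es `mb_effects`, all on one scale, with positive variances
#'   (unless a single estimate).
#' @return An object of class `"mb_meta"`.
#' @export
pool_random_effects <- function(es) {
  if (is.null(es) || nrow(es) == 0)
    stop("no estimates to pool", call. = FALSE)
  if (length(unique(es$scale)) > 1)
    stop("cannot pool effects on different scales", call. = FALSE)
  if (nrow(es) >= 2 && any(es$var <= 0))
    stop("all variances must be positive", call. = FALSE)
  out <- .meta_core(es)
  out$estimates <- es
  out$subgroups <- NULL
  out$q_between <- NA_real_
  out$i2_subgroup <- NA_real_
  class(out) <- "mb_meta"
  out
}

#' Subgroup random-effects meta-analysis
#'
#' Each subgroup receives its own DerSimonian-Laird `tau^2` (singletons
#' are reported without pooling).  Between-subgroup heterogeneity is
#' `Q_between = Q_total - sum(Q_within)` with
#' `I^2_subgroup = max(0, (Q_between - (g-1))/Q_between) * 100`.
#'
#' @param es `mb_effects`.
#' @param grouping character/factor label per estimate.
#' @return `"mb_meta"` with a `subgroups` list of per-label `"mb_meta"`
#'   results (in first-appearance order), `q_between` and `i2_subgroup`.
#' @export
subgroup_analysis <- function(es, grouping) {
  if (length(grouping) != nrow(es))
    stop("grouping must label every estimate", call. = FALSE)
  if (any(is.na(grouping)))
    stop("grouping labels must not be missing", call. = FALSE)
  labels <- unique(as.character(grouping))
  if (length(labels) == 0) stop("empty subgroup label set", call. = FALSE)
  overall <- pool_random_effects(es)
  subs <- lapply(labels, function(lb) {
    pool_random_effects(es[grouping == lb, , drop = FALSE])
  })
  names(subs) <- labels
  q_within <- sum(vapply(subs, function(m) m$q, numeric(1)))
  q_between <- max(0, overall$q - q_within)
  g <- length(labels)
  i2_sub <- if (q_between > 0) max(0, (q_between - (g - 1)) / q_between) * 100
            else 0
  overall$subgroups <- subs
  overall$q_between <- q_between
  overall$i2_subgroup <- i2_sub
  overall$grouping <- as.character(grouping)
  overall
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and
#' a two-sided p-value.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (!is.finite(va) || !is.finite(vb))
    stop("groups must have finite variance", call. = FALSE)
  if (va + vb == 0) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
  tt <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Forest-plot table
#'
#' Flattens a meta-analysis into the rows a forest plot draws: one line
#' per study (with its percentage weight in the pooled set), a diamond per
#' subgroup, and the overall diamond.  Study rows keep input order within
#' their subgroup.
#'
#' @param meta an `"mb_meta"` object.
#' @return Data frame with columns `row_type` (`study`, `subgroup`,
#'   `overall`), `label`, `subgroup`, `estimate`, `ci_low`, `ci_high`,
#'   `weight_pct`, `k`, `tau2`, `i2`.
#' @export
forest_table <- function(meta) {
  stopifnot(inherits(meta, "mb_meta"))
  mk_row <- function(row_type, label, subgroup, est, lo, hi, w, k, tau2,
                     i2) {
    data.frame(row_type = row_type, label = label, subgroup = subgroup,
               estimate = est, ci_low = lo, ci_high = hi, weight_pct = w,
               k = k, tau2 = tau2, i2 = i2, stringsAsFactors = FALSE)
  }
  study_rows <- function(m, subgroup) {
    es <- m$estimates
    do.call(rbind, lapply(seq_len(nrow(es)), function(i) {
      mk_row("study", es$source[i], subgroup, es$estimate[i],
             es$ci_low[i], es$ci_high[i], 100 * m$weights[i], 1L, NA, NA)
    }))
  }
  diamond <- function(m, row_type, label) {
    p <- m$pooled
    mk_row(row_type, label, label, p$estimate, p$ci_low, p$ci_high,
           NA_real_, m$k, m$tau2, m$i2)
  }
  if (is.null(meta$subgroups)) {
    out <- rbind(study_rows(meta, NA_character_),
                 diamond(meta, "overall", "overall"))
  } else {
    parts <- lapply(names(meta$subgroups), function(lb) {
      m <- meta$subgroups[[lb]]
      # study weights are normalized within their subgroup's pooled set
      rbind(study_rows(m, lb), diamond(m, "subgroup", lb))
    })
    out <- rbind(do.call(rbind, parts),
                 diamond(meta, "overall", "overall"))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.mb_meta <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(
    "<mb_meta> k = %d, pooled = %.2f [%.2f, %.2f] (%s)\n",
    x$k, p$estimate, p$ci_low, p$ci_high, p$scale))
  cat(sprintf("  tau^2 = %.3f, Q = %.2f (df %d), I^2 = %.1f%%\n",
              x$tau2, x$q, x$df, x$i2))
  if (!is.null(x$subgroups)) {
    cat(sprintf("  %d subgroups, Q_between = %.2f, subgroup I^2 = %.1f%%\n",
                length(x$subgroups), x$q_between, x$i2_subgroup))
  }
  invisible(x)
}
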