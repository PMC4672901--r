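# Effect sizes for two-arm PI summaries.
#
# The headline metric is the percentage change of the experimental arm's
# mean Performance Index relative to its control, with a delta-method
# standard error for the ratio of two independent means:
#
#   pct = 100 * (m_e / m_c - 1)
#   SE(pct) = 100 * |m_e / m_c| * sqrt(cv_e^2 + cv_c^2),  cv = SE(m)/m
#
# Raw PI differences are carried alongside since the two give equivalent
# inferences on these data.  All intervals use the normal 1.96 multiplier.

.z95 <- stats::qnorm(0.975)

.effect_scales <- c("raw_pi", "percent_change", "learning_percent",
                    "rescue_percent", "heat_adjusted_percent")

.mk_effects <- function(estimate, se, scale, n_exp = NA_integer_,
                        n_ctrl = NA_integer_, source = NA_character_) {
  stopifnot(scale %in% .effect_scales)
  out <- data.frame(
    source = source, estimate = estimate, se = se, var = se^2,
    ci_low = estimate - .z95 * se, ci_high = estimate + .z95 * se,
    scale = scale, n_exp = n_exp, n_ctrl = n_ctrl,
    stringsAsFactors = FALSE)
  class(out) <- c("mb_effects", "data.frame")
  out
}

.check_scale <- function(es, expected) {
  stopifnot(inherits(es, "mb_effects"))
  if (!all(es$scale == expected)) {
    stop("expected effects on the '", expected, "' scale, got: ",
         paste(unique(es$scale), collapse = ", "), call. = FALSE)
  }
  invisible(es)
}

#' Percentage-change effect size with delta-method SE
#'
#' @param m_exp,se_exp mean PI and SEM of the experimental arm.
#' @param m_ctrl,se_ctrl mean PI and SEM of the control arm.
#' @param n_exp,n_ctrl optional iteration counts, carried along.
#' @param source optional record labels.
#' @return An `mb_effects` data frame (one row per input element) on the
#'   `percent_change` scale.
#' @export
percent_change <- function(m_exp, se_exp, m_ctrl, se_ctrl,
                           n_exp = NA_integer_, n_ctrl = NA_integer_,
                           source = NA_character_) {
  if (any(se_exp < 0, na.rm = TRUE) || any(se_ctrl < 0, na.rm = TRUE))
    stop("standard errors must be nonnegative", call. = FALSE)
  if (any(m_ctrl == 0, na.rm = TRUE))
    stop("control mean of 0 leaves the percentage change undefined",
         call. = FALSE)
  if (any(m_exp == 0 & se_exp > 0, na.rm = TRUE))
    stop("experimental mean of 0 with positive SE: delta-method CV is ",
         "degenerate; use raw_change() instead", call. = FALSE)
  ratio <- m_exp / m_ctrl
  cv2 <- ifelse(m_exp == 0, 0, (se_exp / m_exp)^2) + (se_ctrl / m_ctrl)^2
  .mk_effects(estimate = 100 * (ratio - 1),
              se = 100 * abs(ratio) * sqrt(cv2),
              scale = "percent_change",
              n_exp = n_exp, n_ctrl = n_ctrl, source = source)
}

#' Raw PI-difference effect size
#'
#' @inheritParams percent_change
#' @return An `mb_effects` data frame on the `raw_pi` scale.
#' @export
raw_change <- function(m_exp, se_exp, m_ctrl, se_ctrl,
                       n_exp = NA_integer_, n_ctrl = NA_integer_,
                       source = NA_character_) {
  if (any(se_exp < 0, na.rm = TRUE) || any(se_ctrl < 0, na.rm = TRUE))
    stop("standard errors must be nonnegative", call. = FALSE)
  .mk_effects(estimate = m_exp - m_ctrl,
              se = sqrt(se_exp^2 + se_ctrl^2),
              scale = "raw_pi",
              n_exp = n_exp, n_ctrl = n_ctrl, source = source)
}

#' Convert a percentage change to the learning scale
#'
#' Learning as a percentage of wild type memory is the impairment effect
#' plus 100; a -60% change thus reads as 40% of wild-type learning.  SEs
#' and interval widths are unchanged.
#'
#' @param es `mb_effects` on the `percent_change` scale.
#' @return `mb_effects` on the `learning_percent` scale.
#' @export
to_learning_scale <- function(es) {
  .check_scale(es, "percent_change")
  .mk_effects(estimate = 100 + es$estimate, se = es$se,
              scale = "learning_percent",
              n_exp = es$n_exp, n_ctrl = es$n_ctrl, source = es$source)
}

#' Rescue relative to the mutant baseline
#'
#' Subtracts the pooled mutant learning level (40% of wild type for the
#' strong rutabaga hypomorphs) so that 0 means "no rescue".
#'
#' @param es `mb_effects` on the `learning_percent` scale.
#' @param mutant_ref mutant learning level in percent.
#' @return `mb_effects` on the `rescue_percent` scale.
#' @export
rescue_relative <- function(es, mutant_ref) {
  .check_scale(es, "learning_percent")
  stopifnot(is.numeric(mutant_ref), length(mutant_ref) == 1)
  .mk_effects(estimate = es$estimate - mutant_ref, se = es$se,
              scale = "rescue_percent",
              n_exp = es$n_exp, n_ctrl = es$n_ctrl, source = es$source)
}

#' Impairment relative to the heat-effect baseline
#'
#' Subtracts the synthetic heat-control learning level (83% of wild type)
#' so that 0 means "no effect beyond heating".
#'
#' @param es `mb_effects` on the `learning_percent` scale.
#' @param heat_ref heat-control learning level in percent.
#' @return `mb_effects` on the `heat_adjusted_percent` scale.
#' @export
heat_adjusted <- function(es, heat_ref) {
  .check_scale(es, "learning_percent")
  stopifnot(is.numeric(heat_ref), length(heat_ref) == 1)
  .mk_effects(estimate = es$estimate - heat_ref, se = es$se,
              scale = "heat_adjusted_percent",
              n_exp = es$n_exp, n_ctrl = es$n_ctrl, source = es$source)
}

#' Compute per-experiment effect sizes for a dataset
#'
#' @param ds an [mb_dataset()] whose PI columns are populated.
#' @param scale `"percent"` (delta-method percentage change) or `"raw"`
#'   (PI difference).
#' @return `mb_effects` with one row per record, `source` =
#'   `study|panel|genotype`.
#' @export
compute_effects <- function(ds, scale = c("percent", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(ds, "mb_dataset"))
  need <- c("pi_exp_mean", "pi_exp_sem", "pi_ctrl_mean", "pi_ctrl_sem")
  if (any(vapply(need, function(cn) all(is.na(ds[[cn]])), logical(1))) &&
      nrow(ds) > 0) {
    stop("dataset has no PI summaries (the packaged fixture ships ",
         "without them); supply a CSV with pi_* columns filled or a ",
         "simulated dataset", call. = FALSE)
  }
  src <- paste(ds$study_id, ds$figure_panel, ds$genotype_exp, sep = "|")
  f <- if (scale == "percent") percent_change else raw_change
  f(ds$pi_exp_mean, ds$pi_exp_sem, ds$pi_ctrl_mean, ds$pi_ctrl_sem,
    n_exp = ds$n_exp, n_ctrl = ds$n_ctrl, source = src)
}

#' @export
print.mb_effects <- function(x, ...) {
  cat(sprintf("<mb_effects> %d effects on scale(s): %s\n", nrow(x),
              paste(unique(x$scale), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
`[.mb_effects` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), names(x)))
    class(out) <- c("mb_effects", "data.frame")
  out
}
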