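# Conditional reproduction of the headline published estimates.  The
# per-experiment PI values live in the deposited supplementary dataset,
# which is not redistributable inside this package; once exported to the
# package's CSV schema (pi_* columns filled), this entry point reruns the
# pooling pipeline and returns the five headline quantities.

#' Reproduce headline pooled estimates from deposited per-experiment data
#'
#' Requires a CSV in the [mb_schema()] layout with PI means/SEMs filled
#' in (an export of the deposited supplementary spreadsheet).  Returns
#' the pooled mutant effect, the heat effect, the alphabeta+gamma rescue,
#' and the alphabeta and alphabeta+gamma inactivation reductions, all in
#' percent.
#'
#' @param path path to the per-experiment CSV.
#' @return Named numeric vector: `rut_mutant_effect`, `heat_effect`,
#'   `alphabeta_gamma_rescue`, `shi_alphabeta_reduction`,
#'   `shi_alphabeta_gamma_reduction`.
#' @export
reproduce_published <- function(path) {
  if (missing(path) || is.null(path) || !file.exists(path)) {
    stop("supplementary per-experiment data not found",
         if (!missing(path) && !is.null(path))
           paste0(" at '", path, "'") else "",
         ": export the deposited spreadsheet to the package CSV schema ",
         "(see mb_schema()) and pass its path", call. = FALSE)
  }
  ds <- read_experiments(path)
  if (all(is.na(ds$pi_exp_mean)))
    stop("file has no PI values; reproduction needs the deposited ",
         "per-experiment summaries", call. = FALSE)
  pool_pct <- function(keep) {
    es <- compute_effects(ds[keep, , drop = FALSE], "percent")
    pool_random_effects(es)$pooled$estimate
  }
  mut <- pool_pct(ds$intervention == "rut_mutant")
  heat <- pool_pct(ds$intervention == "heat_control")
  lobe <- assign_lobe_category(ds, reassign_201Y = FALSE)
  abg_rescue <- (100 + pool_pct(ds$intervention == "rut_rescue" &
                                  lobe == "alphabeta_gamma")) -
    (100 + mut)
  shi_ab <- (100 + pool_pct(ds$intervention == "shi_inactivation" &
                              lobe == "alphabeta")) - (100 + heat)
  shi_abg <- (100 + pool_pct(ds$intervention == "shi_inactivation" &
                               lobe == "alphabeta_gamma")) - (100 + heat)
  c(rut_mutant_effect = mut,
    heat_effect = heat,
    alphabeta_gamma_rescue = abg_rescue,
    shi_alphabeta_reduction = -shi_ab,
    shi_alphabeta_gamma_reduction = -shi_abg)
}
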