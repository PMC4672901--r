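# Synthetic datasets with the statistical structure the analysis assumes:
# study-clustered effects, driver effects proportional to Kenyon-cell
# counts, moderator effects (delay, benzaldehyde), shared-control blocks
# whose control arm is drawn once and reused, and iteration-level
# truncated-normal PI noise summarized to per-arm mean/SEM.

.default_drivers <- function() {
  # synthetic cell counts: plausible Kenyon-cell magnitudes only, not the
  # counts of any published anatomical study
  data.frame(
    driver = c("dA", "dB", "dC", "dD", "dE", "dF", "dG", "dH", "dI"),
    cell_count = c(150, 300, 450, 600, 800, 1000, 1300, 1700, 2100),
    lobe_category = c("alphabeta", "alphaprime_betaprime", "alphabeta",
                      "gamma", "gamma", "alphabeta_gamma",
                      "alphabeta_gamma", "all_lobes", "all_lobes"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults describe a corpus shaped like the reviewed literature: a
#' handful of studies contributing ~80 experiments, 3-24 T-maze
#' iterations per arm, control PIs concentrated around 0.75, a 40%
#' mutant learning baseline, and moderator effects of post-training delay
#' and benzaldehyde odors.
#'
#' @param n_studies number of study clusters.
#' @param experiments_per_study integer range (min, max) of intervention
#'   experiments per study.
#' @param iterations_per_arm integer range of iterations per arm.
#' @param control_pi_mean,control_pi_sd distribution of true control PIs.
#' @param tau study-cluster SD on the learning-percent scale.
#' @param rho within shared-control-block correlation of effect-scale
#'   residuals, in `[0, 0.99]`.
#' @param sigma_iter iteration-level PI SD.
#' @param sigma_resid experiment-level residual SD on the learning scale
#'   (split into a block-shared and an independent part according to
#'   `rho`).
#' @param drivers data frame `driver`, `cell_count`, `lobe_category`.
#' @param slope_per_cell learning % per Kenyon cell.
#' @param mutant_learning mutant baseline learning (% of wild type).
#' @param heat_effect heat-control learning change (%) for shibire-style
#'   simulations.
#' @param covariate_effects named numeric: learning-% effects of `TIME`
#'   (per minute) and `BENZALDEHYDE` (presence).
#' @param intervention `"rut_rescue"` (shared controls, mutant baseline)
#'   or `"shi_inactivation"` (matched controls, heat baseline).
#' @param baselines_per_study mutant or heat-control records per study.
#' @param block_size_max largest shared-control block.
#' @param seed integer RNG seed.
#' @return list of class `"mb_sim_config"`.
#' @export
sim_config <- function(n_studies = 7,
                       experiments_per_study = c(8, 14),
                       iterations_per_arm = c(6, 18),
                       control_pi_mean = 0.75,
                       control_pi_sd = 0.08,
                       tau = 5,
                       rho = 0.3,
                       sigma_iter = 0.15,
                       sigma_resid = 6,
                       drivers = .default_drivers(),
                       slope_per_cell = 0.02,
                       mutant_learning = 40,
                       heat_effect = -17,
                       covariate_effects = c(TIME = -3, BENZALDEHYDE = 5),
                       intervention = c("rut_rescue", "shi_inactivation"),
                       baselines_per_study = 2,
                       block_size_max = 3,
                       seed = 1L) {
  intervention <- match.arg(intervention)
  cfg <- list(n_studies = as.integer(n_studies),
              experiments_per_study = as.integer(experiments_per_study),
              iterations_per_arm = as.integer(iterations_per_arm),
              control_pi_mean = control_pi_mean,
              control_pi_sd = control_pi_sd,
              tau = tau, rho = rho, sigma_iter = sigma_iter,
              sigma_resid = sigma_resid, drivers = drivers,
              slope_per_cell = slope_per_cell,
              mutant_learning = mutant_learning,
              heat_effect = heat_effect,
              covariate_effects = covariate_effects,
              intervention = intervention,
              baselines_per_study = as.integer(baselines_per_study),
              block_size_max = as.integer(block_size_max),
              seed = as.integer(seed))
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs[[length(errs) + 1L]] <<- msg
  chk(cfg$n_studies >= 1, "n_studies must be >= 1")
  chk(length(cfg$experiments_per_study) == 2 &&
        all(cfg$experiments_per_study >= 1), "bad experiments_per_study")
  chk(length(cfg$iterations_per_arm) == 2 &&
        all(cfg$iterations_per_arm >= 2),
      "iterations_per_arm must be >= 2")
  chk(cfg$tau >= 0 && cfg$sigma_iter >= 0 && cfg$sigma_resid >= 0 &&
        cfg$control_pi_sd >= 0, "all SDs must be >= 0")
  chk(cfg$rho >= 0 && cfg$rho <= 0.99, "rho must lie in [0, 0.99]")
  chk(abs(cfg$control_pi_mean) <= 1, "control_pi_mean must be a PI")
  chk(all(c("driver", "cell_count", "lobe_category") %in%
            names(cfg$drivers)) && nrow(cfg$drivers) >= 1,
      "drivers needs columns driver, cell_count, lobe_category")
  chk(all(c("TIME", "BENZALDEHYDE") %in% names(cfg$covariate_effects)),
      "covariate_effects needs TIME and BENZALDEHYDE")
  if (length(errs) > 0)
    stop("invalid simulation config:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  class(cfg) <- "mb_sim_config"
  cfg
}

# sample() resolves a scalar n to 1:n; ranges here may be degenerate
.rsamp <- function(lo, hi, n = 1) {
  v <- lo:hi
  if (length(v) == 1) rep(v, n) else sample(v, n, replace = TRUE)
}

# truncated-normal draws on [-1, 1] by rejection (sigma is far smaller
# than the support in any realistic configuration)
.rtrunc_pi <- function(n, mu, sigma) {
  if (sigma == 0) return(rep(mu, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    x <- stats::rnorm(length(todo), mu, sigma)
    ok <- x >= -1 & x <= 1
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Simulate one arm's iterations
#'
#' Draws `n` iteration-level PIs from a normal truncated to `[-1, 1]` and
#' returns their mean and SEM.
#'
#' @param mu true PI in `[-1, 1]`.
#' @param sigma iteration SD (>= 0).
#' @param n number of iterations (>= 2).
#' @param seed optional seed applied locally (caller RNG preserved).
#' @return list with `mean` and `sem`.
#' @export
simulate_iterations <- function(mu, sigma, n, seed = NULL) {
  if (n < 2) stop("need at least 2 iterations per arm", call. = FALSE)
  if (abs(mu) > 1) stop("mu must be a PI in [-1, 1]", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  x <- .rtrunc_pi(n, mu, sigma)
  list(mean = mean(x), sem = stats::sd(x) / sqrt(n))
}

#' Simulate a summary-level dataset with known truth
#'
#' Generates an [mb_dataset()] that passes all corpus validation
#' invariants, together with the ground truth needed for parameter
#' recovery: per-experiment true learning levels and per-driver true
#' residual effects (`slope_per_cell * cell_count`).
#'
#' For `rut_rescue`, experiments within a study are grouped into
#' shared-control blocks whose control arm is drawn once and reused;
#' residuals additionally contain a block-shared component so that the
#' within-block correlation of effect-scale residuals equals `rho` in the
#' noiseless-iteration limit.  For `shi_inactivation`, controls are
#' matched (no blocks).
#'
#' @param cfg an [sim_config()].
#' @return list with `dataset` ([mb_dataset()]) and `truth` (list:
#'   `experiments`, `drivers`, `config`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "mb_sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  rut <- cfg$intervention == "rut_rescue"
  baseline <- if (rut) cfg$mutant_learning else 100 + cfg$heat_effect
  odors <- c("MCH-BEN", "OCT-BEN", "MCH-OCT", "EA-IA")
  rows <- list(); truths <- list()
  for (s in seq_len(cfg$n_studies)) {
    sid <- sprintf("Sim study %02d", s)
    b_i <- stats::rnorm(1, 0, cfg$tau)
    n_exp <- .rsamp(cfg$experiments_per_study[1],
                    cfg$experiments_per_study[2])
    n_base <- cfg$baselines_per_study
    total <- n_exp + n_base
    # block assignment: interventions share controls in rut mode
    if (rut && cfg$block_size_max > 1) {
      sizes <- c()
      while (sum(sizes) < n_exp) {
        sizes <- c(sizes, sample(seq_len(cfg$block_size_max), 1))
      }
      sizes[length(sizes)] <- sizes[length(sizes)] -
        (sum(sizes) - n_exp)
      sizes <- sizes[sizes > 0]
      blk <- rep(seq_along(sizes), sizes)
    } else {
      blk <- seq_len(n_exp)
    }
    blk <- c(blk, max(blk, 0) + seq_len(n_base))  # baselines solo
    kinds <- c(rep("intervention", n_exp), rep("baseline", n_base))
    drv_idx <- sample(nrow(cfg$drivers), total, replace = TRUE)
    delay <- sample(c(0, 2, 3, 5), total, replace = TRUE)
    odor <- sample(odors, total, replace = TRUE)
    ben <- grepl("BEN", odor)
    u_blk <- stats::rnorm(max(blk), 0, sqrt(cfg$rho) * cfg$sigma_resid)
    mu_c_blk <- pmin(0.95, pmax(0.05,
      stats::rnorm(max(blk), cfg$control_pi_mean, cfg$control_pi_sd)))
    ctrl_cache <- vector("list", max(blk))
    for (e in seq_len(total)) {
      is_int <- kinds[e] == "intervention"
      drv <- cfg$drivers[drv_idx[e], ]
      e_res <- stats::rnorm(1, 0, sqrt(1 - cfg$rho) * cfg$sigma_resid)
      L <- baseline +
        (if (is_int) cfg$slope_per_cell * drv$cell_count else 0) +
        cfg$covariate_effects[["TIME"]] * delay[e] +
        cfg$covariate_effects[["BENZALDEHYDE"]] * ben[e] +
        b_i + u_blk[blk[e]] + e_res
      mu_c <- mu_c_blk[blk[e]]
      mu_e <- pmin(1, pmax(-1, mu_c * L / 100))
      n_e <- .rsamp(cfg$iterations_per_arm[1], cfg$iterations_per_arm[2])
      if (is.null(ctrl_cache[[blk[e]]])) {
        n_c <- .rsamp(cfg$iterations_per_arm[1], cfg$iterations_per_arm[2])
        xc <- .rtrunc_pi(n_c, mu_c, cfg$sigma_iter)
        ctrl_cache[[blk[e]]] <- list(
          n = n_c, mean = mean(xc),
          sem = if (cfg$sigma_iter == 0) 0 else stats::sd(xc) / sqrt(n_c))
      }
      ctl <- ctrl_cache[[blk[e]]]
      xe <- .rtrunc_pi(n_e, mu_e, cfg$sigma_iter)
      sem_e <- if (cfg$sigma_iter == 0) 0 else stats::sd(xe) / sqrt(n_e)
      interv <- if (is_int) {
        if (rut) "rut_rescue" else "shi_inactivation"
      } else {
        if (rut) "rut_mutant" else "heat_control"
      }
      gexp <- if (is_int) {
        sprintf("%s; %s; UAS-%s #%d", if (rut) "rut2080" else "shi-ts",
                drv$driver, if (rut) "rut" else "shi", e)
      } else {
        sprintf("%s #%d", if (rut) "rut2080" else "Canton-S", e)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = sid, figure_panel = sprintf("P%d", e),
        genotype_exp = gexp,
        genotype_ctrl = sprintf("control B%d", blk[e]),
        n_exp = n_e, n_ctrl = ctl$n,
        pi_exp_mean = mean(xe), pi_exp_sem = sem_e,
        pi_ctrl_mean = ctl$mean, pi_ctrl_sem = ctl$sem,
        intervention = interv,
        lobe_category = if (is_int) drv$lobe_category else "none",
        driver = if (is_int) drv$driver else NA_character_,
        odor_pair = odor[e], benzaldehyde = ben[e],
        temperature_c = 25, shock_v = 90, current_type = "unknown",
        delay_min = delay[e], rh_pct = NA_real_,
        shared_control_id = if (rut) sprintf("%s|B%d", sid, blk[e])
                            else NA_character_,
        stringsAsFactors = FALSE)
      truths[[length(truths) + 1L]] <- data.frame(
        study_id = sid, figure_panel = sprintf("P%d", e),
        driver = if (is_int) drv$driver else NA_character_,
        kind = kinds[e], true_learning = L, true_pct = L - 100,
        stringsAsFactors = FALSE)
    }
  }
  ds <- mb_dataset(do.call(rbind, rows),
                   provenance = sprintf("simulated(seed=%d)", cfg$seed))
  truth <- list(
    experiments = do.call(rbind, truths),
    drivers = data.frame(
      driver = cfg$drivers$driver,
      cell_count = cfg$drivers$cell_count,
      lobe_category = cfg$drivers$lobe_category,
      true_effect = cfg$slope_per_cell * cfg$drivers$cell_count,
      true_per_cell = cfg$slope_per_cell,
      stringsAsFactors = FALSE),
    config = cfg)
  list(dataset = ds, truth = truth)
}
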