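test_that("likelihood matches the dense multivariate-normal oracle", {
  for (seed in 1:12) {
    fr <- random_frame(seed, bcs = seed %% 2 == 0)
    beta <- c(1, -0.5, 2)
    for (pars in list(c(0, 0, 1), c(2, 0.4, 1.5), c(0.5, 0.8, 0.3))) {
      got <- mbmeta:::.glmm_loglik_frame(beta, pars[1], pars[2], pars[3],
                                         fr)
      want <- oracle_glmm_loglik(beta, pars[1], pars[2], pars[3], fr)
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("exported likelihood agrees with the oracle on dataset input", {
  sim <- quick_sim(21, n_studies = 3, experiments_per_study = c(3, 5))
  ds <- sim$dataset[sim$dataset$intervention == "rut_rescue", ]
  spec <- glmm_spec("percent_change", c("TIME", "BENZALDEHYDE"))
  fr <- build_model_frame(ds, spec)
  params <- list(beta = c(-50, -2, 4), tau2 = 20, rho = 0.25, sigma2 = 2)
  got <- glmm_loglik(params, spec, ds)
  want <- oracle_glmm_loglik(params$beta, params$tau2, params$rho,
                             params$sigma2, fr)
  expect_equal(got, want, tolerance = 1e-8)
  # record order is irrelevant for the stacked likelihood
  perm <- sample(nrow(ds))
  expect_equal(glmm_loglik(params, spec, ds[perm, ]), got,
               tolerance = 1e-8)
  expect_error(glmm_loglik(list(beta = 1, tau2 = 0, rho = 0, sigma2 = 1),
                           spec, ds), "length")
})

test_that("degenerate limit reduces to ordinary least squares", {
  fr <- random_frame(33)
  fr$w <- rep(1, length(fr$y))
  ols <- lm(fr$y ~ fr$X - 1)
  s2 <- sum(residuals(ols)^2) / length(fr$y)  # ML variance
  ll_ols <- sum(dnorm(fr$y, fitted(ols), sqrt(s2), log = TRUE))
  got <- mbmeta:::.glmm_loglik_frame(coef(ols), 0, 0, s2, fr)
  expect_equal(got, ll_ols, tolerance = 1e-8)
})

test_that("fit reduces to weighted least squares when tau2 = rho = 0", {
  # single study + singleton blocks force tau2 = 0 and rho = 0, so the
  # GLS profile is exactly WLS whatever sigma2 the optimizer lands on
  sim <- quick_sim(8, n_studies = 1, experiments_per_study = c(12, 12),
                   block_size_max = 1, tau = 0)
  ds <- sim$dataset[sim$dataset$intervention == "rut_rescue", ]
  spec <- glmm_spec("percent_change", c("TIME", "BENZALDEHYDE"))
  fit <- suppressWarnings(fit_glmm(spec, ds))
  fr <- build_model_frame(ds, spec)
  wls <- lm.wfit(fr$X, fr$y, fr$w)
  expect_equal(unname(fit$beta), unname(coef(wls)), tolerance = 1e-6)
  expect_identical(fit$tau2, 0)
  expect_identical(fit$rho, 0)
  expect_true(fit$converged)
})

test_that("duplicating records at half weight leaves the fit unchanged", {
  sim <- quick_sim(13, n_studies = 3, experiments_per_study = c(5, 7))
  ds <- sim$dataset[sim$dataset$intervention == "rut_rescue", ]
  spec <- glmm_spec("percent_change", "TIME",
                    residual_structure = "diagonal")
  fr <- build_model_frame(ds, spec)
  # a single pseudo-study pins tau2 = 0, where weight-equivalence is exact
  fr$study <- rep("S1", length(fr$y))
  fr2 <- list(y = c(fr$y, fr$y), X = rbind(fr$X, fr$X),
              w = c(fr$w / 2, fr$w / 2), study = c(fr$study, fr$study),
              block = c(fr$block, paste0(fr$block, "_dup")),
              driver = c(fr$driver, fr$driver), centers = fr$centers,
              structure = "diagonal")
  f1 <- mbmeta:::.fit_glmm_frame(fr)
  f2 <- mbmeta:::.fit_glmm_frame(fr2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})

test_that("fitting improves on the starting point and flags convergence", {
  sim <- quick_sim(17, n_studies = 4, experiments_per_study = c(5, 8))
  ds <- sim$dataset[sim$dataset$intervention == "rut_rescue", ]
  spec <- glmm_spec("percent_change", c("TIME", "BENZALDEHYDE"))
  fit <- fit_glmm(spec, ds)
  expect_true(fit$converged)
  expect_true(fit$rho >= 0 && fit$rho < 0.99)
  expect_gte(fit$tau2, 0)
  expect_gt(fit$sigma2, 0)
  # likelihood at the optimum beats nearby perturbed parameter points
  for (f in c(0.5, 2)) {
    ll <- mbmeta:::.glmm_loglik_frame(fit$beta, fit$tau2 * f,
                                      min(0.98, fit$rho + 0.1),
                                      fit$sigma2 * f, fit$frame)
    expect_gte(fit$loglik, ll - 1e-6)
  }
  # TEMPERATURE is constant in simulated worlds: a zero column after
  # centering, hence a rank-deficient design
  expect_error(fit_glmm(glmm_spec("percent_change",
                                  c("TIME", "TEMPERATURE")), ds),
               "rank deficient")
})

test_that("generalized R2 is 0 for equal fits and saturates at 1", {
  sim <- quick_sim(19, n_studies = 4, experiments_per_study = c(6, 9))
  ds <- sim$dataset[sim$dataset$intervention == "rut_rescue", ]
  null <- suppressWarnings(fit_glmm(glmm_spec("percent_change"), ds))
  full <- suppressWarnings(
    fit_glmm(glmm_spec("percent_change", c("TIME", "BENZALDEHYDE")), ds))
  expect_equal(generalized_r2(null, null)$r2, 0)
  r2 <- generalized_r2(full, null)$r2
  expect_true(r2 >= 0 && r2 <= 1)
  # matches the formula computed from the logliks directly
  expect_equal(r2, 1 - exp(-2 / full$n * (full$loglik - null$loglik)),
               tolerance = 1e-12)
  expect_error(generalized_r2(null, full), "not nested")
  # bootstrap CI brackets the point estimate
  gb <- generalized_r2(full, null, bootstrap = 30, seed = 4)
  expect_length(gb$ci, 2)
  expect_true(gb$ci[1] <= gb$ci[2])
})

test_that("driver summaries count records and respect the reference", {
  sim <- quick_sim(23, n_studies = 4, experiments_per_study = c(6, 9))
  ds <- sim$dataset[sim$dataset$intervention == "rut_rescue", ]
  spec <- glmm_spec("percent_change", c("TIME", "BENZALDEHYDE"))
  fit <- fit_glmm(spec, ds)
  cc <- sim$truth$drivers[, c("driver", "cell_count")]
  de <- residual_driver_effects(fit, reference = 40, cellcounts = cc)
  counts <- table(ds$driver)
  for (d in de$driver) {
    expect_identical(de$n_experiments[de$driver == d],
                     as.integer(counts[[d]]))
  }
  expect_equal(de$per_cell_effect * de$cell_count, de$effect,
               tolerance = 1e-10)
  # shifting the reference shifts every effect by the same amount
  de83 <- residual_driver_effects(fit, reference = 83, cellcounts = cc)
  expect_equal(de$effect - de83$effect, rep(43, nrow(de)))
  expect_equal(de$se, de83$se)
})

test_that("intercept-only driver summaries match the effect-size scales", {
  # with no covariates, tau2 = rho = 0, the adjusted record values are the
  # observations themselves, so the driver effect equals the pooled
  # learning-scale / heat-adjusted arithmetic from the effect module
  sim <- quick_sim(29, n_studies = 1, experiments_per_study = c(8, 8),
                   block_size_max = 1, tau = 0)
  ds <- sim$dataset[sim$dataset$intervention == "rut_rescue", ]
  fit <- suppressWarnings(fit_glmm(glmm_spec("percent_change"), ds))
  de <- residual_driver_effects(fit, reference = 83)
  es <- compute_effects(ds)
  ha <- heat_adjusted(to_learning_scale(es), 83)
  for (d in de$driver) {
    idx <- which(ds$driver == d)
    w <- 1 / es$var[idx]
    expect_equal(de$effect[de$driver == d],
                 sum(w * ha$estimate[idx]) / sum(w), tolerance = 1e-6)
  }
})

test_that("cell-count regression recovers exact fits and scales", {
  de <- structure(data.frame(
    driver = letters[1:5], effect = 0.02 * c(100, 400, 800, 1500, 2000),
    se = 1, n_experiments = c(2L, 3L, 4L, 5L, 6L),
    cell_count = c(100, 400, 800, 1500, 2000),
    per_cell_effect = 0.02, lobe_category = "gamma",
    stringsAsFactors = FALSE), class = c("mb_driver_effects",
                                         "data.frame"))
  # lm warns about the essentially perfect fit; that is the point here
  m <- suppressWarnings(cellcount_regression(de))
  expect_equal(m$slope, 0.02, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-10)
  expect_equal(m$r2_generalized, 1, tolerance = 1e-6)
  # doubling weights changes nothing
  de2 <- de; de2$n_experiments <- de$n_experiments * 2L
  m2 <- suppressWarnings(cellcount_regression(de2))
  expect_equal(m2$slope, m$slope)
  expect_equal(m2$r2_generalized, m$r2_generalized, tolerance = 1e-9)
  expect_error(cellcount_regression(de[1:2, ]), "at least 3")
  de3 <- de; de3$cell_count <- rep(500, 5)
  expect_error(cellcount_regression(de3), "unidentifiable")
})

test_that("per-cell model synthesizes categories and their contrasts", {
  de <- structure(data.frame(
    driver = letters[1:6], effect = c(2, 4, 3, 6, 10, 20),
    se = c(0, 0, 0.1, 0.1, 0.2, 0.4),
    n_experiments = 2L,
    cell_count = c(100, 200, 300, 600, 500, 1000),
    per_cell_effect = NA_real_,
    lobe_category = rep(c("gamma", "alphabeta", "all_lobes"), each = 2),
    stringsAsFactors = FALSE), class = c("mb_driver_effects",
                                         "data.frame"))
  pcm <- per_cell_model(de)
  cats <- pcm$categories
  # identical per-cell effects with zero SE collapse to that value, CI
  # width zero
  g <- cats[cats$lobe_category == "gamma", ]
  expect_equal(g$estimate, 0.02)
  expect_equal(g$ci_high - g$ci_low, 0)
  ab <- cats[cats$lobe_category == "alphabeta", ]
  expect_equal(ab$estimate, 0.01, tolerance = 1e-12)
  # single-driver category passes through
  one <- per_cell_model(de[5, , drop = FALSE])
  expect_equal(one$categories$estimate, 10 / 500)
  expect_equal(one$categories$se, 0.2 / 500)
  # equal-potency categories: pairwise differences cover 0
  eq <- de
  eq$effect <- 0.02 * eq$cell_count + rnorm(6, 0, 1e-3)
  eq$se <- 0.5
  pw <- per_cell_model(eq)$pairwise
  expect_true(all(pw$ci_low <= 0 & pw$ci_high >= 0))
  # zero counts are excluded with a warning
  z <- de; z$cell_count[1] <- 0
  expect_warning(per_cell_model(z), "excluded")
})
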