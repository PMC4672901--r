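# Independent oracles.  These deliberately re-derive results from the
# textbook formulas with naive accumulation loops and dense matrices so
# they share no code path with the package implementation.

# mb_effects builder for hand-specified estimates/variances
fx_effects <- function(estimate, var, scale = "percent_change") {
  se <- sqrt(var)
  k <- length(estimate)
  structure(
    data.frame(source = if (k) paste0("e", seq_len(k)) else character(0),
               estimate = estimate, se = se, var = var,
               ci_low = estimate - 1.959963984540054 * se,
               ci_high = estimate + 1.959963984540054 * se,
               scale = rep(scale, k), n_exp = rep(1L, k),
               n_ctrl = rep(1L, k), stringsAsFactors = FALSE),
    class = c("mb_effects", "data.frame"))
}

# drop the provenance attribute for value-only comparisons
strip_prov <- function(d) {
  d <- as.data.frame(d)
  attr(d, "provenance") <- NULL
  d
}

# textbook DerSimonian-Laird random-effects meta-analysis
oracle_meta <- function(y, v) {
  k <- length(y)
  sw <- 0; swy <- 0; sw2 <- 0
  for (i in seq_len(k)) {
    w <- 1 / v[i]
    sw <- sw + w; swy <- swy + w * y[i]; sw2 <- sw2 + w^2
  }
  ybar <- swy / sw
  q <- 0
  for (i in seq_len(k)) q <- q + (y[i] - ybar)^2 / v[i]
  df <- k - 1
  tau2 <- max(0, (q - df) / (sw - sw2 / sw))
  sws <- 0; swys <- 0
  for (i in seq_len(k)) {
    ws <- 1 / (v[i] + tau2)
    sws <- sws + ws; swys <- swys + ws * y[i]
  }
  list(pooled = swys / sws, se = sqrt(1 / sws), tau2 = tau2, q = q,
       i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0)
}

# dense multivariate-normal log-likelihood for the mixed model, built
# from an explicit n x n covariance matrix
oracle_glmm_loglik <- function(beta, tau2, rho, sigma2, fr) {
  n <- length(fr$y)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (fr$study[i] == fr$study[j]) V[i, j] <- V[i, j] + tau2
      if (i == j) {
        V[i, j] <- V[i, j] + sigma2 / fr$w[i]
      } else if (fr$structure == "block_compound_symmetry" &&
                 fr$block[i] == fr$block[j]) {
        V[i, j] <- V[i, j] + rho * sigma2 / sqrt(fr$w[i] * fr$w[j])
      }
    }
  }
  r <- fr$y - as.vector(fr$X %*% beta)
  ld <- determinant(V, logarithm = TRUE)
  -0.5 * (n * log(2 * pi) + as.numeric(ld$modulus) +
            drop(t(r) %*% solve(V) %*% r))
}

# random small mixed-model frame (n <= 30) for oracle comparisons
random_frame <- function(seed, bcs = TRUE) {
  set.seed(seed)
  n_study <- sample(2:4, 1)
  per <- sample(2:8, n_study, replace = TRUE)
  n <- sum(per)
  study <- rep(sprintf("S%d", seq_len(n_study)), per)
  block <- unlist(lapply(seq_len(n_study), function(s) {
    m <- per[s]
    b <- sort(sample(seq_len(max(1, m %/% 2)), m, replace = TRUE))
    sprintf("S%d_B%d", s, b)
  }))
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = runif(n))
  list(y = rnorm(n, 2, 3), X = X, w = runif(n, 0.5, 4),
       study = study, block = block, driver = rep(NA_character_, n),
       centers = c(),
       structure = if (bcs) "block_compound_symmetry" else "diagonal")
}

# small simulated dataset with PI values for end-to-end tests
quick_sim <- function(seed = 1, ...) {
  simulate_dataset(sim_config(seed = seed, ...))
}

fx_learning <- function(estimate, var = 4) {
  fx_effects(estimate, var, scale = "learning_percent")
}

# shi-style driver panel: the reviewed inactivation corpus spans only the
# alphabeta and alphabeta+gamma categories
.default_shi_drivers <- function() {
  d <- mbmeta:::.default_drivers()
  d[d$lobe_category %in% c("alphabeta", "alphabeta_gamma"), ]
}
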