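test_that("worked two-study example: tau2 = 46, pooled 5 +/- 5, I2 = 92%", {
  es <- fx_effects(c(0, 10), c(4, 4))
  expect_equal(dl_tau2(es), 46)
  m <- pool_random_effects(es)
  expect_equal(m$pooled$estimate, 5)
  expect_equal(m$pooled$se, 5)
  expect_equal(m$i2, 92)
  expect_equal(m$q, 12.5)
  expect_identical(m$df, 1L)
})

test_that("tau2 truncates at zero and guards its preconditions", {
  expect_equal(dl_tau2(fx_effects(c(3, 3, 3), c(1, 2, 3))), 0)
  # Q < df forces truncation
  expect_equal(dl_tau2(fx_effects(c(0, 1), c(100, 100))), 0)
  expect_error(dl_tau2(fx_effects(5, 2)), "at least 2")
  expect_error(dl_tau2(fx_effects(c(1, 2), c(0, 1))), "positive")
  expect_error(pool_random_effects(fx_effects(numeric(0), numeric(0))),
               "no estimates")
})

test_that("pooling matches the textbook oracle on random instances", {
  set.seed(11)
  for (i in 1:200) {
    k <- sample(2:10, 1)
    y <- rnorm(k, 0, 10)
    v <- runif(k, 0.1, 9)
    m <- pool_random_effects(fx_effects(y, v))
    o <- oracle_meta(y, v)
    expect_equal(m$pooled$estimate, o$pooled, tolerance = 1e-10)
    expect_equal(m$pooled$se, o$se, tolerance = 1e-10)
    expect_equal(m$tau2, o$tau2, tolerance = 1e-10)
    expect_equal(m$i2, o$i2, tolerance = 1e-10)
    expect_gte(m$tau2, 0)
    expect_true(m$i2 >= 0 && m$i2 < 100)
    # pooled estimate stays inside the convex hull of the inputs
    expect_gte(m$pooled$estimate, min(y))
    expect_lte(m$pooled$estimate, max(y))
    # RE pooled SE is never tighter than fixed-effect pooled SE
    expect_gte(m$pooled$se + 1e-12, sqrt(1 / sum(1 / v)))
  }
})

test_that("single estimates pass through; null weights change nothing", {
  one <- fx_effects(7, 2.5)
  m <- pool_random_effects(one)
  expect_equal(m$pooled$estimate, 7)
  expect_equal(m$pooled$se, sqrt(2.5))
  expect_equal(m$tau2, 0)
  # equal variances -> unweighted mean
  eq <- pool_random_effects(fx_effects(c(1, 2, 6), c(3, 3, 3)))
  expect_equal(eq$pooled$estimate, 3)
  # an (almost) infinite-variance study has no influence
  base <- pool_random_effects(fx_effects(c(1, 2, 6), c(3, 3, 3)))
  plus <- pool_random_effects(fx_effects(c(1, 2, 6, 50), c(3, 3, 3, 1e12)))
  expect_equal(plus$pooled$estimate, base$pooled$estimate,
               tolerance = 1e-6)
})

test_that("subgroup analysis partitions heterogeneity", {
  es <- fx_effects(c(1, 2, 1, 2), c(1, 1, 1, 1))
  m <- subgroup_analysis(es, c("a", "a", "b", "b"))
  expect_equal(m$q_between, 0)
  expect_equal(m$i2_subgroup, 0)
  expect_identical(m$k, sum(vapply(m$subgroups, function(s) s$k,
                                   integer(1))))
  # groups separated by ~10 SEs: nearly all between-group heterogeneity
  far <- fx_effects(c(0, 0.5, -0.5, 10, 10.5, 9.5), rep(1, 6))
  mf <- subgroup_analysis(far, rep(c("lo", "hi"), each = 3))
  expect_gt(mf$i2_subgroup, 90)
  expect_equal(mf$q_between,
               mf$q - sum(vapply(mf$subgroups, function(s) s$q,
                                 numeric(1))),
               tolerance = 1e-10)
  # singleton subgroups are reported unpooled
  ms <- subgroup_analysis(fx_effects(c(1, 2, 3), c(1, 1, 1)),
                          c("a", "a", "solo"))
  expect_identical(ms$subgroups$solo$k, 1L)
  expect_equal(ms$subgroups$solo$pooled$estimate, 3)
  expect_error(subgroup_analysis(es, c("a", "a")), "every estimate")
  expect_error(subgroup_analysis(es, c("a", NA, "b", "b")), "missing")
})

test_that("Welch test matches the reference implementation to 1e-10", {
  set.seed(5)
  for (i in 1:50) {
    a <- rnorm(sample(3:20, 1), 0, runif(1, 0.5, 3))
    b <- rnorm(sample(3:20, 1), runif(1, -2, 2), runif(1, 0.5, 3))
    got <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  idt <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idt$t, 0)
  expect_equal(idt$p, 1)
  sep <- welch_t(c(0, 0, 0, 0) + rnorm(4, 0, 1e-8),
                 c(1, 1, 1, 1) + rnorm(4, 0, 1e-8))
  expect_lt(sep$p, 1e-10)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("forest tables carry normalized weights and grouped order", {
  es <- fx_effects(c(1, 2, 5, 6, 7), c(1, 1, 2, 2, 2))
  m <- subgroup_analysis(es, c("g1", "g1", "g2", "g2", "g2"))
  tab <- forest_table(m)
  expect_identical(tab$row_type[nrow(tab)], "overall")
  for (g in c("g1", "g2")) {
    rows <- tab[tab$row_type == "study" & tab$subgroup == g, ]
    expect_equal(sum(rows$weight_pct), 100, tolerance = 0.01)
  }
  # rows stay grouped: studies of g1 precede its diamond, then g2
  expect_identical(tab$row_type,
                   c("study", "study", "subgroup",
                     "study", "study", "study", "subgroup", "overall"))
  expect_identical(tab$label[tab$row_type == "study"],
                   paste0("e", 1:5))
  # single-study meta: one row plus a diamond equal to it
  one <- forest_table(pool_random_effects(fx_effects(4, 2)))
  expect_identical(nrow(one), 2L)
  expect_equal(one$estimate[1], one$estimate[2])
  expect_equal(one$ci_low[1], one$ci_low[2])
})
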