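test_that("packaged fixture reproduces the printed accounting exactly", {
  ds <- table1_fixture()
  rut <- ds$intervention %in% c("rut_rescue", "rut_mutant")
  expect_identical(summarize_counts(ds, rut),
                   list(rows = 81L, sum_n_exp = 748L, sum_n_ctrl = 745L))
  expect_identical(summarize_counts(ds, !rut),
                   list(rows = 37L, sum_n_exp = 263L, sum_n_ctrl = 265L))
  expect_identical(
    summarize_counts(ds, ds$intervention == "rut_mutant")$sum_n_exp, 340L)
  expect_identical(sum(ds$intervention == "heat_control"), 23L)
  # five mutant genotype subgroups, all mutant rows classified
  ms <- mutant_subgroup(ds)
  expect_setequal(unique(ms[!is.na(ms)]),
                  c("rut2080", "rut2080_driver", "rut2080_UAS-rut",
                    "rut1_UAS-rut", "rut1"))
  expect_identical(sum(!is.na(ms)), 36L)
  # heat controls split into the three genotype classes
  expect_identical(as.vector(table(heat_control_class(ds))),
                   c(10L, 11L, 2L)[order(c("driver", "uas_shi",
                                           "wild_type"))])
})

test_that("fixture is deterministic and PI-free with shared controls", {
  a <- table1_fixture()
  b <- table1_fixture()
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(is.na(a$pi_exp_mean)))
  rut <- a$intervention %in% c("rut_rescue", "rut_mutant")
  expect_true(all(!is.na(a$shared_control_id[rut])))
  expect_true(all(is.na(a$shared_control_id[!rut])))
  # linkage groups multiple experiments onto one control arm somewhere
  expect_gt(max(table(a$shared_control_id[rut])), 1)
})

test_that("read/write round-trips and parses ranges and empty files", {
  ds <- table1_fixture()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_experiments(ds, tmp)
  back <- read_experiments(tmp)
  expect_equal(strip_prov(back), strip_prov(ds))

  # range midpoints: write a raw CSV with a textual temperature range
  df <- as.data.frame(ds[1, ])
  df$temperature_c <- "21-25"
  df$rh_pct <- "60-68"
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, tmp2, row.names = FALSE, na = "")
  parsed <- read_experiments(tmp2)
  expect_equal(parsed$temperature_c, 23)
  expect_equal(parsed$rh_pct, 64)

  # header-only file -> empty dataset
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(ds)[0, ], tmp3, row.names = FALSE)
  empty <- read_experiments(tmp3)
  expect_s3_class(empty, "mb_dataset")
  expect_identical(nrow(empty), 0L)
  expect_identical(summarize_counts(empty, function(d) d$n_exp > 0),
                   list(rows = 0L, sum_n_exp = 0L, sum_n_ctrl = 0L))
})

test_that("validation rejects broken records with informative errors", {
  ds <- as.data.frame(table1_fixture())
  dup <- rbind(ds, ds[1, ])
  expect_error(mb_dataset(dup), "duplicate")
  bad_ben <- ds
  bad_ben$benzaldehyde[1] <- !bad_ben$benzaldehyde[1]
  expect_error(mb_dataset(bad_ben), "benzaldehyde")
  bad_n <- ds
  bad_n$n_exp[3] <- 0L
  expect_error(mb_dataset(bad_n), "n_exp")
  bad_lobe <- ds
  bad_lobe$lobe_category[ds$intervention == "rut_rescue"][1] <- "none"
  expect_error(mb_dataset(bad_lobe), "lobe")
  bad_sc <- ds
  # same shared id across two different studies
  bad_sc$shared_control_id[c(1, 20)] <- "SCX"
  expect_error(mb_dataset(bad_sc), "shared_control_id")
  expect_error(mb_dataset(ds[, -1]), "missing columns")
  expect_error(read_experiments(tempfile()), "not found")
})

test_that("201Y reassignment moves exactly the gamma 201Y records", {
  ds <- table1_fixture()
  base <- assign_lobe_category(ds, reassign_201Y = FALSE)
  expect_identical(base, ds$lobe_category)
  moved <- assign_lobe_category(ds, reassign_201Y = TRUE)
  is201 <- !is.na(ds$driver) & ds$driver == "201Y" &
    ds$lobe_category == "gamma"
  expect_true(any(is201))
  expect_true(all(moved[is201] == "alphabeta_gamma"))
  expect_identical(moved[!is201], base[!is201])
  # non-201Y drivers like c739 are untouched
  c739 <- which(!is.na(ds$driver) & ds$driver == "c739")
  expect_identical(moved[c739], base[c739])
})
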