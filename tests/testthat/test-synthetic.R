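test_that("noise-free generation reproduces the model exactly", {
  d <- generate_uptake_dataset(swing_params(), geom, prot2,
                               noise = noise_model(cv = 0), seed = 7)
  expect_equal(nrow(d), 2 * 5 * 3)
  pred <- predict_uptake(swing_params(), geom, prot2)
  wide <- merge(d, pred, by = c("challenge", "time_min"),
                suffixes = c("", "_pred"))
  expect_equal(wide$uptake_pmol, wide$uptake_pmol_pred, tolerance = 1e-4)
  expect_identical(attr(d, "provenance"), "synthetic")
  expect_identical(attr(d, "seed"), 7)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  a <- generate_uptake_dataset(swing_params(), geom, prot2, seed = 11)
  b <- generate_uptake_dataset(swing_params(), geom, prot2, seed = 11)
  c <- generate_uptake_dataset(swing_params(), geom, prot2, seed = 12)
  expect_identical(a$uptake_pmol, b$uptake_pmol)
  expect_false(identical(a$uptake_pmol, c$uptake_pmol))
  expect_true(all(a$uptake_pmol >= 0))
})

test_that("noise models scatter replicates as specified", {
  big <- challenge_protocol(FeCHG = 20, duration = 15)
  d <- generate_uptake_dataset(swing_params(), geom, big,
                               noise = noise_model(cv = 0.2),
                               n_replicates = 200, seed = 5)
  truthd <- generate_uptake_dataset(swing_params(), geom, big,
                                    noise = noise_model(cv = 0), seed = 5)
  at15 <- d$uptake_pmol[d$time_min == 15]
  t15 <- truthd$uptake_pmol[truthd$time_min == 15][1]
  expect_equal(mean(at15), t15, tolerance = 0.05)
  expect_equal(stats::sd(at15) / t15, 0.2, tolerance = 0.15)
  # additive noise has absolute spread
  da <- generate_uptake_dataset(swing_params(), geom, big,
                                noise = noise_model("additive-gaussian",
                                                    sd = 0.5),
                                n_replicates = 200, seed = 5)
  expect_equal(stats::sd(da$uptake_pmol[da$time_min == 15]), 0.5,
               tolerance = 0.2)
  expect_error(noise_model(cv = -1), ">= 0")
})

test_that("mucosal-block summary computes reductions and folds", {
  d <- tibble::tibble(
    challenge = rep(1:2, each = 2),
    time_min = rep(c(3, 6), 2),
    replicate = 1L,
    uptake_pmol = c(10, 12, 3.42, 12)
  )
  s <- mucosal_block_summary(d)
  expect_equal(s$reduction_pct[s$time_min == 3], 65.8)
  expect_equal(s$fold[s$time_min == 3], 10 / 3.42)
  expect_equal(s$reduction_pct[s$time_min == 6], 0)
  expect_equal(s$fold[s$time_min == 6], 1)
  expect_error(mucosal_block_summary(d[d$challenge == 1, ]), "both")
})

test_that("swing-model synthetic data show an early-decaying mucosal block", {
  d <- generate_uptake_dataset(swing_params(), geom, prot2,
                               noise = noise_model(cv = 0), seed = 1)
  s <- mucosal_block_summary(d)
  # second-challenge uptake strictly below first at early times
  expect_true(all(s$u2[s$time_min <= 9] < s$u1[s$time_min <= 9]))
  # reduction is largest early and decays over the window
  expect_gt(s$reduction_pct[1], s$reduction_pct[nrow(s)])
})

test_that("dose fraction converts uptake to percent of the apical dose", {
  expect_equal(dose_fraction(9.4, 2000), 0.47)
  expect_equal(dose_fraction(3.8, 2000), 0.19)
  expect_error(dose_fraction(1, 0))
})

test_that("uptake tables round-trip through CSV with validation", {
  d <- generate_uptake_dataset(swing_params(), geom, prot2, seed = 9)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_uptake_table(d, tmp)
  back <- read_uptake_table(tmp)
  expect_equal(as.data.frame(back),
               as.data.frame(d[, c("challenge", "time_min", "replicate",
                                   "uptake_pmol")]),
               ignore_attr = TRUE)
  # 15-row single-challenge table: 5 times x 3 replicates
  d1 <- d[d$challenge == 1, ]
  write_uptake_table(d1, tmp)
  expect_equal(nrow(read_uptake_table(tmp)), 15)

  bad <- d
  bad$uptake_pmol[4] <- -1
  write.csv(bad[, c("challenge", "time_min", "replicate", "uptake_pmol")],
            tmp, row.names = FALSE)
  expect_error(read_uptake_table(tmp), "negative uptake at rows 4")
  dup <- rbind(d[1, ], d)
  write.csv(dup[, c("challenge", "time_min", "replicate", "uptake_pmol")],
            tmp, row.names = FALSE)
  expect_error(read_uptake_table(tmp), "duplicate")
  write.csv(d[, c("challenge", "time_min")], tmp, row.names = FALSE)
  expect_error(read_uptake_table(tmp), "missing columns")
})

test_that("plot builders return ggplot objects", {
  tr <- run_protocol(swing_params(), geom, prot2, points_per_challenge = 31L)
  d <- generate_uptake_dataset(swing_params(), geom, prot2, seed = 1,
                               points_per_challenge = 31L)
  expect_s3_class(autoplot(tr, "uptake", data = d), "ggplot")
  expect_s3_class(autoplot(tr, "fractions"), "ggplot")
  st <- sensitivity_table(swing_params(), geom, prot1)
  expect_s3_class(plot_sensitivity(st), "ggplot")
  expect_s3_class(plot_mucosal_block(mucosal_block_summary(d)), "ggplot")
})
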