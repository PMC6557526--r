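test_that("predicted uptake behaves at the edges", {
  p0 <- swing_params(DMT1_E = 0)
  pred <- predict_uptake(p0, geom, prot1, challenge = rep(1L, 5),
                         time = c(3, 6, 9, 12, 15))
  expect_equal(pred$uptake_pmol, rep(0, 5))
  empty <- predict_uptake(swing_params(), geom, prot1,
                          challenge = integer(), time = numeric())
  expect_equal(nrow(empty), 0)
  # default grid: every sampling time of every challenge
  full <- predict_uptake(swing_params(), geom, prot2)
  expect_equal(nrow(full), 10)
  expect_true(all(full$uptake_pmol > 0))
})

test_that("the MSE objective matches its definition", {
  truth <- swing_params()
  d <- generate_uptake_dataset(truth, geom, prot1,
                               noise = noise_model(cv = 0), seed = 1)
  # data generated by the scored parameters: zero error to solver tolerance
  expect_lt(uptake_mse(truth, d, geom, prot1), 1e-6)
  # an all-zero prediction scores the mean square of the observed means
  ybar <- aggregate(uptake_pmol ~ time_min, data = d, FUN = mean)$uptake_pmol
  expect_equal(uptake_mse(swing_params(DMT1_E = 0), d, geom, prot1),
               mean(ybar^2), tolerance = 1e-8)
  # replicate-level aggregation scores every record
  d2 <- d
  d2$uptake_pmol[d2$replicate == 2] <- d2$uptake_pmol[d2$replicate == 2] + 1
  expect_gt(uptake_mse(truth, d2, geom, prot1, aggregate = "replicates"),
            uptake_mse(truth, d2, geom, prot1, aggregate = "mean"))
  expect_error(uptake_mse(truth, d[0, ], geom, prot1), "no observations")
})

test_that("fitting honours fixed parameters and perfect starts", {
  truth <- swing_params()
  d <- generate_uptake_dataset(truth, geom, prot1,
                               noise = noise_model(cv = 0), seed = 2)
  all_fixed <- fit_parameters(truth, d, geom, prot1,
                              fixed = names(unclass(truth)))
  expect_identical(unclass(all_fixed$params), unclass(truth))
  expect_lt(all_fixed$mse, 1e-6)
  expect_true(all_fixed$converged)

  from_truth <- fit_parameters(truth, d, geom, prot1, maxit = 300,
                               restarts = 1)
  expect_lt(from_truth$mse, 1e-6)
})

test_that("coefficient of determination matches its definition", {
  y <- c(3.1, 7.4, 9.9, 14.2, 16.4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  yhat <- y + c(0.5, -0.3, 0.2, -0.1, 0)
  expect_equal(r_squared(y, yhat),
               1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  # invariant under common affine rescaling
  expect_equal(r_squared(2 * y + 3, 2 * yhat + 3), r_squared(y, yhat))
  expect_error(r_squared(rep(1, 3), c(1, 2, 3)), "zero variance")
})

test_that("AICc follows the closed form and its limits", {
  expect_equal(aicc(15, 10, 1), 0 + 20 + 220 / 4)
  # correction vanishes as n grows: AICc -> AIC = n log(mse) + 2K
  n <- 1e6
  expect_equal(aicc(n, 10, 1) - (n * log(1) + 20), 0, tolerance = 1e-3)
  # strictly increasing in mse at fixed (n, K)
  expect_lt(aicc(15, 10, 0.5), aicc(15, 10, 1))
  # small-sample correction undefined when n <= K + 1
  expect_error(aicc(5, 10, 1), "undefined")
  expect_error(aicc(11, 10, 1), "undefined")
})

test_that("model comparison selects the lower-AICc model", {
  fake_fit <- function(model, mse, K, n) {
    structure(list(model = model, mse = mse, n_free = K, n_obs = n),
              class = "dmt1_fit")
  }
  a <- fake_fit("switch", mse = 2.0, K = 10, n = 15)
  b <- fake_fit("swing", mse = 0.8, K = 9, n = 15)
  cmp <- compare_models(a, b)
  expect_identical(cmp$selected_model, "swing")
  expect_equal(cmp$aicc_a, aicc(15, 10, 2.0))
  # antisymmetric under argument swap
  rev <- compare_models(b, a)
  expect_equal(rev$delta_aicc, -cmp$delta_aicc)
  # identical fits tie
  tie <- compare_models(a, a)
  expect_identical(tie$selected, "tie")
  expect_error(compare_models(a, fake_fit("swing", 1, 9, 10)), "different")
})

test_that("jackknife folds cover the data and summarise the fit", {
  truth <- swing_params()
  d <- generate_uptake_dataset(truth, geom, prot1,
                               noise = noise_model(cv = 0), seed = 3)
  jk <- jackknife_fit(truth, d, geom, prot1, maxit = 250, fold_maxit = 120,
                      restarts = 0)
  # one fold per (mean) observation; 5 sampling times in challenge 1
  expect_equal(jk$n_obs, 5)
  expect_equal(length(jk$loo_errors), 5)
  expect_equal(nrow(jk$fold_estimates), 5)
  # noise-free data, true start: near-zero generalization error, R^2 ~ 1
  expect_lt(jk$mse_jk, 1e-4)
  expect_gt(jk$r_squared, 0.9999)
  td <- tidy(jk)
  expect_identical(td$term, names(unclass(truth)))
  expect_true(all(td$ci_half_width >= 0))
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
  gl <- glance(jk)
  expect_identical(gl$model, "swing")
  expect_equal(gl$n_free, 9)
  expect_error(jackknife_fit(truth, d[d$time_min == 3, ], geom, prot1),
               "at least 3")
})
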