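# Retention-index calibration, RI models, prediction and expansion.

test_that("calibration recovers an exact line and reports errors", {
  cal <- make_calibration(k = 0.3, b = 1.0)
  expect_equal(cal$k, 0.3, tolerance = 1e-10)
  expect_equal(cal$b, 1.0, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1)
  expect_error(fit_ri_calibration(data.frame(carbon_number = 20, rt_min = 5)),
               "2 distinct")
  # symmetric perturbation keeps the slope near truth
  obs <- data.frame(carbon_number = 20:30, rt_min = 0.3 * (20:30) + 1)
  obs$rt_min <- obs$rt_min + rep(c(0.01, -0.01), length.out = 11)
  cal2 <- fit_ri_calibration(obs)
  expect_equal(cal2$k, 0.3, tolerance = 0.01 / 0.3)
  expect_warning(
    fit_ri_calibration(data.frame(carbon_number = c(20, 21, 22, 23),
                                  rt_min = c(5, 9, 5.5, 9.5))),
    "r-squared"
  )
})

test_that("rt <-> ri conversion is the exact affine pair", {
  cal <- make_calibration(k = 0.5, b = 2.0)
  expect_equal(rt_to_ri(12.0, cal), 2000)
  expect_equal(rt_to_ri(cal$b, cal), 0)
  expect_equal(ri_to_rt(0, cal), cal$b)
  expect_equal(ri_to_rt(2000, cal), 12.0)
  # a perfect Cn calibrant maps to 100 n
  expect_equal(rt_to_ri(0.5 * (20:30) + 2.0, cal), 100 * (20:30))
  set.seed(4)
  x <- runif(100, 0, 3500)
  expect_equal(rt_to_ri(ri_to_rt(x, cal), cal), x, tolerance = 1e-9)
})

test_that("shipped models carry the published constants", {
  m <- shipped_ri_models()
  expect_equal(unname(coef(m[["14:0"]])), c(1131, 97, -29))
  expect_equal(m[["14:0"]]$r_squared, 0.9989)
  expect_equal(unname(coef(m[["16:0"]])), c(1429, 90, -29))
  expect_equal(m[["16:0"]]$r_squared, 0.9982)
  expect_equal(unname(coef(m[["18:0"]])), c(1704, 83, -28))
  expect_equal(m[["18:0"]]$r_squared, 0.9976)
})

test_that("predictions reproduce hand arithmetic from the model constants", {
  m <- shipped_ri_models()
  expect_equal(predict_ri(m[["14:0"]], 18, 9), 2616)
  expect_equal(predict_ri(m[["16:0"]], 16, 9), 2608)
  expect_equal(predict_ri(m[["18:0"]], 14, 10), 2586)
  expect_warning(predict_ri(m[["14:0"]], 20, 9), "extrapolat")
})

test_that("predicted RI is monotone in both predictors for shipped models", {
  for (m in shipped_ri_models()) {
    grid <- expand.grid(x1 = 14:18, x2 = 5:12)
    ri <- predict_ri(m, grid$x1, grid$x2)
    up <- predict_ri(m, grid$x1 + 1L, grid$x2, warn_extrapolation = FALSE)
    right <- predict_ri(m, grid$x1, grid$x2 + 1L, warn_extrapolation = FALSE)
    expect_true(all(up > ri))
    expect_true(all(right < ri))
  }
})

test_that("fitting noiseless model-generated grids recovers the coefficients", {
  for (m in shipped_ri_models()) {
    grid <- expand.grid(fa_carbon = 14:18, ester_position = 5:12)
    grid$ri <- predict_ri(m, grid$fa_carbon, grid$ester_position)
    fit <- fit_ri_model(grid, m$hfa_key)
    expect_equal(coef(fit), coef(m), tolerance = 1e-9)
    expect_equal(fit$r_squared, 1)
    expect_equal(fit$fa_carbon_range, c(14, 18))
    expect_equal(fit$position_range, c(5, 12))
  }
})

test_that("rank-deficient designs are rejected with the predictor named", {
  grid <- expand.grid(fa_carbon = 14:18, ester_position = 9)
  grid$ri <- 1131 + 97 * grid$fa_carbon - 29 * grid$ester_position
  expect_error(fit_ri_model(grid, "14:0"), "ester_position")
  grid2 <- expand.grid(fa_carbon = 16, ester_position = 5:12)
  grid2$ri <- 1131 + 97 * grid2$fa_carbon - 29 * grid2$ester_position
  expect_error(fit_ri_model(grid2, "14:0"), "fa_carbon")
  expect_error(fit_ri_model(data.frame(fa_carbon = 14, ester_position = 5,
                                       ri = 2344)[0, ], "x"), "3 observations")
})

test_that("coefficient recovery from noisy grids is unbiased", {
  m <- shipped_ri_models()[["14:0"]]
  reps <- simulate(m, nsim = 50, seed = 42, noise_sd = 3)
  slopes <- vapply(reps, function(d) coef(fit_ri_model(d, "14:0"))["fa_carbon"],
                   numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 97), 2 * se + 1e-9)
})

test_that("model simulation is reproducible under a seed", {
  m <- shipped_ri_models()[["16:0"]]
  a <- simulate(m, nsim = 3, seed = 9, noise_sd = 3)
  b <- simulate(m, nsim = 3, seed = 9, noise_sd = 3)
  expect_identical(a, b)
})

test_that("expansion spans 15 families on the default grids", {
  pred <- expand_predictions()
  expect_equal(length(unique(pred$family)), 15L)
  expect_equal(nrow(pred), 120L)  # 5 FA carbons x 8 positions x 3 models
  one <- expand_predictions(shipped_ri_models()[1], positions = 9L)
  expect_equal(nrow(one), 5L)
  # every row equals the generating affine map
  m <- shipped_ri_models()
  for (i in sample(nrow(pred), 10)) {
    expect_equal(pred$predicted_ri[i],
                 predict_ri(m[[pred$hfa[i]]], pred$fa_carbon[i],
                            pred$ester_position[i], warn_extrapolation = FALSE))
  }
})
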