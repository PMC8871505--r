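test_that("net OD follows the transmission definition", {
  expect_equal(film_net_od(40000, 40000), 0)
  expect_equal(film_net_od(40000, 4000), 1)
  expect_error(film_net_od(40000, 0), "positive")
  expect_error(film_net_od(-1, 10), "positive")
})

test_that("an exact line is fitted exactly", {
  cv <- fit_dose_response(calibration_points(c(0, 2, 4), c(0, 0.2, 0.4)),
                          linear_max_dose = 4)
  expect_equal(cv$slope, 0.1, tolerance = 1e-14)
  expect_equal(cv$intercept, 0, tolerance = 1e-14)
})

test_that("weighted fit equals the normal-equations oracle", {
  set.seed(5)
  for (rep in 1:5) {
    d <- c(0, 2, 4, 6, 8, 10)
    sd <- runif(6, 0.01, 0.05)
    y <- 0.2 + 0.084 * d + rnorm(6, sd = sd)
    cv <- fit_dose_response(calibration_points(d, y, sd),
                            linear_max_dose = 10)
    W <- diag(1 / sd^2)
    X <- cbind(1, d)
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
    covb <- solve(t(X) %*% W %*% X)
    expect_equal(cv$intercept, beta[1], tolerance = 1e-10)
    expect_equal(cv$slope, beta[2], tolerance = 1e-10)
    expect_equal(cv$slope_se, sqrt(covb[2, 2]), tolerance = 1e-10)
  }
})

test_that("inversion is the exact inverse on the linear range", {
  cv <- fit_dose_response(
    calibration_points(c(0, 2, 4, 6), 0.01 + 0.084 * c(0, 2, 4, 6)),
    linear_max_dose = 6)
  expect_equal(invert_response(cv, cv$intercept)$dose, 0)
  for (d in c(0.5, 2.2, 5.9)) {
    inv <- invert_response(cv, predict(cv, d))
    expect_equal(inv$dose, d, tolerance = 1e-12)
    expect_false(inv$saturated)
  }
  # slope 0.084, intercept ~0, response 0.42 -> 5 Gy
  cv0 <- fit_dose_response(calibration_points(c(0, 2, 4), 0.084 * c(0, 2, 4)),
                           linear_max_dose = 4)
  inv <- invert_response(cv0, 0.42)
  expect_equal(inv$dose, 5, tolerance = 1e-12)
  expect_true(inv$saturated)   # 5 Gy exceeds the 4 Gy linear bound
  clip <- invert_response(cv0, -0.1)
  expect_equal(clip$dose, 0)
  expect_true(clip$clipped)
})

test_that("degenerate calibrations are rejected", {
  expect_error(fit_dose_response(calibration_points(c(0, 2), c(0, 0.2)),
                                 linear_max_dose = 4), "3 usable")
  expect_error(fit_dose_response(calibration_points(c(2, 2, 2), c(1, 2, 3)),
                                 linear_max_dose = 4), "distinct")
  cvz <- fit_dose_response(calibration_points(c(0, 2, 4), c(0, 0.2, 0.4)),
                           linear_max_dose = 4)
  cvz$slope <- 0
  expect_error(invert_response(cvz, 0.3), "zero")
})

test_that("slope recovery is unbiased with calibrated interval coverage", {
  doses <- c(0, 2, 4, 6, 8, 10)
  truth <- 0.084
  nrep <- 200
  slopes <- numeric(nrep)
  covered <- logical(nrep)
  for (i in seq_len(nrep)) {
    pts <- simulate_calibration_points(doses, truth, response_sd = 0.02,
                                       seed = 5000 + i)
    cv <- fit_dose_response(pts, linear_max_dose = 10)
    slopes[i] <- cv$slope
    covered[i] <- abs(cv$slope - truth) <= 2 * cv$slope_se
  }
  expect_lt(abs(mean(slopes) - truth) / truth, 0.01)
  expect_gte(mean(covered), 0.90)
})

test_that("film slope recovery holds at the film sensitivity", {
  doses <- c(0, 1, 2, 3, 4)
  truth <- 0.100
  slopes <- vapply(1:200, function(i) {
    pts <- simulate_calibration_points(doses, truth, response_sd = 0.01,
                                       seed = 9000 + i)
    fit_dose_response(pts, linear_max_dose = 4)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - truth) / truth, 0.01)
})

test_that("auto linear-range detection flags early saturation", {
  # saturating generator: onset on the 8 Gy scale, visible curvature by 10
  doses <- 0:10
  hits <- vapply(1:50, function(i) {
    set.seed(300 + i)
    y <- 0.8 * (1 - exp(-doses / 8)) + rnorm(11, sd = 0.01)
    cv <- fit_dose_response(calibration_points(doses, y, 0.01),
                            linear_max_dose = "auto")
    cv$linear_max_dose <= 8
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  # genuinely linear data keeps the full range
  cv_lin <- fit_dose_response(
    simulate_calibration_points(0:10, 0.084, response_sd = 0.01, seed = 2),
    linear_max_dose = "auto")
  expect_equal(cv_lin$linear_max_dose, 10)
})

test_that("forward-simulated gel calibration recovers the R2 sensitivity", {
  gel <- gel_response_model(noise_sigma = 10)  # 1% of s0
  slopes <- vapply(1:20, function(i) {
    cal <- simulate_gel_calibration(c(0, 2, 4, 6, 8, 10), gel, seed = i)
    fit_dose_response(cal, linear_max_dose = 10)$slope
  }, numeric(1))
  # the full forward path (Rician noise, mild saturation) stays within a
  # few percent of the configured 0.084 normalized-R2 slope
  expect_lt(abs(mean(slopes) - 0.084), 0.003)
})
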