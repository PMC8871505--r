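test_that("shot fields scale to the prescription and are symmetric", {
  g <- fine_grid(n = 61L, spacing = 0.5)
  d <- make_shot_dose_field(shot_spec(4, prescription_dose = 4), g)
  # 4 Gy prescribed at the 50% isodose -> 8 Gy at the center
  expect_equal(max(d$dose), 8, tolerance = 1e-12)
  p <- extract_profile(d, "z", through = c(100, 100, 100))
  n <- length(p$values)
  expect_equal(p$values, rev(p$values), tolerance = 1e-12)
})

test_that("generated FWHM tracks the nominal width within one spacing", {
  for (col in c(4, 8, 16)) {
    nom <- collimator_defaults(col)$nominal_fwhm
    g <- fine_grid(n = 2L * ceiling(nom / 0.5) + 21L, spacing = 0.5)
    d <- make_shot_dose_field(shot_spec(col), g)
    f <- fwhm(extract_profile(d, "z", normalize = TRUE))
    expect_lt(abs(f$fwhm - nom), 0.5)
  }
})

test_that("multiple shots superpose additively, exactly", {
  g <- fine_grid(n = 41L, spacing = 0.5)
  s1 <- shot_spec(4, center = c(98, 100, 100))
  s2 <- shot_spec(4, center = c(102, 100, 100), prescription_dose = 2)
  both <- make_shot_dose_field(list(s1, s2), g)
  sum_of <- make_shot_dose_field(s1, g)$dose + make_shot_dose_field(s2, g)$dose
  expect_identical(both$dose, sum_of)
})

test_that("unplaceable or unresolvable shots are rejected", {
  g <- fine_grid(n = 21L, spacing = 0.5)
  expect_error(make_shot_dose_field(shot_spec(4, center = c(200, 100, 100)), g),
               "outside")
  coarse <- grid_spec(c(9, 9, 9), 4, origin = c(84, 84, 84))
  expect_error(make_shot_dose_field(shot_spec(4), coarse), "unresolvable")
})

test_that("gel response is linear at low dose and saturates on scale", {
  gel <- noiseless_gel()
  s_abs <- gel$sensitivity * gel$r2_baseline
  d <- seq(0.5, gel$saturation_dose / 10, length.out = 20)
  lin <- gel$r2_baseline + s_abs * d
  rel <- abs(gel_r2(d, gel) - lin) / (s_abs * d)
  expect_lt(max(rel), 0.05)
  expect_lt(gel_r2(1e6, gel), gel$r2_baseline + s_abs * gel$saturation_dose + 1e-9)
})

test_that("MRI forward model matches scalar signal evaluations", {
  g <- grid_spec(c(3, 3, 1), 1)
  gel <- noiseless_gel(r2_baseline = 10)
  # zero dose, no noise -> uniform S(TE) = s0 exp(-r2_baseline TE)
  p0 <- mri_forward(dose_grid(array(0, c(3, 3, 1)), g), gel)
  expect_equal(unique(as.vector(p0$s1)), gel$s0 * exp(-10 * 0.089))
  expect_equal(unique(as.vector(p0$s2)), gel$s0 * exp(-10 * 0.145))
  # dose chosen so R2 = 20 s^-1 -> S(TE 89 ms) = s0 e^-1.78
  d20 <- stats::uniroot(function(d) gel_r2(d, gel) - 20, c(0, 100),
                        tol = 1e-14)$root
  p <- mri_forward(dose_grid(array(d20, c(3, 3, 1)), g), gel)
  expect_equal(p$s1[1], gel$s0 * exp(-1.78), tolerance = 1e-12)
  expect_equal(p$te1, 89)
  expect_equal(p$te2, 145)
})

test_that("MRI forward model rejects bad echo times and negative dose", {
  g <- grid_spec(c(2, 2, 1), 1)
  d <- dose_grid(array(1, c(2, 2, 1)), g)
  expect_error(mri_forward(d, noiseless_gel(), te_pair = c(89, 89)), "differ")
  d$dose[1] <- -1
  expect_error(mri_forward(d, noiseless_gel()), "negative")
})

test_that("noise realizations are seed-deterministic and seed-sensitive", {
  g <- grid_spec(c(8, 8, 2), 1)
  d <- dose_grid(array(2, c(8, 8, 2)), g)
  gel <- gel_response_model(noise_sigma = 5)
  a <- mri_forward(d, gel, seed = 42)
  b <- mri_forward(d, gel, seed = 42)
  c <- mri_forward(d, gel, seed = 43)
  expect_identical(a$s1, b$s1)
  expect_identical(a$s2, b$s2)
  expect_false(identical(a$s1, c$s1))
  film <- film_response_model(noise_sigma = 50)
  fa <- film_forward(matrix(2, 6, 6), film, seed = 7)
  fb <- film_forward(matrix(2, 6, 6), film, seed = 7)
  fc <- film_forward(matrix(2, 6, 6), film, seed = 8)
  expect_identical(fa$pixels, fb$pixels)
  expect_false(identical(fa$pixels, fc$pixels))
})

test_that("film forward model reproduces the OD response", {
  film <- film_response_model()
  expect_equal(film$low_dose_slope, 0.1)
  s0 <- film_forward(matrix(0, 4, 4), film)
  expect_equal(unique(as.vector(s0$pixels)), film$pv0)
  expect_equal(unique(as.vector(s0$od)), 0)
  # low-dose slope 0.100 -> OD(0.1 Gy) ~ 0.010 within 1%
  od <- film_od(0.1, film)
  expect_lt(abs(od - 0.010) / 0.010, 0.01)
  # monotonicity
  d <- seq(0, 40, by = 0.5)
  expect_true(all(diff(film_od(d, film)) >= 0))
  expect_error(film_forward(matrix(-1, 2, 2), film), "nonnegative")
})
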