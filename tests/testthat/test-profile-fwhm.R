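test_that("profile extraction honors grid geometry and normalization", {
  g <- fine_grid(n = 41L, spacing = 0.5)
  d <- make_shot_dose_field(shot_spec(4), g)
  p <- extract_profile(d, "z", through = c(100, 100, 100), normalize = TRUE)
  expect_equal(max(p$values), 100)
  expect_equal(unique(round(diff(p$positions), 12)), 0.5)
  expect_equal(p$values, rev(p$values), tolerance = 1e-9)
  expect_error(extract_profile(d, "z", through = c(100, 500, 100)), "outside")
})

test_that("FWHM of elementary shapes matches hand values", {
  # rectangular pulse of width 6 mm (edges land midway between samples)
  pos_half <- seq(-9.5, 9.5, by = 1)
  rect <- ifelse(abs(pos_half) <= 3, 100, 0)
  expect_equal(fwhm(list(positions = pos_half, values = rect))$fwhm, 6)
  # triangle peaking at 100, zero at +/-4 -> crossings at +/-2
  pos <- seq(-10, 10, by = 1)
  tri <- pmax(0, 100 - 25 * abs(pos))
  f <- fwhm(list(positions = pos, values = tri))
  expect_equal(f$fwhm, 4)
  expect_equal(f$left_crossing, -2)
  expect_equal(f$right_crossing, 2)
  expect_equal(f$peak_position, 0)
  # truncated profile errors
  expect_error(fwhm(list(positions = pos, values = 100 - 0.1 * abs(pos))),
               "half-maximum")
})

test_that("FWHM is scale- and translation-equivariant", {
  g <- fine_grid(n = 61L, spacing = 0.5)
  p <- extract_profile(make_shot_dose_field(shot_spec(8), g), "z")
  f0 <- fwhm(p)
  scaled <- list(positions = p$positions, values = 3.7 * p$values)
  expect_equal(fwhm(scaled)$fwhm, f0$fwhm, tolerance = 1e-12)
  shifted <- list(positions = p$positions + 12.5, values = p$values)
  fs <- fwhm(shifted)
  expect_equal(fs$fwhm, f0$fwhm, tolerance = 1e-12)
  expect_equal(fs$left_crossing, f0$left_crossing + 12.5, tolerance = 1e-9)
})

test_that("FWHM error shrinks monotonically under grid refinement", {
  errs <- vapply(c(0.5, 0.25, 0.125), function(h) {
    n <- 2L * ceiling(8 / h) + 1L
    # center deliberately off the voxel lattice so interpolation error shows
    g <- grid_spec(rep(n, 3), h, origin = c(100, 100, 100.03) - (n - 1L) / 2 * h)
    d <- make_shot_dose_field(shot_spec(4, center = c(100, 100, 100)), g)
    f <- fwhm(extract_profile(d, "z", through = c(100, 100, 100)))
    abs(f$fwhm - 6.2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("deviation arithmetic reproduces the published comparison table", {
  expect_equal(fwhm_deviation(11.3, 11.8, "measured"), 4.2)
  expect_equal(fwhm_deviation(6.2, 5.6, "reference"), 9.7)
  expect_equal(fwhm_deviation(6.2, 5.9, "reference"), 4.8)
  expect_equal(fwhm_deviation(19.8, 19.5, "reference"), 1.5)
  expect_equal(fwhm_deviation(6.2, 6.2), 0)
  expect_error(fwhm_deviation(-1, 5), "positive")
  tab <- fwhm_deviation_table()
  gel <- tab[tab$method == "gel", ]
  expect_lte(max(pmin(gel$dev_pct_reference, gel$dev_pct_measured)), 5)
  ebt3 <- tab[tab$method == "ebt3", ]
  expect_equal(range(ebt3$delta_mm), c(0.3, 1.6))
})
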