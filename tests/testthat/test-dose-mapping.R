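noise_free_recon <- function(collimator = 8, n = 61L, spacing = 0.5) {
  g <- fine_grid(n = n, spacing = spacing)
  gel <- noiseless_gel()
  truth <- make_shot_dose_field(shot_spec(collimator), g)
  pair <- mri_forward(truth, gel)
  nmap <- normalize_response(compute_r2_map(pair),
                             truth$dose < 0.005 * max(truth$dose))
  curve <- fit_dose_response(
    simulate_gel_calibration(c(0, 2, 4, 6, 8, 10, 12, 16), gel, seed = 1),
    linear_max_dose = 16)
  list(truth = truth, recon = reconstruct_dose_map(nmap, curve),
       curve = curve)
}

test_that("noise-free reconstruction inverts the forward model", {
  r <- noise_free_recon()
  ok <- r$recon$valid & r$truth$dose <= r$curve$linear_max_dose
  err <- max(abs(r$recon$dose[ok] - r$truth$dose[ok]))
  expect_lt(err, 0.01 * max(r$truth$dose))
  expect_identical(r$recon$grid, r$truth$grid)   # geometry carried through
  expect_equal(r$recon$provenance, "gel-MRI")
})

test_that("vial series reconstructs in dose order with saturation flags", {
  # five vials at the plan doses; calibration linear to 16 Gy
  plan <- c(10, 13, 18.6, 26, 43.3)
  gel <- noiseless_gel()
  curve <- fit_dose_response(
    simulate_gel_calibration(c(0, 2, 4, 6, 8, 10, 12, 16), gel, seed = 1),
    linear_max_dose = 16)
  g <- grid_spec(c(7, 7, 3), c(0.5, 0.5, 2.5))
  shp <- c(7, 7, 3)
  maxima <- numeric(5); sat <- logical(5)
  for (i in seq_along(plan)) {
    vial <- array(0, shp); vial[2:6, 2:6, ] <- plan[i]
    pair <- mri_forward(dose_grid(vial, g), gel)
    nmap <- normalize_response(compute_r2_map(pair, 0), vial == 0)
    rec <- reconstruct_dose_map(nmap, curve)
    maxima[i] <- max(rec$dose[rec$valid])
    sat[i] <- any(rec$saturated)
  }
  expect_true(all(diff(maxima) > 0))
  expect_identical(sat, c(FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("invalid response voxels stay invalid; mismatched kinds error", {
  g <- grid_spec(c(3, 3, 1), 1)
  m <- r2_map(array(NA_real_, c(3, 3, 1)), array(FALSE, c(3, 3, 1)), g,
              normalized = TRUE, reference_r2 = 10)
  curve <- fit_dose_response(calibration_points(c(0, 2, 4), c(0, 0.2, 0.4)),
                             linear_max_dose = 4)
  rec <- reconstruct_dose_map(m, curve)
  expect_false(any(rec$valid))
  film_curve <- fit_dose_response(calibration_points(c(0, 2, 4), c(0, 0.2, 0.4)),
                                  linear_max_dose = 4, method = "film_od")
  expect_error(reconstruct_dose_map(m, film_curve), "mismatch")
  raw <- r2_map(array(1, c(3, 3, 1)), array(TRUE, c(3, 3, 1)), g)
  expect_error(reconstruct_dose_map(raw, curve), "normalized")
})

test_that("isodose labels are nested, monotone and cover the top level", {
  g <- fine_grid(n = 41L, spacing = 0.5)
  d <- make_shot_dose_field(shot_spec(8), g)
  iso <- render_isodose_map(d, levels = c(90, 50, 10))
  lab <- iso$labels
  # label 1 is the >= 90% region; regions nest: 90% inside 50% inside 10%
  r90 <- lab %in% 1L
  r50 <- lab %in% 1:2
  r10 <- lab %in% 1:3
  expect_true(all(r50[r90]))
  expect_true(all(r10[r50]))
  expect_gt(sum(r90), 0)
  expect_gt(sum(r50), sum(r90))
  # monotone labeling: raising a voxel's dose never drops it to a lower band
  # (numerically, the label moves toward 1 or stays, and never falls to 0)
  d2 <- d; d2$dose <- d$dose * 1.2 + 0.01
  d2$dose <- pmin(d2$dose, max(d$dose))  # keep the same Dmax scale
  iso2 <- render_isodose_map(dose_grid(d2$dose, g), levels = c(90, 50, 10))
  was_in <- lab > 0L
  expect_true(all(iso2$labels[was_in] > 0L))
  expect_true(all(iso2$labels[was_in] <= lab[was_in]))
  # uniform field: everything in the top band
  u <- dose_grid(array(5, c(4, 4, 2)), grid_spec(c(4, 4, 2), 1))
  expect_true(all(render_isodose_map(u, c(90, 50, 10))$labels == 1))
  expect_error(render_isodose_map(d, numeric(0)), "nonempty")
})

test_that("the 50% band diameter equals the field FWHM within a spacing", {
  g <- fine_grid(n = 81L, spacing = 0.25)
  d <- make_shot_dose_field(shot_spec(4), g)
  iso <- render_isodose_map(d, levels = 50)
  mid <- (dim(iso$labels) + 1L) %/% 2L
  along_z <- iso$labels[mid[1], mid[2], ]
  diam <- sum(along_z >= 1L) * g$spacing[3]
  expect_lt(abs(diam - 6.2), g$spacing[3] + 1e-9)
})
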