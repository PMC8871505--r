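test_that("two-point map equals a per-voxel scalar oracle", {
  set.seed(11)
  g <- grid_spec(c(6, 5, 3), 1)
  s1 <- array(runif(90, 50, 200), c(6, 5, 3))
  s2 <- array(runif(90, 20, 150), c(6, 5, 3))
  pair <- echo_image_pair(s1, s2, 89, 145, g)
  m <- compute_r2_map(pair, signal_floor = 0)
  oracle <- array(NA_real_, dim(s1))
  for (i in 1:6) for (j in 1:5) for (k in 1:3)
    oracle[i, j, k] <- log(s1[i, j, k] / s2[i, j, k]) / ((145 - 89) / 1000)
  expect_equal(m$r2, oracle, tolerance = 1e-15)
})

test_that("hand-evaluated rates come out in s^-1", {
  g <- grid_spec(c(2, 2, 1), 1)
  # equal signals -> zero rate
  p0 <- echo_image_pair(array(100, c(2, 2, 1)), array(100, c(2, 2, 1)),
                        89, 145, g)
  expect_equal(unique(as.vector(compute_r2_map(p0, 0)$r2)), 0)
  # signal ratio e over TE 89/145 ms -> 1/0.056 s = 17.857 s^-1
  pe <- echo_image_pair(array(exp(1) * 50, c(2, 2, 1)),
                        array(50, c(2, 2, 1)), 89, 145, g)
  expect_equal(unique(as.vector(compute_r2_map(pe, 0)$r2)), 1 / 0.056,
               tolerance = 1e-12)
})

test_that("low-signal voxels are masked without disturbing neighbors", {
  g <- grid_spec(c(3, 1, 1), 1)
  s1 <- array(c(100, 100, 100), c(3, 1, 1))
  s2 <- array(c(50, 0, 50), c(3, 1, 1))
  m <- compute_r2_map(echo_image_pair(s1, s2, 89, 145, g), signal_floor = 0)
  expect_false(m$valid[2, 1, 1])
  expect_true(is.na(m$r2[2, 1, 1]))
  expect_equal(m$r2[c(1, 3)], rep(log(2) / 0.056, 2))
})

test_that("map is invariant to echo order and inverse to the forward model", {
  g <- fine_grid(n = 31L, spacing = 0.5)
  gel <- noiseless_gel()
  d <- make_shot_dose_field(shot_spec(4), g)
  pair <- mri_forward(d, gel)
  swapped <- echo_image_pair(pair$s2, pair$s1, pair$te2, pair$te1, g)
  m1 <- compute_r2_map(pair, 0)
  m2 <- compute_r2_map(swapped, 0)
  expect_identical(m1$r2, m2$r2)
  expect_lt(max(abs(m1$r2 - gel_r2(d$dose, gel))), 1e-9)
})

test_that("echo pairs with mismatched shapes or equal TEs are rejected", {
  g <- grid_spec(c(2, 2, 1), 1)
  expect_error(echo_image_pair(array(1, c(2, 2, 1)), array(1, c(2, 3, 1)),
                               89, 145, g), "shape")
  expect_error(echo_image_pair(array(1, c(2, 2, 1)), array(1, c(2, 2, 1)),
                               89, 89, g), "differ")
})

test_that("normalization rescales to the reference region once", {
  g <- grid_spec(c(4, 4, 1), 1)
  r2 <- array(12, c(4, 4, 1))
  ref <- array(FALSE, c(4, 4, 1)); ref[, 1:2, 1] <- TRUE
  r2[ref] <- 10
  m <- r2_map(r2, array(TRUE, c(4, 4, 1)), g)
  nm <- normalize_response(m, ref)
  expect_equal(nm$reference_r2, 10)
  expect_equal(unique(nm$r2[!ref]), 0.2)   # (12 - 10) / 10
  expect_equal(unique(nm$r2[ref]), 0)
  expect_error(normalize_response(nm, ref), "already")
  expect_error(normalize_response(m, array(FALSE, c(4, 4, 1))), "empty")
  bad <- r2_map(r2, array(FALSE, c(4, 4, 1)), g)
  expect_error(normalize_response(bad, ref), "no valid")
})
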