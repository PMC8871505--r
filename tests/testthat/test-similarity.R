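test_that("Sobel responds to a unit step with magnitude 4", {
  img <- cbind(matrix(0, 6, 3), matrix(1, 6, 3))
  e <- sobel_magnitude(img)
  expect_equal(unique(as.vector(e[, 3:4])), 4)   # columns flanking the step
  expect_true(all(e[, c(1, 6)] == 0))
  expect_true(all(sobel_magnitude(matrix(2, 5, 5)) == 0))
})

test_that("isodose segmentation yields nested bands over a clean field", {
  g <- fine_grid(n = 41L, spacing = 0.5)
  d <- make_shot_dose_field(shot_spec(8), g)
  pct <- pmin(100 * d$dose[21, , ] / robust_dmax(d), 100)
  seg <- isodose_segment(pct, levels = c(90, 50, 10))
  expect_true(all(seg$bands[pct >= 90] == 1))  # band 1 = >= 90% isodose
  r90 <- seg$bands %in% 1L; r50 <- seg$bands %in% 1:2
  r10 <- seg$bands %in% 1:3
  expect_true(all(r50[r90]) && all(r10[r50]))
  # constant map at 50%: no edges, everything in the 10% band
  seg0 <- isodose_segment(matrix(50, 8, 8), levels = c(90, 10))
  expect_true(all(seg0$edges == 0))
  expect_equal(unique(as.vector(seg0$bands)), 2L)
  expect_error(isodose_segment(pct, numeric(0)), "nonempty")
  expect_error(isodose_segment(matrix(150, 4, 4), 50), "normalized")
})

test_that("translation alignment recovers constructed shifts", {
  img <- structured_image(41)
  expect_identical(align_translation(img, img), c(0L, 0L))
  shifted <- shift_image(img, c(3, -2), fill = 0)
  expect_identical(align_translation(shifted, img), c(-3L, 2L))
  # inverse consistency
  other <- shift_image(img, c(2, 4), fill = 0) + 0.1 * structured_image(41)
  expect_identical(align_translation(img, other),
                   -align_translation(other, img))
  expect_error(align_translation(matrix(1, 5, 5), matrix(1, 5, 5)),
               "degenerate")
})

test_that("SSIM is exact on identical and constant images", {
  img <- structured_image(31)
  r <- ssim_compare(img, img, window = 11)
  expect_equal(r$global_ssim, 1)
  seg <- isodose_segment(100 * img / max(img), c(90, 50, 10))
  rb <- ssim_compare(img, img, bands = seg, window = 11)
  expect_true(all(rb$per_band$ssim == 1))
  # zero-variance closed form: SSIM = (2 mx my + C1) / (mx^2 + my^2 + C1)
  a <- matrix(30, 15, 15); b <- matrix(50, 15, 15)
  r2 <- ssim_compare(a, b, window = 11, dynamic_range = 100)
  c1 <- (0.01 * 100)^2
  expect_equal(r2$global_ssim, (2 * 30 * 50 + c1) / (30^2 + 50^2 + c1),
               tolerance = 1e-8)
  expect_error(ssim_compare(img, img[1:10, 1:10]), "shape")
  expect_error(ssim_compare(img, img, window = 12), "odd")
  expect_error(ssim_compare(img, img, window = 101), "larger")
})

test_that("SSIM is symmetric, bounded and degrades with noise", {
  set.seed(21)
  a <- structured_image(31) + matrix(rnorm(961, sd = 0.1), 31)
  b <- structured_image(31) + matrix(rnorm(961, sd = 0.1), 31)
  expect_equal(ssim_compare(a, b)$global_ssim,
               ssim_compare(b, a)$global_ssim, tolerance = 1e-14)
  expect_true(all(abs(ssim_compare(a, b)$ssim_map) <= 1 + 1e-9))
  base <- structured_image(41)
  eps <- matrix(rnorm(1681), 41)   # one pattern, growing amplitude
  scores <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(s)
    ssim_compare(base, base + s * eps, dynamic_range = 10)$global_ssim,
    numeric(1))
  expect_true(all(diff(scores) < 0))
})
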