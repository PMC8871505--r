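# Small fixtures shared across the suite; everything is generated in code.

fine_grid <- function(n = 81L, spacing = 0.25, center = c(100, 100, 100)) {
  grid_spec(rep(n, 3), spacing, origin = center - (n - 1L) / 2 * spacing)
}

noiseless_gel <- function(...) gel_response_model(noise_sigma = 0, ...)

# A smooth structured test image (superposed Gaussians), deterministic.
structured_image <- function(n = 41L) {
  x <- seq(-1, 1, length.out = n)
  g <- function(cx, cy, s) outer(x, x, function(a, b)
    exp(-((a - cx)^2 + (b - cy)^2) / (2 * s^2)))
  10 * g(0, 0, 0.3) + 4 * g(0.4, -0.3, 0.15)
}

small_qa_config <- function(seed = 1L) {
  cfg <- default_qa_config()
  cfg$seed <- seed
  cfg$grid <- list(shape = c(5L, 61L, 61L), spacing = c(2.5, 0.5, 0.5),
                   center = c(100, 100, 100))
  cfg$shots <- list(list(collimator = 4, prescription_dose = 4))
  cfg$film_scan <- list(dpi = 300, region_mm = 16)
  cfg
}
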