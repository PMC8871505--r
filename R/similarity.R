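#' @name similarity
#' @title Dose-distribution similarity: alignment, segmentation, SSIM
#' @description
#' Comparison of a reconstructed planar dose distribution against a
#' reference map: integer-pixel translation alignment by normalized
#' cross-correlation, Sobel edge extraction with nested isodose-band
#' segmentation, and per-band structural similarity (SSIM) scoring.
NULL

# 2D convolution with a small kernel and reflected (mirror) boundary.
conv2_reflect <- function(img, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  ri <- c(rev(seq_len(kr) + 1L), seq_len(n), n - seq_len(kr))
  ci <- c(rev(seq_len(kc) + 1L), seq_len(m), m - seq_len(kc))
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(0, n, m)
  for (i in seq_len(nrow(kernel)))
    for (j in seq_len(ncol(kernel)))
      out <- out + kernel[i, j] *
        pad[(nrow(kernel) - i) + seq_len(n), (ncol(kernel) - j) + seq_len(m)]
  out
}

# Separable Gaussian smoothing with reflected boundary.
gauss_smooth <- function(img, window = 11L, sigma = 1.5) {
  half <- (window - 1L) / 2
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  img <- conv2_reflect(img, matrix(k, ncol = 1))
  conv2_reflect(img, matrix(k, nrow = 1))
}

#' Sobel gradient magnitude
#'
#' 3x3 Sobel kernels with reflected boundary handling; the magnitude is
#' `sqrt(gx^2 + gy^2)`. A unit step responds with magnitude 4 on the step
#' line.
#'
#' @param img 2D numeric matrix.
#' @return Matrix of gradient magnitudes, same shape.
#' @export
sobel_magnitude <- function(img) {
  img <- as.matrix(img)
  if (nrow(img) < 2L || ncol(img) < 2L) stop("image too small for Sobel")
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # gradient across rows
  ky <- t(kx)
  gx <- conv2_reflect(img, kx)
  gy <- conv2_reflect(img, ky)
  sqrt(gx^2 + gy^2)
}

#' Segment a normalized dose map into isodose bands
#'
#' Extracts the Sobel edge-magnitude image and labels each pixel with the
#' highest isodose level it meets (nested thresholding), so the bands
#' partition the map: label 0 is below the lowest level, label k means the
#' pixel is at or above `levels[k]` but below `levels[k-1]`.
#'
#' @param map 2D matrix of normalized dose in percent (0..100 scale).
#' @param levels isodose levels in percent, strictly decreasing.
#' @return A list with `bands` (integer label matrix), `edges` (Sobel
#'   magnitude matrix) and the `levels`.
#' @export
isodose_segment <- function(map, levels = c(90, 80, 70, 60, 50, 30, 10)) {
  map <- as.matrix(map)
  if (!length(levels)) stop("'levels' must be nonempty")
  if (length(levels) > 1L && any(diff(levels) >= 0))
    stop("'levels' must be strictly decreasing")
  if (min(map, na.rm = TRUE) < -1e-9 || max(map, na.rm = TRUE) > 100 + 1e-6)
    stop("'map' must be normalized to the 0..100 percent scale")
  edges <- sobel_magnitude(map)
  bands <- matrix(0L, nrow(map), ncol(map))
  for (k in rev(seq_along(levels)))
    bands[!is.na(map) & map >= levels[k]] <- k
  bands[is.na(map)] <- NA_integer_
  list(bands = bands, edges = edges, levels = levels)
}

#' Integer-pixel translation alignment by normalized cross-correlation
#'
#' Searches integer shifts of `moving` against `fixed` (same pixel spacing)
#' and returns the shift maximizing the Pearson correlation over the
#' overlap. Ties break toward the smallest shift magnitude, then
#' lexicographically, for determinism. The search demands at least 25%
#' area overlap.
#'
#' @param moving,fixed 2D matrices of identical shape.
#' @param max_shift search radius in pixels per axis; default a quarter of
#'   the image size.
#' @return Integer vector `c(dr, dc)`: `moving` shifted by this lands on
#'   `fixed` (row, column convention).
#' @export
align_translation <- function(moving, fixed, max_shift = NULL) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!identical(dim(moving), dim(fixed)))
    stop("'moving' and 'fixed' must share their shape")
  n <- nrow(fixed); m <- ncol(fixed)
  if (stats::sd(moving) == 0 || stats::sd(fixed) == 0)
    stop("degenerate (constant) image; alignment undefined")
  if (is.null(max_shift)) max_shift <- floor(min(n, m) / 4)
  max_shift <- as.integer(max_shift)
  best <- c(0L, 0L); best_score <- -Inf
  for (dr in -max_shift:max_shift) {
    for (dc in -max_shift:max_shift) {
      rf <- max(1L, 1L + dr):min(n, n + dr)
      cf <- max(1L, 1L + dc):min(m, m + dc)
      if (length(rf) * length(cf) < 0.25 * n * m) next
      a <- fixed[rf, cf]
      b <- moving[rf - dr, cf - dc]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      score <- stats::cor(as.vector(a), as.vector(b))
      better <- score > best_score + 1e-12 ||
        (abs(score - best_score) <= 1e-12 &&
           (sum(c(dr, dc)^2) < sum(best^2) ||
              (sum(c(dr, dc)^2) == sum(best^2) &&
                 (dr < best[1] || (dr == best[1] && dc < best[2])))))
      if (better) { best_score <- score; best <- c(dr, dc) }
    }
  }
  if (!is.finite(best_score)) stop("no admissible shift with >= 25% overlap")
  best
}

#' Shift a matrix by whole pixels
#'
#' @param img 2D matrix.
#' @param shift integer `c(dr, dc)` as returned by [align_translation()].
#' @param fill value for exposed pixels; default `NA`.
#' @return The shifted matrix.
#' @export
shift_image <- function(img, shift, fill = NA_real_) {
  img <- as.matrix(img)
  n <- nrow(img); m <- ncol(img)
  out <- matrix(fill, n, m)
  dr <- as.integer(shift[1]); dc <- as.integer(shift[2])
  rf <- max(1L, 1L + dr):min(n, n + dr)
  cf <- max(1L, 1L + dc):min(m, m + dc)
  if (length(rf) > 0 && length(cf) > 0)
    out[rf, cf] <- img[rf - dr, cf - dc]
  out
}

#' Structural similarity between two aligned dose maps, per isodose band
#'
#' Standard SSIM with Gaussian-window local statistics (default 11x11,
#' sigma 1.5) and stabilization constants `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2` for dynamic range `L`. The global score is the mean
#' local SSIM over valid pixels; per-band scores average over the pixels of
#' each isodose band.
#'
#' @param a,b 2D matrices of identical shape (aligned).
#' @param bands optional integer band-label matrix from [isodose_segment()].
#' @param window odd window size in pixels; default 11 (truncated to the
#'   image if necessary).
#' @param sigma Gaussian window SD in pixels; default 1.5.
#' @param dynamic_range value range L; default `max(a, b) - min(a, b)`.
#' @param shift integer shift already applied; recorded in the result.
#' @return An object of class `similarity_result`: `global_ssim`,
#'   `per_band` (data frame of level and ssim, levels decreasing),
#'   `ssim_map`, `window`, `c1`, `c2`, `shift`.
#' @export
ssim_compare <- function(a, b, bands = NULL, window = 11L, sigma = 1.5,
                         dynamic_range = NULL, shift = c(0L, 0L)) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("'a' and 'b' must share their shape")
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("'window' must be odd")
  if (window > min(dim(a))) stop("'window' larger than the image")
  if (is.null(dynamic_range))
    dynamic_range <- max(a, b, na.rm = TRUE) - min(a, b, na.rm = TRUE)
  if (!is.finite(dynamic_range) || dynamic_range <= 0) dynamic_range <- 1
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  mu_a <- gauss_smooth(a, window, sigma)
  mu_b <- gauss_smooth(b, window, sigma)
  var_a <- gauss_smooth(a * a, window, sigma) - mu_a^2
  var_b <- gauss_smooth(b * b, window, sigma) - mu_b^2
  cov_ab <- gauss_smooth(a * b, window, sigma) - mu_a * mu_b
  ssim_map <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  global <- mean(ssim_map[is.finite(ssim_map)])
  per_band <- NULL
  if (!is.null(bands)) {
    if (is.list(bands)) {
      levels <- bands$levels
      bands <- bands$bands
    } else levels <- sort(unique(bands[bands > 0]), decreasing = TRUE)
    if (!identical(dim(bands), dim(a)))
      stop("'bands' must match the image shape")
    per_band <- data.frame(level = levels, ssim = NA_real_)
    for (k in seq_along(levels)) {
      inb <- !is.na(bands) & bands == k & is.finite(ssim_map)
      if (any(inb)) per_band$ssim[k] <- mean(ssim_map[inb])
    }
  }
  structure(list(global_ssim = global, per_band = per_band,
                 ssim_map = ssim_map, window = window, sigma = sigma,
                 c1 = c1, c2 = c2, shift = as.integer(shift)),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("similarity_result: global SSIM %.4f (window %d, sigma %.2g)\n",
              x$global_ssim, x$window, x$sigma))
  if (!is.null(x$per_band)) {
    for (i in seq_len(nrow(x$per_band)))
      cat(sprintf("  >= %3g%% band: SSIM %.4f\n",
                  x$per_band$level[i], x$per_band$ssim[i]))
  }
  invisible(x)
}

#' Band SSIM at or above the radiosurgical isodose
#'
#' Convenience accessor: the mean local SSIM over all pixels at or above
#' the 50%-of-Dmax isodose — the "radiosurgical dose range" band.
#'
#' @param result a [ssim_compare()] result with per-band scores.
#' @param bands the band labels used (list from [isodose_segment()]).
#' @return The pooled SSIM over pixels with level >= 50%.
#' @export
radiosurgical_band_ssim <- function(result, bands) {
  stopifnot(inherits(result, "similarity_result"))
  if (is.list(bands)) {
    levels <- bands$levels; lab <- bands$bands
  } else stop("'bands' must be an isodose_segment() result")
  k50 <- which(levels >= 50)
  if (!length(k50)) stop("no band at or above the 50% isodose")
  inb <- !is.na(lab) & lab %in% k50 & is.finite(result$ssim_map)
  if (!any(inb)) stop("no pixels in the >= 50% band")
  mean(result$ssim_map[inb])
}
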