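#' Dual-echo image pair
#'
#' Two co-registered spin-echo magnitude images of the same object at two
#' echo times, the input of two-point R2 mapping.
#'
#' @param s1,s2 magnitude images (arrays of identical shape).
#' @param te1,te2 echo times in ms; must differ.
#' @param grid the [grid_spec()] both images live on (shape must match for
#'   3D arrays).
#' @return An object of class `echo_image_pair`.
#' @export
echo_image_pair <- function(s1, s2, te1, te2, grid) {
  s1 <- as.array(s1); s2 <- as.array(s2)
  if (!identical(dim(s1), dim(s2)))
    stop("'s1' and 's2' must share their shape")
  if (!is.finite(te1) || !is.finite(te2) || te1 <= 0 || te2 <= 0)
    stop("echo times must be positive (ms)")
  if (te1 == te2) stop("TE1 and TE2 must differ")
  stopifnot(inherits(grid, "grid_spec"))
  if (length(dim(s1)) == 3L && !identical(dim(s1), as.integer(grid$shape)))
    stop("image shape does not match the grid")
  structure(list(s1 = s1, s2 = s2, te1 = te1, te2 = te2, grid = grid),
            class = "echo_image_pair")
}

#' @export
print.echo_image_pair <- function(x, ...) {
  cat(sprintf("echo_image_pair: %s voxels, TE %g / %g ms\n",
              paste(dim(x$s1), collapse = " x "), x$te1, x$te2))
  invisible(x)
}

# Rician magnitude noise: Gaussian noise of SD sigma on each complex channel.
rician <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  re <- signal + stats::rnorm(n, sd = sigma)
  im <- stats::rnorm(n, sd = sigma)
  out <- sqrt(re^2 + im^2)
  dim(out) <- dim(signal)
  out
}

#' Forward-model a dose field into a dual-echo MRI pair
#'
#' Mono-exponential spin-echo signal `S(TE) = s0 * exp(-R2(D) * TE)` with
#' `R2(D)` from [gel_r2()], plus Rician magnitude noise (Gaussian noise on
#' both complex channels) of SD `noise_sigma`. TEs are carried in ms and
#' converted to seconds inside the signal model.
#'
#' @param dose a [dose_grid()] with nonnegative dose.
#' @param gel a [gel_response_model()].
#' @param te_pair numeric length-2, echo times in ms; default `c(89, 145)`.
#' @param seed integer seed driving the noise realization.
#' @return An [echo_image_pair()] on the dose grid.
#' @examples
#' g <- grid_spec(c(9, 9, 3), c(0.5, 0.5, 2.5))
#' d <- dose_grid(array(2, c(9, 9, 3)), g)
#' p <- mri_forward(d, gel_response_model(noise_sigma = 0))
#' p$te1; p$te2
#' @export
mri_forward <- function(dose, gel, te_pair = c(89, 145), seed = 1L) {
  stopifnot(inherits(dose, "dose_grid"), inherits(gel, "gel_response_model"))
  if (length(te_pair) != 2L || any(!is.finite(te_pair)) || any(te_pair <= 0))
    stop("'te_pair' must be two positive echo times (ms)")
  if (te_pair[1] == te_pair[2]) stop("TE1 and TE2 must differ")
  if (any(dose$dose < 0)) stop("negative dose voxels")
  r2 <- gel_r2(dose$dose, gel)
  s <- function(te_ms) gel$s0 * exp(-r2 * te_ms / 1000)
  s1 <- s(te_pair[1]); s2 <- s(te_pair[2])
  if (gel$noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    s1 <- rician(s1, gel$noise_sigma)
    s2 <- rician(s2, gel$noise_sigma)
  }
  echo_image_pair(s1, s2, te_pair[1], te_pair[2], dose$grid)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Film scan container
#'
#' A scanned radiochromic film: 2D pixel-value matrix in the 16-bit range,
#' its pixel spacing (from the scan dpi), the analysed color channel, and
#' optionally a derived net-OD matrix.
#'
#' @param pixels 2D numeric matrix of nonnegative pixel values.
#' @param pixel_spacing mm per pixel (`25.4 / dpi`).
#' @param channel analysed channel; default `"red"` (standard radiochromic
#'   practice) or `"gray"` for grayscale scans.
#' @param od optional matrix of net optical densities, same shape.
#' @return An object of class `film_scan`.
#' @export
film_scan <- function(pixels, pixel_spacing, channel = "gray", od = NULL) {
  pixels <- as.matrix(pixels)
  if (any(pixels < 0)) stop("pixel values must be nonnegative")
  if (!is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("'pixel_spacing' must be positive (mm)")
  if (!is.null(od)) {
    od <- as.matrix(od)
    if (!identical(dim(od), dim(pixels)))
      stop("'od' must match the pixel matrix shape")
  }
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 channel = channel, od = od),
            class = "film_scan")
}

#' @export
print.film_scan <- function(x, ...) {
  cat(sprintf("film_scan: %d x %d px, %.4g mm/px, channel %s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing, x$channel,
              if (is.null(x$od)) "" else ", net OD attached"))
  invisible(x)
}

#' Forward-model a planar dose field into a film scan
#'
#' Net OD follows the saturating film response [film_od()]; pixel value is
#' `pv0 * 10^(-OD)` with additive Gaussian scanner noise, clipped to the
#' 16-bit range. OD is monotonically nondecreasing in dose.
#'
#' @param dose_slice 2D matrix of nonnegative dose in Gy.
#' @param film a [film_response_model()].
#' @param pixel_spacing mm per pixel of the simulated scan; default
#'   `25.4 / 1200` (a 1200 dpi scan).
#' @param seed integer seed for the noise realization.
#' @return A [film_scan()] with the noiseless net OD attached.
#' @export
film_forward <- function(dose_slice, film, pixel_spacing = 25.4 / 1200,
                         seed = 1L) {
  stopifnot(inherits(film, "film_response_model"))
  dose_slice <- as.matrix(dose_slice)
  if (any(!is.finite(dose_slice)) || any(dose_slice < 0))
    stop("'dose_slice' must be finite and nonnegative")
  od <- film_od(dose_slice, film)
  pv <- film$pv0 * 10^(-od)
  if (film$noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    pv <- pv + stats::rnorm(length(pv), sd = film$noise_sigma)
    dim(pv) <- dim(od)
  }
  pv <- pmin(pmax(pv, 0), 65535)
  film_scan(pv, pixel_spacing, channel = "gray", od = od)
}
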