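#' Per-voxel transverse relaxation-rate map
#'
#' Holds R2 = 1/T2 in s^-1 per voxel with a validity mask, grid geometry,
#' and normalization metadata.
#'
#' @param r2 array of R2 values (s^-1); entries outside `valid` carry `NA`.
#' @param valid logical array marking voxels with a defined rate.
#' @param grid the [grid_spec()] geometry.
#' @param normalized `TRUE` once [normalize_response()] has been applied.
#' @param reference_r2 the reference (zero-dose) mean R2 used to normalize.
#' @return An object of class `r2_map`.
#' @export
r2_map <- function(r2, valid, grid, normalized = FALSE, reference_r2 = NA) {
  r2 <- as.array(r2); valid <- as.array(valid)
  if (!identical(dim(r2), dim(valid)))
    stop("'r2' and 'valid' must share their shape")
  stopifnot(inherits(grid, "grid_spec"))
  if (any(!is.finite(r2[valid])))
    stop("valid voxels must carry finite R2")
  r2[!valid] <- NA_real_
  structure(list(r2 = r2, valid = valid, grid = grid,
                 normalized = isTRUE(normalized),
                 reference_r2 = reference_r2),
            class = "r2_map")
}

#' @export
print.r2_map <- function(x, ...) {
  cat(sprintf("r2_map: %s voxels, %d valid, %s\n",
              paste(dim(x$r2), collapse = " x "), sum(x$valid),
              if (x$normalized)
                sprintf("normalized to R2_ref = %.4g s^-1", x$reference_r2)
              else "raw rates (s^-1)"))
  invisible(x)
}

# Robust noise-SD estimate from first differences along the fastest axis;
# differencing removes smooth structure, MAD resists the remaining edges.
estimate_noise_sd <- function(x) {
  v <- as.vector(x)
  d <- diff(v)
  d <- d[is.finite(d)]
  if (!length(d)) return(0)
  stats::mad(d, center = 0) / sqrt(2)
}

#' Two-point R2 map from a dual-echo pair
#'
#' Computes the transverse relaxation rate per voxel from two spin-echo
#' magnitude images,
#' \deqn{R2 = \frac{\ln(S(TE_1)/S(TE_2))}{TE_2 - TE_1},}
#' with echo times converted from ms to seconds so R2 is in s^-1. Voxels
#' where either signal is at or below `signal_floor` are marked invalid
#' rather than raising an error. Echoes supplied in reversed TE order are
#' swapped internally, so the map is invariant to echo order.
#'
#' @param pair an [echo_image_pair()].
#' @param signal_floor signal level at or below which a voxel is treated as
#'   noise-dominated and masked. The default `"auto"` uses 3x a noise-SD
#'   estimate from robust first differences of the later-echo image; pass a
#'   number (e.g. 0) to override.
#' @return An [r2_map()].
#' @examples
#' g <- grid_spec(c(2, 2, 1), 1)
#' p <- echo_image_pair(array(exp(1), c(2, 2, 1)), array(1, c(2, 2, 1)),
#'                      te1 = 89, te2 = 145, grid = g)
#' compute_r2_map(p, signal_floor = 0)$r2[1]  # 1/0.056 s
#' @export
compute_r2_map <- function(pair, signal_floor = "auto") {
  stopifnot(inherits(pair, "echo_image_pair"))
  s1 <- pair$s1; s2 <- pair$s2
  te1 <- pair$te1; te2 <- pair$te2
  if (te1 > te2) { tmp <- s1; s1 <- s2; s2 <- tmp; tmp <- te1; te1 <- te2; te2 <- tmp }
  if (identical(signal_floor, "auto"))
    signal_floor <- 3 * estimate_noise_sd(s2)
  if (!is.numeric(signal_floor) || !is.finite(signal_floor))
    stop("'signal_floor' must be \"auto\" or a finite number")
  valid <- s1 > signal_floor & s2 > signal_floor & s1 > 0 & s2 > 0
  r2 <- array(NA_real_, dim = dim(s1))
  dte <- (te2 - te1) / 1000  # ms -> s
  r2[valid] <- log(s1[valid] / s2[valid]) / dte
  r2_map(r2, valid, pair$grid)
}

#' Normalize an R2 map to a zero-dose reference region
#'
#' Replaces rates by the normalized response `(R2 - R2_ref) / R2_ref`, where
#' `R2_ref` is the mean rate over the (unirradiated) reference region. The
#' normalized response is the response variable of gel calibration curves.
#' Normalization is recorded in metadata and may be applied only once.
#'
#' @param map an [r2_map()], not yet normalized.
#' @param reference_region logical array (same shape) or voxel index vector
#'   selecting the zero-dose reference.
#' @return The normalized [r2_map()].
#' @export
normalize_response <- function(map, reference_region) {
  stopifnot(inherits(map, "r2_map"))
  if (map$normalized)
    stop("map is already normalized")
  if (is.logical(reference_region)) {
    if (!identical(dim(as.array(reference_region)), dim(map$r2)))
      stop("logical 'reference_region' must match the map shape")
    idx <- which(reference_region)
  } else idx <- as.integer(reference_region)
  if (!length(idx)) stop("'reference_region' is empty")
  idx <- idx[map$valid[idx]]
  if (!length(idx)) stop("'reference_region' contains no valid voxels")
  r2_ref <- mean(map$r2[idx])
  if (!is.finite(r2_ref) || r2_ref == 0)
    stop("reference mean R2 is degenerate")
  r2_map((map$r2 - r2_ref) / r2_ref, map$valid, map$grid,
         normalized = TRUE, reference_r2 = r2_ref)
}
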