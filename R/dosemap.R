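#' Reconstruct a dose map from a response map
#'
#' Applies [invert_response()] per voxel/pixel to a normalized-R2 map (gel
#' MRI) or a net-OD film scan, carrying the grid geometry through unchanged.
#' Invalid response voxels stay invalid in the dose map; inversions beyond
#' the calibrated linear range are flagged saturated.
#'
#' @param response an [r2_map()] (normalized) or a [film_scan()] with a net
#'   OD matrix attached.
#' @param curve a [fit_dose_response()] curve whose `method` matches the
#'   response kind (`"normalized_r2"`/`"mri_intensity"` for an R2 map,
#'   `"film_od"` for a film scan).
#' @return A [dose_grid()] with provenance `"gel-MRI"` or `"film"`. For a
#'   film scan the grid is a 1-slice planar grid at the film's pixel spacing.
#' @export
reconstruct_dose_map <- function(response, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (inherits(response, "r2_map")) {
    if (!curve$method %in% c("normalized_r2", "mri_intensity"))
      stop(sprintf("response kind mismatch: R2 map vs '%s' curve",
                   curve$method))
    if (curve$method == "normalized_r2" && !response$normalized)
      stop("R2 map must be normalized before inversion against a normalized_r2 curve")
    vals <- response$r2
    valid <- response$valid
    grid <- response$grid
    prov <- "gel-MRI"
  } else if (inherits(response, "film_scan")) {
    if (curve$method != "film_od")
      stop(sprintf("response kind mismatch: film scan vs '%s' curve",
                   curve$method))
    if (is.null(response$od))
      stop("film scan carries no net-OD matrix; compute OD first")
    vals <- array(response$od, dim = c(dim(response$od), 1L))
    valid <- array(is.finite(vals), dim = dim(vals))
    grid <- grid_spec(dim(vals),
                      c(response$pixel_spacing, response$pixel_spacing, 1))
    prov <- "film"
  } else stop("'response' must be an r2_map or a film_scan")
  dose <- array(NA_real_, dim = dim(vals))
  sat <- array(FALSE, dim = dim(vals))
  if (any(valid)) {
    inv <- invert_response(curve, vals[valid])
    dose[valid] <- inv$dose
    sat[valid] <- inv$saturated
  }
  dose_grid(dose, grid, valid = valid, saturated = sat, provenance = prov)
}

#' Robust maximum dose of a grid
#'
#' The "% of Dmax" normalization reference: the mean over the hottest 0.5%
#' of valid voxels (at least one voxel). Averaging the top tail suppresses
#' single-voxel noise spikes without depending on the field-of-view size
#' the way a raw global percentile would, and equals the literal maximum on
#' a noise-free flat-topped field.
#'
#' @param dose a [dose_grid()].
#' @param top_fraction fraction of hottest voxels averaged; default 0.005.
#' @return Dose in Gy.
#' @export
robust_dmax <- function(dose, top_fraction = 0.005) {
  stopifnot(inherits(dose, "dose_grid"))
  v <- dose$dose[dose$valid]
  if (!length(v)) stop("dose grid has no valid voxels")
  k <- max(1L, floor(top_fraction * length(v)))
  mean(sort(v, decreasing = TRUE)[seq_len(k)])
}

#' Label voxels by isodose band
#'
#' Each voxel is labeled with the highest isodose level (percent of the
#' robust Dmax) that it meets, so label bands are nested: the region at or
#' above a higher level is contained in every lower level's region.
#'
#' @param dose a [dose_grid()] with positive maximum dose.
#' @param levels isodose levels as percent of Dmax, strictly decreasing,
#'   in (0, 100].
#' @return A list with `labels` (integer array; 0 = below the lowest level,
#'   k = meets `levels[k]`), the `levels`, and the `dmax` used.
#' @export
render_isodose_map <- function(dose, levels = c(90, 50, 10)) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!length(levels)) stop("'levels' must be a nonempty level list")
  if (any(diff(levels) >= 0) && length(levels) > 1L)
    stop("'levels' must be strictly decreasing")
  if (any(levels <= 0) || any(levels > 100))
    stop("'levels' must lie in (0, 100]")
  dmax <- robust_dmax(dose)
  if (dmax <= 0) stop("Dmax must be positive")
  pct <- 100 * dose$dose / dmax
  labels <- array(0L, dim = dim(pct))
  for (k in rev(seq_along(levels)))  # ascending levels overwrite
    labels[!is.na(pct) & pct >= levels[k]] <- k
  labels[!dose$valid] <- NA_integer_
  list(labels = labels, levels = levels, dmax = dmax)
}

#' Write an isodose-banded dose map as a PNG with a JSON legend
#'
#' @param dose a [dose_grid()]; the central Z slice is rendered unless
#'   `slice` names another slice index.
#' @param path output PNG path; a `.json` legend (level to gray value) is
#'   written next to it.
#' @param levels isodose levels, percent of Dmax, strictly decreasing.
#' @param slice Z slice index; default central.
#' @return Invisibly, the paths written.
#' @export
write_isodose_png <- function(dose, path, levels = c(90, 80, 70, 60, 50, 30, 10),
                              slice = NULL) {
  iso <- render_isodose_map(dose, levels)
  if (dim(iso$labels)[1] == 1L) {      # planar grid: render its own plane
    slice <- 1L
    lab <- iso$labels[1, , ]
  } else {
    nz <- dim(iso$labels)[3]
    if (is.null(slice)) slice <- (nz + 1L) %/% 2L
    lab <- iso$labels[, , slice]
  }
  shades <- seq(0, 1, length.out = length(levels) + 1L)
  img <- matrix(shades[ifelse(is.na(lab), 0L, lab) + 1L],
                nrow(lab), ncol(lab))
  png::writePNG(t(img), path)
  legend <- list(levels_pct = levels,
                 gray_values = shades[-1L],
                 background_gray = shades[1L],
                 dmax_gy = iso$dmax, slice = slice)
  jsonlite::write_json(legend, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(path, paste0(path, ".json")))
}
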