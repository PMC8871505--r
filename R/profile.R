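#' Extract a 1D dose profile along a stereotactic axis
#'
#' Samples the line of voxel centers nearest to `through` along the chosen
#' axis — the discrete analogue of the planning system's axis profiles.
#'
#' @param dose a [dose_grid()].
#' @param axis `"x"`, `"y"` or `"z"` (or 1..3).
#' @param through stereotactic mm point the line passes through; default the
#'   grid center.
#' @param normalize if `TRUE`, scale values so the maximum is exactly 100.
#' @return An object of class `profile_1d` with `positions` (mm, voxel
#'   centers), `values`, `axis` and `through`.
#' @export
extract_profile <- function(dose, axis = "z", through = NULL,
                            normalize = FALSE) {
  stopifnot(inherits(dose, "dose_grid"))
  a <- axis_index(axis)
  ext <- grid_extent(dose$grid)
  if (is.null(through))
    through <- colMeans(ext)
  through <- as.numeric(through)
  if (length(through) != 3L || any(!is.finite(through)))
    stop("'through' must be three finite mm coordinates")
  others <- setdiff(1:3, a)
  idx <- integer(3)
  for (o in others) {
    if (through[o] < ext["lower", o] || through[o] > ext["upper", o])
      stop("profile line lies outside the grid")
    ax <- grid_axis(dose$grid, o)
    idx[o] <- which.min(abs(ax - through[o]))
  }
  positions <- grid_axis(dose$grid, a)
  sel <- list(idx[1], idx[2], idx[3])
  sel[[a]] <- seq_len(dose$grid$shape[a])
  values <- dose$dose[sel[[1]], sel[[2]], sel[[3]]]
  values <- as.numeric(values)
  if (normalize) {
    m <- max(values, na.rm = TRUE)
    if (!is.finite(m) || m <= 0) stop("cannot normalize a nonpositive profile")
    values <- 100 * values / m
  }
  structure(list(positions = positions, values = values,
                 axis = c("x", "y", "z")[a], through = through,
                 normalized = normalize),
            class = "profile_1d")
}

#' @export
print.profile_1d <- function(x, ...) {
  cat(sprintf("profile_1d along %s: %d samples, %.3g..%.3g mm%s\n",
              x$axis, length(x$values), min(x$positions), max(x$positions),
              if (isTRUE(x$normalized)) ", normalized to 100" else ""))
  invisible(x)
}

#' Full width at half maximum of a 1D profile
#'
#' The half level is half the observed peak value (leftmost sample on ties);
#' the two half-maximum crossings are located by linear interpolation
#' between the bracketing samples on each side of the peak.
#'
#' @param profile a [extract_profile()] result, or any list with numeric
#'   `positions` (strictly increasing) and `values`.
#' @return An object of class `fwhm_result`: `fwhm` (mm), `left_crossing`,
#'   `right_crossing`, `peak_value`, `peak_position`.
#' @examples
#' p <- list(positions = -5:5, values = pmax(0, 100 - 25 * abs(-5:5)))
#' fwhm(p)$fwhm  # 4: crossings at -2 and +2
#' @export
fwhm <- function(profile) {
  pos <- as.numeric(profile$positions)
  val <- as.numeric(profile$values)
  if (length(pos) != length(val) || length(pos) < 3L)
    stop("profile needs at least 3 samples")
  if (any(diff(pos) <= 0)) stop("positions must be strictly increasing")
  if (any(!is.finite(val))) stop("profile values must be finite")
  ipk <- which.max(val)  # which.max takes the leftmost tie
  peak <- val[ipk]
  half <- peak / 2
  cross <- function(side) {
    ii <- if (side == "left") seq(ipk, 1L) else seq(ipk, length(val))
    below <- which(val[ii] < half)
    if (!length(below))
      stop(sprintf("profile never falls below half-maximum on the %s side (truncated field of view)", side))
    j <- ii[below[1L]]          # first sample below half, outward from peak
    k <- j + if (side == "left") 1L else -1L  # bracketing sample above half
    pos[j] + (pos[k] - pos[j]) * (half - val[j]) / (val[k] - val[j])
  }
  left <- cross("left"); right <- cross("right")
  structure(list(fwhm = right - left, left_crossing = left,
                 right_crossing = right, peak_value = peak,
                 peak_position = pos[ipk]),
            class = "fwhm_result")
}

#' @export
print.fwhm_result <- function(x, ...) {
  cat(sprintf("fwhm_result: %.3f mm (%.3f .. %.3f mm), peak %.4g at %.3f mm\n",
              x$fwhm, x$left_crossing, x$right_crossing, x$peak_value,
              x$peak_position))
  invisible(x)
}

#' Percent deviation between a measured and a reference FWHM
#'
#' `100 * |reference - measured| / denominator`, with the denominator choice
#' made explicit because published comparison tables mix both conventions.
#' The value is rounded to one decimal, as such tables print it.
#'
#' @param reference reference (planning-system) width in mm, > 0.
#' @param measured measured width in mm, > 0.
#' @param denominator `"reference"` or `"measured"`.
#' @return Percent deviation, one decimal.
#' @examples
#' fwhm_deviation(11.3, 11.8, "measured")   # 4.2
#' fwhm_deviation(6.2, 5.6, "reference")    # 9.7
#' @export
fwhm_deviation <- function(reference, measured,
                           denominator = c("reference", "measured")) {
  denominator <- match.arg(denominator)
  if (any(!is.finite(reference)) || any(reference <= 0) ||
      any(!is.finite(measured)) || any(measured <= 0))
    stop("widths must be positive")
  den <- if (denominator == "reference") reference else measured
  round(100 * abs(reference - measured) / den, 1)
}

#' Reference FWHM comparison table for single-shot fields
#'
#' The published Z-axis FWHM comparison for 4 Gy@50% single shots: the
#' planning-system (Gammaplan) reference width per collimator next to the
#' widths measured with RTQA2 film, EBT3 film and modified nPAG gel.
#'
#' @return A data frame with columns `collimator_mm`, `gammaplan_mm`,
#'   `rtqa2_mm`, `ebt3_mm`, `gel_mm`.
#' @export
gk_reference_fwhm <- function() {
  data.frame(
    collimator_mm = c(4, 8, 16),
    gammaplan_mm = c(6.2, 11.3, 19.8),
    rtqa2_mm = c(5.6, 10.4, 17.9),
    ebt3_mm = c(5.9, 10.6, 18.2),
    gel_mm = c(6.4, 11.8, 19.5))
}

#' FWHM deviation table under both denominator conventions
#'
#' @param table a data frame like [gk_reference_fwhm()]: first column the
#'   collimator, second the reference width, remaining columns measured
#'   widths per method.
#' @return A long data frame with `collimator_mm`, `method`, `measured_mm`,
#'   `reference_mm`, `delta_mm`, `dev_pct_reference`, `dev_pct_measured`.
#' @export
fwhm_deviation_table <- function(table = gk_reference_fwhm()) {
  methods <- names(table)[-(1:2)]
  out <- do.call(rbind, lapply(methods, function(m) {
    data.frame(collimator_mm = table[[1]],
               method = sub("_mm$", "", m),
               measured_mm = table[[m]],
               reference_mm = table[[2]])
  }))
  out$delta_mm <- abs(out$reference_mm - out$measured_mm)
  out$dev_pct_reference <-
    fwhm_deviation(out$reference_mm, out$measured_mm, "reference")
  out$dev_pct_measured <-
    fwhm_deviation(out$reference_mm, out$measured_mm, "measured")
  out
}
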