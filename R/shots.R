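#' Gamma Knife shot specification
#'
#' Describes a single-shot irradiation: collimator aperture, stereotactic
#' center, prescription, and the analytic field-shape parameters used by the
#' synthetic generator. Collimator defaults follow the unit's published
#' characteristics: effective output factors 0.814 / 0.90 / 1.00 and
#' treatment-planning reference widths (Z-axis FWHM) 6.2 / 11.3 / 19.8 mm
#' for the 4 / 8 / 16 mm apertures.
#'
#' The prescription convention is "Gy at the prescription isodose": a shot
#' prescribed `prescription_dose` Gy at the 50% isodose delivers twice that
#' at the shot center.
#'
#' @param collimator collimator size in mm; one of 4, 8, 16.
#' @param center stereotactic mm coordinate of the shot center.
#' @param prescription_dose prescribed dose in Gy at `prescription_isodose`.
#' @param prescription_isodose prescription isodose as a fraction of the
#'   center (maximum) dose; default 0.5.
#' @param output_factor effective output factor relative to the 16 mm
#'   collimator; default per collimator.
#' @param dose_rate reference dose rate in Gy/min used for beam-on-time
#'   bookkeeping; default 2.52.
#' @param nominal_fwhm target full width at half maximum (mm) of the
#'   generated field; default is the planning-system reference per collimator.
#' @param penumbra_sigma Gaussian penumbra width (mm); default
#'   `nominal_fwhm / 6`.
#' @return An object of class `shot_spec`.
#' @examples
#' shot_spec(4, prescription_dose = 4)
#' @export
shot_spec <- function(collimator,
                      center = c(100, 100, 100),
                      prescription_dose = 4,
                      prescription_isodose = 0.5,
                      output_factor = NULL,
                      dose_rate = 2.52,
                      nominal_fwhm = NULL,
                      penumbra_sigma = NULL) {
  collimator <- as.numeric(collimator)
  if (!collimator %in% c(4, 8, 16))
    stop("'collimator' must be 4, 8 or 16 (mm)")
  defaults <- collimator_defaults(collimator)
  if (is.null(output_factor)) output_factor <- defaults$output_factor
  if (is.null(nominal_fwhm)) nominal_fwhm <- defaults$nominal_fwhm
  if (is.null(penumbra_sigma)) penumbra_sigma <- nominal_fwhm / 6
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("'center' must be three finite mm coordinates")
  if (!is.finite(prescription_isodose) || prescription_isodose <= 0 ||
      prescription_isodose > 1)
    stop("'prescription_isodose' must lie in (0, 1]")
  if (!is.finite(prescription_dose) || prescription_dose < 0)
    stop("'prescription_dose' must be a nonnegative dose in Gy")
  if (!is.finite(nominal_fwhm) || nominal_fwhm <= 0)
    stop("'nominal_fwhm' must be positive (mm)")
  if (!is.finite(output_factor) || output_factor <= 0 || output_factor > 1)
    stop("'output_factor' must lie in (0, 1]")
  if (!is.finite(penumbra_sigma) || penumbra_sigma <= 0)
    stop("'penumbra_sigma' must be positive (mm)")
  structure(list(collimator = collimator, center = center,
                 prescription_dose = prescription_dose,
                 prescription_isodose = prescription_isodose,
                 output_factor = output_factor, dose_rate = dose_rate,
                 nominal_fwhm = nominal_fwhm,
                 penumbra_sigma = penumbra_sigma),
            class = "shot_spec")
}

collimator_defaults <- function(collimator) {
  i <- match(collimator, c(4, 8, 16))
  list(output_factor = c(0.814, 0.90, 1.00)[i],
       nominal_fwhm = c(6.2, 11.3, 19.8)[i])
}

#' @export
print.shot_spec <- function(x, ...) {
  cat(sprintf(
    "shot_spec: %g mm collimator at (%s) mm, %g Gy@%g%%, FWHM %g mm\n",
    x$collimator, paste(format(x$center), collapse = ", "),
    x$prescription_dose, 100 * x$prescription_isodose, x$nominal_fwhm))
  invisible(x)
}

#' Beam-on time bookkeeping for a shot
#'
#' Delivered dose equals dose rate x beam-on time x effective output factor,
#' so the beam-on time for the center (maximum) dose is
#' `Dmax / (dose_rate * output_factor)`. The output factor enters only this
#' bookkeeping; it does not rescale the normalized field shape.
#'
#' @param shot a [shot_spec()].
#' @return Beam-on time in minutes.
#' @export
shot_beam_time <- function(shot) {
  stopifnot(inherits(shot, "shot_spec"))
  dmax <- shot$prescription_dose / shot$prescription_isodose
  dmax / (shot$dose_rate * shot$output_factor)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Radial flat-top-with-Gaussian-penumbra profile: a flat disc of half-width
# `a` convolved (in 1D) with a Gaussian of SD `sigma`; error-function edges.
flat_top_profile <- function(r, a, sigma) {
  s <- sigma * sqrt(2)
  0.5 * (erf((a - r) / s) + erf((a + r) / s))
}

# Analytic FWHM of flat_top_profile for plateau half-width a.
profile_fwhm_analytic <- function(a, sigma) {
  g0 <- flat_top_profile(0, a, sigma)
  half <- function(x) flat_top_profile(x, a, sigma) - g0 / 2
  upper <- a + 6 * sigma
  2 * stats::uniroot(half, c(0, upper), tol = 1e-12)$root
}

# Solve for the plateau half-width that gives an exact target FWHM. In the
# a -> 0 limit the profile tends to a Gaussian with FWHM 2*sqrt(2 log 2)*sigma,
# the smallest width this shape can produce.
plateau_halfwidth <- function(fwhm, sigma) {
  min_fwhm <- 2 * sqrt(2 * log(2)) * sigma
  if (fwhm <= min_fwhm * 1.0001)
    stop(sprintf(
      "penumbra_sigma %.3g mm too large for nominal_fwhm %.3g mm (minimum attainable FWHM %.3g mm)",
      sigma, fwhm, min_fwhm))
  f <- function(a) profile_fwhm_analytic(a, sigma) - fwhm
  stats::uniroot(f, c(1e-9, fwhm), tol = 1e-12)$root
}

#' Absorbed-dose grid
#'
#' Container for a scalar absorbed-dose field (Gy) on a regular stereotactic
#' grid, with a validity mask, a saturation flag (doses inverted beyond the
#' calibrated linear range), and a provenance tag.
#'
#' @param dose 3D numeric array of absorbed dose in Gy.
#' @param grid the [grid_spec()] the array lives on.
#' @param valid logical array of the same shape; `TRUE` where dose is defined.
#' @param saturated logical array; `TRUE` where a reconstructed dose exceeded
#'   the calibrated linear range.
#' @param provenance one of `"truth"`, `"gel-MRI"`, `"film"`, `"reference"`.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(dose, grid, valid = NULL, saturated = NULL,
                      provenance = "truth") {
  stopifnot(inherits(grid, "grid_spec"))
  dose <- as.array(dose)
  if (!identical(dim(dose), as.integer(grid$shape)))
    stop("dose array shape does not match the grid")
  if (is.null(valid)) valid <- array(TRUE, dim = dim(dose))
  if (is.null(saturated)) saturated <- array(FALSE, dim = dim(dose))
  provenance <- match.arg(provenance,
                          c("truth", "gel-MRI", "film", "reference"))
  if (any(dose[valid] < 0, na.rm = TRUE))
    stop("negative dose in valid voxels")
  if (any(saturated & !valid))
    stop("'saturated' must be a subset of 'valid'")
  structure(list(dose = dose, grid = grid, valid = valid,
                 saturated = saturated, provenance = provenance),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- x$dose[x$valid]
  cat(sprintf(
    "dose_grid [%s]: %s voxels, %d valid, dose %.3g..%.3g Gy\n",
    x$provenance, paste(x$grid$shape, collapse = " x "),
    sum(x$valid),
    if (length(d)) min(d) else NA, if (length(d)) max(d) else NA))
  invisible(x)
}

#' Generate a superposed single-shot dose field
#'
#' Each shot contributes a radially symmetric flat-top field with
#' error-function penumbra, scaled so the dose at the shot center equals
#' `prescription_dose / prescription_isodose` and the 1D FWHM of the field
#' through the center equals `nominal_fwhm` (the plateau half-width is solved
#' for the exact analytic FWHM). Multiple shots superpose additively.
#'
#' @param shots a [shot_spec()] or a list of them.
#' @param grid a [grid_spec()].
#' @return A [dose_grid()] with provenance `"truth"`.
#' @examples
#' g <- grid_spec(c(33, 33, 33), 0.5, origin = c(92, 92, 92))
#' d <- make_shot_dose_field(shot_spec(4), g)
#' max(d$dose)  # 8 Gy: 4 Gy prescribed at the 50% isodose
#' @export
make_shot_dose_field <- function(shots, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (inherits(shots, "shot_spec")) shots <- list(shots)
  if (!length(shots) || !all(vapply(shots, inherits, TRUE, "shot_spec")))
    stop("'shots' must be a shot_spec or a list of shot_spec")
  ext <- grid_extent(grid)
  dose <- array(0, dim = grid$shape)
  ax <- lapply(1:3, grid_axis, grid = grid)
  for (shot in shots) {
    if (any(shot$center < ext["lower", ] | shot$center > ext["upper", ]))
      stop("shot center lies outside the grid extent")
    if (shot$nominal_fwhm < 2 * max(grid$spacing))
      stop(sprintf(
        "nominal_fwhm %.3g mm unresolvable on spacing %s mm (need >= 2 voxels)",
        shot$nominal_fwhm, paste(format(grid$spacing), collapse = " x ")))
    a <- plateau_halfwidth(shot$nominal_fwhm, shot$penumbra_sigma)
    d2 <- lapply(1:3, function(i) (ax[[i]] - shot$center[i])^2)
    r <- sqrt(outer(outer(d2[[1]], d2[[2]], "+"), d2[[3]], "+"))
    dmax <- shot$prescription_dose / shot$prescription_isodose
    g0 <- flat_top_profile(0, a, shot$penumbra_sigma)
    dose <- dose + (dmax / g0) *
      flat_top_profile(r, a, shot$penumbra_sigma)
  }
  dose_grid(dose, grid, provenance = "truth")
}
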