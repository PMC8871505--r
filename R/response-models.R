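#' Gel dose-response model (normalized R2)
#'
#' Dose-to-R2 model for an nPAG polymer gel: radiation-induced polymerization
#' raises the transverse relaxation rate R2 = 1/T2. The model is linear at
#' low dose with a saturating-exponential roll-off,
#' \deqn{R2(D) = R2_0 + s_{abs} \, D_{sat} \, (1 - e^{-D/D_{sat}}),}
#' where the absolute slope is `sensitivity * r2_baseline` so that the
#' *normalized* response `(R2 - R2_0)/R2_0` has low-dose slope `sensitivity`
#' (Gy^-1), the quantity calibration curves report.
#'
#' @param r2_baseline zero-dose R2 in s^-1 (default 8, i.e. T2 = 125 ms).
#' @param sensitivity normalized-R2 slope per Gy; default 0.084.
#' @param saturation_dose Gy scale of the saturating regime; default 400,
#'   giving a nearly linear response (<2.5% droop) over the calibrated range.
#' @param s0 proton-density signal scale of the MRI forward model.
#' @param noise_sigma magnitude-noise SD in signal units.
#' @return An object of class `gel_response_model`.
#' @export
gel_response_model <- function(r2_baseline = 8, sensitivity = 0.084,
                               saturation_dose = 400, s0 = 1000,
                               noise_sigma = 0) {
  if (!is.finite(sensitivity) || sensitivity <= 0)
    stop("'sensitivity' must be positive")
  if (!is.finite(r2_baseline) || r2_baseline <= 0)
    stop("'r2_baseline' must be positive")
  if (!is.finite(saturation_dose) || saturation_dose <= 0)
    stop("'saturation_dose' must be positive")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("'noise_sigma' must be >= 0")
  if (!is.finite(s0) || s0 <= 0) stop("'s0' must be positive")
  structure(list(r2_baseline = r2_baseline, sensitivity = sensitivity,
                 saturation_dose = saturation_dose, s0 = s0,
                 noise_sigma = noise_sigma),
            class = "gel_response_model")
}

#' R2 as a function of dose under a gel model
#'
#' @param dose dose values in Gy (vector or array).
#' @param gel a [gel_response_model()].
#' @return R2 in s^-1, same shape as `dose`.
#' @export
gel_r2 <- function(dose, gel) {
  stopifnot(inherits(gel, "gel_response_model"))
  s_abs <- gel$sensitivity * gel$r2_baseline
  gel$r2_baseline +
    s_abs * gel$saturation_dose * (1 - exp(-dose / gel$saturation_dose))
}

#' Radiochromic film response model
#'
#' Net optical density versus dose follows a saturating exponential,
#' \deqn{OD(D) = OD_{sat} (1 - e^{-D/D_s}),}
#' whose low-dose slope is `od_saturation / dose_scale` (about 0.1 Gy^-1 for
#' RTQA2/EBT3 film read on a flatbed scanner). Pixel value follows
#' transmission: `PV = pv0 * 10^(-OD)`.
#'
#' @param od_saturation maximum net OD; default 0.5.
#' @param dose_scale Gy constant of the saturating exponential; default 5,
#'   so saturation is evident from about 4 Gy upward.
#' @param pv0 unexposed-film pixel value (16-bit range); default 40000.
#' @param noise_sigma additive pixel-value noise SD; default 0.
#' @return An object of class `film_response_model` with the derived
#'   `low_dose_slope = od_saturation / dose_scale` field.
#' @export
film_response_model <- function(od_saturation = 0.5, dose_scale = 5,
                                pv0 = 40000, noise_sigma = 0) {
  if (!is.finite(od_saturation) || od_saturation <= 0)
    stop("'od_saturation' must be positive")
  if (!is.finite(dose_scale) || dose_scale <= 0)
    stop("'dose_scale' must be positive")
  if (!is.finite(pv0) || pv0 <= 0) stop("'pv0' must be positive")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("'noise_sigma' must be >= 0")
  structure(list(od_saturation = od_saturation, dose_scale = dose_scale,
                 pv0 = pv0, noise_sigma = noise_sigma,
                 low_dose_slope = od_saturation / dose_scale),
            class = "film_response_model")
}

#' Net OD as a function of dose under a film model
#'
#' @param dose dose values in Gy.
#' @param film a [film_response_model()].
#' @return Net optical density, same shape as `dose`.
#' @export
film_od <- function(dose, film) {
  stopifnot(inherits(film, "film_response_model"))
  film$od_saturation * (1 - exp(-dose / film$dose_scale))
}
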