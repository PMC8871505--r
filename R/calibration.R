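#' Calibration points
#'
#' A table of (dose, response) calibration samples: gel cuvettes read out as
#' normalized R2 or MRI pixel intensity, or film pieces read out as net OD.
#' Doses follow the Gy-at-prescription-isodose bookkeeping convention of the
#' analysis at hand; the fit is agnostic to the axis as long as it is used
#' consistently.
#'
#' @param dose numeric vector of delivered doses (Gy), >= 0.
#' @param response numeric vector of responses (unitless).
#' @param response_sd per-point response SD (same units); 0 means unknown.
#' @return A data frame of class `calibration_points`.
#' @export
calibration_points <- function(dose, response, response_sd = 0) {
  dose <- as.numeric(dose); response <- as.numeric(response)
  if (length(dose) != length(response))
    stop("'dose' and 'response' lengths differ")
  response_sd <- rep_len(as.numeric(response_sd), length(dose))
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and >= 0")
  if (any(!is.finite(response)))
    stop("responses must be finite")
  if (any(!is.finite(response_sd)) || any(response_sd < 0))
    stop("'response_sd' must be finite and >= 0")
  structure(data.frame(dose = dose, response = response,
                       response_sd = response_sd),
            class = c("calibration_points", "data.frame"))
}

#' Net optical density of an exposed film
#'
#' Standard net-OD definition from transmission pixel values:
#' `OD = log10(pv_unexposed / pv_exposed)`; an unexposed film has OD 0.
#'
#' @param pv_unexposed pixel value of the unexposed film (> 0).
#' @param pv_exposed pixel value(s) of the exposed film (> 0); vectorized.
#' @return Net OD, same shape as `pv_exposed`.
#' @examples
#' film_net_od(40000, 4000)  # 1.0
#' @export
film_net_od <- function(pv_unexposed, pv_exposed) {
  if (any(!is.finite(pv_unexposed)) || any(pv_unexposed <= 0) ||
      any(!is.finite(pv_exposed)) || any(pv_exposed <= 0))
    stop("pixel values must be positive")
  log10(pv_unexposed / pv_exposed)
}

wls_fit <- function(dose, response, sd) {
  weighted <- all(sd > 0)
  w <- if (weighted) 1 / sd^2 else rep(1, length(dose))
  X <- cbind(1, dose)
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * response))
  fitted <- as.vector(X %*% beta)
  resid <- response - fitted
  rss <- sum(w * resid^2)
  n <- length(dose)
  cov_unscaled <- solve(XtWX)
  # Known per-point variances -> covariance is (X'WX)^-1 directly;
  # unweighted -> classical residual-variance rescale.
  covb <- if (weighted) cov_unscaled else cov_unscaled * rss / max(n - 2L, 1L)
  list(intercept = beta[1], slope = beta[2],
       intercept_se = sqrt(covb[1, 1]), slope_se = sqrt(covb[2, 2]),
       rss = rss, weights = w, fitted = fitted, n = n)
}

# Weighted lack-of-fit test of the linear model against a saturating
# exponential y = A (1 - exp(-d/s)) + b. Returns the p-value, or NA when the
# alternative cannot be fitted (too few points or no curvature to fit).
saturation_lack_of_fit <- function(dose, response, w) {
  n <- length(dose)
  if (n < 4L) return(NA_real_)
  lin <- stats::lm.wfit(cbind(1, dose), response, w)
  rss_lin <- sum(w * lin$residuals^2)
  scale2 <- sum(w * (response - stats::weighted.mean(response, w))^2)
  if (rss_lin <= 1e-18 * max(scale2, 1e-300)) return(1)  # exact line
  slope0 <- lin$coefficients[2]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ A * (1 - exp(-dose / s)) + b,
      start = list(A = slope0 * 4 * max(dose), s = 4 * max(dose),
                   b = lin$coefficients[1]),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  rss_sat <- sum(w * stats::residuals(fit)^2)
  if (rss_sat >= rss_lin) return(1)
  f <- ((rss_lin - rss_sat) / 1) / (rss_sat / (n - 3L))
  stats::pf(f, 1, n - 3L, lower.tail = FALSE)
}

#' Fit a dose-response calibration curve
#'
#' Weighted least squares (weights `1/sd^2`; unweighted when any sd is 0)
#' of response against dose over the linear range. With
#' `linear_max_dose = "auto"` the linear-range bound is chosen as the
#' largest candidate bound (default candidates 4, 8, 10, 20, 40 Gy) for
#' which a lack-of-fit F-test of the linear model against a
#' saturating-exponential alternative is not significant at `alpha`;
#' if every candidate shows lack of fit, the smallest usable candidate is
#' kept (the data saturate early and only the lowest doses are trusted).
#'
#' @param points a [calibration_points()] table (or coercible data frame).
#' @param linear_max_dose upper dose bound of the fitted linear range (Gy),
#'   or `"auto"`.
#' @param method response kind: `"normalized_r2"`, `"mri_intensity"` or
#'   `"film_od"`; recorded so reconstruction can check compatibility.
#' @param candidates candidate bounds for auto selection.
#' @param alpha significance level of the lack-of-fit test; default 0.05.
#' @return An object of class `calibration_curve` with fields `slope`
#'   (sensitivity, Gy^-1), `intercept`, `slope_se`, `linear_max_dose`,
#'   `method`, and the fitted points.
#' @examples
#' pts <- calibration_points(c(0, 2, 4), c(0, 0.2, 0.4))
#' fit_dose_response(pts, linear_max_dose = 4)$slope  # 0.1
#' @export
fit_dose_response <- function(points, linear_max_dose = "auto",
                              method = c("normalized_r2", "mri_intensity",
                                         "film_od"),
                              candidates = c(4, 8, 10, 20, 40),
                              alpha = 0.05) {
  method <- match.arg(method)
  if (!inherits(points, "calibration_points"))
    points <- calibration_points(points$dose, points$response,
                                 if (is.null(points$response_sd)) 0
                                 else points$response_sd)
  usable <- function(bound) which(points$dose <= bound + 1e-12)
  if (identical(linear_max_dose, "auto")) {
    candidates <- sort(candidates[candidates <= max(points$dose) + 1e-12],
                       decreasing = TRUE)
    if (!length(candidates)) candidates <- max(points$dose)
    chosen <- NULL
    smallest_ok <- NULL
    for (b in candidates) {
      idx <- usable(b)
      if (length(idx) < 3L || length(unique(points$dose[idx])) < 2L) next
      smallest_ok <- b
      sd <- points$response_sd[idx]
      w <- if (all(sd > 0)) 1 / sd^2 else rep(1, length(idx))
      p <- saturation_lack_of_fit(points$dose[idx], points$response[idx], w)
      if (is.na(p) || p >= alpha) { chosen <- b; break }
    }
    if (is.null(chosen)) {
      if (is.null(smallest_ok))
        stop("no candidate bound leaves >= 3 usable points")
      # every candidate shows lack of fit: keep the smallest usable bound
      chosen <- smallest_ok
    }
    linear_max_dose <- chosen
  }
  if (!is.numeric(linear_max_dose) || !is.finite(linear_max_dose))
    stop("'linear_max_dose' must be a dose in Gy or \"auto\"")
  if (linear_max_dose > max(points$dose) + 1e-12)
    linear_max_dose <- max(points$dose)
  idx <- usable(linear_max_dose)
  if (length(idx) < 3L)
    stop("fewer than 3 usable points within the linear range")
  if (length(unique(points$dose[idx])) < 2L)
    stop("calibration needs at least 2 distinct doses")
  fit <- wls_fit(points$dose[idx], points$response[idx],
                 points$response_sd[idx])
  structure(list(points = points, slope = fit$slope,
                 intercept = fit$intercept, slope_se = fit$slope_se,
                 intercept_se = fit$intercept_se,
                 linear_max_dose = linear_max_dose, method = method,
                 n_used = fit$n, rss = fit$rss),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration_curve [%s]: slope %.4g +/- %.2g Gy^-1, intercept %.3g, linear to %.3g Gy (%d points)\n",
    x$method, x$slope, x$slope_se, x$intercept, x$linear_max_dose, x$n_used))
  invisible(x)
}

#' Predicted response at given doses
#'
#' @param object a `calibration_curve`.
#' @param dose doses in Gy.
#' @param ... unused.
#' @return Predicted response values.
#' @export
predict.calibration_curve <- function(object, dose, ...) {
  object$intercept + object$slope * dose
}

#' Invert a calibration curve: response to dose
#'
#' `dose = (response - intercept) / slope`. Doses above the calibrated
#' linear range are returned but flagged `saturated`; negative inversions
#' are clipped to 0 and flagged `clipped`.
#'
#' @param curve a [fit_dose_response()] curve with nonzero slope.
#' @param response response value(s).
#' @return A list with numeric `dose` and logical `saturated`, `clipped`
#'   of the same shape.
#' @examples
#' cv <- fit_dose_response(calibration_points(c(0, 2, 4), c(0, 0.168, 0.336)),
#'                         linear_max_dose = 4)
#' invert_response(cv, 0.42)$dose  # 5 Gy
#' @export
invert_response <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("curve slope is zero; cannot invert")
  dose <- (response - curve$intercept) / curve$slope
  clipped <- !is.na(dose) & dose < 0
  dose[clipped] <- 0
  saturated <- !is.na(dose) & dose > curve$linear_max_dose
  list(dose = dose, saturated = saturated, clipped = clipped)
}

#' Simulate linear-truth calibration points
#'
#' Draws calibration responses from the straight line
#' `response = intercept + slope * dose` with independent Gaussian noise of
#' SD `response_sd` per point — the generating model under which slope
#' recovery and interval coverage of the weighted fit are well defined.
#'
#' @param dose dose axis (Gy).
#' @param slope true sensitivity (Gy^-1).
#' @param intercept true intercept; default 0.
#' @param response_sd noise SD, scalar or per point.
#' @param seed integer seed.
#' @return A [calibration_points()] table carrying the true `response_sd`.
#' @export
simulate_calibration_points <- function(dose, slope, intercept = 0,
                                        response_sd = 0.02, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  sd <- rep_len(response_sd, length(dose))
  resp <- intercept + slope * dose + stats::rnorm(length(dose), sd = sd)
  calibration_points(dose, resp, sd)
}

#' Simulate a gel calibration experiment end to end
#'
#' Forward-models one uniform cuvette per dose through the MRI signal model
#' ([mri_forward()]), maps each back to R2 ([compute_r2_map()]), normalizes
#' to the zero-dose cuvette, and summarizes each cuvette's mean normalized
#' response and its standard error as a calibration point. The zero-dose
#' cuvette itself anchors the reference rate, so its point is (0, 0) by
#' construction with the reference's SE attached.
#'
#' @param doses doses in Gy (should include 0; one is added if absent).
#' @param gel a [gel_response_model()]; its `noise_sigma` drives the Rician
#'   noise of every cuvette image.
#' @param te_pair echo times in ms; default `c(89, 145)`.
#' @param seed integer seed (one draw per cuvette, derived from it).
#' @param cuvette_shape voxel counts of the uniform cuvette ROI.
#' @return A [calibration_points()] table on the supplied dose axis.
#' @export
simulate_gel_calibration <- function(doses, gel, te_pair = c(89, 145),
                                     seed = 1L,
                                     cuvette_shape = c(7, 7, 3)) {
  stopifnot(inherits(gel, "gel_response_model"))
  doses <- sort(unique(c(0, as.numeric(doses))))
  g <- grid_spec(cuvette_shape, c(0.5, 0.5, 2.5))
  nvox <- prod(cuvette_shape)
  mean_r2 <- numeric(length(doses))
  se_r2 <- numeric(length(doses))
  for (i in seq_along(doses)) {
    d <- dose_grid(array(doses[i], cuvette_shape), g)
    pair <- mri_forward(d, gel, te_pair = te_pair,
                        seed = as.integer(seed) * 997L + i)
    m <- compute_r2_map(pair, signal_floor = 0)
    v <- m$r2[m$valid]
    mean_r2[i] <- mean(v)
    se_r2[i] <- stats::sd(v) / sqrt(length(v))
  }
  r2_ref <- mean_r2[doses == 0]
  resp <- (mean_r2 - r2_ref) / r2_ref
  resp_sd <- se_r2 / r2_ref
  if (gel$noise_sigma == 0) resp_sd <- rep(0, length(doses))
  calibration_points(doses, resp, resp_sd)
}

#' Simulate a film calibration experiment end to end
#'
#' Forward-models one uniformly exposed film patch per dose
#' ([film_forward()]), computes each patch's mean net OD against the
#' unexposed patch via [film_net_od()], and returns the calibration table.
#'
#' @param doses doses in Gy (0 added if absent).
#' @param film a [film_response_model()].
#' @param seed integer seed.
#' @param patch_px side length of the square film patch in pixels.
#' @return A [calibration_points()] table.
#' @export
simulate_film_calibration <- function(doses, film, seed = 1L,
                                      patch_px = 15L) {
  stopifnot(inherits(film, "film_response_model"))
  doses <- sort(unique(c(0, as.numeric(doses))))
  mean_pv <- numeric(length(doses))
  se_od <- numeric(length(doses))
  for (i in seq_along(doses)) {
    slice <- matrix(doses[i], patch_px, patch_px)
    scan <- film_forward(slice, film, seed = as.integer(seed) * 991L + i)
    pv <- scan$pixels[scan$pixels > 0]
    mean_pv[i] <- mean(pv)
    se_od[i] <- stats::sd(log10(pv)) / sqrt(length(pv))
  }
  pv0_hat <- mean_pv[doses == 0]
  od <- film_net_od(pv0_hat, mean_pv)
  if (film$noise_sigma == 0) se_od <- rep(0, length(doses))
  calibration_points(doses, od, se_od)
}
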