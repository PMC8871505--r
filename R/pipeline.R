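#' Default QA pipeline configuration
#'
#' The bundled defaults reproduce the study conditions: single 4 Gy@50%
#' shots per collimator (4, 8, 16 mm) centered at (100, 100, 100) mm, a
#' sagittal-style grid with 2.5 mm slices and 0.5 mm in-plane spacing,
#' TE 89/145 ms dual-echo readout, gel and film response models at the
#' reported sensitivities, and the 5% FWHM deviation limit.
#'
#' @return A nested configuration list (serializable to YAML).
#' @export
default_qa_config <- function() {
  list(
    seed = 1L,
    threshold_pct = 5,
    te_pair = c(89, 145),
    grid = list(shape = c(13L, 81L, 81L),
                spacing = c(2.5, 0.5, 0.5),
                center = c(100, 100, 100)),
    shots = list(
      list(collimator = 4, prescription_dose = 4),
      list(collimator = 8, prescription_dose = 4),
      list(collimator = 16, prescription_dose = 4)),
    gel = list(r2_baseline = 8, sensitivity = 0.084, saturation_dose = 400,
               s0 = 1000, noise_sigma = 0),
    film = list(od_saturation = 0.5, dose_scale = 5, pv0 = 40000,
                noise_sigma = 0),
    calibration = list(doses = c(0, 2, 4, 6, 8, 10, 12, 16),
                       linear_max_dose = 16),
    profile = list(axis = "z", denominator = "reference"),
    film_scan = list(dpi = 1200, region_mm = 24),
    similarity = list(levels = c(90, 80, 70, 60, 50, 30, 10), window = 11))
}

qa_config_schema <- list(
  seed = NULL, threshold_pct = NULL, te_pair = NULL,
  grid = c("shape", "spacing", "center"),
  shots = NA,  # list of shot entries, validated separately
  gel = c("r2_baseline", "sensitivity", "saturation_dose", "s0",
          "noise_sigma"),
  film = c("od_saturation", "dose_scale", "pv0", "noise_sigma"),
  calibration = c("doses", "linear_max_dose"),
  profile = c("axis", "denominator"),
  film_scan = c("dpi", "region_mm"),
  similarity = c("levels", "window"))

shot_keys <- c("collimator", "prescription_dose", "prescription_isodose",
               "output_factor", "dose_rate", "nominal_fwhm",
               "penumbra_sigma")

#' Validate a QA pipeline configuration
#'
#' Checks the nested key structure against the documented schema and errors
#' naming every unknown key. Missing sections fall back to
#' [default_qa_config()] values during the run.
#'
#' @param config a configuration list, or a path to a YAML file.
#' @return The validated configuration list, invisibly merged over the
#'   defaults.
#' @export
validate_qa_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  bad <- setdiff(names(config), names(qa_config_schema))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in names(config)) {
    allowed <- qa_config_schema[[sec]]
    if (is.null(allowed) || identical(allowed, NA)) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad))
      stop(sprintf("unknown config key(s) under '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  if (!is.null(config$shots)) {
    for (i in seq_along(config$shots)) {
      bad <- setdiff(names(config$shots[[i]]), shot_keys)
      if (length(bad))
        stop(sprintf("unknown config key(s) under 'shots[%d]': %s", i,
                     paste(bad, collapse = ", ")))
    }
  }
  defaults <- default_qa_config()
  merged <- utils::modifyList(defaults, config)
  # shots entries are unnamed, which modifyList skips: replace wholesale
  if (!is.null(config$shots)) merged$shots <- config$shots
  invisible(merged)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

pipeline_grid <- function(gcfg) {
  shape <- as.integer(gcfg$shape)
  spacing <- as.numeric(gcfg$spacing)
  origin <- as.numeric(gcfg$center) - (shape - 1L) / 2 * spacing
  grid_spec(shape, spacing, origin)
}

as_shot <- function(entry) do.call(shot_spec, entry)

#' Run the full gel/film dosimetry QA pipeline
#'
#' Executes, per configured shot: truth-field simulation, gel MRI forward
#' modelling, two-point R2 mapping, normalization against the unirradiated
#' region, gel calibration and dose-map reconstruction, film forward
#' modelling with net-OD calibration and reconstruction, FWHM profile
#' analysis against the planning reference widths (both deviation
#' conventions), and SSIM-based similarity of the reconstructed gel dose
#' plane against truth. All randomness derives from the configured seed, so
#' identical configurations yield identical reports.
#'
#' @param config a configuration list or YAML path; see
#'   [default_qa_config()] and [validate_qa_config()].
#' @return An object of class `qa_report`.
#' @export
run_qa_pipeline <- function(config = default_qa_config()) {
  cfg <- validate_qa_config(config)
  seed <- as.integer(cfg$seed)
  grid <- pipeline_grid(cfg$grid)
  gel <- do.call(gel_response_model, cfg$gel)
  film <- do.call(film_response_model, cfg$film)
  te_pair <- as.numeric(cfg$te_pair)
  denom <- match.arg(cfg$profile$denominator,
                     c("reference", "measured", "both"))
  axis <- cfg$profile$axis

  # calibrations are shared across shots
  gel_cal <- simulate_gel_calibration(cfg$calibration$doses, gel,
                                      te_pair = te_pair, seed = seed)
  gel_curve <- fit_dose_response(gel_cal, cfg$calibration$linear_max_dose,
                                 method = "normalized_r2")
  film_cal <- simulate_film_calibration(cfg$calibration$doses, film,
                                        seed = seed + 7L)
  film_curve <- fit_dose_response(film_cal, "auto", method = "film_od")

  fwhm_rows <- list()
  similarity <- list()
  for (i in seq_along(cfg$shots)) {
    shot <- as_shot(cfg$shots[[i]])
    truth <- make_shot_dose_field(shot, grid)

    # --- gel arm: MRI forward -> R2 -> normalize -> reconstruct
    pair <- mri_forward(truth, gel, te_pair = te_pair,
                        seed = seed * 100L + i)
    rmap <- compute_r2_map(pair)
    dmax <- max(truth$dose)
    ref_region <- truth$dose < 0.005 * dmax
    if (sum(ref_region) < 50)
      stop("grid too small: no unirradiated reference region for normalization")
    nmap <- normalize_response(rmap, ref_region)
    recon <- reconstruct_dose_map(nmap, gel_curve)
    prof_gel <- extract_profile(recon, axis = axis, through = shot$center,
                                normalize = TRUE)
    fw_gel <- fwhm(prof_gel)

    # --- film arm: planar truth at scanner resolution in the (y, z) plane
    px <- 25.4 / cfg$film_scan$dpi
    n <- 2L * floor(cfg$film_scan$region_mm / 2 / px) + 1L
    fgrid <- grid_spec(c(1L, n, n), c(grid$spacing[1], px, px),
                       origin = c(shot$center[1],
                                  shot$center[2] - (n - 1L) / 2 * px,
                                  shot$center[3] - (n - 1L) / 2 * px))
    ftruth <- make_shot_dose_field(shot, fgrid)
    scan <- film_forward(ftruth$dose[1, , ], film, pixel_spacing = px,
                         seed = seed * 100L + 50L + i)
    scan$od <- film_net_od(film$pv0, pmax(scan$pixels, 1))
    frecon <- reconstruct_dose_map(scan, film_curve)
    # film grid dims are (y, z, 1): the stereotactic Z is the 2nd axis
    prof_film <- extract_profile(frecon, axis = "y", normalize = TRUE)
    fw_film <- fwhm(prof_film)

    ref_mm <- shot$nominal_fwhm
    fwhm_rows[[length(fwhm_rows) + 1L]] <- data.frame(
      collimator_mm = shot$collimator, method = c("gel", "film"),
      reference_mm = ref_mm,
      measured_mm = c(fw_gel$fwhm, fw_film$fwhm),
      dev_pct_reference = fwhm_deviation(ref_mm,
                                         c(fw_gel$fwhm, fw_film$fwhm),
                                         "reference"),
      dev_pct_measured = fwhm_deviation(ref_mm,
                                        c(fw_gel$fwhm, fw_film$fwhm),
                                        "measured"))

    # --- similarity of the central reconstructed plane against truth
    ix <- (grid$shape[1] + 1L) %/% 2L
    tru_plane <- truth$dose[ix, , ]
    rec_plane <- recon$dose[ix, , ]
    rec_plane[!recon$valid[ix, , ]] <- 0
    tru_pct <- pmin(100 * tru_plane / robust_dmax(truth), 100)
    rec_pct <- pmin(100 * rec_plane / robust_dmax(recon), 100)
    shift <- align_translation(rec_pct, tru_pct)
    rec_al <- shift_image(rec_pct, shift, fill = 0)
    seg <- isodose_segment(tru_pct, cfg$similarity$levels)
    sim <- ssim_compare(tru_pct, rec_al, bands = seg,
                        window = cfg$similarity$window,
                        dynamic_range = 100, shift = shift)
    similarity[[as.character(shot$collimator)]] <- list(
      collimator_mm = shot$collimator,
      shift_px = shift,
      global_ssim = sim$global_ssim,
      band50_ssim = radiosurgical_band_ssim(sim, seg),
      per_band = sim$per_band)
  }
  fwhm_table <- do.call(rbind, fwhm_rows)

  dev_col <- if (denom == "measured") "dev_pct_measured" else "dev_pct_reference"
  pass <- vapply(split(fwhm_table, fwhm_table$method), function(d)
    max(d[[dev_col]]) <= cfg$threshold_pct, TRUE)

  structure(list(
    meta = list(config_hash = config_hash(cfg), seed = seed,
                package = "gkdosegel",
                version = as.character(utils::packageVersion("gkdosegel"))),
    calibration = list(
      gel = list(slope = gel_curve$slope, slope_se = gel_curve$slope_se,
                 intercept = gel_curve$intercept,
                 linear_max_dose = gel_curve$linear_max_dose),
      film = list(slope = film_curve$slope, slope_se = film_curve$slope_se,
                  intercept = film_curve$intercept,
                  linear_max_dose = film_curve$linear_max_dose)),
    fwhm = fwhm_table,
    similarity = similarity,
    threshold_pct = cfg$threshold_pct,
    deviation_convention = denom,
    pass = as.list(pass)),
    class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("qa_report (seed %d, config %s)\n", x$meta$seed,
              substr(x$meta$config_hash, 1, 8)))
  cat(sprintf("  gel calibration:  slope %.4g +/- %.2g Gy^-1 (linear to %g Gy)\n",
              x$calibration$gel$slope, x$calibration$gel$slope_se,
              x$calibration$gel$linear_max_dose))
  cat(sprintf("  film calibration: slope %.4g +/- %.2g Gy^-1 (linear to %g Gy)\n",
              x$calibration$film$slope, x$calibration$film$slope_se,
              x$calibration$film$linear_max_dose))
  cat("  FWHM (mm), deviation vs reference | vs measured:\n")
  f <- x$fwhm
  for (i in seq_len(nrow(f)))
    cat(sprintf("    %2g mm %-4s: ref %5.2f, meas %5.2f, %4.1f%% | %4.1f%%\n",
                f$collimator_mm[i], f$method[i], f$reference_mm[i],
                f$measured_mm[i], f$dev_pct_reference[i],
                f$dev_pct_measured[i]))
  for (s in x$similarity)
    cat(sprintf("  similarity %2g mm: global SSIM %.4f, >=50%% band %.4f\n",
                s$collimator_mm, s$global_ssim, s$band50_ssim))
  cat(sprintf("  pass at %g%% (%s denominator): %s\n", x$threshold_pct,
              x$deviation_convention,
              paste(sprintf("%s=%s", names(x$pass),
                            unlist(x$pass)), collapse = ", ")))
  invisible(x)
}
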