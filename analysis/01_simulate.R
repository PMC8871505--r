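#!/usr/bin/env Rscript
# Simulate the study's irradiation and readout conditions: single 4 Gy@50%
# shots per collimator on a sagittal-style grid, forward-modelled into a
# dual-echo MRI pair and a 1200 dpi film scan. Writes the ground-truth dose
# maps and example raw data under results/simulated/.

suppressMessages(library(gkdosegel))
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

grid <- grid_spec(c(13, 81, 81), c(2.5, 0.5, 0.5),
                  origin = c(100, 100, 100) - (c(13, 81, 81) - 1) / 2 * c(2.5, 0.5, 0.5))
gel <- gel_response_model(noise_sigma = 0)

# the exported truth maps are the central sagittal plane (full 3D fields
# are regenerated on demand by make_shot_dose_field)
plane <- grid_spec(c(1, 81, 81), c(2.5, 0.5, 0.5),
                   origin = c(100, 100 - 20, 100 - 20))
for (col in c(4, 8, 16)) {
  shot <- shot_spec(col, prescription_dose = 4)
  truth <- make_shot_dose_field(shot, grid)
  write_dose_csv(make_shot_dose_field(shot, plane),
                 file.path(out, sprintf("truth_plane_%02dmm.csv", col)))
  cat(sprintf("%2d mm collimator: Dmax %.2f Gy, beam-on %.2f min (output factor %.3f)\n",
              col, max(truth$dose), shot_beam_time(shot), shot$output_factor))
}

# example raw data for the 4 mm shot
shot <- shot_spec(4, prescription_dose = 4)
truth <- make_shot_dose_field(shot, grid)
pair <- mri_forward(truth, gel, seed = 1)
paths <- write_echo_series(pair, out, prefix = "gel_4mm_echo")
cat("echo volumes:", paste(basename(paths), collapse = ", "),
    sprintf("(TE %g / %g ms)\n", pair$te1, pair$te2))

px <- 25.4 / 1200
n <- 2L * floor(12 / px) + 1L
fgrid <- grid_spec(c(1L, n, n), c(2.5, px, px),
                   origin = c(100, 100 - (n - 1L) / 2 * px, 100 - (n - 1L) / 2 * px))
ftruth <- make_shot_dose_field(shot, fgrid)
scan <- film_forward(ftruth$dose[1, , ], film_response_model(), pixel_spacing = px)
write_film_scan(scan, file.path(out, "film_4mm.tif"))
cat(sprintf("film scan: %d x %d px at %.4f mm/px\n", n, n, px))
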