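#!/usr/bin/env Rscript
# Step 1: simulate the two-channel study volumes with ground truth.
#
# Two developmental-stage samples are emulated: an early stage with many
# small, well-innervated islets and a later stage with fewer, larger, less
# densely innervated islets — the contrast the downstream population
# comparisons are designed to detect. Channels are written as multi-page
# float TIFF stacks under scratch/ (regenerable bulk data); ground truth
# goes to results/ as CSV.

suppressMessages(library(voxislet))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

stages <- list(
  early = synth_config(volume_shape = c(256, 256, 60), n_islets = 60,
                       radius_distribution = list(name = "lognormal",
                                                  median_um = 30, shape = 0.3,
                                                  trunc_min_um = 10,
                                                  trunc_max_um = 150),
                       innervation_range = c(0.5, 0.9), seed = 101),
  late = synth_config(volume_shape = c(256, 256, 60), n_islets = 35,
                      radius_distribution = list(name = "lognormal",
                                                 median_um = 45, shape = 0.35,
                                                 trunc_min_um = 10,
                                                 trunc_max_um = 150),
                      innervation_range = c(0.2, 0.6), seed = 102))

truth_rows <- list()
for (stage in names(stages)) {
  out <- generate_islet_volume(stages[[stage]], sample_id = stage)
  write_volume(out$islet, file.path("scratch", paste0(stage, "_islet.tif")))
  write_volume(out$nerve, file.path("scratch", paste0(stage, "_nerve.tif")))
  n <- length(out$truth$islet_radii)
  truth_rows[[stage]] <- data.frame(
    stage = stage, islet = seq_len(n),
    cx_um = out$truth$islet_centers[, 1],
    cy_um = out$truth$islet_centers[, 2],
    cz_um = out$truth$islet_centers[, 3],
    radius_um = out$truth$islet_radii,
    innervation_fraction = out$truth$innervation_fractions)
  cat(sprintf("%s: %d islets, radii %.0f-%.0f um (median %.0f)\n",
              stage, n, min(out$truth$islet_radii),
              max(out$truth$islet_radii), median(out$truth$islet_radii)))
}
truth <- do.call(rbind, truth_rows)
write.csv(truth, "results/ground_truth.csv", row.names = FALSE)
cat("wrote scratch/<stage>_{islet,nerve}.tif and results/ground_truth.csv\n")
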