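#!/usr/bin/env Rscript
# Step 3: score peri-islet nerve signal and flag artifacts.
#
# Detection is re-run (the per-islet masks needed for scoring are not
# serialized with the population CSVs), the nerve channel is adaptively
# thresholded per section, every islet's neighborhood (convex hull offset
# outward by 2 px / 10 um) is scored, and records beyond three standard
# deviations of the pooled reference on either artifact criterion are
# flagged. The innervation contrast between the two simulated stages is then
# summarized.

suppressMessages(library(voxislet))
truth <- read.csv("results/ground_truth.csv")

scored <- list()
for (stage in unique(truth$stage)) {
  vi <- normalize_intensity(load_volume(
    file.path("scratch", paste0(stage, "_islet.tif")), c(5, 5, 5),
    "islet", stage))
  vn <- normalize_intensity(load_volume(
    file.path("scratch", paste0(stage, "_nerve.tif")), c(5, 5, 5),
    "nerve", stage))
  pop <- detect_islets(vi, stage_label = stage)
  pop <- score_population(pop, vn)
  pop <- exclude_artifacts(pop)   # pooled-self reference
  scored[[stage]] <- pop
  kept <- !pop$excluded
  cat(sprintf(
    "%s: %d scored, %d flagged; interaction score median %.2f (IQR %.2f-%.2f)\n",
    stage, sum(kept), sum(pop$excluded & nzchar(pop$exclusion_reason)),
    median(pop$interaction_score[kept]),
    quantile(pop$interaction_score[kept], 0.25),
    quantile(pop$interaction_score[kept], 0.75)))
  df <- as.data.frame(pop)
  df$stage <- stage
  write.csv(df, file.path("results", paste0("scored_population_", stage,
                                            ".csv")), row.names = FALSE)
}

a <- scored[[1]]$interaction_score[!scored[[1]]$excluded]
b <- scored[[2]]$interaction_score[!scored[[2]]$excluded]
tt <- stat_tests(a, b, "t")
ks <- stat_tests(a, b, "ks")
cat(sprintf(
  "stage contrast in innervation: t-test p = %.3g, KS p = %.3g\n",
  tt$p_value, ks$p_value))
cat("wrote results/scored_population_<stage>.csv\n")
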