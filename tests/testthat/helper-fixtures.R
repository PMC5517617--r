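# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except temporary files the tests write.

# a rasterized disk mask/image on a square grid
make_disk <- function(n, cx, cy, r, value = 1, base = 0) {
  img <- matrix(base, n, n)
  d2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cy)^2, `+`)
  img[d2 <= r^2] <- value
  img
}

# brute-force voxel-counting oracle: voxels whose centres lie inside a sphere
sphere_voxel_count <- function(dims, voxel_size, center_um, radius_um) {
  xs <- (seq_len(dims[1]) - 0.5) * voxel_size[1]
  ys <- (seq_len(dims[2]) - 0.5) * voxel_size[2]
  zs <- (seq_len(dims[3]) - 0.5) * voxel_size[3]
  d2 <- outer(outer((xs - center_um[1])^2, (ys - center_um[2])^2, `+`),
              (zs - center_um[3])^2, `+`)
  sum(d2 <= radius_um^2)
}

# small noiseless well-separated multi-sphere volume; xy-separated so MIP
# detection sees each sphere once
separated_spheres <- function(n_islets = 8, seed = 1, dims = c(220, 220, 24),
                              r_min = 15, r_max = 55, noise = 0) {
  generate_islet_volume(synth_config(
    volume_shape = dims, n_islets = n_islets,
    radius_distribution = list(name = "uniform", min_um = r_min,
                               max_um = r_max),
    min_center_separation = 30, n_filaments = 0,
    background_noise_sd = noise, z_contain = FALSE, xy_separation = TRUE,
    seed = seed))
}

# embed a volume's grid into a larger zero grid at a voxel offset; used for
# exact translation-equivariance checks away from image borders
embed_volume <- function(v, big_xy, offset_px) {
  d <- dim(v$intensities)
  arr <- array(0, c(big_xy, big_xy, d[3]))
  arr[offset_px[1] + seq_len(d[1]), offset_px[2] + seq_len(d[2]), ] <-
    v$intensities
  channel_volume(arr, v$voxel_size, v$channel_name, v$sample_id)
}

# population of synthetic records with Gaussian artifact-exclusion scores,
# for calibration checks of the 3-SD rule
gaussian_population <- function(n, seed, f_mean = 0.1, f_sd = 0.02,
                                e_mean = 3, e_sd = 0.5) {
  set.seed(seed)
  df <- voxislet:::islet_record_row(1L, "mc", 1L, c(1L, 1L))[rep(1, n), ]
  df$islet_id <- seq_len(n)
  df$area_px <- 100L
  df$nerve_positive_fraction <- rnorm(n, f_mean, f_sd)
  df$entropy_score <- rnorm(n, e_mean, e_sd)
  rownames(df) <- NULL
  islet_population(df, pixel_size = 5)
}

# match each detected record to the nearest true centre; returns data.frame
# of detected radius, true radius, and centre offset
match_to_truth <- function(pop, truth) {
  do.call(rbind, lapply(seq_len(nrow(pop)), function(i) {
    d <- sqrt((truth$islet_centers[, 1] - pop$cx_um[i])^2 +
              (truth$islet_centers[, 2] - pop$cy_um[i])^2)
    j <- which.min(d)
    data.frame(detected_um = pop$radius_um[i], true_um = truth$islet_radii[j],
               offset_um = d[j])
  }))
}
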