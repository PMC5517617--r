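#' Configuration for the synthetic two-channel pancreas volume generator
#'
#' The generator emulates the structure the volumetric pipeline is built for:
#' a field of roughly spherical, bright, insulin-positive islets over a dim
#' noisy background, with nerve/neural-crest signal concentrated in a thin
#' shell around each islet. Each islet carries its own innervation fraction
#' (the fraction of its peri-islet shell occupied by nerve signal), which is
#' the ground truth the innervation score is validated against.
#'
#' Defaults describe a desk-scale developing pancreas block: 1.28 x 1.28 x
#' 0.3 mm at isotropic 5 um voxels, 40 islets with lognormal radii (median
#' 40 um, log-sd 0.35, truncated to 10-150 um), 10 um innervation shells with
#' per-islet occupancy uniform on [0.2, 0.8], a few unassociated nerve
#' filaments, and Gaussian background noise with sd 2% of the channel
#' maximum, clipped at zero.
#'
#' @param volume_shape integer length-3, grid size in voxels `(nx, ny, nz)`.
#' @param voxel_size numeric length-3, voxel spacing in um.
#' @param n_islets number of islets to place (may be 0).
#' @param radius_distribution list: `name` is `"lognormal"` (parameters
#'   `median_um`, `shape` = sd of log radius) or `"uniform"` (parameters
#'   `min_um`, `max_um`); lognormal draws are truncated to
#'   `[trunc_min_um, trunc_max_um]`.
#' @param min_center_separation minimum gap in um between islet *surfaces*
#'   (centre distance must exceed the radius sum by this much).
#' @param shell_thickness_um thickness of the peri-islet nerve shell, um.
#' @param innervation_range range of the per-islet shell occupancy fraction,
#'   drawn uniformly.
#' @param n_filaments number of unassociated random-walk nerve filaments.
#' @param filament_steps length of each filament walk, in voxel-sized steps.
#' @param background_noise_sd Gaussian noise sd as a fraction of the channel
#'   intensity scale; 0 gives noiseless channels.
#' @param intensity_scale named numeric, peak intensity of the `islet` and
#'   `nerve` channels on the normalized `[0, 1]` scale.
#' @param z_contain if `TRUE` (default) spheres are placed fully inside the
#'   volume in z as well as x,y; if `FALSE` the z centre is uniform over the
#'   whole depth and spheres may be clipped by the axial faces, as islets at
#'   the faces of a real imaging block are.
#' @param xy_separation if `TRUE`, the minimum-separation constraint is also
#'   enforced on the x,y-projected centre distance, so islets stay separated
#'   in maximum-intensity projections ("well-separated" fixtures); default
#'   `FALSE` (3D separation only, as in a real organ where distinct islets
#'   can overlap in projection).
#' @param seed integer RNG seed; identical configurations with identical
#'   seeds reproduce volumes bit-for-bit.
#' @param max_attempts rejection-sampling budget per islet before placement
#'   fails with an error.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(volume_shape = c(256, 256, 60),
                         voxel_size = c(5, 5, 5),
                         n_islets = 40,
                         radius_distribution = list(name = "lognormal",
                                                    median_um = 40,
                                                    shape = 0.35,
                                                    trunc_min_um = 10,
                                                    trunc_max_um = 150),
                         min_center_separation = 25,
                         shell_thickness_um = 10,
                         innervation_range = c(0.2, 0.8),
                         n_filaments = 3,
                         filament_steps = 150,
                         background_noise_sd = 0.02,
                         intensity_scale = c(islet = 1, nerve = 1),
                         z_contain = TRUE,
                         xy_separation = FALSE,
                         seed = 1L,
                         max_attempts = 10000L) {
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            n_islets >= 0, shell_thickness_um >= 0,
            min_center_separation >= 0, background_noise_sd >= 0,
            length(innervation_range) == 2L,
            all(innervation_range >= 0), all(innervation_range <= 1))
  structure(list(volume_shape = volume_shape,
                 voxel_size = as.numeric(voxel_size),
                 n_islets = as.integer(n_islets),
                 radius_distribution = radius_distribution,
                 min_center_separation = min_center_separation,
                 shell_thickness_um = shell_thickness_um,
                 innervation_range = as.numeric(innervation_range),
                 n_filaments = as.integer(n_filaments),
                 filament_steps = as.integer(filament_steps),
                 background_noise_sd = background_noise_sd,
                 intensity_scale = intensity_scale,
                 z_contain = isTRUE(z_contain),
                 xy_separation = isTRUE(xy_separation),
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "synth_config")
}

draw_radii <- function(dist, n) {
  if (n == 0L) return(numeric(0))
  if (dist$name == "uniform") {
    stats::runif(n, dist$min_um, dist$max_um)
  } else if (dist$name == "lognormal") {
    lo <- dist$trunc_min_um %||% 0
    hi <- dist$trunc_max_um %||% Inf
    out <- numeric(0)
    for (i in 1:100) {
      r <- stats::rlnorm(2L * n, meanlog = log(dist$median_um),
                         sdlog = dist$shape)
      out <- c(out, r[r >= lo & r <= hi])
      if (length(out) >= n) return(out[seq_len(n)])
    }
    stop("could not draw ", n, " radii inside the truncation bounds")
  } else stop("unknown radius distribution: ", dist$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a two-channel synthetic pancreas volume with ground truth
#'
#' Places `config$n_islets` spheres by rejection sampling under the
#' minimum-separation constraint, rasterizes them into the islet channel in
#' physical (um) coordinates (so spheres stay round under anisotropic voxel
#' spacing), paints a partial spherical-cap shell of nerve signal around each
#' islet covering its drawn innervation fraction, optionally adds
#' unassociated random-walk filaments, and finally adds clipped Gaussian
#' background noise to both channels.
#'
#' @param config a [synth_config()].
#' @param sample_id sample identifier stored in the outputs.
#' @return A list with elements `islet` and `nerve` (both
#'   [channel_volume()]s) and `truth`, a `ground_truth` list with
#'   `islet_centers` (n x 3 matrix, um), `islet_radii` (um),
#'   `innervation_fractions`, `sample_id` and `seed`.
#' @examples
#' out <- generate_islet_volume(synth_config(volume_shape = c(64, 64, 16),
#'                                           n_islets = 2, seed = 7))
#' out$truth$islet_radii
#' @export
generate_islet_volume <- function(config, sample_id = "synthetic") {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  dims <- config$volume_shape
  vs <- config$voxel_size
  extent <- dims * vs
  radii <- sort(draw_radii(config$radius_distribution, config$n_islets),
                decreasing = TRUE)
  if (config$n_islets > 0 &&
      (2 * max(radii) > extent[1] || 2 * max(radii) > extent[2] ||
       (config$z_contain && 2 * max(radii) > extent[3])))
    stop("volume too small: a drawn radius of ", round(max(radii), 1),
         " um does not fit the ", paste(round(extent), collapse = " x "),
         " um volume")

  centers <- matrix(numeric(0), 0, 3)
  for (i in seq_len(config$n_islets)) {
    r <- radii[i]
    placed <- FALSE
    for (a in seq_len(config$max_attempts)) {
      cx <- stats::runif(1, r, extent[1] - r)
      cy <- stats::runif(1, r, extent[2] - r)
      cz <- if (config$z_contain) stats::runif(1, r, extent[3] - r)
            else stats::runif(1, 0, extent[3])
      if (nrow(centers) > 0) {
        gap <- radii[seq_len(i - 1)] + r + config$min_center_separation
        d <- sqrt(colSums((t(centers) - c(cx, cy, cz))^2))
        ok <- all(d >= gap)
        if (ok && config$xy_separation) {
          dxy <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
          ok <- all(dxy >= gap)
        }
      } else ok <- TRUE
      if (ok) { centers <- rbind(centers, c(cx, cy, cz)); placed <- TRUE; break }
    }
    if (!placed)
      stop("failed to place islet ", i, " of ", config$n_islets, " after ",
           config$max_attempts, " attempts under the minimum-separation ",
           "constraint (", config$min_center_separation, " um)")
  }
  fractions <- stats::runif(config$n_islets, config$innervation_range[1],
                            config$innervation_range[2])

  islet_int <- unname(config$intensity_scale["islet"])
  nerve_int <- unname(config$intensity_scale["nerve"])
  islet_arr <- array(0, dims)
  nerve_arr <- array(0, dims)
  xs <- voxel_centers(dims[1], vs[1])
  ys <- voxel_centers(dims[2], vs[2])
  zs <- voxel_centers(dims[3], vs[3])

  for (i in seq_len(config$n_islets)) {
    cc <- centers[i, ]
    r_out <- radii[i] + config$shell_thickness_um
    ix <- which(abs(xs - cc[1]) <= r_out)
    iy <- which(abs(ys - cc[2]) <= r_out)
    iz <- which(abs(zs - cc[3]) <= r_out)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xs[ix] - cc[1])^2
    dy2 <- (ys[iy] - cc[2])^2
    dz2 <- (zs[iz] - cc[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    inside <- d2 <= radii[i]^2
    sub <- islet_arr[ix, iy, iz, drop = FALSE]
    sub[inside] <- pmax(sub[inside], islet_int)
    islet_arr[ix, iy, iz] <- sub

    # partial shell: spherical cap around a random axis covering the islet's
    # innervation fraction of the shell voxels (exact voxel count)
    shell <- which(d2 > radii[i]^2 & d2 <= r_out^2)
    if (length(shell) > 0 && fractions[i] > 0) {
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      idx <- arrayInd(shell, dim(d2))
      vx <- xs[ix][idx[, 1]] - cc[1]
      vy <- ys[iy][idx[, 2]] - cc[2]
      vz <- zs[iz][idx[, 3]] - cc[3]
      proj <- (vx * axis[1] + vy * axis[2] + vz * axis[3]) / sqrt(d2[shell])
      n_take <- round(fractions[i] * length(shell))
      take <- shell[order(proj, decreasing = TRUE)[seq_len(n_take)]]
      subn <- nerve_arr[ix, iy, iz, drop = FALSE]
      subn[take] <- pmax(subn[take], nerve_int)
      nerve_arr[ix, iy, iz] <- subn
    }
  }

  # unassociated filaments: persistent random walks in um space
  for (f in seq_len(config$n_filaments)) {
    pos <- stats::runif(3) * extent
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    step <- min(vs)
    for (s in seq_len(config$filament_steps)) {
      idx <- pmin(pmax(ceiling(pos / vs), 1L), dims)
      nerve_arr[idx[1], idx[2], idx[3]] <- nerve_int
      dir <- dir + 0.4 * stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir * step
      pos <- pmin(pmax(pos, 0), extent - 1e-9)
    }
  }

  if (config$background_noise_sd > 0) {
    islet_arr <- islet_arr +
      stats::rnorm(length(islet_arr), 0, config$background_noise_sd * islet_int)
    nerve_arr <- nerve_arr +
      stats::rnorm(length(nerve_arr), 0, config$background_noise_sd * nerve_int)
    islet_arr <- pmin(pmax(islet_arr, 0), 1)
    nerve_arr <- pmin(pmax(nerve_arr, 0), 1)
  }

  truth <- structure(list(islet_centers = centers, islet_radii = radii,
                          innervation_fractions = fractions,
                          sample_id = sample_id, seed = config$seed),
                     class = "ground_truth")
  list(islet = channel_volume(islet_arr, vs, "islet", sample_id),
       nerve = channel_volume(nerve_arr, vs, "nerve", sample_id),
       truth = truth)
}

#' Generate a 2D stained-section test image
#'
#' Disks of uniform cell intensity on a uniform background with optional
#' additive Gaussian noise; the fixture for signal-over-background
#' quantification of stained sections.
#'
#' @param n_cells number of cells (disks); may be 0.
#' @param cell_intensity,background_intensity intensities on the normalized
#'   scale; `cell_intensity > background_intensity >= 0` is required.
#' @param cell_radius_px disk radius in pixels.
#' @param shape image size `(nx, ny)`.
#' @param noise_sd additive Gaussian noise sd (default 0).
#' @param seed integer RNG seed.
#' @return List with `image` (matrix) and `centers` (n x 2 matrix of pixel
#'   coordinates).
#' @export
generate_stain_image <- function(n_cells, cell_intensity, background_intensity,
                                 cell_radius_px, shape = c(256, 256),
                                 noise_sd = 0, seed = 1L) {
  stopifnot(cell_intensity > background_intensity, background_intensity >= 0,
            n_cells >= 0, cell_radius_px > 0)
  set.seed(seed)
  img <- matrix(background_intensity, shape[1], shape[2])
  centers <- matrix(numeric(0), 0, 2)
  r <- cell_radius_px
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (a in 1:10000) {
      cx <- stats::runif(1, r + 1, shape[1] - r)
      cy <- stats::runif(1, r + 1, shape[2] - r)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) > 2 * r + 4)) {
        centers <- rbind(centers, c(cx, cy)); placed <- TRUE; break
      }
    }
    if (!placed) stop("failed to place ", n_cells, " non-overlapping cells ",
                      "of radius ", r, " px in a ",
                      paste(shape, collapse = " x "), " image")
  }
  for (i in seq_len(nrow(centers))) {
    ix <- max(1, floor(centers[i, 1] - r)):min(shape[1], ceiling(centers[i, 1] + r))
    iy <- max(1, floor(centers[i, 2] - r)):min(shape[2], ceiling(centers[i, 2] + r))
    d2 <- outer((ix - centers[i, 1])^2, (iy - centers[i, 2])^2, `+`)
    sub <- img[ix, iy, drop = FALSE]
    sub[d2 <= r^2] <- cell_intensity
    img[ix, iy] <- sub
  }
  if (noise_sd > 0) img <- pmax(img + stats::rnorm(length(img), 0, noise_sd), 0)
  list(image = img, centers = centers)
}

#' Generate a first-order clearing time series
#'
#' Samples `y = y_max * (1 - exp(-k t))` at the given timepoints with
#' additive Gaussian noise, emulating UV-spectrophotometry absorbance
#' measurements of a clearing tissue block.
#'
#' @param y_max asymptotic absorbance change (> 0).
#' @param k clearing rate constant, per hour (> 0).
#' @param timepoints hours, non-empty and non-negative.
#' @param noise_sd Gaussian noise sd on y (default 0).
#' @param seed integer RNG seed.
#' @return `data.frame` with columns `t` (hours) and `y`.
#' @export
generate_clearing_series <- function(y_max, k, timepoints, noise_sd = 0,
                                     seed = 1L) {
  stopifnot(y_max > 0, k > 0, length(timepoints) > 0, all(timepoints >= 0))
  set.seed(seed)
  y <- y_max * (1 - exp(-k * timepoints))
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  data.frame(t = as.numeric(timepoints), y = y)
}
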