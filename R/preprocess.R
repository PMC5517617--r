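#' Downsample a volume in-plane by bilinear interpolation
#'
#' Large organ volumes are downsampled before analysis; scaling applies to
#' the x and y axes only by default (the z axis of confocal stacks is already
#' coarse relative to the in-plane sampling), and the voxel spacing is
#' rescaled so the physical extent of the volume is preserved.
#'
#' @param v a [channel_volume()].
#' @param factor scale factor in `(0, 1]`; 1 is the identity.
#' @param in_plane_only if `FALSE`, z is also rescaled by `factor`.
#' @return A [channel_volume()] with scaled grid and voxel size.
#' @export
downsample_volume <- function(v, factor, in_plane_only = TRUE) {
  stopifnot(is_channel_volume(v), factor > 0, factor <= 1)
  if (factor == 1) return(v)
  d <- dim(v$intensities)
  nx <- round(d[1] * factor); ny <- round(d[2] * factor)
  nz <- if (in_plane_only) d[3] else round(d[3] * factor)
  if (nx < 1 || ny < 1 || nz < 1)
    stop("downsampling factor ", factor, " gives a degenerate output shape")
  img <- EBImage::Image(v$intensities)
  out <- EBImage::imageData(EBImage::resize(img, w = nx, h = ny,
                                            filter = "bilinear"))
  if (length(dim(out)) == 2L) out <- array(out, c(nx, ny, 1L))
  if (!in_plane_only && nz != d[3]) {
    # resample z by the same bilinear rule, plane-profile-wise
    src <- out
    out <- array(0, c(nx, ny, nz))
    pos <- (seq_len(nz) - 0.5) * d[3] / nz + 0.5
    lo <- pmin(pmax(floor(pos), 1L), d[3])
    hi <- pmin(lo + 1L, d[3])
    w <- pos - lo
    for (k in seq_len(nz))
      out[, , k] <- src[, , lo[k]] * (1 - w[k]) + src[, , hi[k]] * w[k]
  }
  new_vs <- v$voxel_size * c(d[1] / nx, d[2] / ny, d[3] / nz)
  channel_volume(pmax(out, 0), new_vs, v$channel_name, v$sample_id)
}

#' Normalize channel volumes to a common intensity scale
#'
#' Each volume is linearly rescaled so that its upper reference quantile maps
#' to 1.0, compensating for staining and expression variability between
#' samples. The transform is monotone, so intensity orderings within a
#' volume are preserved; values above the reference quantile (hot pixels)
#' are clipped to 1.
#'
#' @param volumes a list of [channel_volume()]s (a single volume is accepted).
#' @param quantile reference quantile mapped to 1.0; the default 0.999 is
#'   robust to isolated hot pixels, `1.0` uses the maximum.
#' @return A list of rescaled [channel_volume()]s (or a single volume if a
#'   single volume was supplied). All-zero volumes are returned unchanged
#'   with a warning.
#' @export
normalize_intensity <- function(volumes, quantile = 0.999) {
  single <- is_channel_volume(volumes)
  if (single) volumes <- list(volumes)
  stopifnot(length(volumes) > 0, all(vapply(volumes, is_channel_volume,
                                            logical(1))),
            quantile > 0, quantile <= 1)
  out <- lapply(volumes, function(v) {
    ref <- stats::quantile(v$intensities, probs = quantile, names = FALSE,
                           type = 7)
    if (ref <= 0) {
      warning("volume '", v$sample_id, "/", v$channel_name,
              "' has no signal at the reference quantile; left unchanged")
      return(v)
    }
    channel_volume(pmin(v$intensities / ref, 1), v$voxel_size,
                   v$channel_name, v$sample_id)
  })
  if (single) out[[1]] else out
}

#' Mask a volume to a manually selected region of interest
#'
#' Voxels outside the mask (e.g. intestine or spleen adjacent to the
#' pancreas) are set to zero; voxels inside are unchanged.
#'
#' @param v a [channel_volume()].
#' @param mask logical (or 0/1) array of the same shape as the volume.
#' @return A [channel_volume()].
#' @export
apply_roi_mask <- function(v, mask) {
  stopifnot(is_channel_volume(v))
  if (!identical(dim(mask), dim(v$intensities)))
    stop("mask shape (", paste(dim(mask), collapse = "x"),
         ") does not match volume shape (",
         paste(dim(v$intensities), collapse = "x"), ")")
  out <- v$intensities
  out[!(mask > 0)] <- 0
  channel_volume(out, v$voxel_size, v$channel_name, v$sample_id)
}

#' Maximum-intensity-project a volume into thick sections
#'
#' Partitions the z extent into consecutive slabs of
#' `ceiling(thickness / z_spacing)` planes (the final slab may be shorter but
#' is kept and analyzed) and computes the per-pixel maximum over each slab.
#' The default 150 um thickness corresponds to three standard deviations
#' beyond the mean islet size, so a section almost always contains a whole
#' islet's equatorial profile.
#'
#' @param v a [channel_volume()].
#' @param thickness_um section thickness in um; must be at least the z voxel
#'   spacing.
#' @return An object of class `projection_stack`: list with `sections` (list
#'   of matrices), `z_ranges` (n x 2 matrix of 1-based inclusive plane
#'   indices), `section_thickness` (um), `pixel_size` (um, in-plane) and
#'   `z_spacing` (um).
#' @export
project_sections <- function(v, thickness_um = 150) {
  stopifnot(is_channel_volume(v))
  zsp <- v$voxel_size[3]
  if (thickness_um < zsp)
    stop("section thickness (", thickness_um,
         " um) is below the z voxel spacing (", zsp, " um)")
  nz <- dim(v$intensities)[3]
  planes_per <- as.integer(ceiling(thickness_um / zsp))
  starts <- seq(1L, nz, by = planes_per)
  ends <- pmin(starts + planes_per - 1L, nz)
  sections <- lapply(seq_along(starts), function(i)
    mip_slab(v$intensities, starts[i], ends[i]))
  structure(list(sections = sections,
                 z_ranges = cbind(start = starts, end = ends),
                 section_thickness = thickness_um,
                 pixel_size = v$voxel_size[1:2],
                 z_spacing = zsp),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf("<projection_stack> %d sections of %g um (%d planes each)\n",
              length(x$sections), x$section_thickness,
              x$z_ranges[1, 2] - x$z_ranges[1, 1] + 1L))
  invisible(x)
}

# per-pixel maximum over an inclusive plane range
mip_slab <- function(arr, z_start, z_end) {
  out <- arr[, , z_start]
  if (z_end > z_start)
    for (k in (z_start + 1L):z_end) out <- pmax(out, arr[, , k])
  out
}
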