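#' A single-channel 3D intensity volume
#'
#' The raw substrate of all volumetric analyses: a non-negative 3D intensity
#' grid for one imaging channel (e.g. the insulin channel or the neural-crest
#' channel) together with its physical voxel spacing in micrometres.
#'
#' Conventions: the grid is indexed `[x, y, z]`; voxel `i` (1-based) spans the
#' physical interval `[(i-1)*s, i*s)` along its axis, so the physical position
#' of a voxel centre is `(i - 0.5) * s` with `s` the spacing for that axis.
#'
#' @param intensities 3D numeric array of non-negative intensities, `[x, y, z]`.
#' @param voxel_size numeric length-3, voxel spacing in micrometres `(x, y, z)`.
#' @param channel_name character scalar naming the channel.
#' @param sample_id character scalar identifying the sample.
#' @return An object of class `channel_volume`: a list with elements
#'   `intensities`, `voxel_size`, `channel_name`, `sample_id`.
#' @examples
#' v <- channel_volume(array(runif(4 * 4 * 2), c(4, 4, 2)), c(5, 5, 5), "ins")
#' dim(v$intensities)
#' @export
channel_volume <- function(intensities, voxel_size, channel_name = "channel",
                           sample_id = "sample") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array")
  if (length(intensities) == 0L) stop("volume grid must be non-empty")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (micrometres)")
  structure(
    list(intensities = intensities, voxel_size = voxel_size,
         channel_name = as.character(channel_name)[1L],
         sample_id = as.character(sample_id)[1L]),
    class = "channel_volume")
}

#' @export
print.channel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<channel_volume> %s / %s: %d x %d x %d voxels at (%g, %g, %g) um\n",
    x$sample_id, x$channel_name, d[1], d[2], d[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

is_channel_volume <- function(x) inherits(x, "channel_volume")

#' Load a channel volume from a multi-page TIFF stack
#'
#' One page per z-plane; all pages must share the same in-plane dimensions.
#' Intensities are returned on the scale stored in the file (32-bit float
#' pages written by [write_volume()] round-trip at float precision).
#'
#' @param path path to a readable multi-page TIFF file.
#' @param voxel_size voxel spacing in micrometres `(x, y, z)`.
#' @param channel_name,sample_id metadata attached to the volume.
#' @return A [channel_volume()].
#' @seealso [write_volume()]
#' @export
load_volume <- function(path, voxel_size, channel_name = "channel",
                        sample_id = "sample") {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("failed to read TIFF '", path,
                                             "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF '", path, "' contains no pages")
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent page shapes in '", path, "' (page ",
         which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1], ")")
  # readTIFF returns matrices [row, col]; rows advance along y in the file.
  # Transpose so the first array index is x, matching the package convention.
  arr <- array(0, c(dims[2, 1], dims[1, 1], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first sample of multi-sample page
    arr[, , k] <- t(p)
  }
  channel_volume(arr, voxel_size, channel_name, sample_id)
}

#' Write a channel volume as a multi-page 32-bit float TIFF stack
#'
#' Intensities are stored as-is; values are expected on the package's
#' normalized scale in `[0, 1]` (values outside that range are not stored
#' reliably by the TIFF float path and raise an error).
#'
#' @param v a [channel_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_channel_volume(v))
  if (max(v$intensities) > 1 + 1e-9)
    stop("write_volume stores intensities on the normalized [0, 1] scale; ",
         "rescale (see normalize_intensity) before writing")
  d <- dim(v$intensities)
  pages <- lapply(seq_len(d[3]), function(k) t(v$intensities[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

# physical centre coordinates (um) of voxel indices along one axis
voxel_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing
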