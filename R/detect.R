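#' Detection pipeline configuration
#'
#' Tunable parameters of the islet segmentation and refinement stages. The
#' defaults follow the volumetric pipeline's description: 150 um MIP
#' sections, global Otsu thresholding per section with an erode-then-dilate
#' noise-removal pass, a 5-pixel minimum region size, per-islet refinement in
#' a bounding box padded by 20 px with a dilate-then-erode pass, 8-connected
#' in-plane labeling, and a 3x3 square structuring element.
#'
#' @param min_region_px minimum pixel count for a region to count as an islet.
#' @param margin_px padding (px) added around a candidate's bounding box for
#'   per-islet refinement.
#' @param section_thickness_um MIP section thickness in um.
#' @param section_morph_order,refine_morph_order order of the morphological
#'   noise-removal pass at the section and refinement stages.
#' @param brush_size width of the square structuring element.
#' @param connectivity 4 or 8 (in-plane), for connected-component labeling.
#' @param otsu_levels histogram bin count for the Otsu threshold.
#' @param dedup if `TRUE`, [detect_islets()] merges duplicate detections of
#'   the same islet in adjacent sections (centroids within one mean radius);
#'   off by default to match the per-section analysis.
#' @return list of class `detect_config`.
#' @export
detect_config <- function(min_region_px = 5L, margin_px = 20L,
                          section_thickness_um = 150,
                          section_morph_order = "erode_dilate",
                          refine_morph_order = "dilate_erode",
                          brush_size = 3L, connectivity = 8L,
                          otsu_levels = 256L, dedup = FALSE) {
  stopifnot(min_region_px >= 1, margin_px >= 0, connectivity %in% c(4L, 8L))
  structure(list(min_region_px = as.integer(min_region_px),
                 margin_px = as.integer(margin_px),
                 section_thickness_um = section_thickness_um,
                 section_morph_order = section_morph_order,
                 refine_morph_order = refine_morph_order,
                 brush_size = as.integer(brush_size),
                 connectivity = as.integer(connectivity),
                 otsu_levels = as.integer(otsu_levels),
                 dedup = isTRUE(dedup)),
            class = "detect_config")
}

#' Segment islet candidates on one MIP section
#'
#' Global Otsu threshold, one morphological noise-removal pass, connected
#' component labeling, and removal of regions below the minimum size.
#' Constant-intensity sections (no signal, degenerate Otsu histogram) give an
#' empty candidate list.
#'
#' @param section 2D intensity matrix.
#' @param min_region_px minimum region size in pixels (default 5).
#' @param config a [detect_config()]; its `min_region_px` is overridden by
#'   the explicit argument.
#' @return List of candidates, each a list with `area_px`, `centroid`
#'   (integer pixel coordinates), `bbox` (`x0, x1, y0, y1`) and `pixels`
#'   (n x 2 matrix of pixel coordinates).
#' @export
segment_section <- function(section, min_region_px = 5L,
                            config = detect_config()) {
  stopifnot(is.matrix(section), length(section) > 0)
  th <- otsu_threshold(section, config$otsu_levels)
  if (!is.finite(th)) {
    message("constant-intensity section: no candidates")
    return(list())
  }
  mask <- section > th
  if (!any(mask)) return(list())
  mask <- morph_cleanup(mask, config$section_morph_order, config$brush_size)
  lab <- label_regions(mask, config$connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  out <- list()
  for (i in seq_len(n)) {
    px <- which(lab == i, arr.ind = TRUE)
    if (nrow(px) < min_region_px) next
    out[[length(out) + 1L]] <- list(
      area_px = nrow(px),
      centroid = c(round(mean(px[, 1])), round(mean(px[, 2]))),
      bbox = c(x0 = min(px[, 1]), x1 = max(px[, 1]),
               y0 = min(px[, 2]), y1 = max(px[, 2])),
      pixels = px)
  }
  out
}

#' Circle-equivalent radius from a convex-hull area
#'
#' The islet radius estimate assumes the convex hull of the refined region
#' approximates a circle: `radius_um = sqrt(hull_area_px / pi) * pixel_size`.
#'
#' @param hull_area_px hull area in pixels (> 0).
#' @param pixel_size in-plane pixel size in um.
#' @return Radius in um.
#' @examples
#' estimate_radius(pi * 100, 5)  # 50 um
#' @export
estimate_radius <- function(hull_area_px, pixel_size) {
  if (any(hull_area_px <= 0)) stop("hull area must be positive")
  sqrt(hull_area_px / pi) * pixel_size
}

#' Refine one islet candidate at full local resolution
#'
#' Crops the candidate's bounding box padded by `margin_px` (clipped to the
#' volume bounds), max-projects the crop over the candidate's section
#' z-range, re-applies an Otsu threshold, runs the noise-removal pass, keeps
#' the connected component overlapping the original candidate, and measures
#' it: pixel area, convex-hull pixel area, circle-equivalent radius, and a
#' moments-based ellipse. A candidate that vanishes under the local
#' re-threshold yields a record flagged `excluded` with reason
#' `"refinement-empty"`.
#'
#' @param volume_context the source [channel_volume()].
#' @param candidate one candidate from [segment_section()].
#' @param z_range inclusive 1-based plane indices `(start, end)` of the
#'   candidate's section.
#' @param config a [detect_config()].
#' @param islet_id,section_index identifiers stored in the record.
#' @return List with `record` (one-row data.frame, see [detect_islets()])
#'   and `masks` (crop offset, refined region mask, hull mask).
#' @export
refine_islet <- function(volume_context, candidate, z_range,
                         config = detect_config(), islet_id = 1L,
                         section_index = 1L) {
  stopifnot(is_channel_volume(volume_context))
  d <- dim(volume_context$intensities)
  px_size <- volume_context$voxel_size[1]
  m <- config$margin_px
  x0 <- max(1L, candidate$bbox["x0"] - m); x1 <- min(d[1], candidate$bbox["x1"] + m)
  y0 <- max(1L, candidate$bbox["y0"] - m); y1 <- min(d[2], candidate$bbox["y1"] + m)
  crop <- mip_slab(volume_context$intensities, z_range[1], z_range[2])[x0:x1, y0:y1,
                                                                       drop = FALSE]
  empty_record <- function(reason) {
    rec <- islet_record_row(islet_id, volume_context$sample_id, section_index,
                            z_range)
    rec$excluded <- TRUE
    rec$exclusion_reason <- reason
    list(record = rec, masks = NULL)
  }
  th <- otsu_threshold(crop, config$otsu_levels)
  if (!is.finite(th)) return(empty_record("refinement-empty"))
  mask <- morph_cleanup(crop > th, config$refine_morph_order, config$brush_size)
  if (!any(mask)) return(empty_record("refinement-empty"))
  lab <- label_regions(mask, config$connectivity)
  # component overlapping the original candidate (largest overlap; fall back
  # to the component nearest the candidate centroid)
  cand_local <- cbind(candidate$pixels[, 1] - x0 + 1L,
                      candidate$pixels[, 2] - y0 + 1L)
  labs_at <- lab[cand_local]
  labs_at <- labs_at[labs_at > 0]
  if (length(labs_at) > 0) {
    keep <- as.integer(names(which.max(table(labs_at))))
  } else {
    cc <- c(candidate$centroid[1] - x0 + 1L, candidate$centroid[2] - y0 + 1L)
    px_all <- which(lab > 0, arr.ind = TRUE)
    nearest <- which.min((px_all[, 1] - cc[1])^2 + (px_all[, 2] - cc[2])^2)
    keep <- lab[px_all[nearest, , drop = FALSE]]
  }
  region <- lab == keep
  area_px <- sum(region)
  hull <- hull_mask(region)
  hull_area <- sum(hull)
  ell <- moments_ellipse(region)
  pts <- mask_coords(region)
  rec <- islet_record_row(islet_id, volume_context$sample_id, section_index,
                          z_range)
  rec$cx_um <- (x0 - 1L + mean(pts[, 1]) - 0.5) * px_size
  rec$cy_um <- (y0 - 1L + mean(pts[, 2]) - 0.5) * volume_context$voxel_size[2]
  rec$area_px <- area_px
  rec$hull_area_px <- hull_area
  rec$radius_um <- estimate_radius(hull_area, px_size)
  rec$ellipse_major_um <- ell$semi_major * px_size
  rec$ellipse_minor_um <- ell$semi_minor * px_size
  rec$ellipse_orientation_rad <- ell$orientation
  rec$excluded <- FALSE
  rec$exclusion_reason <- ""
  list(record = rec,
       masks = list(offset = c(x0, y0), region = region, hull = hull,
                    section_index = section_index))
}

islet_record_row <- function(islet_id, sample_id, section_index, z_range) {
  data.frame(islet_id = as.integer(islet_id), sample_id = sample_id,
             section_index = as.integer(section_index),
             cx_um = NA_real_, cy_um = NA_real_,
             z_start = as.integer(z_range[1]), z_end = as.integer(z_range[2]),
             area_px = NA_integer_, hull_area_px = NA_real_,
             radius_um = NA_real_, ellipse_major_um = NA_real_,
             ellipse_minor_um = NA_real_, ellipse_orientation_rad = NA_real_,
             neighborhood_px = NA_integer_,
             neighborhood_positive_px = NA_integer_,
             interaction_score = NA_real_,
             nerve_positive_fraction = NA_real_, entropy_score = NA_real_,
             excluded = FALSE, exclusion_reason = "",
             stringsAsFactors = FALSE)
}

#' Detect all islets in a channel volume
#'
#' End-to-end detection: the volume is maximum-intensity-projected into
#' sections ([project_sections()]), each section is segmented
#' ([segment_section()]), and every candidate is refined at full local
#' resolution ([refine_islet()]). Records excluded during refinement are
#' retained (flagged), never deleted.
#'
#' @param v a preprocessed (normalized, masked) [channel_volume()].
#' @param config a [detect_config()].
#' @param stage_label developmental-stage or group label stored with the
#'   population (e.g. `"P6"`, `"d101"`).
#' @param keep_masks if `TRUE` (default) per-islet region and hull masks are
#'   kept in the population's `masks` attribute for downstream innervation
#'   scoring.
#' @return An `islet_population`: a `data.frame` with one row per islet
#'   record (see [refine_islet()] for the morphometric columns;
#'   innervation columns are `NA` until scored) carrying attributes
#'   `pixel_size`, `sample_id`, `stage_label`, `config` and `masks`.
#' @export
detect_islets <- function(v, config = detect_config(), stage_label = "",
                          keep_masks = TRUE) {
  stopifnot(is_channel_volume(v), inherits(config, "detect_config"))
  stack <- project_sections(v, config$section_thickness_um)
  records <- list()
  masks <- list()
  next_id <- 1L
  for (s in seq_along(stack$sections)) {
    cands <- segment_section(stack$sections[[s]], config$min_region_px, config)
    for (cand in cands) {
      ref <- refine_islet(v, cand, stack$z_ranges[s, ], config,
                          islet_id = next_id, section_index = s)
      records[[next_id]] <- ref$record
      if (keep_masks) masks[[next_id]] <- ref$masks
      next_id <- next_id + 1L
    }
  }
  df <- if (length(records)) do.call(rbind, records)
        else islet_record_row(1L, v$sample_id, 1L, c(1L, 1L))[0, ]
  pop <- islet_population(df, pixel_size = v$voxel_size[1],
                          sample_id = v$sample_id, stage_label = stage_label,
                          config = config,
                          masks = if (keep_masks) masks else NULL)
  if (config$dedup) pop <- deduplicate_islets(pop)
  pop
}

#' Assemble an islet population object
#'
#' @param records data.frame of islet records.
#' @param pixel_size in-plane pixel size, um.
#' @param sample_id,stage_label sample metadata.
#' @param config the [detect_config()] used (or `NULL`).
#' @param masks optional per-record mask list.
#' @return `islet_population` (a classed `data.frame`).
#' @export
islet_population <- function(records, pixel_size, sample_id = "sample",
                             stage_label = "", config = NULL, masks = NULL) {
  if (nrow(records) > 0 && anyDuplicated(records$islet_id))
    stop("islet_ids must be unique within a population")
  structure(records,
            class = c("islet_population", "data.frame"),
            pixel_size = pixel_size, sample_id = sample_id,
            stage_label = stage_label, config = config, masks = masks)
}

#' @export
print.islet_population <- function(x, ...) {
  kept <- sum(!x$excluded)
  cat(sprintf("<islet_population> %s%s: %d records (%d retained)\n",
              attr(x, "sample_id"),
              if (nzchar(attr(x, "stage_label")))
                paste0(" [", attr(x, "stage_label"), "]") else "",
              nrow(x), kept))
  if (kept > 0)
    cat(sprintf("  radius_um: median %.1f, range [%.1f, %.1f]\n",
                stats::median(x$radius_um[!x$excluded]),
                min(x$radius_um[!x$excluded]), max(x$radius_um[!x$excluded])))
  invisible(x)
}

#' Merge duplicate detections of one islet across adjacent sections
#'
#' Sections are analyzed independently, so an islet spanning a section
#' boundary can be detected twice. This optional post-hoc correction flags
#' the smaller of two records in *adjacent* sections whose centroids lie
#' within one mean radius of each other (reason `"duplicate-adjacent-section"`).
#'
#' @param pop an `islet_population`.
#' @return The population with duplicate records flagged excluded.
#' @export
deduplicate_islets <- function(pop) {
  stopifnot(inherits(pop, "islet_population"))
  ok <- which(!pop$excluded)
  if (length(ok) < 2) return(pop)
  for (i in ok) for (j in ok) {
    if (i >= j || pop$excluded[i] || pop$excluded[j]) next
    if (abs(pop$section_index[i] - pop$section_index[j]) != 1L) next
    dist <- sqrt((pop$cx_um[i] - pop$cx_um[j])^2 +
                 (pop$cy_um[i] - pop$cy_um[j])^2)
    if (dist <= mean(c(pop$radius_um[i], pop$radius_um[j]))) {
      drop <- if (pop$radius_um[i] < pop$radius_um[j]) i else j
      pop$excluded[drop] <- TRUE
      pop$exclusion_reason[drop] <- "duplicate-adjacent-section"
    }
  }
  pop
}
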