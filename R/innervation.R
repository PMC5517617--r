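#' Innervation-scoring parameters
#'
#' @param offset_px outward offset of the islet neighborhood beyond the
#'   convex hull, in pixels (default 2, i.e. 10 um at 5 um/px).
#' @param nerve_erosion_px erosion applied to positive nerve regions before
#'   counting (default 1 px, i.e. 5 um).
#' @param adaptive_block_px odd block width of the local-mean adaptive
#'   threshold (default 51).
#' @param adaptive_offset constant subtracted from the local mean; a pixel is
#'   positive when it exceeds `local_mean + adaptive_offset`.
#' @param exclusion_sd_multiplier artifact-exclusion multiplier (default 3:
#'   records more than three standard deviations above the reference mean on
#'   either criterion are flagged).
#' @return list of class `neighborhood_params`.
#' @export
neighborhood_params <- function(offset_px = 2L, nerve_erosion_px = 1L,
                                adaptive_block_px = 51L, adaptive_offset = 0,
                                exclusion_sd_multiplier = 3) {
  stopifnot(offset_px >= 0, nerve_erosion_px >= 0,
            adaptive_block_px >= 3, adaptive_block_px %% 2 == 1)
  structure(list(offset_px = as.integer(offset_px),
                 nerve_erosion_px = as.integer(nerve_erosion_px),
                 adaptive_block_px = as.integer(adaptive_block_px),
                 adaptive_offset = adaptive_offset,
                 exclusion_sd_multiplier = exclusion_sd_multiplier),
            class = "neighborhood_params")
}

#' Islet neighborhood mask
#'
#' The neighborhood of an islet is its filled convex hull offset outward by
#' `offset_px`: every pixel whose Euclidean distance to the hull is at most
#' `offset_px` (clipped at the image bounds). It includes the islet interior,
#' so nerve signal both surrounding and within the islet is counted.
#'
#' @param hull_mask logical matrix, the filled convex hull.
#' @param offset_px outward offset in pixels (0 returns the hull itself).
#' @return Logical matrix of the same shape.
#' @export
neighborhood_mask <- function(hull_mask, offset_px = 2L) {
  stopifnot(is.matrix(hull_mask), any(hull_mask), offset_px >= 0)
  if (offset_px == 0L) return(hull_mask > 0)
  bg <- 1 - (hull_mask > 0)
  storage.mode(bg) <- "double"
  dist_to_hull <- EBImage::imageData(EBImage::distmap(bg, metric = "euclidean"))
  dist_to_hull <= offset_px
}

#' Positive nerve pixels of a section
#'
#' Local-arithmetic-mean adaptive threshold of the nerve channel followed by
#' erosion of each positive region, the pipeline's noise-reduction step
#' before counting nerve signal. Exposed separately so a section shared by
#' many islets is thresholded once.
#'
#' @param nerve_section 2D intensity matrix.
#' @param params a [neighborhood_params()].
#' @return Logical matrix of surviving positive pixels.
#' @export
nerve_positive_mask <- function(nerve_section, params = neighborhood_params()) {
  stopifnot(is.matrix(nerve_section))
  b <- params$adaptive_block_px
  kern <- matrix(1 / (b * b), b, b)
  local_mean <- EBImage::imageData(
    EBImage::filter2(EBImage::Image(nerve_section), kern,
                     boundary = "replicate"))
  # strictly above the local mean plus offset, so a flat (e.g. all-zero)
  # section has no positive pixels
  pos <- nerve_section > local_mean + params$adaptive_offset
  if (params$nerve_erosion_px > 0L)
    for (i in seq_len(params$nerve_erosion_px)) pos <- bin_erode(pos, 3L)
  pos
}

#' Score nerve signal in one islet's neighborhood
#'
#' Counts surviving positive nerve pixels inside the islet neighborhood and
#' forms the interaction (innervation) score: positive pixels divided by the
#' islet's own pixel area. Also records the neighborhood positive-pixel
#' fraction and the histogram entropy of the nerve crop over the
#' neighborhood, the two artifact-exclusion criteria.
#'
#' @param nerve_section 2D nerve-channel matrix aligned with the islet's
#'   section (same projection).
#' @param islet a `list(record, masks)` pair as returned by [refine_islet()].
#' @param params a [neighborhood_params()].
#' @param positives optional precomputed [nerve_positive_mask()] of the
#'   section.
#' @return The islet with its record's `neighborhood_px`,
#'   `neighborhood_positive_px`, `interaction_score`,
#'   `nerve_positive_fraction` and `entropy_score` filled in.
#' @export
score_innervation <- function(nerve_section, islet,
                              params = neighborhood_params(),
                              positives = NULL) {
  rec <- islet$record
  if (is.null(islet$masks) || isTRUE(rec$excluded)) return(islet)
  if (is.na(rec$area_px) || rec$area_px == 0L)
    stop("islet ", rec$islet_id, " has zero pixel area; cannot score")
  if (is.null(positives)) positives <- nerve_positive_mask(nerve_section, params)
  off <- islet$masks$offset
  hull <- islet$masks$hull
  # embed the crop-frame hull into the section frame
  full <- matrix(FALSE, nrow(nerve_section), ncol(nerve_section))
  full[off[1] + seq_len(nrow(hull)) - 1L,
       off[2] + seq_len(ncol(hull)) - 1L] <- hull
  nbhd <- neighborhood_mask(full, params$offset_px)
  pos_px <- sum(positives & nbhd)
  rec$neighborhood_px <- sum(nbhd)
  rec$neighborhood_positive_px <- pos_px
  rec$interaction_score <- pos_px / rec$area_px
  rec$nerve_positive_fraction <- pos_px / rec$neighborhood_px
  rec$entropy_score <- shannon_entropy(nerve_section[nbhd])
  islet$record <- rec
  islet
}

#' Score a whole detected population against the nerve channel
#'
#' Projects the nerve channel into the same sections the population was
#' detected on, thresholds each section once, and scores every record.
#'
#' @param pop an `islet_population` from [detect_islets()] with masks kept.
#' @param nerve_volume the nerve-channel [channel_volume()], same grid as the
#'   detection channel.
#' @param params a [neighborhood_params()].
#' @return The population with innervation columns filled.
#' @export
score_population <- function(pop, nerve_volume,
                             params = neighborhood_params()) {
  stopifnot(inherits(pop, "islet_population"), is_channel_volume(nerve_volume))
  masks <- attr(pop, "masks")
  if (is.null(masks)) stop("population carries no masks; re-run detect_islets",
                           " with keep_masks = TRUE")
  cfg <- attr(pop, "config")
  stack <- project_sections(nerve_volume, cfg$section_thickness_um)
  pos_cache <- list()
  for (i in seq_len(nrow(pop))) {
    if (pop$excluded[i] || is.null(masks[[i]])) next
    s <- pop$section_index[i]
    key <- as.character(s)
    if (is.null(pos_cache[[key]]))
      pos_cache[[key]] <- nerve_positive_mask(stack$sections[[s]], params)
    islet <- score_innervation(stack$sections[[s]],
                               list(record = pop[i, ], masks = masks[[i]]),
                               params, positives = pos_cache[[key]])
    for (col in c("neighborhood_px", "neighborhood_positive_px",
                  "interaction_score", "nerve_positive_fraction",
                  "entropy_score"))
      pop[[col]][i] <- islet$record[[col]]
  }
  pop
}

# population standard deviation (denominator n), so exclusion thresholds are
# invariant to duplicating the reference population
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Flag artifact records by the 3-standard-deviation rule
#'
#' Computes, from a reference population (a held-out test dataset, or the
#' population itself), the mean and standard deviation of the neighborhood
#' positive-pixel fraction and of the entropy score; any record strictly
#' exceeding `mean + sd_multiplier * sd` on either criterion is flagged
#' excluded (such regions correspond to non-neural features). Thresholds are
#' computed once from the reference and can be reused across samples by
#' passing the same reference.
#'
#' @param pop an `islet_population` with innervation columns filled.
#' @param reference another scored `islet_population`, or `"self"` (default)
#'   to use `pop` itself.
#' @param sd_multiplier exclusion multiplier (default 3).
#' @return `pop` with artifact records flagged (`excluded`,
#'   `exclusion_reason`), carrying the thresholds used in attribute
#'   `exclusion_thresholds`.
#' @export
exclude_artifacts <- function(pop, reference = "self", sd_multiplier = 3) {
  stopifnot(inherits(pop, "islet_population"))
  ref <- if (identical(reference, "self")) pop else reference
  scored <- !ref$excluded & !is.na(ref$nerve_positive_fraction) &
    !is.na(ref$entropy_score)
  if (sum(scored) < 2)
    stop("reference population must contain at least two scored records ",
         "(standard deviation undefined)")
  frac <- ref$nerve_positive_fraction[scored]
  ent <- ref$entropy_score[scored]
  thr <- c(fraction = mean(frac) + sd_multiplier * pop_sd(frac),
           entropy = mean(ent) + sd_multiplier * pop_sd(ent))
  for (i in seq_len(nrow(pop))) {
    if (pop$excluded[i] || is.na(pop$nerve_positive_fraction[i])) next
    reasons <- character(0)
    if (pop$nerve_positive_fraction[i] > thr["fraction"])
      reasons <- c(reasons, "artifact-positive-fraction")
    if (pop$entropy_score[i] > thr["entropy"])
      reasons <- c(reasons, "artifact-entropy")
    if (length(reasons)) {
      pop$excluded[i] <- TRUE
      pop$exclusion_reason[i] <- paste(reasons, collapse = "+")
    }
  }
  attr(pop, "exclusion_thresholds") <- thr
  pop
}
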