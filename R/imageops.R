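# Internal 2D image primitives shared by detection, innervation scoring and
# the staining assay. EBImage provides thresholding and morphology; the
# pieces the pipeline defines itself (8-connected labeling on top of
# bwlabel, hull-pixel area, moments ellipse, edge-count perimeter, histogram
# entropy) live here.

# Otsu threshold of a 2D intensity grid on a 256-bin histogram.
# Returns Inf for (near-)constant input so that `x > th` is empty, the
# degenerate-case contract for segmentation.
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) return(Inf)
  scaled <- (x - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1),
                      levels = as.integer(levels))
  rng[1] + th * diff(rng)
}

# Connected-component labeling of a logical matrix with configurable
# connectivity. bwlabel is 4-connected; for 8-connectivity, labels that touch
# diagonally are merged with a union-find pass over diagonal label pairs.
label_regions <- function(mask, connectivity = 8L) {
  storage.mode(mask) <- "double"
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  n <- max(lab)
  if (connectivity == 4L || n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor label pairs (both nonzero, different)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # down-right
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]   # up-right / down-left pairing
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Binary erosion / dilation with a square brush; `size` is the brush width.
bin_erode <- function(mask, size = 3L) {
  storage.mode(mask) <- "double"
  EBImage::imageData(EBImage::erode(mask, EBImage::makeBrush(size, "box"))) > 0
}

bin_dilate <- function(mask, size = 3L) {
  storage.mode(mask) <- "double"
  EBImage::imageData(EBImage::dilate(mask, EBImage::makeBrush(size, "box"))) > 0
}

# Noise-removal pass used by the section and refinement stages; the order of
# the two operations is configurable because the pipeline applies
# erode-then-dilate at the section stage and dilate-then-erode at the
# per-islet refinement stage.
morph_cleanup <- function(mask, order = c("erode_dilate", "dilate_erode"),
                          size = 3L) {
  order <- match.arg(order)
  if (order == "erode_dilate") bin_dilate(bin_erode(mask, size), size)
  else bin_erode(bin_dilate(mask, size), size)
}

# Pixel coordinates (x = row index, y = col index) of TRUE entries.
mask_coords <- function(mask) which(mask, arr.ind = TRUE)

# Convex-hull pixel mask of a region: all pixels of the grid whose centres
# lie inside (or on) the convex hull of the region's pixel centres. The hull
# area used for the circle-equivalent radius is the count of these pixels,
# the discrete convex area of the region.
hull_mask <- function(mask) {
  pts <- mask_coords(mask)
  if (nrow(pts) == 0L) return(mask & FALSE)
  if (nrow(pts) <= 2L) return(mask)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  if (length(h) <= 2L) return(mask)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  xr <- range(hx); yr <- range(hy)
  xs <- xr[1]:xr[2]; ys <- yr[1]:yr[2]
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  inside <- points_in_convex_polygon(gx, gy, hx, hy)
  out[cbind(gx[inside], gy[inside])] <- TRUE
  out
}

# Membership test against a convex polygon given in hull (clockwise or
# counter-clockwise) order; boundary points count as inside.
points_in_convex_polygon <- function(px, py, hx, hy) {
  n <- length(hx)
  ex <- hx[c(2:n, 1)] - hx; ey <- hy[c(2:n, 1)] - hy
  # orientation sign of the polygon
  s <- sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)
  sgn <- if (s >= 0) 1 else -1
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    cross <- ex[i] * (py - hy[i]) - ey[i] * (px - hx[i])
    inside <- inside & (sgn * cross >= -1e-9)
  }
  inside
}

# Polygon area by the shoelace formula (used as the test oracle counterpart
# and for hull areas of explicit polygons).
shoelace_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Moments-based ellipse of a pixel region: semi-axes and orientation from the
# second central moments, the standard regionprops construction in which a
# solid disk of radius r has both semi-axes equal to r.
moments_ellipse <- function(mask) {
  pts <- mask_coords(mask)
  n <- nrow(pts)
  if (n == 0L) return(list(semi_major = NA_real_, semi_minor = NA_real_,
                           orientation = NA_real_))
  cx <- mean(pts[, 1]); cy <- mean(pts[, 2])
  # + 1/12: variance of the unit pixel itself, so a single pixel has a
  # nonzero, pixel-sized ellipse
  mxx <- mean((pts[, 1] - cx)^2) + 1 / 12
  myy <- mean((pts[, 2] - cy)^2) + 1 / 12
  mxy <- mean((pts[, 1] - cx) * (pts[, 2] - cy))
  common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (mxx + myy + common) / 2
  l2 <- (mxx + myy - common) / 2
  list(semi_major = 2 * sqrt(l1), semi_minor = 2 * sqrt(max(l2, 0)),
       orientation = 0.5 * atan2(2 * mxy, mxx - myy))
}

# Perimeter estimate from the count of 4-adjacent object/background pixel
# edges, scaled by pi/4 (unbiased for digitized disks).
perimeter_estimate <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  edges <- sum(padded[2:(nr + 1L), 2:(nc + 1L)] & !padded[1:nr, 2:(nc + 1L)]) +
           sum(padded[2:(nr + 1L), 2:(nc + 1L)] & !padded[3:(nr + 2L), 2:(nc + 1L)]) +
           sum(padded[2:(nr + 1L), 2:(nc + 1L)] & !padded[2:(nr + 1L), 1:nc]) +
           sum(padded[2:(nr + 1L), 2:(nc + 1L)] & !padded[2:(nr + 1L), 3:(nc + 2L)])
  edges * pi / 4
}

#' Shannon entropy of an intensity histogram
#'
#' Entropy (in bits) of the `bins`-bin histogram of the supplied intensities,
#' binned over their own range. Used as the texture-based artifact score of
#' nerve-channel crops: genuine sparse neural signal has low-entropy crops,
#' while dense non-neural artifacts score high.
#'
#' @param x numeric vector or matrix of intensities.
#' @param bins number of histogram bins (default 256).
#' @return Entropy in bits; 0 for constant input.
#' @export
shannon_entropy <- function(x, bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(0)
  rng <- range(x)
  if (diff(rng) <= 0) return(0)
  cuts <- findInterval(x, seq(rng[1], rng[2], length.out = bins + 1L),
                       rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(cuts, nbins = bins)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}
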