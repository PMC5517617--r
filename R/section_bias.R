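#' Resampling power experiment on two islet populations
#'
#' Emulates a manual-measurement experiment of size `n`: per repetition, `n`
#' records are drawn with replacement from each population and the group
#' means of the chosen metric are compared by a two-tailed unpaired t-test.
#' Reports the fraction of repetitions reaching significance and the min-max
#' range of the per-repetition means, the two quantities that show how
#' statistical power and experiment-to-experiment variability scale with
#' sample size.
#'
#' @param popA,popB `islet_population`s (excluded records are ignored) or
#'   plain numeric vectors of the metric.
#' @param n islets sampled per experiment (>= 2).
#' @param metric record column to compare, `"radius_um"` or
#'   `"interaction_score"` (ignored for numeric input).
#' @param n_reps repetitions (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed integer RNG seed.
#' @param var_equal classic equal-variance t-test (default) or Welch.
#' @return `sampling_sim_result`: list with `proportion_significant`,
#'   `mean_range` (2 x 2 matrix, rows = populations, columns = min/max of
#'   per-repetition means), `p_values`, and the call parameters.
#' @export
sampling_experiment <- function(popA, popB, n, metric = "radius_um",
                                n_reps = 100L, alpha = 0.05, seed = 1L,
                                var_equal = TRUE) {
  xa <- metric_values(popA, metric)
  xb <- metric_values(popB, metric)
  stopifnot(length(xa) > 0, length(xb) > 0, n >= 2, n_reps >= 1)
  set.seed(seed)
  p <- ma <- mb <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sa <- sample(xa, n, replace = TRUE)
    sb <- sample(xb, n, replace = TRUE)
    ma[r] <- mean(sa); mb[r] <- mean(sb)
    p[r] <- stat_tests(sa, sb, "t", var_equal = var_equal)$p_value
  }
  structure(list(n_per_experiment = as.integer(n),
                 n_repetitions = as.integer(n_reps), alpha = alpha,
                 metric = metric,
                 proportion_significant = mean(p < alpha),
                 mean_range = rbind(popA = range(ma), popB = range(mb)),
                 p_values = p, seed = as.integer(seed)),
            class = "sampling_sim_result")
}

metric_values <- function(pop, metric) {
  if (is.numeric(pop)) return(pop[is.finite(pop)])
  if (!metric %in% names(pop))
    stop("metric '", metric, "' is not a column of the population")
  v <- pop[[metric]][!pop$excluded]
  v[is.finite(v)]
}

#' @export
print.sampling_sim_result <- function(x, ...) {
  cat(sprintf(
    "<sampling_sim_result> %s, n = %d x %d reps: %.0f%% significant at alpha = %g\n",
    x$metric, x$n_per_experiment, x$n_repetitions,
    100 * x$proportion_significant, x$alpha))
  invisible(x)
}

#' Extract virtual 2D sections from a volume
#'
#' Partitions the volume into consecutive MIP slabs of the stated thickness
#' (starting at z = 0) and samples them at the stated spacing. The count
#' scale factor is the ratio of total slabs to sampled slabs, used to scale
#' section-based islet counts to the whole volume (3 for the every-third
#' default).
#'
#' @param volume a [channel_volume()].
#' @param thickness_um slab thickness in um (at least the z spacing, at most
#'   the volume depth).
#' @param spacing `"every_third"`, `"all"`, or an integer vector of slab
#'   indices.
#' @param n_sections optional expected number of sections; an error is
#'   raised if the volume cannot supply them.
#' @return List with `sections` (MIP matrices), `z_ranges`,
#'   `count_scale_factor`, and `thickness_um`.
#' @export
virtual_sections <- function(volume, thickness_um, spacing = "every_third",
                             n_sections = NULL) {
  stopifnot(is_channel_volume(volume))
  zsp <- volume$voxel_size[3]
  nz <- dim(volume$intensities)[3]
  if (thickness_um < zsp) stop("section thickness below z spacing")
  if (thickness_um > nz * zsp)
    stop("volume too thin (", nz * zsp, " um) for ", thickness_um,
         " um sections")
  planes_per <- as.integer(ceiling(thickness_um / zsp))
  starts <- seq(1L, nz, by = planes_per)
  ends <- pmin(starts + planes_per - 1L, nz)
  n_total <- length(starts)
  idx <- if (identical(spacing, "every_third")) seq(1L, n_total, by = 3L)
         else if (identical(spacing, "all")) seq_len(n_total)
         else as.integer(spacing)
  if (any(idx < 1L | idx > n_total))
    stop("requested slab indices outside 1..", n_total)
  if (!is.null(n_sections) && length(idx) < n_sections)
    stop("volume supplies only ", length(idx), " sections, ", n_sections,
         " requested")
  if (!is.null(n_sections)) idx <- idx[seq_len(n_sections)]
  list(sections = lapply(idx, function(i)
         mip_slab(volume$intensities, starts[i], ends[i])),
       z_ranges = cbind(start = starts[idx], end = ends[idx]),
       count_scale_factor = n_total / length(idx),
       thickness_um = thickness_um)
}

#' Classify a 2D-section radius against its 3D radius
#'
#' The mutually exclusive, exhaustive classification of section-based
#' measurements: objects below the size threshold in both views are excluded
#' as sub-islet features; `false_negative` means the 2D radius would have
#' (incorrectly) excluded an islet whose 3D radius passes the threshold;
#' `false_positive` the reverse; surviving pairs are `within_tolerance` when
#' the 2D estimate is within the relative tolerance of the 3D value, and
#' otherwise an under- or over-estimate.
#'
#' @param r2d,r3d radii in um (vectorized).
#' @param size_threshold_um minimum radius to qualify as an islet
#'   (default 10, about one endocrine cell diameter).
#' @param tolerance relative agreement tolerance (default 0.10).
#' @return Character vector of classes: `excluded_small`, `false_negative`,
#'   `false_positive`, `within_tolerance`, `underestimate_gt_10pct`,
#'   `overestimate_gt_10pct`.
#' @examples
#' classify_radius_pair(8, 15)   # false_negative
#' classify_radius_pair(48, 50)  # within_tolerance
#' @export
classify_radius_pair <- function(r2d, r3d, size_threshold_um = 10,
                                 tolerance = 0.10) {
  stopifnot(length(r2d) == length(r3d))
  thr <- size_threshold_um
  out <- character(length(r2d))
  small2 <- r2d < thr
  small3 <- r3d < thr
  out[small2 & small3] <- "excluded_small"
  out[small2 & !small3] <- "false_negative"
  out[!small2 & small3] <- "false_positive"
  rest <- !small2 & !small3
  rel <- abs(r2d - r3d) / r3d
  out[rest & rel <= tolerance] <- "within_tolerance"
  out[rest & rel > tolerance & r2d < r3d] <- "underestimate_gt_10pct"
  out[rest & rel > tolerance & r2d >= r3d] <- "overestimate_gt_10pct"
  out
}

#' Underestimation factor of a section-based radius
#'
#' `(r3d - r2d) / r3d`: the relative shortfall of the 2D measurement.
#'
#' @param r2d,r3d radii in um; `r3d` must be positive.
#' @return Numeric vector.
#' @export
underestimation_factor <- function(r2d, r3d) {
  if (any(r3d <= 0)) stop("r3d must be positive")
  (r3d - r2d) / r3d
}

#' Compare islet radii measured on virtual 2D sections against 3D
#'
#' For each section thickness: islets are detected on the virtual sections
#' (giving the 2D radius), and each detection is re-analyzed in a 3D context
#' with the same x,y bounding box but a z-range extended by the mean islet
#' radius plus three standard deviations on each side (giving the 3D
#' radius). Pairs are classified by [classify_radius_pair()] and the mean
#' underestimation factor is summarized per thickness.
#'
#' @param volume islet-channel [channel_volume()] (normalized).
#' @param thicknesses section thicknesses to sweep, um.
#' @param size_threshold_um,tolerance classification parameters.
#' @param config a [detect_config()].
#' @param spacing section sampling passed to [virtual_sections()]
#'   (default `"all"`: the sweep uses every slab).
#' @return List of class `slice_comparison`: `records` (one row per
#'   islet-thickness pair), `summary` (per-thickness class fractions, mean
#'   underestimation factor, scaled counts), and `z_extension_um`.
#' @export
compare_2d_3d <- function(volume, thicknesses = c(5, 10, 20, 40, 80, 110),
                          size_threshold_um = 10, tolerance = 0.10,
                          config = detect_config(), spacing = "all") {
  stopifnot(is_channel_volume(volume))
  zsp <- volume$voxel_size[3]
  nz <- dim(volume$intensities)[3]
  if (max(thicknesses) > nz * zsp)
    stop("volume depth (", nz * zsp, " um) below the largest thickness")
  # 3D reference population for the z-extension rule
  cfg3d <- config
  cfg3d$section_thickness_um <- nz * zsp
  pop3d <- detect_islets(volume, cfg3d, keep_masks = FALSE)
  r3 <- pop3d$radius_um[!pop3d$excluded]
  if (length(r3) == 0) stop("no islets detected in the 3D reference pass")
  z_ext_um <- if (length(r3) >= 2) mean(r3) + 3 * stats::sd(r3)
              else mean(r3)  # sd undefined for a single islet
  ext_planes <- ceiling(z_ext_um / zsp)

  records <- list()
  for (Tum in thicknesses) {
    vs <- virtual_sections(volume, Tum, spacing)
    rid <- 0L
    for (s in seq_len(nrow(vs$z_ranges))) {
      zr <- vs$z_ranges[s, ]
      cands <- segment_section(vs$sections[[s]], config$min_region_px, config)
      for (cand in cands) {
        rid <- rid + 1L
        r2d <- refine_islet(volume, cand, zr, config, rid, s)$record
        if (r2d$excluded) next
        zr3 <- c(max(1L, zr[1] - ext_planes), min(nz, zr[2] + ext_planes))
        r3d <- refine_islet(volume, cand, zr3, config, rid, s)$record
        if (r3d$excluded) next
        records[[length(records) + 1L]] <- data.frame(
          thickness_um = Tum, section_index = s, islet_id = rid,
          r2d_um = r2d$radius_um, r3d_um = r3d$radius_um,
          stringsAsFactors = FALSE)
      }
    }
  }
  rec <- if (length(records)) do.call(rbind, records) else
    data.frame(thickness_um = numeric(0), section_index = integer(0),
               islet_id = integer(0), r2d_um = numeric(0),
               r3d_um = numeric(0))
  if (nrow(rec) > 0) {
    rec$classification <- classify_radius_pair(rec$r2d_um, rec$r3d_um,
                                               size_threshold_um, tolerance)
    rec$underestimation_factor <- underestimation_factor(rec$r2d_um,
                                                         rec$r3d_um)
  } else {
    rec$classification <- character(0)
    rec$underestimation_factor <- numeric(0)
  }
  classes <- c("excluded_small", "false_negative", "false_positive",
               "within_tolerance", "underestimate_gt_10pct",
               "overestimate_gt_10pct")
  summ <- do.call(rbind, lapply(thicknesses, function(Tum) {
    r <- rec[rec$thickness_um == Tum, ]
    if (nrow(r) == 0) message("no islets detected at ", Tum, " um thickness")
    compared <- r[r$classification != "excluded_small", ]
    frac <- if (nrow(r)) vapply(classes, function(cl)
      mean(r$classification == cl), numeric(1)) else
      stats::setNames(rep(NA_real_, length(classes)), classes)
    data.frame(thickness_um = Tum, n_pairs = nrow(r),
               t(frac),
               mean_underestimation = if (nrow(compared))
                 mean(compared$underestimation_factor) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(records = rec, summary = summ, z_extension_um = z_ext_um,
                 pop3d = pop3d),
            class = "slice_comparison")
}

#' Monte-Carlo sphere-sectioning bias
#'
#' Geometric simulation of the stereological bias: spheres of the given
#' radii are cut by MIP slabs of the given thickness at uniformly random
#' axial positions, and the apparent (largest in-slab cross-section) radius
#' is compared to the true radius. In the thin-slab limit the mean apparent
#' to true ratio tends to the chord average `E[sqrt(1 - u^2)] = pi / 4`.
#'
#' @param thicknesses_um slab thicknesses to evaluate (0 = infinitesimal
#'   plane).
#' @param radii_um sphere radii to draw from (recycled uniformly at random).
#' @param n_draws Monte-Carlo draws per thickness.
#' @param seed integer RNG seed.
#' @return `data.frame` with `thickness_um`, `mean_ratio` (mean r2d/r3d) and
#'   `mean_underestimation` (= 1 - mean_ratio).
#' @export
simulate_section_bias <- function(thicknesses_um, radii_um = 50,
                                  n_draws = 1e5, seed = 1L) {
  stopifnot(all(thicknesses_um >= 0), all(radii_um > 0), n_draws >= 1)
  set.seed(seed)
  out <- lapply(thicknesses_um, function(Tum) {
    R <- if (length(radii_um) == 1L) rep(radii_um, n_draws)
         else sample(radii_um, n_draws, replace = TRUE)
    s <- stats::runif(n_draws, -R - Tum, R)  # slab [s, s + T], centre at 0
    d <- pmax(pmax(s, -(s + Tum)), 0)        # distance of slab to centre
    ratio <- sqrt(pmax(1 - (d / R)^2, 0))
    data.frame(thickness_um = Tum, mean_ratio = mean(ratio),
               mean_underestimation = 1 - mean(ratio))
  })
  do.call(rbind, out)
}

#' Compare the largest-k islets between 2D sections and 3D
#'
#' Sorts each section's 2D radii descending (ties broken by islet id for
#' determinism), averages the largest `min(k, available)` per section, does
#' the same for the 3D population, and compares the pooled largest-k 2D
#' radii against the largest-k 3D radii with a two-sided Mann-Whitney test.
#'
#' @param radii_2d a list of numeric radius vectors (one per section), or a
#'   `slice_comparison` records data.frame with `section_index` and `r2d_um`.
#' @param pop3d an `islet_population` or numeric vector of 3D radii.
#' @param k number of largest islets per section (default 20).
#' @return List with `section_means`, `mean_2d` (grand mean of section
#'   means), `mean_3d`, `p_value` (Mann-Whitney) and `k`.
#' @export
top_k_comparison <- function(radii_2d, pop3d, k = 20L) {
  stopifnot(k >= 1)
  if (is.data.frame(radii_2d))
    radii_2d <- split(radii_2d$r2d_um, radii_2d$section_index)
  r3 <- if (is.numeric(pop3d)) pop3d else metric_values(pop3d, "radius_um")
  if (length(radii_2d) == 0 || all(lengths(radii_2d) == 0) || length(r3) == 0)
    stop("empty inputs")
  top <- function(x, k) {
    x <- x[order(-x, seq_along(x))]
    x[seq_len(min(k, length(x)))]
  }
  top2d <- lapply(radii_2d, top, k = k)
  top3d <- top(r3, k)
  mw <- stat_tests(unlist(top2d), top3d, "mannwhitney")
  list(section_means = vapply(top2d, mean, numeric(1)),
       mean_2d = mean(vapply(top2d, mean, numeric(1))),
       mean_3d = mean(top3d),
       p_value = mw$p_value, k = as.integer(k))
}

#' Two-sample tests used throughout the analyses
#'
#' A thin uniform wrapper over the two-tailed unpaired Student t-test
#' (equal-variance by default, Welch by flag), the two-sample
#' Kolmogorov-Smirnov test, and the two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test. Zero-variance t-test input with equal means returns
#' p = 1 by convention (p = 0 if the means differ).
#'
#' @param x,y numeric samples.
#' @param kind `"t"`, `"ks"` or `"mannwhitney"`.
#' @param var_equal for `kind = "t"`: classic Student (default) or Welch.
#' @return List with `kind`, `statistic`, `p_value`.
#' @export
stat_tests <- function(x, y, kind = c("t", "ks", "mannwhitney"),
                       var_equal = TRUE) {
  kind <- match.arg(kind)
  if (kind == "t") {
    stopifnot(length(x) >= 2, length(y) >= 2)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      message("zero-variance t-test input; p by convention")
      return(list(kind = kind, statistic = 0,
                  p_value = if (mean(x) == mean(y)) 1 else 0))
    }
    ht <- stats::t.test(x, y, var.equal = var_equal)
  } else if (kind == "ks") {
    stopifnot(length(x) >= 1, length(y) >= 1)
    ht <- suppressWarnings(stats::ks.test(x, y))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
  }
  list(kind = kind, statistic = unname(ht$statistic),
       p_value = unname(ht$p.value))
}
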