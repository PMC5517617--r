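#' A clearing time series
#'
#' Absorbance (optical transparency) measurements of a clearing tissue block
#' over time, the input to the first-order kinetics fit.
#'
#' @param timepoints hours, strictly increasing.
#' @param absorbance non-negative measurements, same length.
#' @param tissue,gel_formulation,temperature_C metadata (e.g. `"brain"`,
#'   `"A4B4P0"`, 37).
#' @return List of class `clearing_series`.
#' @export
clearing_series <- function(timepoints, absorbance, tissue = "",
                            gel_formulation = "", temperature_C = NA_real_) {
  stopifnot(length(timepoints) == length(absorbance),
            all(diff(timepoints) > 0), all(absorbance >= 0))
  structure(list(timepoints = as.numeric(timepoints),
                 absorbance = as.numeric(absorbance),
                 tissue = tissue, gel_formulation = gel_formulation,
                 temperature_C = temperature_C),
            class = "clearing_series")
}

#' Fit first-order clearing kinetics
#'
#' Least-squares fit of the one-phase exponential association
#' `y = y_max * (1 - exp(-k t))`, the model for tissue clearing as a
#' single-reactant transformation reaction with first-order rate kinetics.
#' Fitting is by Levenberg-Marquardt with multiple starting points
#' (`y_max0 = max(y)`, `k0 = 1 / median(t > 0)` and perturbations); the best
#' converged fit by residual sum of squares is returned.
#'
#' @param series a [clearing_series()], or a data.frame with columns `t`
#'   and `y` (e.g. from [generate_clearing_series()]).
#' @param n_starts number of multi-start perturbations (default 5).
#' @return List of class `kinetics_fit`: `y_max`, `k` (per hour),
#'   `residual_sse`, `normalized_rate` (NA until [normalize_rate()]),
#'   `degenerate` flag. An all-zero series returns a fit flagged
#'   `degenerate` with `k = NA`.
#' @export
fit_clearing_rate <- function(series, n_starts = 5L) {
  if (inherits(series, "clearing_series"))
    series <- data.frame(t = series$timepoints, y = series$absorbance)
  stopifnot(is.data.frame(series), all(c("t", "y") %in% names(series)))
  if (nrow(series) < 3) stop("need at least 3 timepoints to fit")
  t <- series$t; y <- series$y
  if (all(y == 0)) {
    warning("all-zero series: degenerate fit (no clearing signal)")
    return(structure(list(y_max = 0, k = NA_real_, residual_sse = 0,
                          normalized_rate = NA_real_, degenerate = TRUE),
                     class = "kinetics_fit"))
  }
  y0 <- max(y)
  k0 <- 1 / max(stats::median(t[t > 0]), .Machine$double.eps)
  mults <- c(1, 0.25, 0.5, 2, 4, 8, 0.1)[seq_len(max(2L, n_starts + 1L))]
  fits <- list()
  tried <- character(0)
  for (m in mults) {
    start <- list(y_max = y0, k = k0 * m)
    tried <- c(tried, sprintf("y_max=%.4g, k=%.4g", start$y_max, start$k))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ y_max * (1 - exp(-k * t)),
                        data = data.frame(t = t, y = y), start = start,
                        lower = c(y_max = 0, k = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0)
    stop("kinetics fit did not converge from any start; starts tried: ",
         paste(tried, collapse = "; "))
  sse <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(sse)]]
  cf <- stats::coef(best)
  structure(list(y_max = unname(cf["y_max"]), k = unname(cf["k"]),
                 residual_sse = min(sse), normalized_rate = NA_real_,
                 degenerate = FALSE),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) cat("<kinetics_fit> degenerate (no signal)\n")
  else cat(sprintf("<kinetics_fit> y_max = %.4g, k = %.4g /h (SSE %.3g)%s\n",
                   x$y_max, x$k, x$residual_sse,
                   if (is.na(x$normalized_rate)) ""
                   else sprintf(", normalized rate %.3g", x$normalized_rate)))
  invisible(x)
}

#' Normalize a clearing rate to a reference fit
#'
#' Rates are expressed relative to a reference condition (conventionally
#' brain tissue in the standard gel formulation cleared at 37 C):
#' `normalized_rate = k / k_reference`.
#'
#' @param fit,reference `kinetics_fit` objects; the reference must have a
#'   positive rate.
#' @return `fit` with `normalized_rate` set.
#' @export
normalize_rate <- function(fit, reference) {
  stopifnot(inherits(fit, "kinetics_fit"), inherits(reference, "kinetics_fit"))
  if (is.na(reference$k) || reference$k <= 0)
    stop("reference fit must have a positive rate constant")
  fit$normalized_rate <- fit$k / reference$k
  fit
}

#' Signal-over-background ratio of a stained section image
#'
#' Quantifies staining quality: Otsu threshold, one-pixel erosion,
#' morphological closing, connected-component region properties, exclusion
#' of non-cellular features by size and roundness
#' (`4 * pi * area / perimeter^2`, with the perimeter estimated from
#' object/background pixel edges), then the ratio of the mean intensity over
#' retained region pixels to the mean intensity over all pixels outside
#' retained regions.
#'
#' @param image 2D intensity matrix.
#' @param min_area_px,max_area_px region size bounds in pixels.
#' @param min_roundness minimum roundness to count as cellular (default 0.5).
#' @param closing_size brush width of the morphological closing.
#' @return List with `ratio` (NA with `undefined = TRUE` if no region
#'   survives the filters), `regions` (data.frame of area, roundness, mean
#'   intensity per retained region) and `n_regions`.
#' @export
staining_snr <- function(image, min_area_px = 20, max_area_px = 2000,
                         min_roundness = 0.5, closing_size = 3L) {
  stopifnot(is.matrix(image), length(image) > 0)
  th <- otsu_threshold(image)
  undefined <- function(msg) {
    warning("signal-over-background undefined: ", msg)
    list(ratio = NA_real_, undefined = TRUE,
         regions = data.frame(area_px = numeric(0), roundness = numeric(0),
                              mean_intensity = numeric(0)),
         n_regions = 0L)
  }
  if (!is.finite(th)) return(undefined("uniform image"))
  mask <- image > th
  mask <- bin_erode(mask, 3L)
  storage.mode(mask) <- "double"
  mask <- EBImage::imageData(
    EBImage::closing(mask, EBImage::makeBrush(closing_size, "box"))) > 0
  if (!any(mask)) return(undefined("no pixels above threshold after cleanup"))
  lab <- label_regions(mask, 8L)
  keep <- matrix(FALSE, nrow(image), ncol(image))
  regions <- list()
  for (i in seq_len(max(lab))) {
    reg <- lab == i
    a <- sum(reg)
    if (a < min_area_px || a > max_area_px) next
    peri <- perimeter_estimate(reg)
    roundness <- 4 * pi * a / peri^2
    if (roundness < min_roundness) next
    keep <- keep | reg
    regions[[length(regions) + 1L]] <-
      data.frame(area_px = a, roundness = roundness,
                 mean_intensity = mean(image[reg]))
  }
  if (length(regions) == 0L)
    return(undefined("no region passed the size/roundness filters"))
  signal <- mean(image[keep])
  background <- mean(image[!keep])
  list(ratio = signal / background, undefined = FALSE,
       regions = do.call(rbind, regions), n_regions = length(regions))
}

#' Normalize a protein-loss assay by starting sample weight
#'
#' @param bca_protein_ug protein measured in the clearing solution, ug.
#' @param sample_weight_mg starting sample weight, mg (> 0).
#' @return ug protein per mg starting tissue (vectorized).
#' @examples
#' protein_loss_normalize(50, 100)  # 0.5
#' @export
protein_loss_normalize <- function(bca_protein_ug, sample_weight_mg) {
  if (any(sample_weight_mg <= 0)) stop("sample weight must be positive")
  if (any(bca_protein_ug < 0)) stop("protein quantity cannot be negative")
  bca_protein_ug / sample_weight_mg
}
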