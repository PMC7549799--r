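#' Normalized 2-D Gaussian kernel
#'
#' Square kernel of side \code{2 * radius + 1} with values proportional to
#' \code{exp(-(x^2 + y^2) / (2 sigma^2))}, normalized to sum to 1.
#'
#' @param sigma Gaussian scale, > 0.
#' @param radius Kernel radius in pixels; default \code{ceiling(3 * sigma)}.
#' @return Numeric matrix of size \code{(2 radius + 1)^2}.
#' @export
#' @examples
#' k <- gaussianKernel(1.2)
#' abs(sum(k) - 1) < 1e-12
gaussianKernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("parameter error: sigma must be a single value > 0")
  radius <- as.integer(radius)
  if (radius < 1L) stop("parameter error: radius must be >= 1")
  ax <- (-radius):radius
  g1 <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

# Gaussian smoothing by separable clamped-index (replicate-pad) convolution.
# Exactly equals direct 2-D convolution with the normalized truncated kernel
# because clamping is applied per coordinate.
gaussianSmooth <- function(image, sigma, radius = ceiling(3 * sigma)) {
  ax <- (-radius):radius
  w <- exp(-ax^2 / (2 * sigma^2))
  w <- w / sum(w)
  out <- matrix(0, nrow(image), ncol(image))
  for (j in seq_along(ax)) out <- out + w[j] * shiftClamped(image, ax[j], 0L)
  out2 <- matrix(0, nrow(image), ncol(image))
  for (j in seq_along(ax)) out2 <- out2 + w[j] * shiftClamped(out, 0L, ax[j])
  out2
}

#' Build a Gaussian scale stack
#'
#' Smooths the input raster with Gaussians of scale
#' \code{sigma0 * k^(i-1)}, \code{i = 1..nLevels}, using replicate padding
#' at the borders. Each level is smoothed independently from the input so
#' the scales are exact, not cascaded approximations.
#'
#' @param image Grayscale raster, at least 8 x 8.
#' @param sigma0 Base scale (> 0); default 1.6.
#' @param k Scale multiplier (> 1) between levels; default \code{sqrt(2)}.
#' @param nLevels Number of levels (>= 2); default 5.
#' @return A \linkS4class{ScaleStack}.
#' @export
buildScaleStack <- function(image, sigma0 = 1.6, k = sqrt(2), nLevels = 5L) {
  validateGrayImage(image, minSide = 8L)
  nLevels <- as.integer(nLevels)
  if (nLevels < 2L) stop("parameter error: nLevels must be >= 2")
  if (k <= 1) stop("parameter error: k must be > 1")
  if (sigma0 <= 0) stop("parameter error: sigma0 must be > 0")
  sigmas <- sigma0 * k^(seq_len(nLevels) - 1L)
  levels <- lapply(sigmas, function(s) gaussianSmooth(image, s))
  new("ScaleStack", levels = levels, sigmas = sigmas, k = k, sigma0 = sigma0)
}

#' Difference-of-Gaussians stack
#'
#' Elementwise differences between adjacent smoothing levels,
#' \code{D[m] = L[m+1] - L[m]}; a stack of n levels yields n - 1
#' differences. Each difference is tagged with the lower scale of its pair.
#'
#' @param stack A \linkS4class{ScaleStack}.
#' @return A \linkS4class{DoGStack}.
#' @export
dogDifferences <- function(stack) {
  stopifnot(is(stack, "ScaleStack"))
  n <- length(stack@levels)
  diffs <- lapply(seq_len(n - 1L), function(m)
    stack@levels[[m + 1L]] - stack@levels[[m]])
  new("DoGStack", diffs = diffs, sigmas = stack@sigmas[seq_len(n - 1L)])
}

#' Standard-deviation threshold over a DoG stack
#'
#' Computes the elementwise mean raster over the difference levels and the
#' population standard deviation of the samples around it. Under
#' \code{"pooled"} (default) the deviations of all levels and pixels are
#' pooled into one scalar threshold,
#' \code{sqrt(sum_m sum_xy (D_m - Dbar)^2 / (n_levels * n_pixels))};
#' under \code{"per_level"} a separate threshold is computed for each
#' difference level (same centring raster, per-level averaging).
#'
#' @param dog A \linkS4class{DoGStack}.
#' @param pooling \code{"pooled"} or \code{"per_level"}.
#' @return A \linkS4class{ScaleThreshold}.
#' @export
dogThreshold <- function(dog, pooling = c("pooled", "per_level")) {
  stopifnot(is(dog, "DoGStack"))
  pooling <- match.arg(pooling)
  n <- length(dog@diffs)
  meanStack <- Reduce(`+`, dog@diffs) / n
  sq <- vapply(dog@diffs, function(d) sum((d - meanStack)^2), numeric(1))
  npix <- length(meanStack)
  value <- if (pooling == "pooled") sqrt(sum(sq) / (n * npix))
           else sqrt(sq / npix)
  new("ScaleThreshold", value = value, meanStack = meanStack,
      pooling = pooling)
}

#' Prune DoG samples against the standard-deviation threshold
#'
#' Builds the per-level retention mask that limits the downstream extremum
#' search. Three readings of the thresholding rule are provided:
#' \code{"signed_le"} (the literal inequality) retains a sample iff
#' \code{D_m(x,y) <= sigma_Dm}; \code{"abs_le"} iff
#' \code{|D_m(x,y)| <= sigma_Dm}; \code{"abs_gt"} iff
#' \code{|D_m(x,y)| > sigma_Dm}, i.e. it discards the sub-threshold samples
#' as redundant and keeps only the salient ones — the reading consistent
#' with using the threshold to prune redundancy while preserving the
#' significant contour points (note that \code{"abs_le"} retains only
#' samples whose magnitude is below the threshold, which a downstream
#' contrast test then rejects wholesale). With a per-level threshold each
#' level is compared against its own value.
#'
#' @param dog A \linkS4class{DoGStack}.
#' @param threshold A \linkS4class{ScaleThreshold} computed from \code{dog}.
#' @param mode Retention rule, \code{"signed_le"} (default),
#'   \code{"abs_le"} or \code{"abs_gt"}.
#' @return A \linkS4class{ReducedDoG}.
#' @export
reduceScales <- function(dog, threshold,
                         mode = c("signed_le", "abs_le", "abs_gt")) {
  stopifnot(is(dog, "DoGStack"), is(threshold, "ScaleThreshold"))
  mode <- match.arg(mode)
  if (!identical(dim(threshold@meanStack), dim(dog@diffs[[1]])))
    stop("consistency error: threshold was computed on a different shape")
  n <- length(dog@diffs)
  tvals <- if (length(threshold@value) == 1L) rep(threshold@value, n)
           else threshold@value
  if (length(tvals) != n)
    stop("consistency error: threshold level count does not match dog")
  retained <- lapply(seq_len(n), function(m) {
    switch(mode,
           signed_le = dog@diffs[[m]] <= tvals[m],
           abs_le = abs(dog@diffs[[m]]) <= tvals[m],
           abs_gt = abs(dog@diffs[[m]]) > tvals[m])
  })
  new("ReducedDoG", diffs = dog@diffs, sigmas = dog@sigmas,
      retained = retained, mode = mode, threshold = threshold@value)
}

# An unpruned view of a DoG stack: every sample retained. Used to measure
# what the sigma-threshold pruning buys relative to the full stack.
unreducedDoG <- function(dog) {
  stopifnot(is(dog, "DoGStack"))
  retained <- lapply(dog@diffs, function(d)
    matrix(TRUE, nrow(d), ncol(d)))
  new("ReducedDoG", diffs = dog@diffs, sigmas = dog@sigmas,
      retained = retained, mode = "none", threshold = Inf)
}
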