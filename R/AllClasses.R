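#' @import methods
NULL

#' The six dorsal fin shape classes
#'
#' Blue whale dorsal fins are catalogued by outline shape as seen from either
#' flank: falcate (sickle-shaped, concave trailing edge), hooked (curled tip)
#' or triangular (straight edges), each photographed from the right or left
#' side. The declared order is fixed and used for tie-breaking throughout.
#'
#' @return Character vector of the six class labels, in declared order.
#' @export
#' @examples
#' finClasses()
finClasses <- function() {
  c("right_falcate", "left_falcate", "right_hooked", "left_hooked",
    "right_triangular", "left_triangular")
}

## Rasters (the "GrayImage" unit) are plain numeric matrices with luminance
## in [0,1]; element [r, c] is pixel (x = c - 1, y = r - 1) in the 0-based,
## half-open coordinate convention used by every interface in this package.

#' Validate a grayscale raster
#'
#' Checks the package-wide raster contract: a finite numeric matrix with all
#' values in \code{[0,1]}. Feature-extraction entry points additionally
#' require at least 8 x 8 pixels (\code{minSide = 8}).
#'
#' @param image Numeric matrix, luminance in \code{[0,1]}.
#' @param minSide Minimum number of rows and columns required.
#' @return The image, invisibly; stops with an informative error otherwise.
#' @export
validateGrayImage <- function(image, minSide = 1L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (anyNA(image) || any(!is.finite(image)))
    stop("image contains non-finite values")
  if (any(image < 0) || any(image > 1))
    stop("image values must lie in [0,1]")
  if (nrow(image) < minSide || ncol(image) < minSide)
    stop(sprintf("image must be at least %d x %d pixels", minSide, minSide))
  invisible(image)
}

#' Gaussian scale stack
#'
#' Ordered Gaussian-smoothed versions L(x, y, sigma_i) of one source raster,
#' with sigma_i = sigma0 * k^(i-1) strictly increasing.
#'
#' @slot levels List of numeric matrices, all the same shape.
#' @slot sigmas Numeric vector of smoothing scales, strictly increasing.
#' @slot k Scale multiplier (> 1) between adjacent levels.
#' @slot sigma0 Base scale (> 0).
#' @export
setClass("ScaleStack",
  representation(levels = "list", sigmas = "numeric", k = "numeric",
                 sigma0 = "numeric"),
  validity = function(object) {
    if (length(object@levels) != length(object@sigmas))
      return("levels and sigmas differ in length")
    if (length(object@levels) < 2L)
      return("a scale stack needs at least 2 levels")
    if (object@sigma0 <= 0) return("sigma0 must be > 0")
    if (object@k <= 1) return("k must be > 1")
    dims <- vapply(object@levels, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      return("all levels must share one shape")
    rat <- object@sigmas[-1] / object@sigmas[-length(object@sigmas)]
    if (any(abs(rat - object@k) > 1e-9))
      return("sigmas must follow sigma[i+1] = k * sigma[i]")
    TRUE
  })

#' Difference-of-Gaussians stack
#'
#' Per-scale differences D_m = L(., k sigma_m) - L(., sigma_m) of a parent
#' \linkS4class{ScaleStack}; \code{sigmas} holds the lower scale of each pair.
#'
#' @slot diffs List of numeric matrices, one per difference level.
#' @slot sigmas Numeric vector, the lower sigma of each adjacent pair.
#' @export
setClass("DoGStack",
  representation(diffs = "list", sigmas = "numeric"),
  validity = function(object) {
    if (length(object@diffs) != length(object@sigmas))
      return("diffs and sigmas differ in length")
    if (length(object@diffs) < 1L) return("need at least one difference")
    dims <- vapply(object@diffs, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      return("all difference rasters must share one shape")
    TRUE
  })

#' Scale-pruning threshold
#'
#' The standard-deviation threshold sigma_Dm computed over a
#' \linkS4class{DoGStack}, together with the elementwise mean raster it is
#' centred on. Under pooled mode \code{value} has length 1; under per-level
#' pooling it has one entry per difference level.
#'
#' @slot value Nonnegative numeric threshold(s).
#' @slot meanStack Numeric matrix, the elementwise mean over levels.
#' @slot pooling Either \code{"pooled"} or \code{"per_level"}.
#' @export
setClass("ScaleThreshold",
  representation(value = "numeric", meanStack = "matrix",
                 pooling = "character"),
  validity = function(object) {
    if (any(object@value < 0)) return("threshold value must be >= 0")
    if (!object@pooling %in% c("pooled", "per_level"))
      return("pooling must be 'pooled' or 'per_level'")
    TRUE
  })

#' Reduced difference-of-Gaussians stack
#'
#' A \linkS4class{DoGStack} plus a per-level logical retention mask produced
#' by thresholding against sigma_Dm; non-retained samples are excluded from
#' the downstream extremum search.
#'
#' @slot diffs List of numeric matrices (as in \linkS4class{DoGStack}).
#' @slot sigmas Numeric vector of lower sigmas.
#' @slot retained List of logical matrices, one per level, same shapes.
#' @slot mode Retention rule used: \code{"signed_le"}, \code{"abs_le"} or
#'   \code{"none"}.
#' @slot threshold Numeric threshold value(s) the mask was built from.
#' @export
setClass("ReducedDoG",
  representation(diffs = "list", sigmas = "numeric", retained = "list",
                 mode = "character", threshold = "numeric"),
  validity = function(object) {
    if (length(object@retained) != length(object@diffs))
      return("one retention mask per difference level required")
    for (i in seq_along(object@diffs)) {
      if (!identical(dim(object@diffs[[i]]), dim(object@retained[[i]])))
        return("retention mask shape must match its difference raster")
      if (!is.logical(object@retained[[i]]))
        return("retention masks must be logical")
    }
    if (!object@mode %in% c("signed_le", "abs_le", "abs_gt", "none"))
      return("mode must be 'signed_le', 'abs_le', 'abs_gt' or 'none'")
    TRUE
  })

#' Gradient magnitude and orientation fields
#'
#' Central-difference gradient of one smoothed level: magnitude
#' M(x,y) >= 0 and orientation theta(x,y) in (-pi, pi], with theta = 0
#' wherever both differences vanish.
#'
#' @slot magnitude Numeric matrix, nonnegative.
#' @slot orientation Numeric matrix, angles in (-pi, pi].
#' @export
setClass("GradientField",
  representation(magnitude = "matrix", orientation = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@magnitude), dim(object@orientation)))
      return("magnitude and orientation shapes differ")
    if (any(object@magnitude < 0)) return("magnitude must be nonnegative")
    TRUE
  })

#' A set of keypoint descriptors for one image
#'
#' Fixed-length (128 = 4 x 4 spatial cells x 8 orientation bins)
#' gradient-histogram descriptors, one row per oriented keypoint, with the
#' keypoint geometry alongside.
#'
#' @slot values Numeric matrix, one 128-vector per row, each L2-normalized
#'   after clamping entries at 0.2 (the final renormalization can lift
#'   clamped entries marginally above the cap, as in classic SIFT).
#' @slot keypoints Data frame with columns \code{x}, \code{y} (0-based
#'   sub-pixel coordinates), \code{level}, \code{sigma}, \code{orientation}
#'   (radians in [0, 2 pi)), \code{contrast}.
#' @slot configHash Hash of the extraction configuration that produced them.
#' @export
setClass("DescriptorSet",
  representation(values = "matrix", keypoints = "data.frame",
                 configHash = "character"),
  validity = function(object) {
    if (nrow(object@values) != nrow(object@keypoints))
      return("one keypoint row per descriptor row required")
    if (nrow(object@values) > 0 && ncol(object@values) != 128L)
      return("descriptors must have length 128")
    need <- c("x", "y", "level", "sigma", "orientation", "contrast")
    if (!all(need %in% names(object@keypoints)))
      return(paste("keypoints must have columns:",
                   paste(need, collapse = ", ")))
    TRUE
  })

#' Trained nearest-centroid (median-estimation) class model
#'
#' One aggregated descriptor centroid per dorsal fin class, built by
#' elementwise mean (default) or median over all training descriptors of
#' that class.
#'
#' @slot centroids Numeric matrix, 6 rows (declared class order) x 128.
#' @slot aggregator \code{"mean"} or \code{"median"}.
#' @slot classes Character vector of class labels (row order of centroids).
#' @slot configHash Hash of the feature-extraction configuration the
#'   training descriptors were produced under.
#' @export
setClass("ClassModel",
  representation(centroids = "matrix", aggregator = "character",
                 classes = "character", configHash = "character"),
  validity = function(object) {
    if (nrow(object@centroids) != length(object@classes))
      return("one centroid per class required")
    if (!object@aggregator %in% c("mean", "median"))
      return("aggregator must be 'mean' or 'median'")
    if (anyNA(object@centroids)) return("centroids contain NA")
    TRUE
  })

#' Result of classifying one image
#'
#' @slot distances Named numeric vector of per-class aggregate squared
#'   Euclidean distances.
#' @slot predicted Predicted class label (argmin distance, ties resolved by
#'   declared class order).
#' @slot nSampleDescriptors Number of descriptors in the classified sample.
#' @export
setClass("MatchResult",
  representation(distances = "numeric", predicted = "character",
                 nSampleDescriptors = "integer"),
  validity = function(object) {
    if (is.null(names(object@distances)))
      return("distances must be named by class")
    if (any(object@distances < 0)) return("distances must be nonnegative")
    if (!object@predicted %in% names(object@distances))
      return("predicted label must be one of the distance names")
    TRUE
  })

#' Two-by-two confusion counts
#'
#' @slot tp,tn,fp,fn Nonnegative integer counts.
#' @slot denominator Total evaluated units (pixels or images);
#'   equals tp + tn + fp + fn.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", tn = "integer", fp = "integer",
                 fn = "integer", denominator = "integer"),
  validity = function(object) {
    v <- c(object@tp, object@tn, object@fp, object@fn)
    if (any(v < 0)) return("counts must be nonnegative")
    if (sum(v) != object@denominator)
      return("tp + tn + fp + fn must equal denominator")
    TRUE
  })

#' Receiver operating characteristic curve
#'
#' @slot points Data frame with columns \code{threshold}, \code{fpr},
#'   \code{tpr}; includes the (0,0) and (1,1) endpoints.
#' @slot auc Trapezoidal area under the curve, in [0,1].
#' @export
setClass("RocCurve",
  representation(points = "data.frame", auc = "numeric"),
  validity = function(object) {
    if (!all(c("fpr", "tpr") %in% names(object@points)))
      return("points must have fpr and tpr columns")
    if (object@auc < 0 || object@auc > 1) return("auc must lie in [0,1]")
    TRUE
  })

#' A rendered synthetic dorsal-fin sample
#'
#' @slot image Numeric matrix in [0,1], the rendered (possibly noisy) image.
#' @slot contourTruth Logical matrix marking the ground-truth outline pixels
#'   of the rendered fin (before noise).
#' @slot label One of the six class labels.
#' @slot spec The generating specification (list, see \code{\link{finSpec}}).
#' @export
setClass("FinSample",
  representation(image = "matrix", contourTruth = "matrix",
                 label = "character", spec = "list"),
  validity = function(object) {
    if (!identical(dim(object@image), dim(object@contourTruth)))
      return("image and contourTruth shapes differ")
    if (!object@label %in% finClasses())
      return("label must be one of finClasses()")
    TRUE
  })
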