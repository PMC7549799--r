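## Accessor generics: user code reads slots through these, never via @.

#' @rdname accessors
#' @export
setGeneric("stackLevels", function(x) standardGeneric("stackLevels"))
#' @rdname accessors
#' @export
setGeneric("stackSigmas", function(x) standardGeneric("stackSigmas"))
#' @rdname accessors
#' @export
setGeneric("dogDiffs", function(x) standardGeneric("dogDiffs"))
#' @rdname accessors
#' @export
setGeneric("retainedMask", function(x) standardGeneric("retainedMask"))
#' @rdname accessors
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))
#' @rdname accessors
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))
#' @rdname accessors
#' @export
setGeneric("keypoints", function(x) standardGeneric("keypoints"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("modelClasses", function(x) standardGeneric("modelClasses"))
#' @rdname accessors
#' @export
setGeneric("predictedClass", function(x) standardGeneric("predictedClass"))
#' @rdname accessors
#' @export
setGeneric("classDistances", function(x) standardGeneric("classDistances"))
#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("finImage", function(x) standardGeneric("finImage"))
#' @rdname accessors
#' @export
setGeneric("contourTruth", function(x) standardGeneric("contourTruth"))
#' @rdname accessors
#' @export
setGeneric("finLabel", function(x) standardGeneric("finLabel"))
#' @rdname accessors
#' @export
setGeneric("configHash", function(x) standardGeneric("configHash"))

#' Accessors for finprint S4 objects
#'
#' Read-only accessors for the slots of the package's S4 containers.
#'
#' @param x An S4 object from this package.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("stackLevels", "ScaleStack", function(x) x@levels)
#' @rdname accessors
#' @export
setMethod("stackSigmas", "ScaleStack", function(x) x@sigmas)
#' @rdname accessors
#' @export
setMethod("stackSigmas", "DoGStack", function(x) x@sigmas)
#' @rdname accessors
#' @export
setMethod("stackSigmas", "ReducedDoG", function(x) x@sigmas)
#' @rdname accessors
#' @export
setMethod("dogDiffs", "DoGStack", function(x) x@diffs)
#' @rdname accessors
#' @export
setMethod("dogDiffs", "ReducedDoG", function(x) x@diffs)
#' @rdname accessors
#' @export
setMethod("retainedMask", "ReducedDoG", function(x) x@retained)
#' @rdname accessors
#' @export
setMethod("thresholdValue", "ScaleThreshold", function(x) x@value)
#' @rdname accessors
#' @export
setMethod("thresholdValue", "ReducedDoG", function(x) x@threshold)
#' @rdname accessors
#' @export
setMethod("descriptorValues", "DescriptorSet", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("keypoints", "DescriptorSet", function(x) x@keypoints)
#' @rdname accessors
#' @export
setMethod("centroids", "ClassModel", function(x) x@centroids)
#' @rdname accessors
#' @export
setMethod("modelClasses", "ClassModel", function(x) x@classes)
#' @rdname accessors
#' @export
setMethod("predictedClass", "MatchResult", function(x) x@predicted)
#' @rdname accessors
#' @export
setMethod("classDistances", "MatchResult", function(x) x@distances)
#' @rdname accessors
#' @export
setMethod("aucValue", "RocCurve", function(x) x@auc)
#' @rdname accessors
#' @export
setMethod("rocPoints", "RocCurve", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("finImage", "FinSample", function(x) x@image)
#' @rdname accessors
#' @export
setMethod("contourTruth", "FinSample", function(x) x@contourTruth)
#' @rdname accessors
#' @export
setMethod("finLabel", "FinSample", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("configHash", "DescriptorSet", function(x) x@configHash)
#' @rdname accessors
#' @export
setMethod("configHash", "ClassModel", function(x) x@configHash)

setMethod("show", "ScaleStack", function(object) {
  d <- dim(object@levels[[1]])
  cat(sprintf("ScaleStack: %d levels of %d x %d, sigma %.3g .. %.3g (k = %.4g)\n",
              length(object@levels), d[1], d[2],
              min(object@sigmas), max(object@sigmas), object@k))
})

setMethod("show", "DoGStack", function(object) {
  d <- dim(object@diffs[[1]])
  cat(sprintf("DoGStack: %d difference levels of %d x %d\n",
              length(object@diffs), d[1], d[2]))
})

setMethod("show", "ReducedDoG", function(object) {
  tot <- sum(vapply(object@retained, length, integer(1)))
  kept <- sum(vapply(object@retained, sum, numeric(1)))
  cat(sprintf("ReducedDoG: %d levels, mode '%s', %d / %d samples retained (%.1f%%)\n",
              length(object@diffs), object@mode, kept, tot, 100 * kept / tot))
})

setMethod("show", "DescriptorSet", function(object) {
  cat(sprintf("DescriptorSet: %d descriptors of length %d (config %s)\n",
              nrow(object@values),
              if (nrow(object@values)) ncol(object@values) else 128L,
              object@configHash))
})

setMethod("show", "ClassModel", function(object) {
  cat(sprintf("ClassModel: %d classes, aggregator '%s' (config %s)\n",
              length(object@classes), object@aggregator, object@configHash))
  cat(" ", paste(object@classes, collapse = ", "), "\n")
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: predicted '%s' from %d descriptors\n",
              object@predicted, object@nSampleDescriptors))
  print(round(object@distances, 4))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              object@tp, object@tn, object@fp, object@fn, object@denominator))
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d points, AUC = %.4f\n",
              nrow(object@points), object@auc))
})

setMethod("show", "FinSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("FinSample: '%s', %d x %d px, noise sigma %.3g\n",
              object@label, d[1], d[2], object@spec$noiseSigma))
})
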