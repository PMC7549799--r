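#' Train the nearest-centroid (median-estimation) class model
#'
#' Aggregates all training descriptors of each fin class into one centroid
#' vector, elementwise. The default aggregator is the mean (the published
#' formula averages); the elementwise median is available under the scheme's
#' name. Every class must contribute at least one descriptor.
#'
#' @param descSets List of \linkS4class{DescriptorSet}, one per training
#'   image.
#' @param labels Character vector of class labels, parallel to
#'   \code{descSets}; each must be one of \code{\link{finClasses}}.
#' @param aggregator \code{"mean"} (default) or \code{"median"}.
#' @param configHash Optional extraction-configuration hash to stamp into
#'   the model; defaults to the hash carried by the first descriptor set.
#' @return A \linkS4class{ClassModel}.
#' @export
trainClassModel <- function(descSets, labels,
                            aggregator = c("mean", "median"),
                            configHash = NULL) {
  aggregator <- match.arg(aggregator)
  if (length(descSets) != length(labels))
    stop("descSets and labels must have equal length")
  bad <- setdiff(unique(labels), finClasses())
  if (length(bad) > 0)
    stop(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")))
  cls <- finClasses()
  cent <- matrix(NA_real_, length(cls), 128L,
                 dimnames = list(cls, NULL))
  for (cl in cls) {
    rows <- lapply(descSets[labels == cl], descriptorValues)
    mat <- do.call(rbind, rows)
    if (is.null(mat) || nrow(mat) == 0L)
      stop(sprintf("training error: class '%s' has no descriptors", cl))
    cent[cl, ] <- if (aggregator == "mean") colMeans(mat)
                  else apply(mat, 2L, stats::median)
  }
  if (is.null(configHash))
    configHash <- if (length(descSets) > 0) descSets[[1]]@configHash else ""
  new("ClassModel", centroids = cent, aggregator = aggregator,
      classes = cls, configHash = configHash)
}

#' Aggregate squared Euclidean distance from a sample to a class centroid
#'
#' The matching statistic: the sum over all descriptors d of the sample of
#' the squared L2 norm \code{||d - centroid_j||^2}.
#'
#' @param sample A \linkS4class{DescriptorSet} (non-empty).
#' @param model A \linkS4class{ClassModel}.
#' @param class One of the model's class labels.
#' @return Nonnegative scalar.
#' @export
descriptorDistance <- function(sample, model, class) {
  stopifnot(is(sample, "DescriptorSet"), is(model, "ClassModel"))
  if (nrow(sample@values) == 0L)
    stop("classification error: sample has no descriptors")
  if (!class %in% model@classes)
    stop(sprintf("unknown class '%s'", class))
  d <- sweep(sample@values, 2L, model@centroids[class, ], `-`)
  sum(d^2)
}

#' Classify a descriptor set into one of the six fin classes
#'
#' Computes the aggregate squared Euclidean distance to every class
#' centroid and predicts the argmin; exact ties resolve to the earliest
#' class in declared order.
#'
#' @param sample A \linkS4class{DescriptorSet} (non-empty).
#' @param model A \linkS4class{ClassModel}.
#' @return A \linkS4class{MatchResult}.
#' @export
classifyFin <- function(sample, model) {
  stopifnot(is(sample, "DescriptorSet"), is(model, "ClassModel"))
  if (nrow(sample@values) == 0L)
    stop("classification error: sample has no descriptors")
  X <- sample@values
  C <- model@centroids
  # ||d - c||^2 summed over d: n*||c||^2 - 2 sum(d) . c + sum ||d||^2
  sumX <- colSums(X)
  sumX2 <- sum(X^2)
  dist <- nrow(X) * rowSums(C^2) - 2 * as.vector(C %*% sumX) + sumX2
  dist <- pmax(dist, 0)
  names(dist) <- model@classes
  pred <- model@classes[which.min(dist)]  # which.min takes the first tie
  new("MatchResult", distances = dist, predicted = pred,
      nSampleDescriptors = nrow(X))
}

#' K-nearest-neighbour baseline classifier
#'
#' Distance from the sample to each training image is the chamfer-style sum
#' over sample descriptors of the minimum squared Euclidean distance to any
#' descriptor of that image. The predicted class is the majority vote over
#' the K nearest training images; a vote tie resolves to the tied class
#' with the smallest summed distance.
#'
#' @param sample A \linkS4class{DescriptorSet} (non-empty).
#' @param trainSets List of \linkS4class{DescriptorSet} (training images).
#' @param trainLabels Character labels parallel to \code{trainSets}.
#' @param K Odd neighbour count, \code{1 <= K <= length(trainSets)}.
#' @return Predicted class label (character scalar).
#' @export
knnClassify <- function(sample, trainSets, trainLabels, K = 3L) {
  K <- as.integer(K)
  if (K %% 2L == 0L || K < 1L || K > length(trainSets))
    stop("parameter error: K must be odd and within 1..n_train")
  if (nrow(sample@values) == 0L)
    stop("classification error: sample has no descriptors")
  X <- sample@values
  x2 <- rowSums(X^2)
  dists <- vapply(trainSets, function(ts) {
    Y <- ts@values
    if (nrow(Y) == 0L) return(Inf)
    # cross squared distances, min over training descriptors per sample row
    cross <- outer(x2, rowSums(Y^2), `+`) - 2 * X %*% t(Y)
    sum(pmax(apply(cross, 1L, min), 0))
  }, numeric(1))
  o <- order(dists)[seq_len(K)]
  votes <- table(trainLabels[o])
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) return(top)
  sums <- vapply(top, function(cl)
    sum(dists[o][trainLabels[o] == cl]), numeric(1))
  top[which.min(sums)]
}

#' Write a class model to versioned JSON
#'
#' @param model A \linkS4class{ClassModel}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeClassModel <- function(model, path) {
  stopifnot(is(model, "ClassModel"))
  obj <- list(
    version = 1L,
    type = "finprint_class_model",
    aggregator = model@aggregator,
    config_hash = model@configHash,
    classes = model@classes,
    centroids = lapply(seq_len(nrow(model@centroids)),
                       function(i) unname(model@centroids[i, ]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a class model from JSON
#'
#' @param path File written by \code{\link{writeClassModel}}.
#' @return A \linkS4class{ClassModel}.
#' @export
readClassModel <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file '%s' not found", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "finprint_class_model"))
    stop("format error: not a finprint class model file")
  cent <- if (is.matrix(obj$centroids)) obj$centroids
          else do.call(rbind, lapply(obj$centroids, as.numeric))
  rownames(cent) <- obj$classes
  new("ClassModel", centroids = cent, aggregator = obj$aggregator,
      classes = obj$classes, configHash = obj$config_hash)
}
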