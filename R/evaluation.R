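#' Two-by-two confusion counts
#'
#' Tallies TP/TN/FP/FN for a chosen positive class over paired predicted
#' and truth vectors (or boolean rasters, which are compared elementwise).
#'
#' @param predicted Vector/matrix of predicted labels, or logical values.
#' @param truth Same shape/length as \code{predicted}.
#' @param positive The positive class: a label present in the vectors, or
#'   \code{TRUE} (default) for logical input.
#' @return A \linkS4class{ConfusionCounts}.
#' @export
#' @examples
#' confusionCounts(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
confusionCounts <- function(predicted, truth, positive = TRUE) {
  if (length(predicted) != length(truth))
    stop("consistency error: predicted and truth differ in length")
  p <- as.vector(predicted) == positive
  t <- as.vector(truth) == positive
  new("ConfusionCounts",
      tp = sum(p & t), tn = sum(!p & !t),
      fp = sum(p & !t), fn = sum(!p & t),
      denominator = length(p))
}

#' Specificity TN / (TN + FP)
#'
#' The ability to reject negatives. Returns \code{NA} when no negative
#' units exist (TN + FP = 0) rather than a silent zero.
#'
#' @param counts A \linkS4class{ConfusionCounts}.
#' @return Value in [0,1], or \code{NA_real_} when undefined.
#' @export
specificity <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  den <- counts@tn + counts@fp
  if (den == 0L) NA_real_ else counts@tn / den
}

#' Sensitivity TP / (TP + FN)
#'
#' The ability to detect positives. Returns \code{NA} when no positive
#' units exist (TP + FN = 0).
#'
#' @param counts A \linkS4class{ConfusionCounts}.
#' @return Value in [0,1], or \code{NA_real_} when undefined.
#' @export
sensitivity <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  den <- counts@tp + counts@fn
  if (den == 0L) NA_real_ else counts@tp / den
}

#' Accuracy (TP + TN) / total
#'
#' The proportion of correctly classified units; the denominator is the
#' total number of evaluated units — pixels for pixel-level contour
#' evaluation, images for image-level class evaluation.
#'
#' @param counts A \linkS4class{ConfusionCounts}.
#' @return Value in [0,1].
#' @export
accuracy <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  if (counts@denominator <= 0L)
    stop("parameter error: denominator must be positive")
  (counts@tp + counts@tn) / counts@denominator
}

#' Receiver operating characteristic curve and AUC
#'
#' Sweeps a decision threshold over the unique score values (ties grouped
#' into a single step), collecting (FPR, TPR) points from (0,0) to (1,1),
#' and integrates the area by the trapezoid rule. Higher scores must mean
#' "more positive".
#'
#' @param scores Numeric vector of per-unit scores.
#' @param truth Logical vector (or coercible) of per-unit truth; needs at
#'   least one positive and one negative.
#' @return A \linkS4class{RocCurve}.
#' @export
rocCurve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth))
    stop("consistency error: scores and truth differ in length")
  if (anyNA(scores) || anyNA(truth)) stop("scores/truth contain NA")
  nPos <- sum(truth); nNeg <- sum(!truth)
  if (nPos == 0L || nNeg == 0L)
    stop("evaluation error: truth must contain both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))   # tie groups
  tpCum <- cumsum(t); fpCum <- cumsum(!t)
  last <- which(c(grp[-1] != grp[-length(grp)], TRUE))
  pts <- data.frame(threshold = s[last],
                    fpr = fpCum[last] / nNeg,
                    tpr = tpCum[last] / nPos)
  pts <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), pts)
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  new("RocCurve", points = pts, auc = auc)
}

#' Cross-class accuracy dispersion
#'
#' Population standard deviation of per-class accuracy values — the spread
#' statistic used to compare classifiers across the six fin classes.
#'
#' @param perClassAcc Numeric vector of per-class accuracies (non-empty;
#'   \code{NA} entries are dropped).
#' @return Nonnegative scalar.
#' @export
accDispersion <- function(perClassAcc) {
  x <- perClassAcc[!is.na(perClassAcc)]
  if (length(x) == 0L)
    stop("parameter error: no defined accuracy values")
  sqrt(mean((x - mean(x))^2))
}

#' Evaluate a trained model on labelled descriptor sets
#'
#' Classifies every sample, then scores each of the six classes one-vs-rest:
#' confusion counts from the predicted labels, Sp/Se/Acc, and a per-class
#' ROC curve. The default ROC score is the decision margin — the smallest
#' distance to any other class minus the distance to the class under test —
#' the score whose threshold at zero reproduces the classifier's own argmin
#' decision rule; \code{"neg_distance"} (minus the raw class distance) is
#' available but is confounded by per-image descriptor counts, which enter
#' every class's aggregate distance alike. The returned report has one row
#' per class plus a \code{"macro"} summary row carrying the macro averages,
#' and the population standard deviation of the per-class accuracies in its
#' \code{acc_dispersion} column.
#'
#' @param model A \linkS4class{ClassModel}.
#' @param descSets List of \linkS4class{DescriptorSet} (test images).
#' @param labels True class labels, parallel to \code{descSets}.
#' @param rocScore \code{"margin"} (default) or \code{"neg_distance"}.
#' @return List with elements \code{report} (data frame), \code{predicted}
#'   (character vector), \code{matches} (list of
#'   \linkS4class{MatchResult}), \code{roc} (named list of
#'   \linkS4class{RocCurve}).
#' @export
evaluateClassifier <- function(model, descSets, labels,
                               rocScore = c("margin", "neg_distance")) {
  rocScore <- match.arg(rocScore)
  stopifnot(is(model, "ClassModel"))
  if (length(descSets) != length(labels))
    stop("descSets and labels must have equal length")
  matches <- lapply(descSets, classifyFin, model = model)
  predicted <- vapply(matches, predictedClass, character(1))
  distMat <- do.call(rbind, lapply(matches, classDistances))
  cls <- model@classes
  rows <- vector("list", length(cls))
  roc <- list()
  for (i in seq_along(cls)) {
    cl <- cls[i]
    cc <- confusionCounts(predicted, labels, positive = cl)
    auc <- if (sum(labels == cl) > 0 && sum(labels != cl) > 0) {
      score <- if (rocScore == "margin") {
        apply(distMat, 1L, function(r) min(r[names(r) != cl])) -
          distMat[, cl]
      } else {
        -distMat[, cl]
      }
      r <- rocCurve(score, labels == cl)
      roc[[cl]] <- r
      aucValue(r)
    } else NA_real_
    rows[[i]] <- data.frame(
      class = cl, tp = cc@tp, tn = cc@tn, fp = cc@fp, fn = cc@fn,
      sp = specificity(cc), se = sensitivity(cc), acc = accuracy(cc),
      auc = auc, acc_dispersion = NA_real_)
  }
  rep <- do.call(rbind, rows)
  macro <- data.frame(
    class = "macro",
    tp = sum(rep$tp), tn = sum(rep$tn), fp = sum(rep$fp), fn = sum(rep$fn),
    sp = mean(rep$sp, na.rm = TRUE), se = mean(rep$se, na.rm = TRUE),
    acc = mean(rep$acc, na.rm = TRUE), auc = mean(rep$auc, na.rm = TRUE),
    acc_dispersion = accDispersion(rep$acc))
  list(report = rbind(rep, macro), predicted = predicted,
       matches = matches, roc = roc)
}

#' Macro (mean per-class, one-vs-rest) accuracy of predictions
#'
#' Convenience wrapper: mean over the six classes of the one-vs-rest
#' accuracy of a predicted-label vector. Note this is image-level accuracy
#' in the one-vs-rest sense, not the plain fraction of correct predictions.
#'
#' @param predicted,truth Parallel label vectors.
#' @return Scalar in [0,1].
#' @export
macroAccuracy <- function(predicted, truth) {
  accs <- vapply(finClasses(), function(cl)
    accuracy(confusionCounts(predicted, truth, positive = cl)), numeric(1))
  mean(accs)
}
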