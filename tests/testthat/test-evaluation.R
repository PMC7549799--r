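test_that("confusionCounts tallies the standard 2x2 table", {
  t1 <- c(rep(TRUE, 4), rep(FALSE, 6))
  c1 <- confusionCounts(t1, t1)
  expect_equal(c(c1@tp, c1@tn, c1@fp, c1@fn), c(4L, 6L, 0L, 0L))
  c2 <- confusionCounts(!t1, t1)
  expect_equal(c(c2@tp, c2@tn, c2@fp, c2@fn), c(0L, 0L, 6L, 4L))
  expect_error(confusionCounts(t1, t1[-1]), "length")
  # label input with a positive class
  p <- c("a", "b", "a"); t <- c("a", "a", "b")
  c3 <- confusionCounts(p, t, positive = "a")
  expect_equal(c(c3@tp, c3@tn, c3@fp, c3@fn), c(1L, 0L, 1L, 1L))
  # random vectors vs per-unit tally
  for (seed in 1:4) {
    set.seed(seed)
    p <- sample(c(TRUE, FALSE), 50, TRUE)
    t <- sample(c(TRUE, FALSE), 50, TRUE)
    cc <- confusionCounts(p, t)
    expect_equal(cc@tp, sum(p & t)); expect_equal(cc@tn, sum(!p & !t))
    expect_equal(cc@fp, sum(p & !t)); expect_equal(cc@fn, sum(!p & t))
    expect_equal(cc@tp + cc@tn + cc@fp + cc@fn, cc@denominator)
  }
})

mkCounts <- function(tp, tn, fp, fn) {
  new("ConfusionCounts", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn),
      denominator = as.integer(tp + tn + fp + fn))
}

test_that("Sp, Se and Acc follow their defining ratios with NA when undefined", {
  expect_equal(specificity(mkCounts(0, 9, 1, 0)), 0.9)
  expect_true(is.na(specificity(mkCounts(3, 0, 0, 2))))
  expect_equal(specificity(mkCounts(1, 5, 0, 1)), 1.0)
  expect_equal(sensitivity(mkCounts(7, 0, 0, 3)), 0.7)
  expect_true(is.na(sensitivity(mkCounts(0, 4, 2, 0))))
  expect_equal(sensitivity(mkCounts(5, 1, 1, 0)), 1.0)
  expect_equal(accuracy(mkCounts(4, 6, 0, 0)), 1.0)
  expect_equal(accuracy(mkCounts(0, 0, 6, 4)), 0.0)
  for (seed in 1:4) {
    set.seed(seed)
    v <- as.vector(stats::rmultinom(1, 40, rep(0.25, 4)))
    cc <- mkCounts(v[1], v[2], v[3], v[4])
    expect_equal(accuracy(cc), (v[1] + v[2]) / 40)
    if (v[2] + v[3] > 0) {
      expect_gte(specificity(cc), 0); expect_lte(specificity(cc), 1)
    }
  }
})

test_that("rocCurve matches the all-pairs counting oracle", {
  # perfect separation -> AUC 1; constant scores -> 0.5
  tr <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(aucValue(rocCurve(c(5:1, -(1:5)), tr)), 1.0)
  expect_equal(aucValue(rocCurve(rep(2, 10), tr)), 0.5)
  expect_error(rocCurve(1:5, rep(TRUE, 5)), "both classes")
  for (seed in 1:5) {
    set.seed(seed)
    sc <- sample(seq(0, 1, 0.1), 20, TRUE)  # ties likely
    t <- sample(c(TRUE, FALSE), 20, TRUE)
    if (!any(t) || all(t)) t[1:2] <- c(TRUE, FALSE)
    r <- rocCurve(sc, t)
    expect_equal(aucValue(r), bfAUC(sc, t), tolerance = 1e-12)
    p <- rocPoints(r)
    expect_equal(p$fpr[1], 0); expect_equal(p$tpr[1], 0)
    expect_equal(p$fpr[nrow(p)], 1); expect_equal(p$tpr[nrow(p)], 1)
    expect_true(all(diff(p$fpr) >= 0) && all(diff(p$tpr) >= 0))
  }
})

test_that("rocCurve agrees with an independent ROC implementation", {
  set.seed(10)
  sc <- stats::rnorm(40)
  t <- stats::runif(40) < 0.4
  if (!any(t) || all(t)) t[1:2] <- c(TRUE, FALSE)
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(t, sc, quiet = TRUE, direction = "<",
              levels = c(FALSE, TRUE)))))
  expect_equal(aucValue(rocCurve(sc, t)), ref, tolerance = 1e-10)
})

test_that("AUC is invariant under monotone transforms and flips under label swap", {
  set.seed(3)
  sc <- stats::rnorm(30)
  t <- c(rep(TRUE, 12), rep(FALSE, 18))
  a <- aucValue(rocCurve(sc, t))
  expect_equal(aucValue(rocCurve(exp(sc), t)), a)
  expect_equal(aucValue(rocCurve(3 * sc + 7, t)), a)
  expect_equal(aucValue(rocCurve(atan(sc), t)), a)
  expect_equal(aucValue(rocCurve(sc, !t)), 1 - a)
})

test_that("accDispersion is the population standard deviation", {
  expect_equal(accDispersion(rep(0.9, 6)), 0)
  expect_equal(accDispersion(c(0.8, 0.9)), 0.05)
  set.seed(4)
  x <- stats::runif(6)
  expect_equal(accDispersion(x), sqrt(mean((x - mean(x))^2)))
  expect_error(accDispersion(numeric(0)), "accuracy values")
})

test_that("evaluateClassifier produces the per-class one-vs-rest report", {
  # six synthetic 'images' whose descriptors sit exactly on distinct unit axes
  cls <- finClasses()
  mk <- function(i, jit = 0) {
    v <- numeric(128); v[i] <- 1; v[i + 6] <- jit
    v <- v / sqrt(sum(v^2))
    new("DescriptorSet", values = rbind(v),
        keypoints = data.frame(x = 1, y = 1, level = 1L, sigma = 1.6,
                               orientation = 0, contrast = 0.1),
        configHash = "h")
  }
  train <- lapply(seq_along(cls), function(i) mk(i))
  mod <- trainClassModel(train, cls)
  test <- c(lapply(seq_along(cls), function(i) mk(i, 0.05)),
            list(mk(1, 0.1)))
  labels <- c(cls, "left_falcate")  # one deliberate error
  ev <- evaluateClassifier(mod, test, labels)
  expect_named(ev, c("report", "predicted", "matches", "roc"))
  rep <- ev$report
  expect_equal(rep$class, c(cls, "macro"))
  expect_true(all(c("tp", "tn", "fp", "fn", "sp", "se", "acc", "auc",
                    "acc_dispersion") %in% names(rep)))
  expect_equal(ev$predicted[1:6], cls)
  expect_equal(ev$predicted[7], "right_falcate")  # the planted error
  # macro row aggregates
  expect_equal(rep$acc[7], mean(rep$acc[1:6]))
  expect_equal(rep$acc_dispersion[7], accDispersion(rep$acc[1:6]))
  # per-class accuracy equals its one-vs-rest confusion
  cc <- confusionCounts(ev$predicted, labels, positive = "right_falcate")
  expect_equal(rep$acc[1], accuracy(cc))
})
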