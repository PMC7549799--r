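mkReduced <- function(diffs, sigmas = 2^(seq_along(diffs) - 1)) {
  new("ReducedDoG", diffs = diffs, sigmas = sigmas,
      retained = lapply(diffs, function(d) matrix(TRUE, nrow(d), ncol(d))),
      mode = "none", threshold = Inf)
}

test_that("detectExtrema equals the exhaustive 26-neighbor scan", {
  # all-zero stack -> nothing
  z <- mkReduced(lapply(1:3, function(i) matrix(0, 10, 10)))
  expect_equal(nrow(detectExtrema(z, 1L)), 0L)
  # single interior impulse -> exactly that candidate
  d <- lapply(1:3, function(i) matrix(0, 10, 10))
  d[[2]][5, 6] <- 0.5
  hit <- detectExtrema(mkReduced(d), 1L)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$x, 5L); expect_equal(hit$y, 4L); expect_equal(hit$level, 2L)
  # random stacks vs brute force, several seeds and exclusions
  for (seed in 1:4) {
    diffs <- lapply(1:3, function(i) randMat(16, 16, seed * 7 + i, -1, 1))
    e <- 1L + seed %% 2L
    red <- mkReduced(diffs)
    got <- detectExtrema(red, e)
    want <- bfExtrema(diffs, retainedMask(red), e)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got[, c("x", "y", "level")],
                   want[order(want$level, want$y, want$x), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("detectExtrema honours the retention mask and level minimum", {
  diffs <- lapply(1:3, function(i) randMat(12, 12, 99 + i, -1, 1))
  red <- mkReduced(diffs)
  base <- detectExtrema(red, 1L)
  # mask away every candidate -> empty
  masks <- lapply(diffs, function(d) matrix(TRUE, nrow(d), ncol(d)))
  for (i in seq_len(nrow(base)))
    masks[[base$level[i]]][base$y[i] + 1L, base$x[i] + 1L] <- FALSE
  red2 <- new("ReducedDoG", diffs = diffs, sigmas = red@sigmas,
              retained = masks, mode = "none", threshold = Inf)
  expect_equal(nrow(detectExtrema(red2, 1L)), 0L)
  expect_error(detectExtrema(mkReduced(diffs[1:2]), 1L), "3")
})

test_that("localizeKeypoint recovers planted quadratic vertices", {
  nr <- 16; nc <- 16
  mk <- function(cx, cy, base) {
    m <- matrix(0, nr, nc)
    for (x in 0:(nc - 1)) for (y in 0:(nr - 1))
      m[y + 1, x + 1] <- -0.01 * ((x - cx)^2 + (y - cy)^2) + base
    m
  }
  # vertex exactly on the grid -> zero offset
  dog <- mkDoG(list(mk(7, 8, -0.1) - 0.4, mk(7, 8, -0.1), mk(7, 8, -0.1) - 0.4),
               sigmas = 1.6 * sqrt(2)^(0:2))
  kp <- localizeKeypoint(dog, list(x = 7, y = 8, level = 2),
                         contrastThreshold = 0.01)
  expect_equal(kp$offset, c(0, 0, 0), tolerance = 1e-12)
  # vertex at x-offset 0.3 -> recovered within 1e-6
  dog2 <- mkDoG(list(mk(7.3, 8, -0.1) - 0.4, mk(7.3, 8, -0.1),
                     mk(7.3, 8, -0.1) - 0.4), sigmas = 1.6 * sqrt(2)^(0:2))
  kp2 <- localizeKeypoint(dog2, list(x = 7, y = 8, level = 2),
                          contrastThreshold = 0.01)
  expect_lt(abs(kp2$x - 7.3), 1e-6)
  expect_lt(abs(kp2$y - 8), 1e-6)
  # below the contrast threshold -> rejected
  dog3 <- mkDoG(list(mk(7, 8, 0) - 0.4, mk(7, 8, 0), mk(7, 8, 0) - 0.4),
                sigmas = 1.6 * sqrt(2)^(0:2))
  expect_null(localizeKeypoint(dog3, list(x = 7, y = 8, level = 2),
                               contrastThreshold = 0.03))
})

test_that("gradientField implements the two-pixel central differences", {
  f0 <- gradientField(matrix(0.5, 8, 8))
  expect_true(all(f0@magnitude == 0))
  expect_true(all(f0@orientation == 0))
  # ramp in x: interior magnitude 2 (differences span two pixels), theta 0
  rampx <- matrix(0:7, 8, 8, byrow = TRUE)  # L(x, y) = x
  fx <- gradientField(rampx)
  expect_true(all(fx@magnitude[2:7, 2:7] == 2))
  expect_true(all(fx@orientation[2:7, 2:7] == 0))
  # ramp in y: theta = pi/2
  rampy <- matrix(0:7, 8, 8, byrow = FALSE)
  fy <- gradientField(rampy)
  expect_true(all(fy@magnitude[2:7, 2:7] == 2))
  expect_true(all(fy@orientation[2:7, 2:7] == pi / 2))
})

test_that("assignOrientations finds dominant directions", {
  # single gradient direction -> one orientation at that angle
  rampx <- matrix(seq(0, 1, length.out = 32), 32, 32, byrow = TRUE)
  f <- gradientField(rampx)
  kp <- list(x = 15, y = 15, level = 2, sigma = 1.6, contrast = 0.5)
  o <- assignOrientations(kp, f)
  expect_equal(nrow(o), 1L)
  expect_lt(min(abs(o$orientation - 0), abs(o$orientation - 2 * pi)),
            2 * pi / 36)
  # two equal orthogonal directions -> two orientations under peak80
  half <- cbind(matrix(seq(0, 1, length.out = 16), 32, 16, byrow = TRUE),
                matrix(seq(0, 1, length.out = 16), 32, 16, byrow = FALSE))
  f2 <- gradientField(half)
  o2 <- assignOrientations(list(x = 15.5, y = 15.5, level = 2, sigma = 4,
                                contrast = 0.5), f2)
  expect_gte(nrow(o2), 2L)
  # zero-gradient window -> dropped keypoint
  fz <- gradientField(matrix(0.3, 32, 32))
  expect_equal(nrow(assignOrientations(kp, fz)), 0L)
})

test_that("descriptors are unit-norm, clamped, and rotation-stable", {
  s <- cleanFin()
  st <- buildScaleStack(finImage(s))
  f <- gradientField(stackLevels(st)[[2]])
  kp <- list(x = 48, y = 40, level = 2, sigma = stackSigmas(st)[2],
             contrast = 0.1, orientation = 0.7)
  v <- computeDescriptor(kp, f)
  expect_length(v, 128L)
  expect_lt(abs(sqrt(sum(v^2)) - 1), 1e-6)
  # clamped at 0.2 before the final renormalization; the renorm can lift
  # entries slightly, bounded by 1/sqrt(sum(min(v,0.2)^2)) of the cap
  expect_lte(max(v), 0.25)
  # zero gradients -> rejection
  fz <- gradientField(matrix(0.5, 64, 64))
  expect_null(computeDescriptor(kp, fz))
  # 90-degree rotated image with co-rotated keypoint -> same descriptor
  img <- finImage(s)
  rot <- t(img[nrow(img):1, ])
  f2 <- gradientField(stackLevels(buildScaleStack(rot))[[2]])
  kp2 <- list(x = (nrow(img) - 1) - kp$y, y = kp$x, level = 2,
              sigma = kp$sigma, contrast = 0.1,
              orientation = (kp$orientation + pi / 2) %% (2 * pi))
  v2 <- computeDescriptor(kp2, f2)
  expect_lt(sqrt(sum((v - v2)^2)), 0.15)
})

test_that("extractFeatures is deterministic and translation-equivariant", {
  expect_equal(nrow(descriptorValues(
    extractFeatures(matrix(0.5, 32, 32)))), 0L)
  s <- generateFin(finSpec("right_falcate", heightPx = 128L,
                           widthPx = 128L, noiseSigma = 0, seed = 2))
  d1 <- extractFeatures(finImage(s))
  expect_gte(nrow(descriptorValues(d1)), 1L)
  d1b <- extractFeatures(finImage(s))
  expect_identical(descriptorValues(d1), descriptorValues(d1b))
  expect_identical(keypoints(d1), keypoints(d1b))
  # shift by (5, 5): keypoints follow within 0.5 px
  img <- finImage(s)
  sh <- matrix(0.75, nrow(img), ncol(img))
  sh[6:nrow(img), 6:ncol(img)] <- img[1:(nrow(img) - 5), 1:(ncol(img) - 5)]
  k1 <- keypoints(d1); k2 <- keypoints(extractFeatures(sh))
  expect_gt(nrow(k2), 0)
  err <- vapply(seq_len(nrow(k1)), function(i)
    min(sqrt((k2$x - (k1$x[i] + 5))^2 + (k2$y - (k1$y[i] + 5))^2)),
    numeric(1))
  expect_lt(stats::median(err), 0.5)
})

test_that("oriented keypoints always arise from nonzero-gradient windows", {
  s <- cleanFin()
  st <- buildScaleStack(finImage(s))
  dg <- dogDifferences(st)
  red <- reduceScales(dg, dogThreshold(dg))
  cands <- detectExtrema(red, 4L)
  f <- gradientField(stackLevels(st)[[2]])
  nOri <- 0L
  for (i in seq_len(min(nrow(cands), 10L))) {
    kp <- localizeKeypoint(dg, cands[i, ], contrastThreshold = 0.01)
    if (is.null(kp)) next
    o <- assignOrientations(kp, f)
    nOri <- nOri + nrow(o)
    expect_gte(nrow(o), 1L)  # peak80 with nonzero gradient yields >= 1
  }
  expect_gt(nOri, 0L)
})
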