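#' Gradient magnitude and orientation of a smoothed level
#'
#' Central differences with replicate padding:
#' \code{M(x,y) = sqrt((L(x+1,y) - L(x-1,y))^2 + (L(x,y+1) - L(x,y-1))^2)}
#' and \code{theta = atan2(L(x,y+1) - L(x,y-1), L(x+1,y) - L(x-1,y))}.
#' Note the differences span two pixels and are not halved, so a unit-slope
#' ramp has interior magnitude 2. Orientation covers the full circle
#' (\code{(-pi, pi]}) and is set to 0 wherever both differences vanish.
#'
#' @param level Numeric matrix (a smoothed image level), at least 3 x 3.
#' @return A \linkS4class{GradientField}.
#' @export
gradientField <- function(level) {
  if (!is.matrix(level) || nrow(level) < 3L || ncol(level) < 3L)
    stop("level must be a matrix of at least 3 x 3")
  dx <- shiftClamped(level, 0L, 1L) - shiftClamped(level, 0L, -1L)
  dy <- shiftClamped(level, 1L, 0L) - shiftClamped(level, -1L, 0L)
  mag <- sqrt(dx^2 + dy^2)
  ori <- atan2(dy, dx)
  ori[dx == 0 & dy == 0] <- 0
  new("GradientField", magnitude = mag, orientation = ori)
}

#' Detect scale-space extremum candidates
#'
#' A retained sample at interior level m is a candidate keypoint iff it is
#' strictly greater than, or strictly less than, all 26 neighbors in its
#' 3 x 3 x 3 scale-space neighborhood. Samples within \code{edgeExclusion}
#' pixels of the raster border are excluded.
#'
#' @param reduced A \linkS4class{ReducedDoG} with at least 3 levels.
#' @param edgeExclusion Border margin in pixels (>= 1).
#' @return Data frame with 0-based integer columns \code{x}, \code{y},
#'   level index \code{level}, and the sample \code{value}.
#' @export
detectExtrema <- function(reduced, edgeExclusion = 4L) {
  stopifnot(is(reduced, "ReducedDoG"))
  n <- length(reduced@diffs)
  if (n < 3L)
    stop("size error: extremum detection needs at least 3 difference levels")
  e <- max(as.integer(edgeExclusion), 1L)
  nr <- nrow(reduced@diffs[[1]]); nc <- ncol(reduced@diffs[[1]])
  if (nr <= 2L * e || nc <= 2L * e)
    return(data.frame(x = integer(0), y = integer(0), level = integer(0),
                      value = numeric(0)))
  rows <- (e + 1L):(nr - e)
  cols <- (e + 1L):(nc - e)
  out <- vector("list", n)
  for (m in 2:(n - 1L)) {
    ctr <- reduced@diffs[[m]][rows, cols]
    gt <- matrix(TRUE, length(rows), length(cols))
    lt <- gt
    for (dz in -1L:1L) for (dr in -1L:1L) for (dc in -1L:1L) {
      if (dz == 0L && dr == 0L && dc == 0L) next
      nb <- reduced@diffs[[m + dz]][rows + dr, cols + dc]
      gt <- gt & (ctr > nb)
      lt <- lt & (ctr < nb)
    }
    hit <- (gt | lt) & reduced@retained[[m]][rows, cols]
    if (any(hit)) {
      w <- which(hit, arr.ind = TRUE)
      out[[m]] <- data.frame(x = cols[w[, 2]] - 1L, y = rows[w[, 1]] - 1L,
                             level = m, value = ctr[hit])
    }
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(x = integer(0), y = integer(0), level = integer(0),
                      value = numeric(0))
  rownames(out) <- NULL
  out[order(out$level, out$y, out$x), , drop = FALSE]
}

#' Sub-pixel keypoint localization by quadratic interpolation
#'
#' Fits a 3-D quadratic to the DoG values around a candidate and solves
#' \code{zhat = -H^{-1} grad} with finite-difference gradient and Hessian in
#' (x, y, scale). If any offset component exceeds 0.5 the candidate is moved
#' to the neighboring sample and the fit repeated, up to \code{maxIter}
#' times. Candidates are rejected (returning \code{NULL}) when the fit does
#' not converge, leaves the stack, the Hessian is singular, or the
#' interpolated contrast \code{|D(zhat)|} falls below
#' \code{contrastThreshold}. An optional principal-curvature (edge response)
#' filter can be enabled via \code{edgeThreshold}.
#'
#' @param dog A \linkS4class{DoGStack}.
#' @param candidate One-row data frame or list with 0-based integer
#'   \code{x}, \code{y} and level index \code{level} (interior).
#' @param contrastThreshold Minimum interpolated \code{|D|}; default 0.03
#'   on [0,1] luminance.
#' @param maxIter Maximum relocation steps; default 5.
#' @param edgeThreshold If non-\code{NULL}, reject keypoints whose spatial
#'   Hessian curvature ratio exceeds \code{(edgeThreshold+1)^2 /
#'   edgeThreshold}.
#' @return A list with sub-pixel \code{x}, \code{y}, \code{level},
#'   \code{sigma}, \code{offset} (length 3), \code{contrast}; or
#'   \code{NULL} if rejected.
#' @export
localizeKeypoint <- function(dog, candidate, contrastThreshold = 0.03,
                             maxIter = 5L, edgeThreshold = NULL) {
  stopifnot(is(dog, "DoGStack"))
  n <- length(dog@diffs)
  nr <- nrow(dog@diffs[[1]]); nc <- ncol(dog@diffs[[1]])
  r <- as.integer(candidate$y) + 1L
  c <- as.integer(candidate$x) + 1L
  m <- as.integer(candidate$level)
  kRatio <- if (n >= 2L) dog@sigmas[2] / dog@sigmas[1] else sqrt(2)
  for (iter in seq_len(max(1L, as.integer(maxIter)))) {
    if (m < 2L || m > n - 1L || r < 2L || r > nr - 1L || c < 2L || c > nc - 1L)
      return(NULL)
    D0 <- dog@diffs[[m]]; Dp <- dog@diffs[[m + 1L]]; Dm <- dog@diffs[[m - 1L]]
    v <- D0[r, c]
    g <- c(0.5 * (D0[r, c + 1L] - D0[r, c - 1L]),
           0.5 * (D0[r + 1L, c] - D0[r - 1L, c]),
           0.5 * (Dp[r, c] - Dm[r, c]))
    dxx <- D0[r, c + 1L] - 2 * v + D0[r, c - 1L]
    dyy <- D0[r + 1L, c] - 2 * v + D0[r - 1L, c]
    dss <- Dp[r, c] - 2 * v + Dm[r, c]
    dxy <- 0.25 * (D0[r + 1L, c + 1L] - D0[r + 1L, c - 1L] -
                   D0[r - 1L, c + 1L] + D0[r - 1L, c - 1L])
    dxs <- 0.25 * (Dp[r, c + 1L] - Dp[r, c - 1L] -
                   Dm[r, c + 1L] + Dm[r, c - 1L])
    dys <- 0.25 * (Dp[r + 1L, c] - Dp[r - 1L, c] -
                   Dm[r + 1L, c] + Dm[r - 1L, c])
    H <- matrix(c(dxx, dxy, dxs,
                  dxy, dyy, dys,
                  dxs, dys, dss), 3L, 3L)
    off <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(off) || anyNA(off) || any(!is.finite(off))) return(NULL)
    if (all(abs(off) <= 0.5)) {
      val <- v + 0.5 * sum(g * off)
      if (abs(val) < contrastThreshold) return(NULL)
      if (!is.null(edgeThreshold)) {
        det2 <- dxx * dyy - dxy^2
        if (det2 <= 0) return(NULL)
        if ((dxx + dyy)^2 / det2 >
            (edgeThreshold + 1)^2 / edgeThreshold) return(NULL)
      }
      x <- (c - 1L) + off[1]
      y <- (r - 1L) + off[2]
      if (x < 0 || x > nc - 1L || y < 0 || y > nr - 1L) return(NULL)
      return(list(x = x, y = y, level = m,
                  sigma = dog@sigmas[m] * kRatio^off[3],
                  offset = off, contrast = abs(val)))
    }
    c <- c + sign(off[1]) * (abs(off[1]) > 0.5)
    r <- r + sign(off[2]) * (abs(off[2]) > 0.5)
    m <- m + sign(off[3]) * (abs(off[3]) > 0.5)
  }
  NULL
}

#' Assign dominant orientations to a localized keypoint
#'
#' Builds a magnitude-weighted, Gaussian-weighted orientation histogram in a
#' window of radius \code{ceiling(3 * sigma_w)} around the keypoint, with
#' \code{sigma_w = windowSigmaFactor * sigma}. Under \code{"peak80"}
#' (default) every histogram bin reaching at least 80\% of the maximum bin
#' spawns one oriented copy of the keypoint at its bin-center angle; under
#' \code{"literal_mean"} the threshold is instead 0.8 times the plain mean
#' of the raw orientation angles over the window (a faithful alternative
#' reading of the published rule, kept for comparison although it mixes
#' units).
#'
#' @param kp Localized keypoint (list with \code{x}, \code{y},
#'   \code{level}, \code{sigma}, \code{contrast}).
#' @param field \linkS4class{GradientField} of the keypoint's level.
#' @param nBins Number of histogram bins; default 36.
#' @param windowSigmaFactor Gaussian window scale factor; default 1.5.
#' @param peakMode \code{"peak80"} or \code{"literal_mean"}.
#' @return Data frame of oriented keypoints (possibly zero rows) with
#'   columns \code{x}, \code{y}, \code{level}, \code{sigma},
#'   \code{orientation} (radians in [0, 2 pi)), \code{contrast}.
#' @export
assignOrientations <- function(kp, field, nBins = 36L,
                               windowSigmaFactor = 1.5,
                               peakMode = c("peak80", "literal_mean")) {
  stopifnot(is(field, "GradientField"))
  peakMode <- match.arg(peakMode)
  nBins <- as.integer(nBins)
  nr <- nrow(field@magnitude); nc <- ncol(field@magnitude)
  rc <- round(kp$y) + 1L; cc <- round(kp$x) + 1L
  if (rc < 1L || rc > nr || cc < 1L || cc > nc)
    return(orientedKpFrame())  # window entirely outside the image
  sw <- windowSigmaFactor * kp$sigma
  rad <- ceiling(3 * sw)
  rows <- max(1L, rc - rad):min(nr, rc + rad)
  cols <- max(1L, cc - rad):min(nc, cc + rad)
  mag <- field@magnitude[rows, cols, drop = FALSE]
  ori <- field@orientation[rows, cols, drop = FALSE]
  d2 <- outer((rows - rc)^2, (cols - cc)^2, `+`)
  w <- as.vector(mag * exp(-d2 / (2 * sw^2)))
  if (sum(w) == 0) return(orientedKpFrame())
  th <- as.vector(ori) %% (2 * pi)
  bin <- pmin(floor(th / (2 * pi / nBins)) + 1L, nBins)
  h <- numeric(nBins)
  agg <- rowsum(w, bin)
  h[as.integer(rownames(agg))] <- agg[, 1]
  thr <- if (peakMode == "peak80") 0.8 * max(h) else 0.8 * mean(th)
  sel <- which(h >= thr & h > 0)
  if (length(sel) == 0L) return(orientedKpFrame())
  angles <- (sel - 0.5) * 2 * pi / nBins  # bin-center angles
  data.frame(x = kp$x, y = kp$y, level = kp$level, sigma = kp$sigma,
             orientation = angles, contrast = kp$contrast)
}

orientedKpFrame <- function() {
  data.frame(x = numeric(0), y = numeric(0), level = integer(0),
             sigma = numeric(0), orientation = numeric(0),
             contrast = numeric(0))
}

#' Compute the 128-length gradient-histogram descriptor of one oriented
#' keypoint
#'
#' Samples a 16 x 16 grid (spacing equal to the keypoint scale, in pixels)
#' around the keypoint, rotates the sample offsets by minus the keypoint
#' orientation, and accumulates gradient magnitudes into 4 x 4 spatial
#' cells times 8 orientation bins with trilinear interpolation. Magnitudes
#' are weighted by a Gaussian centred on the keypoint whose scale is half
#' the descriptor-window width (\code{"half_window"}, default) or half the
#' keypoint scale (\code{"half_scale"}). The vector is L2-normalized,
#' clamped at 0.2, and renormalized (illumination robustness).
#'
#' @param kp Oriented keypoint (one row of \code{\link{assignOrientations}}
#'   output, as list or data frame row).
#' @param field \linkS4class{GradientField} of the keypoint's level.
#' @param sigmaGMode \code{"half_window"} or \code{"half_scale"}.
#' @return Numeric vector of length 128 with unit L2 norm, or \code{NULL}
#'   if the window contains no gradient energy.
#' @export
computeDescriptor <- function(kp, field,
                              sigmaGMode = c("half_window", "half_scale")) {
  stopifnot(is(field, "GradientField"))
  sigmaGMode <- match.arg(sigmaGMode)
  nr <- nrow(field@magnitude); nc <- ncol(field@magnitude)
  spacing <- kp$sigma
  grid <- seq_len(16L) - 8.5  # -7.5 .. 7.5 in spacing units
  u <- rep(grid, times = 16L)   # descriptor-frame x
  v <- rep(grid, each = 16L)    # descriptor-frame y
  co <- cos(kp$orientation); si <- sin(kp$orientation)
  px <- kp$x + (co * u - si * v) * spacing
  py <- kp$y + (si * u + co * v) * spacing
  # gradient taken at the nearest pixel of each (rotated) sample point
  ri <- pmin(pmax(round(py) + 1, 1), nr)
  ci <- pmin(pmax(round(px) + 1, 1), nc)
  idx <- (ci - 1) * nr + ri
  mag <- field@magnitude[idx]
  rel <- (field@orientation[idx] - kp$orientation) %% (2 * pi)
  winWidth <- 16 * spacing
  sg <- if (sigmaGMode == "half_window") 0.5 * winWidth else 0.5 * kp$sigma
  w <- mag * exp(-((u^2 + v^2) * spacing^2) / (2 * sg^2))
  # trilinear soft assignment into 4 x 4 x 8
  cu <- u / 4 + 1.5   # fractional spatial cell, x
  cv <- v / 4 + 1.5   # fractional spatial cell, y
  ob <- rel / (pi / 4) - 0.5  # fractional orientation bin
  vec <- numeric(128L)
  u0 <- floor(cu); fu <- cu - u0
  v0 <- floor(cv); fv <- cv - v0
  o0 <- floor(ob); fo <- ob - o0
  for (du in 0:1) for (dv in 0:1) for (do in 0:1) {
    uu <- u0 + du; vv <- v0 + dv
    oo <- (o0 + do) %% 8
    ww <- w * (if (du) fu else 1 - fu) * (if (dv) fv else 1 - fv) *
      (if (do) fo else 1 - fo)
    ok <- uu >= 0 & uu <= 3 & vv >= 0 & vv <= 3 & ww > 0
    if (!any(ok)) next
    pos <- ((vv[ok] * 4 + uu[ok]) * 8 + oo[ok]) + 1
    agg <- rowsum(ww[ok], pos)
    api <- as.integer(rownames(agg))
    vec[api] <- vec[api] + agg[, 1]
  }
  nrm <- sqrt(sum(vec^2))
  if (nrm == 0) return(NULL)
  vec <- vec / nrm
  # classic single clamp + renormalize; entries are capped at 0.2 before
  # the final renormalization (which may lift them slightly above it)
  vec <- pmin(vec, 0.2)
  vec / sqrt(sum(vec^2))
}

#' Extract reduced-SIFT descriptors from a grayscale image
#'
#' Deterministic composition of the whole feature pipeline: Gaussian scale
#' stack, difference-of-Gaussians, standard-deviation threshold, scale
#' pruning, 26-neighbor extremum detection, sub-pixel localization,
#' orientation assignment and descriptor computation. Descriptors are
#' ordered by (level, y, x, orientation).
#'
#' @param image Grayscale raster, at least 8 x 8.
#' @param config Configuration list from \code{\link{finConfig}}.
#' @param contourMask Optional logical matrix (e.g. from
#'   \code{\link{extractFinContour}}); when supplied, gradient magnitudes
#'   outside the mask are zeroed before orientation and descriptor
#'   computation, confining descriptors to segmented contour structure.
#' @return A \linkS4class{DescriptorSet}.
#' @export
extractFeatures <- function(image, config = finConfig(), contourMask = NULL) {
  validateGrayImage(image, minSide = 8L)
  ss <- config$scale_space
  fe <- config$features
  stack <- buildScaleStack(image, sigma0 = ss$sigma0, k = ss$k,
                           nLevels = ss$n_levels)
  dog <- dogDifferences(stack)
  reduced <- if (identical(ss$reduce_mode, "none")) {
    unreducedDoG(dog)
  } else {
    thr <- dogThreshold(dog, pooling = ss$pooling)
    reduceScales(dog, thr, mode = ss$reduce_mode)
  }
  cands <- detectExtrema(reduced, edgeExclusion = fe$edge_exclusion)
  fields <- vector("list", length(stack@levels))
  getField <- function(i) {
    if (is.null(fields[[i]])) {
      f <- gradientField(stack@levels[[i]])
      if (!is.null(contourMask)) {
        m <- f@magnitude
        m[!contourMask] <- 0
        f <- new("GradientField", magnitude = m,
                 orientation = f@orientation)
      }
      fields[[i]] <<- f
    }
    fields[[i]]
  }
  kpRows <- list()
  vecs <- list()
  nKept <- 0L
  if (nrow(cands) > 0) for (i in seq_len(nrow(cands))) {
    kp <- localizeKeypoint(dog, cands[i, ],
                           contrastThreshold = fe$contrast_threshold,
                           edgeThreshold = fe$edge_threshold)
    if (is.null(kp)) next
    lvl <- which.min(abs(stack@sigmas - kp$sigma))
    field <- getField(lvl)
    okp <- assignOrientations(kp, field, nBins = fe$n_bins,
                              windowSigmaFactor = fe$window_sigma_factor,
                              peakMode = fe$peak_mode)
    if (nrow(okp) == 0) next
    for (j in seq_len(nrow(okp))) {
      vec <- computeDescriptor(okp[j, ], field,
                               sigmaGMode = fe$sigma_g_mode)
      if (is.null(vec)) next
      nKept <- nKept + 1L
      kpRows[[nKept]] <- okp[j, ]
      vecs[[nKept]] <- vec
    }
  }
  if (nKept == 0L) {
    kpdf <- orientedKpFrame()
    mat <- matrix(numeric(0), 0L, 128L)
  } else {
    kpdf <- do.call(rbind, kpRows)
    rownames(kpdf) <- NULL
    mat <- do.call(rbind, vecs)
    o <- order(kpdf$level, kpdf$y, kpdf$x, kpdf$orientation)
    kpdf <- kpdf[o, , drop = FALSE]
    rownames(kpdf) <- NULL
    mat <- mat[o, , drop = FALSE]
  }
  new("DescriptorSet", values = mat, keypoints = kpdf,
      configHash = finConfigHash(config))
}
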