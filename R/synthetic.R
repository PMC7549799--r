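## Synthetic dorsal-fin renderer: silhouettes from cubic Bezier outlines,
## parameterized so the three shape families (triangular, falcate, hooked)
## emerge from one tip-curl parameter, with left classes as exact mirrors.

curlBands <- list(triangular = c(0, 0.15), falcate = c(0.35, 0.6),
                  hooked = c(0.75, 1.0))

finShapeFamily <- function(label) sub("^(right|left)_", "", label)

#' Mirror a class label across the body axis
#'
#' @param label One of \code{\link{finClasses}}.
#' @return The corresponding opposite-flank label.
#' @export
mirrorLabel <- function(label) {
  if (grepl("^right_", label)) sub("^right_", "left_", label)
  else sub("^left_", "right_", label)
}

#' Specification of one synthetic dorsal-fin image
#'
#' Bundles and validates the generator parameters. \code{tipCurl} drives
#' the shape family — near 0 the outline is triangular (straight edges),
#' mid-range values give the falcate concave trailing edge, high values a
#' hooked curled tip — and must lie in its class band: triangular
#' [0, 0.15], falcate [0.35, 0.6], hooked [0.75, 1.0]. Left-flank classes
#' are exact horizontal mirrors of the right-flank geometry.
#'
#' @param label One of \code{\link{finClasses}}.
#' @param heightPx,widthPx Raster size in pixels; default 96 x 96.
#' @param tipCurl Shape parameter in [0,1]; default is the midpoint of the
#'   class band.
#' @param baseWidthFrac Fin base width as a fraction of the frame, (0,1).
#' @param rotationDeg In-plane rotation, degrees in [-15, 15].
#' @param scale Size factor in [0.5, 2] about the fin centroid.
#' @param noiseSigma Standard deviation of additive zero-mean Gaussian
#'   luminance noise; >= 0.
#' @param background \code{"flat"} or \code{"sea_texture"} (low-frequency
#'   sinusoid mixture emulating the sea surface the fin can blend into).
#' @param seed Integer seed; the render is fully determined by it.
#' @return Validated spec (list).
#' @export
finSpec <- function(label, heightPx = 96L, widthPx = 96L, tipCurl = NULL,
                    baseWidthFrac = 0.45, rotationDeg = 0, scale = 1,
                    noiseSigma = 0, background = c("flat", "sea_texture"),
                    seed = 1L) {
  if (!label %in% finClasses())
    stop(sprintf("spec error: unknown label '%s'", label))
  background <- match.arg(background)
  band <- curlBands[[finShapeFamily(label)]]
  if (is.null(tipCurl)) tipCurl <- mean(band)
  if (tipCurl < band[1] || tipCurl > band[2])
    stop(sprintf(
      "spec error: tipCurl %.3f outside the %s band [%.2f, %.2f]",
      tipCurl, finShapeFamily(label), band[1], band[2]))
  if (baseWidthFrac <= 0 || baseWidthFrac >= 1)
    stop("spec error: baseWidthFrac must be in (0,1)")
  if (abs(rotationDeg) > 15) stop("spec error: rotationDeg outside [-15,15]")
  if (scale < 0.5 || scale > 2) stop("spec error: scale outside [0.5,2]")
  if (noiseSigma < 0) stop("spec error: noiseSigma must be >= 0")
  list(label = label, heightPx = as.integer(heightPx),
       widthPx = as.integer(widthPx), tipCurl = tipCurl,
       baseWidthFrac = baseWidthFrac, rotationDeg = rotationDeg,
       scale = scale, noiseSigma = noiseSigma, background = background,
       seed = as.integer(seed))
}

# Cubic Bezier sampled at nPts parameter values (excluding the end point).
bezier <- function(p0, c1, c2, p3, nPts = 80L) {
  t <- seq(0, 1, length.out = nPts + 1L)[-(nPts + 1L)]
  b0 <- (1 - t)^3; b1 <- 3 * (1 - t)^2 * t; b2 <- 3 * (1 - t) * t^2; b3 <- t^3
  cbind(b0 * p0[1] + b1 * c1[1] + b2 * c2[1] + b3 * p3[1],
        b0 * p0[2] + b1 * c1[2] + b2 * c2[2] + b3 * p3[2])
}

# Right-facing fin outline polygon in unit coordinates (x right, y down).
finOutline <- function(tipCurl, baseWidthFrac) {
  yb <- 0.88; cx <- 0.46
  b1 <- c(cx - baseWidthFrac / 2, yb)        # front (left) base corner
  b2 <- c(cx + baseWidthFrac / 2, yb)        # rear (right) base corner
  tip <- c(cx + 0.06 + 0.30 * tipCurl, 0.16 + 0.20 * tipCurl)
  # leading edge: slight convex bulge toward the front
  chordL <- tip - b1
  nL <- c(chordL[2], -chordL[1]) / sqrt(sum(chordL^2))  # front-side normal
  lead <- bezier(b1, b1 + chordL / 3 + nL * 0.05,
                 b1 + 2 * chordL / 3 + nL * 0.04, tip)
  # trailing edge: concavity and tip curl grow with tipCurl
  chordT <- b2 - tip
  nT <- c(-chordT[2], chordT[1]) / sqrt(sum(chordT^2))  # toward fin interior
  c1 <- tip + chordT * 0.25 + nT * (0.02 + 0.30 * tipCurl)
  c2 <- tip + chordT * 0.65 + nT * (0.01 + 0.12 * tipCurl)
  trail <- bezier(tip, c1, c2, b2)
  base <- bezier(b2, b2 + (b1 - b2) / 3, b2 + 2 * (b1 - b2) / 3, b1, 20L)
  rbind(lead, trail, base)
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
pointsInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    if (y1 != y2) {
      cross <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Render one synthetic dorsal-fin sample
#'
#' Renders a filled fin silhouette (luminance 0.25) from its cubic-curve
#' outline, rotated and scaled about the outline centroid, composited over
#' the background (flat 0.75 or a sea texture), anti-aliased by 3 x 3
#' supersampling, then overlaid with zero-mean Gaussian noise and clipped
#' to [0,1]. The ground-truth contour mask marks the rendered outline
#' pixels before noise. Left-flank classes are produced by rendering the
#' mirrored right-flank geometry and flipping the raster (noise included),
#' so mirror pairs are exact horizontal flips of each other.
#'
#' @param spec A \code{\link{finSpec}}.
#' @return A \linkS4class{FinSample}.
#' @export
generateFin <- function(spec) {
  if (grepl("^left_", spec$label)) {
    rspec <- spec
    rspec$label <- mirrorLabel(spec$label)
    rspec$rotationDeg <- -spec$rotationDeg
    rs <- generateFin(rspec)
    return(new("FinSample",
               image = rs@image[, rev(seq_len(ncol(rs@image))), drop = FALSE],
               contourTruth = rs@contourTruth[, rev(seq_len(ncol(rs@contourTruth))),
                                              drop = FALSE],
               label = spec$label, spec = spec))
  }
  h <- spec$heightPx; w <- spec$widthPx
  poly <- finOutline(spec$tipCurl, spec$baseWidthFrac)
  ctr <- colMeans(poly)
  a <- spec$rotationDeg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
  poly <- sweep(sweep(poly, 2L, ctr) %*% t(R) * spec$scale, 2L, ctr, `+`)
  # unit coords -> pixel coords (pixel centers at 0 .. w-1 / h-1)
  polyPx <- cbind(poly[, 1] * (w - 1), poly[, 2] * (h - 1))
  # 3 x 3 supersampled coverage
  off <- c(-1 / 3, 0, 1 / 3)
  cov <- matrix(0, h, w)
  gx <- rep(0:(w - 1), each = h)
  gy <- rep(0:(h - 1), times = w)
  for (ox in off) for (oy in off) {
    cov <- cov + pointsInPolygon(gx + ox, gy + oy, polyPx)
  }
  cov <- cov / 9
  img <- withLocalSeed(spec$seed, {
    bg <- if (spec$background == "flat") {
      matrix(0.75, h, w)
    } else {
      tex <- matrix(0.75, h, w)
      for (i in 1:3) {
        fr <- stats::runif(2, 0.5, 3) / c(w, h)
        ph <- stats::runif(1, 0, 2 * pi)
        amp <- stats::runif(1, 0.02, 0.05)
        tex <- tex + amp * sin(2 * pi * (outer(0:(h - 1) * fr[2],
                                               0:(w - 1) * fr[1], `+`)) + ph)
      }
      tex <- tex + matrix(stats::rnorm(h * w, 0, 0.015), h, w)
      pmin(pmax(tex, 0.55), 0.95)
    }
    out <- bg + (0.25 - bg) * cov
    if (spec$noiseSigma > 0)
      out <- out + matrix(stats::rnorm(h * w, 0, spec$noiseSigma), h, w)
    pmin(pmax(out, 0), 1)
  })
  # ground-truth contour: dense boundary samples marked on the pixel grid
  truth <- matrix(FALSE, h, w)
  seg <- rbind(polyPx, polyPx[1, ])
  for (i in seq_len(nrow(polyPx))) {
    p <- seg[i, ]; q <- seg[i + 1, ]
    nSub <- max(2L, ceiling(sqrt(sum((q - p)^2)) * 2))
    t <- seq(0, 1, length.out = nSub)
    xs <- pmin(pmax(round(p[1] + t * (q[1] - p[1])), 0), w - 1)
    ys <- pmin(pmax(round(p[2] + t * (q[2] - p[2])), 0), h - 1)
    truth[cbind(ys + 1, xs + 1)] <- TRUE
  }
  new("FinSample", image = img, contourTruth = truth, label = spec$label,
      spec = spec)
}

#' Generate a labelled synthetic dataset
#'
#' Renders \code{nPerClass} samples for each of the six classes in declared
#' class order. Per-sample seeds are derived arithmetically as
#' \code{baseSeed * 10000 + index} so datasets are reproducible and no
#' global random state is consumed. With \code{jitter = TRUE} (default) the
#' rotation (±10 deg), scale ([0.85, 1.2]), tip curl (within the class
#' band) and base width ([0.40, 0.50]) vary per sample.
#'
#' @param nPerClass Samples per class, >= 1.
#' @param baseSeed Integer base seed.
#' @param noiseSigma Gaussian noise level; default 0.02.
#' @param jitter Randomize geometry within class bounds; default TRUE.
#' @param background \code{"flat"} or \code{"sea_texture"}.
#' @param heightPx,widthPx Raster size; default 96 x 96.
#' @return List of \linkS4class{FinSample}, length \code{6 * nPerClass}.
#' @export
generateDataset <- function(nPerClass, baseSeed = 1L, noiseSigma = 0.02,
                            jitter = TRUE, background = "flat",
                            heightPx = 96L, widthPx = 96L) {
  nPerClass <- as.integer(nPerClass)
  if (nPerClass < 1L) stop("nPerClass must be >= 1")
  samples <- vector("list", 6L * nPerClass)
  idx <- 0L
  for (cl in finClasses()) {
    band <- curlBands[[finShapeFamily(cl)]]
    for (j in seq_len(nPerClass)) {
      idx <- idx + 1L
      seedI <- baseSeed * 10000 + idx
      pars <- if (jitter) {
        withLocalSeed(seedI, list(
          tipCurl = stats::runif(1, band[1], band[2]),
          rotationDeg = stats::runif(1, -10, 10),
          scale = stats::runif(1, 0.85, 1.2),
          baseWidthFrac = stats::runif(1, 0.40, 0.50)))
      } else {
        list(tipCurl = mean(band), rotationDeg = 0, scale = 1,
             baseWidthFrac = 0.45)
      }
      spec <- finSpec(cl, heightPx = heightPx, widthPx = widthPx,
                      tipCurl = pars$tipCurl,
                      baseWidthFrac = pars$baseWidthFrac,
                      rotationDeg = pars$rotationDeg, scale = pars$scale,
                      noiseSigma = noiseSigma, background = background,
                      seed = seedI)
      samples[[idx]] <- generateFin(spec)
    }
  }
  samples
}

#' Stratified train/test split
#'
#' Splits sample indices per class so train/test counts within each class
#' differ by at most one from the requested fraction.
#'
#' @param labels Character vector of class labels.
#' @param trainFrac Fraction assigned to training; default 0.5.
#' @param seed Integer seed for the within-class shuffle.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(labels, trainFrac = 0.5, seed = 1L) {
  if (trainFrac <= 0 || trainFrac >= 1)
    stop("trainFrac must be in (0,1)")
  train <- integer(0)
  withLocalSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      nTrain <- round(length(idx) * trainFrac)
      train <- c(train, idx[seq_len(nTrain)])
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Write a synthetic dataset to disk
#'
#' Writes one PNG per sample, ground-truth contour masks as PNGs, and a
#' \code{manifest.csv} with columns \code{path,label,x0,y0,x1,y1} (the ROI
#' is the full frame).
#'
#' @param samples List of \linkS4class{FinSample}.
#' @param dir Output directory (created if missing).
#' @param writeMasks Also write truth masks; default TRUE.
#' @return Path to the manifest, invisibly.
#' @export
writeFinDataset <- function(samples, dir, writeMasks = TRUE) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  if (writeMasks)
    dir.create(file.path(dir, "masks"), recursive = TRUE,
               showWarnings = FALSE)
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    fn <- sprintf("images/%04d_%s.png", i, s@label)
    png::writePNG(s@image, file.path(dir, fn))
    if (writeMasks)
      png::writePNG(s@contourTruth * 1,
                    file.path(dir, sprintf("masks/%04d_%s.png", i, s@label)))
    rows[[i]] <- data.frame(path = fn, label = s@label, x0 = 0L, y0 = 0L,
                            x1 = ncol(s@image), y1 = nrow(s@image))
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}
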