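# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain double loops so they share no code with the implementation.

randMat <- function(nr, nc, seed, lo = 0, hi = 1) {
  set.seed(seed)
  matrix(runif(nr * nc, lo, hi), nr, nc)
}

# direct 2-D convolution with clamped (replicate) indexing
bfConvolveClamped <- function(img, kernel) {
  r <- (nrow(kernel) - 1L) / 2L
  out <- matrix(0, nrow(img), ncol(img))
  for (y in seq_len(nrow(img))) for (x in seq_len(ncol(img))) {
    acc <- 0
    for (dy in -r:r) for (dx in -r:r) {
      yy <- min(max(y + dy, 1L), nrow(img))
      xx <- min(max(x + dx, 1L), ncol(img))
      acc <- acc + kernel[dy + r + 1L, dx + r + 1L] * img[yy, xx]
    }
    out[y, x] <- acc
  }
  out
}

mkDoG <- function(diffs, sigmas = 1.6 * sqrt(2)^(seq_along(diffs) - 1L)) {
  new("DoGStack", diffs = diffs, sigmas = sigmas)
}

# pooled population std of DoG samples around the elementwise mean raster
bfPooledStd <- function(diffs) {
  n <- length(diffs)
  mbar <- Reduce(`+`, diffs) / n
  tot <- 0
  for (m in seq_len(n)) tot <- tot + sum((diffs[[m]] - mbar)^2)
  sqrt(tot / (n * length(mbar)))
}

# exhaustive 26-neighbor extremum scan
bfExtrema <- function(diffs, retained, e) {
  nr <- nrow(diffs[[1]]); nc <- ncol(diffs[[1]]); n <- length(diffs)
  hits <- NULL
  for (m in 2:(n - 1L)) for (r in (e + 1L):(nr - e)) for (c in (e + 1L):(nc - e)) {
    if (!retained[[m]][r, c]) next
    v <- diffs[[m]][r, c]
    gt <- TRUE; lt <- TRUE
    for (dz in -1:1) for (dr in -1:1) for (dc in -1:1) {
      if (dz == 0 && dr == 0 && dc == 0) next
      nb <- diffs[[m + dz]][r + dr, c + dc]
      gt <- gt && v > nb
      lt <- lt && v < nb
    }
    if (gt || lt)
      hits <- rbind(hits, data.frame(x = c - 1L, y = r - 1L, level = m))
  }
  hits
}

# AUC by all-pairs counting: P(s+ > s-) + 0.5 P(s+ == s-)
bfAUC <- function(scores, truth) {
  sp <- scores[truth]; sn <- scores[!truth]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# a small fin image cached per session
cleanFin <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateFin(finSpec("right_falcate", noiseSigma = 0,
                                    seed = 11))
    cache
  }
})
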