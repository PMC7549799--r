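#' Load a photograph as a grayscale raster
#'
#' Reads a PNG, JPEG or TIFF file and returns a luminance matrix in
#' \code{[0,1]}. Color images are converted with the fixed ITU-style weights
#' 0.299 R + 0.587 G + 0.114 B so results do not depend on the decoder;
#' 8-bit samples are divided by 255 (the png/jpeg/tiff readers already do
#' this) and 16-bit samples by 65535. An alpha channel, if present, is
#' ignored.
#'
#' @param path Path to an image file; format chosen by extension
#'   (\code{.png}, \code{.jpg}/\code{.jpeg}, \code{.tif}/\code{.tiff}).
#' @return Numeric matrix, rows = image rows (y), columns = x, values in
#'   \code{[0,1]}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(1, 4, 4), f)
#' img <- loadImage(f)
#' stopifnot(all(img == 1))
loadImage <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("path must be a single file path")
  if (!file.exists(path))
    stop(sprintf("input error: file '%s' does not exist", path))
  if (file.size(path) == 0)
    stop(sprintf("format error: file '%s' is empty", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("format error: unsupported image extension '.%s'", ext)))
  if (is.null(dim(arr)) || length(arr) == 0)
    stop(sprintf("format error: '%s' decoded to an empty raster", path))
  img <- if (length(dim(arr)) == 2L) {
    arr
  } else {
    nch <- dim(arr)[3]
    if (nch >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]  # gray(+alpha)
    }
  }
  img <- pmin(pmax(img, 0), 1)
  validateGrayImage(img)
  img
}

#' Crop a rectangular region of interest
#'
#' Coordinates are 0-based and half-open: the crop covers columns
#' \code{[x0, x1)} and rows \code{[y0, y1)} of the source raster, so the
#' result has shape \code{(y1 - y0) x (x1 - x0)}.
#'
#' @param image Grayscale raster (numeric matrix in \code{[0,1]}).
#' @param roi Numeric vector \code{c(x0, y0, x1, y1)}.
#' @return The cropped raster.
#' @export
#' @examples
#' m <- matrix(seq(0, 1, length.out = 16), 4, 4)
#' identical(cropRoi(m, c(0, 0, 2, 2)), m[1:2, 1:2])
cropRoi <- function(image, roi) {
  validateGrayImage(image)
  if (length(roi) != 4L || anyNA(roi))
    stop("roi must be c(x0, y0, x1, y1)")
  roi <- as.integer(roi)
  x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[3]; y1 <- roi[4]
  if (x0 < 0 || y0 < 0 || x1 > ncol(image) || y1 > nrow(image) ||
      x0 >= x1 || y0 >= y1)
    stop(sprintf(
      "bounds error: roi (%d,%d,%d,%d) invalid for a %d x %d image",
      x0, y0, x1, y1, nrow(image), ncol(image)))
  image[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]
}

#' Extract the dorsal-fin contour from a grayscale ROI
#'
#' Marks pixels whose central-difference gradient magnitude exceeds
#' \code{gradThreshold} and, when \code{minComponent > 0}, keeps only the
#' largest 8-connected component of those pixels. This is a deterministic
#' gradient-based stand-in for a full fin segmentation: on a fin silhouette
#' the surviving component traces the fin edge while isolated noise
#' responses are discarded.
#'
#' @param image Grayscale raster.
#' @param gradThreshold Positive gradient-magnitude threshold (luminance
#'   units per pixel; the central difference spans 2 px, see
#'   \code{\link{gradientField}}).
#' @param minComponent If > 0, restrict the mask to its largest 8-connected
#'   component.
#' @return Logical matrix of the same shape; \code{TRUE} marks contour
#'   pixels. A constant image yields an all-\code{FALSE} mask.
#' @export
extractFinContour <- function(image, gradThreshold = 0.25, minComponent = 1L) {
  validateGrayImage(image)
  if (gradThreshold <= 0) stop("gradThreshold must be > 0")
  field <- gradientField(image)
  mask <- field@magnitude > gradThreshold
  if (minComponent > 0 && any(mask)) {
    lab <- labelComponents8(mask)
    sizes <- tabulate(lab[lab > 0L])
    mask <- lab == which.max(sizes)
  }
  mask
}

# 8-connected component labeling by breadth-first flood fill over the TRUE
# pixels of a logical matrix. Returns an integer matrix (0 = background).
labelComponents8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nextLab <- 0L
  # neighbor linear-index offsets need row/col bounds checks; precompute
  # row and col of every pixel once
  for (start in idx) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue) > 0L) {
      cur <- queue
      queue <- integer(0)
      r <- ((cur - 1L) %% nr) + 1L
      c <- ((cur - 1L) %/% nr) + 1L
      for (dr in -1L:1L) for (dc in -1L:1L) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c + dc
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        nb <- (cc[ok] - 1L) * nr + rr[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb) > 0L) {
          lab[nb] <- nextLab
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}
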