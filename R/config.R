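#' Pipeline configuration
#'
#' Builds the nested configuration list every stage consumes. Defaults are
#' the package's reference settings: a single-octave five-level scale stack
#' at \code{sigma0 = 1.6}, \code{k = sqrt(2)}; literal signed thresholding
#' of the DoG stack; classic contrast threshold 0.03 on [0,1] luminance;
#' 36-bin orientation histograms with a 1.5-sigma Gaussian window; the
#' 80\%-of-peak orientation rule; descriptor Gaussian at half the window
#' width; mean centroid aggregation with 20 training images per class.
#'
#' @param ... Named overrides for individual fields, e.g.
#'   \code{finConfig(scale_space = list(reduce_mode = "abs_le"))} replaces
#'   just that field, keeping the remaining defaults.
#' @return Nested list with blocks \code{scale_space}, \code{features},
#'   \code{classifier}, \code{evaluation}.
#' @export
#' @examples
#' cfg <- finConfig(features = list(contrast_threshold = 0.02))
#' cfg$features$contrast_threshold
finConfig <- function(...) {
  cfg <- list(
    scale_space = list(
      sigma0 = 1.6,
      k = sqrt(2),
      n_levels = 5L,
      reduce_mode = "signed_le",  # "signed_le", "abs_le" or "none"
      pooling = "pooled"
    ),
    features = list(
      contrast_threshold = 0.03,
      n_bins = 36L,
      window_sigma_factor = 1.5,
      peak_mode = "peak80",
      sigma_g_mode = "half_window",
      edge_exclusion = 4L,
      edge_threshold = NULL       # principal-curvature filter off
    ),
    classifier = list(
      aggregator = "mean",
      n_train_per_class = 20L
    ),
    evaluation = list(
      split_seed = 1L,
      train_frac = 0.5
    )
  )
  overrides <- list(...)
  for (blk in names(overrides)) {
    if (!blk %in% names(cfg))
      stop(sprintf("unknown config block '%s'", blk))
    for (fld in names(overrides[[blk]])) {
      if (!fld %in% names(cfg[[blk]]))
        stop(sprintf("unknown config field '%s$%s'", blk, fld))
      cfg[[blk]][fld] <- overrides[[blk]][fld]
    }
  }
  cfg
}

#' Stable hash of a configuration
#'
#' Fingerprints a configuration list so artifacts (descriptor files, class
#' models) can refuse inputs extracted under different settings. Field
#' order does not affect the hash; field values do.
#'
#' @param config Configuration list (see \code{\link{finConfig}}).
#' @return 8-hex-digit character scalar.
#' @export
finConfigHash <- function(config) {
  fnv1a32(canonicalString(config))
}

#' Read a configuration from a YAML file
#'
#' Unknown fields are rejected; missing fields keep their defaults.
#'
#' @param path YAML file with any of the \code{\link{finConfig}} blocks.
#' @return Configuration list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  y <- yaml::read_yaml(path)
  if (is.null(y)) return(finConfig())
  do.call(finConfig, y)
}
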