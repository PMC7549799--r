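#' Read and validate an image manifest
#'
#' The manifest is a headered CSV with columns
#' \code{path,label,x0,y0,x1,y1}; \code{label} must be one of the six fin
#' classes and the ROI columns are 0-based half-open pixel coordinates.
#' Errors name the offending row.
#'
#' @param path Manifest CSV path.
#' @param baseDir Directory image paths are resolved against; defaults to
#'   the manifest's directory.
#' @return Data frame with absolute \code{path} column.
#' @export
readManifest <- function(path, baseDir = dirname(path)) {
  if (!file.exists(path)) stop(sprintf("manifest '%s' not found", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(m)))
    stop(sprintf("manifest must have header columns: %s",
                 paste(need, collapse = ",")))
  for (i in seq_len(nrow(m))) {
    if (!m$label[i] %in% finClasses())
      stop(sprintf("manifest row %d: unknown label '%s'", i, m$label[i]))
    if (anyNA(c(m$x0[i], m$y0[i], m$x1[i], m$y1[i])) ||
        m$x0[i] >= m$x1[i] || m$y0[i] >= m$y1[i] || m$x0[i] < 0 ||
        m$y0[i] < 0)
      stop(sprintf("manifest row %d: invalid roi", i))
  }
  m$path <- ifelse(grepl("^/", m$path), m$path, file.path(baseDir, m$path))
  m
}

#' Write descriptors to versioned JSON
#'
#' @param descSet A \linkS4class{DescriptorSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeDescriptors <- function(descSet, path) {
  stopifnot(is(descSet, "DescriptorSet"))
  kp <- descSet@keypoints
  descs <- lapply(seq_len(nrow(kp)), function(i)
    list(x = kp$x[i], y = kp$y[i], sigma = kp$sigma[i],
         orientation = kp$orientation[i], level = kp$level[i],
         contrast = kp$contrast[i],
         values = unname(descSet@values[i, ])))
  obj <- list(version = 1L, type = "finprint_descriptors",
              config_hash = descSet@configHash, descriptors = descs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read descriptors from JSON
#'
#' @param path File written by \code{\link{writeDescriptors}}.
#' @return A \linkS4class{DescriptorSet}.
#' @export
readDescriptors <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$type, "finprint_descriptors"))
    stop("format error: not a finprint descriptor file")
  n <- length(obj$descriptors)
  if (n == 0L) {
    return(new("DescriptorSet", values = matrix(numeric(0), 0L, 128L),
               keypoints = orientedKpFrame(),
               configHash = obj$config_hash))
  }
  kp <- do.call(rbind, lapply(obj$descriptors, function(d)
    data.frame(x = d$x, y = d$y, level = as.integer(d$level),
               sigma = d$sigma, orientation = d$orientation,
               contrast = d$contrast)))
  vals <- do.call(rbind, lapply(obj$descriptors, function(d)
    as.numeric(unlist(d$values))))
  new("DescriptorSet", values = vals, keypoints = kp,
      configHash = obj$config_hash)
}

logLine <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[finprint] stage=%s %s", stage,
                  paste(names(kv), kv, sep = "=", collapse = " ")))
}

extractFromManifestRow <- function(row, config) {
  img <- loadImage(row$path)
  roi <- cropRoi(img, c(row$x0, row$y0, row$x1, row$y1))
  extractFeatures(roi, config)
}

#' Run one pipeline stage
#'
#' Programmatic equivalent of the \code{finid} command-line tool; the CLI
#' is a thin wrapper over this function. Structured log lines go to stderr
#' and artifacts carry the configuration hash so stages can refuse
#' mismatched inputs.
#'
#' @param command One of \code{"synth"}, \code{"extract"}, \code{"train"},
#'   \code{"classify"}, \code{"evaluate"}.
#' @param config Configuration list (\code{\link{finConfig}}).
#' @param manifest Manifest CSV path (train/evaluate).
#' @param image Image path (extract/classify).
#' @param roi Integer vector \code{c(x0,y0,x1,y1)} (extract/classify);
#'   default full image.
#' @param model Model JSON path (classify/evaluate).
#' @param out Output path (stage-dependent; directory for synth).
#' @param aggregator Centroid aggregator for train.
#' @param nPerClass,seed,noise Synth parameters.
#' @return Stage result, invisibly: the written path (synth/extract/train),
#'   classification list (classify), or evaluation list (evaluate).
#' @export
runPipeline <- function(command, config = finConfig(), manifest = NULL,
                        image = NULL, roi = NULL, model = NULL, out = NULL,
                        aggregator = "mean", nPerClass = 20L, seed = 7L,
                        noise = 0.02) {
  command <- match.arg(command,
                       c("synth", "extract", "train", "classify", "evaluate"))
  t0 <- proc.time()[["elapsed"]]
  res <- switch(command,
    synth = {
      if (is.null(out)) stop("synth requires an output directory")
      samples <- generateDataset(nPerClass, baseSeed = seed,
                                 noiseSigma = noise)
      mpath <- writeFinDataset(samples, out)
      logLine("synth", n = length(samples), out = out)
      mpath
    },
    extract = {
      if (is.null(image)) stop("extract requires --image")
      img <- loadImage(image)
      if (!is.null(roi)) img <- cropRoi(img, roi)
      ds <- extractFeatures(img, config)
      logLine("extract", n_descriptors = nrow(descriptorValues(ds)))
      if (!is.null(out)) writeDescriptors(ds, out)
      if (is.null(out)) ds else out
    },
    train = {
      if (is.null(manifest)) stop("train requires --manifest")
      m <- readManifest(manifest)
      sets <- lapply(seq_len(nrow(m)), function(i)
        extractFromManifestRow(m[i, ], config))
      mod <- trainClassModel(sets, m$label, aggregator = aggregator,
                             configHash = finConfigHash(config))
      logLine("train", n_images = nrow(m),
              n_descriptors = sum(vapply(sets, function(s)
                nrow(descriptorValues(s)), numeric(1))))
      if (!is.null(out)) writeClassModel(mod, out)
      if (is.null(out)) mod else out
    },
    classify = {
      if (is.null(model) || is.null(image))
        stop("classify requires --model and --image")
      mod <- if (is.character(model)) readClassModel(model) else model
      if (nzchar(configHash(mod)) &&
          !identical(configHash(mod), finConfigHash(config)))
        stop(sprintf(
          "refusal: model config hash %s does not match current config %s",
          configHash(mod), finConfigHash(config)))
      img <- loadImage(image)
      if (!is.null(roi)) img <- cropRoi(img, roi)
      ds <- extractFeatures(img, config)
      mr <- classifyFin(ds, mod)
      logLine("classify", predicted = predictedClass(mr),
              n_descriptors = mr@nSampleDescriptors)
      resList <- list(predicted = predictedClass(mr),
                      distances = as.list(classDistances(mr)))
      if (!is.null(out))
        jsonlite::write_json(resList, out, auto_unbox = TRUE, digits = NA)
      resList
    },
    evaluate = {
      if (is.null(model) || is.null(manifest))
        stop("evaluate requires --model and --manifest")
      mod <- if (is.character(model)) readClassModel(model) else model
      if (nzchar(configHash(mod)) &&
          !identical(configHash(mod), finConfigHash(config)))
        stop(sprintf(
          "refusal: model config hash %s does not match current config %s",
          configHash(mod), finConfigHash(config)))
      m <- readManifest(manifest)
      sets <- lapply(seq_len(nrow(m)), function(i)
        extractFromManifestRow(m[i, ], config))
      ev <- evaluateClassifier(mod, sets, m$label)
      logLine("evaluate", n_images = nrow(m),
              macro_acc = sprintf("%.4f",
                ev$report$acc[ev$report$class == "macro"]))
      if (!is.null(out)) {
        if (grepl("\\.json$", out)) {
          jsonlite::write_json(ev$report, out, auto_unbox = TRUE,
                               digits = NA, dataframe = "rows")
        } else {
          utils::write.csv(ev$report, out, row.names = FALSE)
        }
      }
      ev
    })
  logLine(command,
          elapsed_s = sprintf("%.2f", proc.time()[["elapsed"]] - t0))
  invisible(res)
}
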