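#' Write and read a field of view as multi-page TIFF
#'
#' `writeFieldTiff()` stores the image stack as one 32-bit float page per
#' frame plus a JSON sidecar (`<file>.json`) carrying the calibration, ROI
#' label and ground truth; `readFieldTiff()` reconstructs the
#' [FieldOfView-class] from the pair.
#'
#' @param fov a [FieldOfView-class].
#' @param file TIFF path.
#' @return `writeFieldTiff()` returns `file` invisibly; `readFieldTiff()`
#'   returns a [FieldOfView-class].
#' @export
writeFieldTiff <- function(fov, file) {
  rng <- range(fov@frames)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(fov@frames)[3]), function(t)
    (fov@frames[, , t] - rng[1]) / scale)   # TIFF samples live in [0, 1]
  tiff::writeTIFF(pages, file, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixelSize = fov@pixelSize, frameRate = fov@frameRate,
               roiLabel = fov@roiLabel, intensityOffset = rng[1],
               intensityScale = scale, groundTruth = fov@groundTruth)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname writeFieldTiff
#' @export
readFieldTiff <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
  metaFile <- paste0(file, ".json")
  meta <- if (file.exists(metaFile)) jsonlite::read_json(metaFile,
                                                         simplifyVector = TRUE)
  else list(pixelSize = 1, frameRate = 1, roiLabel = "", groundTruth = NULL)
  if (!is.null(meta$intensityScale))
    arr <- arr * as.numeric(meta$intensityScale) +
      as.numeric(meta$intensityOffset)
  gt <- meta$groundTruth
  if (is.null(gt) || !length(gt))
    gt <- data.frame(segmentId = integer(), x0 = numeric(), y0 = numeric(),
                     x1 = numeric(), y1 = numeric(), lengthUm = numeric(),
                     diameterUm = numeric(), velocityUmS = numeric(),
                     perfused = logical())
  new("FieldOfView", frames = arr, pixelSize = as.numeric(meta$pixelSize),
      frameRate = as.numeric(meta$frameRate), roiLabel = meta$roiLabel,
      groundTruth = as.data.frame(gt))
}

#' Write a cohort observation table as CSV
#'
#' @param cohort a [TumorCohort-class] or observations data.frame.
#' @param file CSV path.
#' @param seed optional seed recorded as a header comment.
#' @return `file`, invisibly.
#' @export
writeCohortCsv <- function(cohort, file, seed = NULL) {
  ob <- if (is(cohort, "TumorCohort")) cohort@observations else cohort
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", as.integer(seed)), con)
  utils::write.csv(ob, con, row.names = FALSE)
  invisible(file)
}

#' Read a cohort observation table written by [writeCohortCsv()]
#'
#' @param file CSV path.
#' @return data.frame of observations.
#' @export
readCohortCsv <- function(file) {
  utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
}
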