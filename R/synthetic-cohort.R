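#' Generate a synthetic tumor cohort
#'
#' Draws per-animal engraftment from a Bernoulli distribution with the
#' preset's engraftment probability. Non-engrafted animals yield a single
#' excluded-by-day-7 record. Engrafted animals receive an area series
#' `area(day) = day7Area * relAreaByDay[day]/100 * exp(eps)` with
#' `eps ~ Normal(0, noiseSigma^2)` drawn independently per observation
#' (multiplicative log-normal measurement noise), truncated after the
#' preset's censor day; when censoring applies, the last observed record is
#' flagged `censored_fracture`.
#'
#' @param preset a [GrowthPreset-class].
#' @param seed integer seed; identical `(preset, seed)` give identical output.
#' @return A [TumorCohort-class] whose `observations` also carry a
#'   `trueAreaMm2` column (the noise-free area) as ground truth.
#' @examples
#' co <- generateCohort(growthPreset("FW", "LnCap"), seed = 1)
#' head(observations(co))
#' @export
generateCohort <- function(preset, seed) {
  validObject(preset)
  set.seed(as.integer(seed))
  days <- as.numeric(names(preset@relAreaByDay))
  rows <- vector("list", preset@nImplanted)
  for (i in seq_len(preset@nImplanted)) {
    id <- sprintf("%s-%s-%02d", preset@tissue, preset@cellLine, i)
    engrafted <- stats::runif(1) < preset@engraftProb
    if (!engrafted) {
      rows[[i]] <- data.frame(
        animalId = id, tissue = preset@tissue, cellLine = preset@cellLine,
        day = 7, areaMm2 = NA_real_, trueAreaMm2 = NA_real_,
        status = "excluded_no_engraftment", stringsAsFactors = FALSE)
      next
    }
    keep <- if (is.na(preset@censorDay)) days else days[days <= preset@censorDay]
    trueArea <- preset@day7Area * preset@relAreaByDay[as.character(keep)] / 100
    eps <- stats::rnorm(length(keep), 0, preset@noiseSigma)
    status <- rep("engrafted", length(keep))
    # a censor day means observation ended with fracture-mandated sacrifice;
    # the last observed record carries the flag
    if (!is.na(preset@censorDay)) status[length(status)] <- "censored_fracture"
    rows[[i]] <- data.frame(
      animalId = id, tissue = preset@tissue, cellLine = preset@cellLine,
      day = keep, areaMm2 = unname(trueArea * exp(eps)),
      trueAreaMm2 = unname(trueArea), status = status,
      stringsAsFactors = FALSE)
  }
  new("TumorCohort", observations = do.call(rbind, rows), preset = preset,
      seed = as.integer(seed))
}

#' Render a single-channel tumor frame
#'
#' Renders an epi-illumination mCherry tumor image as a bright disk of the
#' requested area on a darker background. The disk edge is a narrow Gaussian
#' ramp whose half-maximum contour sits exactly at the nominal radius, so an
#' intensity threshold midway between the background and foreground levels
#' recovers the nominal area.
#'
#' @param areaMm2 tumor area (mm^2); 0 renders pure background.
#' @param pixelSize um/pixel (default 32 um, a low-magnification overview
#'   calibration covering a ~4 mm field at the default `dim`).
#' @param dim image size in pixels (length 2).
#' @param backgroundLevel,tumorLevel intensity levels.
#' @param edgeSigmaPx Gaussian edge softness in pixels.
#' @param noiseSd additive Gaussian noise SD (applied with the current RNG
#'   state; seed externally for reproducibility).
#' @param center disk center in pixels; defaults to the image center.
#' @return A numeric matrix of intensities.
#' @examples
#' img <- renderTumorFrame(1.0)
#' segmentTumorArea(img, pixelSize = 32)
#' @export
renderTumorFrame <- function(areaMm2, pixelSize = 32, dim = c(128L, 128L),
                             backgroundLevel = 0.1, tumorLevel = 0.8,
                             edgeSigmaPx = 0.75, noiseSd = 0.02,
                             center = NULL) {
  stopifnot(areaMm2 >= 0, pixelSize > 0)
  if (is.null(center)) center <- (dim + 1) / 2
  img <- matrix(backgroundLevel, dim[1], dim[2])
  if (areaMm2 > 0) {
    rPx <- sqrt(areaMm2 * 1e6 / pi) / pixelSize
    d <- sqrt(outer((seq_len(dim[1]) - center[1])^2,
                    (seq_len(dim[2]) - center[2])^2, "+"))
    img <- backgroundLevel +
      (tumorLevel - backgroundLevel) * stats::pnorm((rPx - d) / edgeSigmaPx)
  }
  if (noiseSd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noiseSd), dim[1])
  img
}

#' Measure a generated cohort through the imaging pipeline
#'
#' Renders every observed tumor area of a cohort as a synthetic frame and
#' re-measures it with [segmentTumorArea()], replacing `areaMm2` by the
#' segmented value. This exercises the full image-based quantification path
#' on data with known ground truth.
#'
#' @param cohort a [TumorCohort-class].
#' @param pixelSize,dim,noiseSd rendering parameters, see
#'   [renderTumorFrame()].
#' @return The cohort with `areaMm2` replaced by segmented areas (the
#'   generated areas are retained in `renderedAreaMm2`).
#' @export
measureCohortAreas <- function(cohort, pixelSize = 32, dim = c(128L, 128L),
                               noiseSd = 0.02) {
  ob <- cohort@observations
  ob$renderedAreaMm2 <- ob$areaMm2
  meas <- vapply(seq_len(nrow(ob)), function(i) {
    if (is.na(ob$areaMm2[i])) return(NA_real_)
    img <- renderTumorFrame(ob$areaMm2[i], pixelSize = pixelSize, dim = dim,
                            noiseSd = noiseSd)
    segmentTumorArea(img, pixelSize = pixelSize)
  }, numeric(1))
  ob$areaMm2 <- meas
  cohort@observations <- ob
  cohort
}
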