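#' Construct a growth preset
#'
#' @param tissue `"FW"` (bone) or `"DSC"` (striated muscle).
#' @param cellLine cell line label.
#' @param nImplanted number of chambers implanted.
#' @param engraftProb per-animal engraftment probability.
#' @param day7Area mean absolute day-7 tumor area (mm^2).
#' @param relAreaByDay named numeric vector of relative areas (%) keyed by
#'   day; the day-7 entry must equal 100.
#' @param censorDay last observed day before fracture censoring, or `NA`.
#' @param noiseSigma log-scale SD of multiplicative area measurement noise.
#' @return A validated [GrowthPreset-class] object.
#' @examples
#' growthPreset("FW", "LnCap")
#' GrowthPreset("DSC", "Test", nImplanted = 10, engraftProb = 0.5,
#'              day7Area = 1, relAreaByDay = c("7" = 100, "14" = 200))
#' @export
GrowthPreset <- function(tissue, cellLine, nImplanted, engraftProb,
                         day7Area, relAreaByDay, censorDay = NA_real_,
                         noiseSigma = 0.15) {
  new("GrowthPreset", tissue = tissue, cellLine = cellLine,
      nImplanted = as.integer(nImplanted), engraftProb = engraftProb,
      day7Area = day7Area, relAreaByDay = relAreaByDay,
      censorDay = as.numeric(censorDay), noiseSigma = noiseSigma)
}

#' Shipped cohort presets for the six tissue x cell-line groups
#'
#' Returns the six experimental groups: LnCap, Du145 and Pc3 prostate cancer
#' cells implanted either in cancellous femoral bone (femur window, 15
#' chambers per group) or in striated muscle (dorsal skinfold chamber, 20
#' chambers per group). Engraftment probabilities encode the observed take
#' rates (93% bone / 70% muscle for LnCap and Du145, 67% / 45% for Pc3).
#' Relative growth anchors (day 7 = 100%) encode the observed weekly values;
#' where only the day-21 value is reported (muscle groups), the day-14 anchor
#' is the log-linear interpolant. Day-7 absolute areas encode the 2-fold
#' larger initial tumor size in muscle relative to bone, and the ~50% smaller
#' initial Pc3 burden. Bone LnCap observation ends after day 14 and bone Pc3
#' after day 21 (fracture censoring).
#'
#' @param noiseSigma log-scale SD of multiplicative area noise applied to all
#'   presets (default 0.15).
#' @return For `growthPresets()`, a named list of [GrowthPreset-class]
#'   objects keyed `"<tissue>:<cellLine>"`; for `growthPreset()`, the single
#'   requested preset.
#' @examples
#' names(growthPresets())
#' growthPreset("FW", "Pc3")
#' @export
growthPresets <- function(noiseSigma = 0.15) {
  gp <- function(...) GrowthPreset(..., noiseSigma = noiseSigma)
  list(
    "FW:LnCap" = gp("FW", "LnCap", 15, 14 / 15, 1.0,
                    c("7" = 100, "14" = 382), censorDay = 14),
    "FW:Du145" = gp("FW", "Du145", 15, 14 / 15, 1.0,
                    c("7" = 100, "14" = 250, "21" = 340)),
    "FW:Pc3"   = gp("FW", "Pc3", 15, 10 / 15, 0.5,
                    c("7" = 100, "14" = 274, "21" = 730), censorDay = 21),
    "DSC:LnCap" = gp("DSC", "LnCap", 20, 14 / 20, 2.0,
                     c("7" = 100, "14" = 100 * sqrt(2.05), "21" = 205)),
    "DSC:Du145" = gp("DSC", "Du145", 20, 14 / 20, 2.0,
                     c("7" = 100, "14" = 150, "21" = 225)),
    "DSC:Pc3"  = gp("DSC", "Pc3", 20, 9 / 20, 1.0,
                    c("7" = 100, "14" = 100 * sqrt(2.10), "21" = 210))
  )
}

#' @rdname growthPresets
#' @param tissue,cellLine group selector.
#' @export
growthPreset <- function(tissue, cellLine, noiseSigma = 0.15) {
  key <- paste0(tissue, ":", cellLine)
  presets <- growthPresets(noiseSigma = noiseSigma)
  if (!key %in% names(presets))
    stop("unknown tissue/cell-line combination: ", key, call. = FALSE)
  presets[[key]]
}

#' Construct vessel-field rendering parameters
#'
#' Defaults describe a 20x intravital recording: 0.5 um/pixel, 10-s recording.
#' The default frame rate (20 frames/s) keeps the inter-frame displacement of
#' the fastest default vessels below a quarter of a typical centerline length
#' so that kymograph cross-correlation is unambiguous.
#'
#' @param fieldSize field extent in um (length 2).
#' @param pixelSize um per pixel.
#' @param nSegments number of vessel segments.
#' @param diameterRange diameter range in um.
#' @param velocityRange centerline velocity range in um/s.
#' @param perfusedFraction probability that a segment is perfused.
#' @param frameRate frames per second.
#' @param duration recording duration in s.
#' @param backgroundLevel,vesselLevel intensity levels (arbitrary units).
#' @param noiseSd additive Gaussian intensity noise SD.
#' @param gapDepth fractional intensity drop inside erythrocyte gaps.
#' @param gapWidthUm Gaussian half-width of a gap (um).
#' @param gapSpacingUm mean spacing between gaps along the vessel (um).
#' @return A validated [VesselFieldParams-class] object.
#' @examples
#' vesselFieldParams(nSegments = 3)
#' @export
vesselFieldParams <- function(fieldSize = c(200, 200), pixelSize = 0.5,
                              nSegments = 4L, diameterRange = c(8, 18),
                              velocityRange = c(150, 600),
                              perfusedFraction = 0.85, frameRate = 20,
                              duration = 10, backgroundLevel = 0.1,
                              vesselLevel = 1.0, noiseSd = 0,
                              gapDepth = 0.6, gapWidthUm = 4,
                              gapSpacingUm = 40) {
  new("VesselFieldParams", fieldSize = fieldSize, pixelSize = pixelSize,
      nSegments = as.integer(nSegments), diameterRange = diameterRange,
      velocityRange = velocityRange, perfusedFraction = perfusedFraction,
      frameRate = frameRate, duration = duration,
      backgroundLevel = backgroundLevel, vesselLevel = vesselLevel,
      noiseSd = noiseSd, gapDepth = gapDepth, gapWidthUm = gapWidthUm,
      gapSpacingUm = gapSpacingUm)
}
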