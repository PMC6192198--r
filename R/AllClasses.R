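#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Growth preset for one tissue x cell-line group
#'
#' A `GrowthPreset` bundles the experimental-design parameters of one cohort:
#' how many chambers were implanted, the engraftment probability, the absolute
#' day-7 tumor area, the relative growth trajectory (day 7 defined as 100%),
#' the day after which femur fracture terminates observation (bone cohorts with
#' rapid growth), and the log-scale standard deviation of multiplicative
#' measurement noise on areas.
#'
#' @slot tissue character, `"FW"` (femur window, bone) or `"DSC"` (dorsal
#'   skinfold chamber, striated muscle).
#' @slot cellLine character, one of `"LnCap"`, `"Du145"`, `"Pc3"`.
#' @slot nImplanted integer, number of chambers implanted.
#' @slot engraftProb numeric in `[0, 1]`, per-animal engraftment probability.
#' @slot day7Area numeric, mean absolute tumor area on day 7 (mm^2).
#' @slot relAreaByDay named numeric, relative area (%) by observation day;
#'   the day-7 entry is 100 by definition.
#' @slot censorDay numeric, last observed day before fracture-mandated
#'   sacrifice, or `NA` when no censoring applies.
#' @slot noiseSigma numeric, SD of the log-normal multiplicative noise on
#'   measured areas.
#' @seealso [growthPreset()], [growthPresets()], [generateCohort()]
#' @exportClass GrowthPreset
setClass("GrowthPreset",
  representation(
    tissue = "character",
    cellLine = "character",
    nImplanted = "integer",
    engraftProb = "numeric",
    day7Area = "numeric",
    relAreaByDay = "numeric",
    censorDay = "numeric",
    noiseSigma = "numeric"
  )
)

setValidity("GrowthPreset", function(object) {
  msg <- character()
  if (!object@tissue %in% c("FW", "DSC"))
    msg <- c(msg, "tissue must be 'FW' or 'DSC'")
  if (length(object@nImplanted) != 1L || object@nImplanted <= 0L)
    msg <- c(msg, "nImplanted must be a positive count")
  if (object@engraftProb < 0 || object@engraftProb > 1)
    msg <- c(msg, "engraftProb must lie in [0, 1]")
  if (object@day7Area <= 0)
    msg <- c(msg, "day7Area must be positive")
  days <- as.numeric(names(object@relAreaByDay))
  if (anyNA(days) || is.unsorted(days, strictly = TRUE))
    msg <- c(msg, "relAreaByDay must be named by strictly increasing days")
  if (!"7" %in% names(object@relAreaByDay) ||
      !isTRUE(all.equal(unname(object@relAreaByDay["7"]), 100)))
    msg <- c(msg, "relAreaByDay must fix day 7 at 100")
  if (is.unsorted(object@relAreaByDay))
    msg <- c(msg, "relAreaByDay must be non-decreasing in day")
  if (object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Rendering parameters for a synthetic microvessel field
#'
#' Describes the geometry, optics and dynamics of a synthetic field of view:
#' field extent and pixel calibration, number of vessel segments with their
#' diameter and centerline-velocity regimes, the fraction of perfused
#' segments, frame rate and recording duration, intensity levels and noise.
#' Perfused vessels are rendered as bright plasma columns (FITC-dextran
#' contrast) interrupted by dark erythrocyte gaps advected at the true
#' velocity; the tube cross-section is Gaussian with FWHM equal to the true
#' diameter.
#'
#' @slot fieldSize numeric length-2, field extent (um).
#' @slot pixelSize numeric, pixel pitch (um/pixel).
#' @slot nSegments integer, number of vessel segments to place.
#' @slot diameterRange numeric length-2, diameter range (um); the lower bound
#'   must be at least two pixels to stay resolvable.
#' @slot velocityRange numeric length-2, centerline velocity range (um/s).
#' @slot perfusedFraction numeric in `[0, 1]`.
#' @slot frameRate numeric, frames/s.
#' @slot duration numeric, recording duration (s); at least 10 s when
#'   velocimetry is intended.
#' @slot backgroundLevel,vesselLevel numeric, intensity levels (arbitrary
#'   units).
#' @slot noiseSd numeric, SD of additive Gaussian intensity noise.
#' @slot gapDepth numeric in `[0, 1]`, fractional intensity drop inside an
#'   erythrocyte gap.
#' @slot gapWidthUm,gapSpacingUm numeric, Gaussian half-width and mean spacing
#'   of the advected gaps (um).
#' @seealso [vesselFieldParams()], [generateVesselField()]
#' @exportClass VesselFieldParams
setClass("VesselFieldParams",
  representation(
    fieldSize = "numeric",
    pixelSize = "numeric",
    nSegments = "integer",
    diameterRange = "numeric",
    velocityRange = "numeric",
    perfusedFraction = "numeric",
    frameRate = "numeric",
    duration = "numeric",
    backgroundLevel = "numeric",
    vesselLevel = "numeric",
    noiseSd = "numeric",
    gapDepth = "numeric",
    gapWidthUm = "numeric",
    gapSpacingUm = "numeric"
  )
)

setValidity("VesselFieldParams", function(object) {
  msg <- character()
  if (length(object@fieldSize) != 2L || any(object@fieldSize <= 0))
    msg <- c(msg, "fieldSize must be two positive extents (um)")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (object@nSegments < 0L) msg <- c(msg, "nSegments must be non-negative")
  if (length(object@diameterRange) != 2L ||
      object@diameterRange[1] > object@diameterRange[2])
    msg <- c(msg, "diameterRange must be an increasing pair")
  if (object@diameterRange[1] < 2 * object@pixelSize)
    msg <- c(msg, "smallest diameter must be at least 2 pixels to be resolvable")
  if (object@perfusedFraction < 0 || object@perfusedFraction > 1)
    msg <- c(msg, "perfusedFraction must lie in [0, 1]")
  if (object@frameRate <= 0 || object@duration <= 0)
    msg <- c(msg, "frameRate and duration must be positive")
  if (any(object@velocityRange > 0) && object@duration < 10)
    msg <- c(msg, "duration must be >= 10 s when velocity estimation is intended")
  if (object@gapDepth < 0 || object@gapDepth > 1)
    msg <- c(msg, "gapDepth must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A recorded field of view
#'
#' Container for one recorded region of interest: the image stack (x, y, time;
#' FITC vessel channel), its spatial and temporal calibration, the ROI label
#' of the three-ROI scheme (two border, one center), and -- for synthetic
#' fields -- the per-segment ground truth used in parameter-recovery tests.
#'
#' @slot frames 3-d numeric array `[x, y, t]` of intensities.
#' @slot pixelSize numeric, um/pixel.
#' @slot frameRate numeric, frames/s.
#' @slot roiLabel character, one of `"border_1"`, `"border_2"`, `"center"`,
#'   or `""` when unassigned.
#' @slot groundTruth data.frame of true segment geometry (possibly empty):
#'   columns `segmentId`, `x0`, `y0`, `x1`, `y1` (um, clipped to the field),
#'   `lengthUm`, `diameterUm`, `velocityUmS`, `perfused`.
#' @seealso [generateVesselField()], [segmentVessels()], [quantifyField()]
#' @exportClass FieldOfView
setClass("FieldOfView",
  representation(
    frames = "array",
    pixelSize = "numeric",
    frameRate = "numeric",
    roiLabel = "character",
    groundTruth = "data.frame"
  )
)

setValidity("FieldOfView", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3-d array [x, y, t]")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (length(msg)) msg else TRUE
})

#' An intermittent extravasation intensity trace
#'
#' Whole-image mean fluorescence intensity sampled intermittently after
#' intravenous FITC-albumin injection, together with the constants entering
#' the effective-permeability model: `I0` (intensity immediately after vessel
#' filling), `Ib` (background), microvascular hematocrit `HT`, plasma
#' clearance time constant `K` (s), and the vessel volume-to-surface ratio
#' `V/S` (um).
#'
#' @slot times numeric, sample times (s), strictly increasing.
#' @slot intensity numeric, mean image intensity per sample.
#' @slot I0 numeric, intensity immediately after filling of all vessels.
#' @slot Ib numeric, background intensity; `I0 > Ib` required.
#' @slot HT numeric, microvascular hematocrit fraction in [0, 1] (default
#'   0.19; at 1 the plasma fraction vanishes and P is 0).
#' @slot K numeric, BSA plasma clearance time constant (s, default 9100).
#' @slot vsRatio numeric, vessel volume-to-surface ratio V/S (um).
#' @seealso [generatePermeabilityTrace()], [estimatePermeability()]
#' @exportClass PermeabilityTrace
setClass("PermeabilityTrace",
  representation(
    times = "numeric",
    intensity = "numeric",
    I0 = "numeric",
    Ib = "numeric",
    HT = "numeric",
    K = "numeric",
    vsRatio = "numeric"
  )
)

setValidity("PermeabilityTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@intensity))
    msg <- c(msg, "times and intensity must have equal length")
  if (length(object@times) < 3L)
    msg <- c(msg, "at least 3 samples are required")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (!(object@I0 > object@Ib))
    msg <- c(msg, "I0 must exceed Ib")
  if (object@HT < 0 || object@HT > 1)
    msg <- c(msg, "HT must lie in [0, 1]")
  if (object@K <= 0) msg <- c(msg, "K must be positive")
  if (object@vsRatio <= 0) msg <- c(msg, "vsRatio must be positive")
  if (length(msg)) msg else TRUE
})

#' A generated tumor cohort
#'
#' Per-animal, per-day tumor observations generated from a [GrowthPreset],
#' together with the preset and the generating seed. The `observations`
#' data.frame has one row per scheduled observation with columns `animalId`,
#' `tissue`, `cellLine`, `day`, `areaMm2`, `status` (one of `engrafted`,
#' `excluded_no_engraftment`, `excluded_infection`, `censored_fracture`).
#'
#' @slot observations data.frame as described above.
#' @slot preset the generating [GrowthPreset].
#' @slot seed integer seed used for generation.
#' @seealso [generateCohort()], [summarizeCohort()]
#' @exportClass TumorCohort
setClass("TumorCohort",
  representation(
    observations = "data.frame",
    preset = "GrowthPreset",
    seed = "integer"
  )
)

#' Cohort-level result
#'
#' Take rate and relative-growth summary for one tissue x cell-line group.
#'
#' @slot tissue,cellLine character group labels.
#' @slot nImplanted,nEngrafted integer counts; engrafted animals are those
#'   with a detectable day-7 tumor.
#' @slot takeRate numeric, exact take rate in percent.
#' @slot takeRatePct integer, take rate rounded to the nearest percent (the
#'   reporting convention).
#' @slot growth data.frame with columns `day`, `meanRel`, `sdRel`, `n`
#'   (relative area, day 7 = 100%).
#' @seealso [summarizeCohort()], [takeRate()]
#' @exportClass CohortResult
setClass("CohortResult",
  representation(
    tissue = "character",
    cellLine = "character",
    nImplanted = "integer",
    nEngrafted = "integer",
    takeRate = "numeric",
    takeRatePct = "integer",
    growth = "data.frame"
  )
)

#' Repeated-measures ANOVA result
#'
#' One-way within-subject ANOVA over time points, with Mauchly's sphericity
#' test and Greenhouse-Geisser degree-of-freedom correction applied when
#' sphericity is rejected (p < 0.05), plus Bonferroni-adjusted pairwise
#' post-tests and the mean +/- SD summary per time point.
#'
#' @slot F numeric F statistic.
#' @slot df1,df2 numeric degrees of freedom actually used for `p`
#'   (Greenhouse-Geisser adjusted when `sphericityApplied` is `FALSE`).
#' @slot epsilonGG numeric Greenhouse-Geisser epsilon.
#' @slot mauchlyW,mauchlyP numeric Mauchly test statistic and p-value
#'   (`NA` when k = 2, where sphericity holds trivially).
#' @slot sphericityApplied logical, `TRUE` when the uncorrected test was used.
#' @slot p numeric p-value of the omnibus test.
#' @slot pUncorrected numeric p-value without the epsilon correction.
#' @slot nSubjects,nTimes integer design size after listwise deletion.
#' @slot posthoc data.frame of pairwise paired t-tests (`timeA`, `timeB`,
#'   `pRaw`, `pAdj`); empty unless the omnibus test is significant.
#' @slot summary data.frame with per-time `mean`, `sd`, `n`.
#' @seealso [rmAnova()]
#' @exportClass StatsResult
setClass("StatsResult",
  representation(
    F = "numeric",
    df1 = "numeric",
    df2 = "numeric",
    epsilonGG = "numeric",
    mauchlyW = "numeric",
    mauchlyP = "numeric",
    sphericityApplied = "logical",
    p = "numeric",
    pUncorrected = "numeric",
    nSubjects = "integer",
    nTimes = "integer",
    posthoc = "data.frame",
    summary = "data.frame"
  )
)
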