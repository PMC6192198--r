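#' Accessors for package classes
#'
#' Small accessor generics: `frames()` returns the image stack of a
#' [FieldOfView], `pixelSize()` and `frameRate()` its calibration,
#' `roiLabel()` its ROI label, `observationArea()` the field area in cm^2,
#' `groundTruth()` the synthetic ground-truth table, `observations()` the
#' per-animal table of a [TumorCohort], and `intensities()` / `sampleTimes()`
#' the samples of a [PermeabilityTrace].
#'
#' @param object an object of the documented class.
#' @return The corresponding slot value (see Details); `observationArea()`
#'   returns a scalar in cm^2.
#' @name accessors
#' @aliases frames pixelSize frameRate roiLabel observationArea groundTruth
#'   observations intensities sampleTimes
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("roiLabel", function(object) standardGeneric("roiLabel"))
#' @rdname accessors
#' @export
setGeneric("observationArea", function(object) standardGeneric("observationArea"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("observations", function(object) standardGeneric("observations"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname accessors
setMethod("frames", "FieldOfView", function(object) object@frames)
#' @rdname accessors
setMethod("pixelSize", "FieldOfView", function(object) object@pixelSize)
#' @rdname accessors
setMethod("frameRate", "FieldOfView", function(object) object@frameRate)
#' @rdname accessors
setMethod("roiLabel", "FieldOfView", function(object) object@roiLabel)
#' @rdname accessors
setMethod("observationArea", "FieldOfView", function(object) {
  d <- dim(object@frames)
  d[1] * d[2] * object@pixelSize^2 * 1e-8  # um^2 -> cm^2
})
#' @rdname accessors
setMethod("groundTruth", "FieldOfView", function(object) object@groundTruth)
#' @rdname accessors
setMethod("observations", "TumorCohort", function(object) object@observations)
#' @rdname accessors
setMethod("intensities", "PermeabilityTrace", function(object) object@intensity)
#' @rdname accessors
setMethod("sampleTimes", "PermeabilityTrace", function(object) object@times)

setMethod("show", "GrowthPreset", function(object) {
  cat(sprintf("GrowthPreset %s / %s: n=%d, engraftProb=%.3f, day7Area=%.2f mm^2\n",
              object@tissue, object@cellLine, object@nImplanted,
              object@engraftProb, object@day7Area))
  cat("  relAreaByDay:",
      paste(sprintf("d%s=%.0f%%", names(object@relAreaByDay),
                    object@relAreaByDay), collapse = ", "), "\n")
  if (!is.na(object@censorDay))
    cat(sprintf("  fracture censoring after day %g\n", object@censorDay))
})

setMethod("show", "FieldOfView", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FieldOfView %s: %d x %d px (%.1f x %.1f um), %d frames @ %g fps\n",
              if (nzchar(object@roiLabel)) object@roiLabel else "<unlabeled>",
              d[1], d[2], d[1] * object@pixelSize, d[2] * object@pixelSize,
              d[3], object@frameRate))
  if (nrow(object@groundTruth))
    cat(sprintf("  ground truth: %d segments (%d perfused)\n",
                nrow(object@groundTruth), sum(object@groundTruth$perfused)))
})

setMethod("show", "PermeabilityTrace", function(object) {
  cat(sprintf(
    "PermeabilityTrace: %d samples over %.0f s; I0=%.3g, Ib=%.3g, HT=%.2f, K=%.3g s, V/S=%.2f um\n",
    length(object@times), max(object@times), object@I0, object@Ib,
    object@HT, object@K, object@vsRatio))
})

setMethod("show", "TumorCohort", function(object) {
  ob <- object@observations
  cat(sprintf("TumorCohort %s / %s (seed %d): %d animals, %d observations\n",
              object@preset@tissue, object@preset@cellLine, object@seed,
              length(unique(ob$animalId)), sum(!is.na(ob$areaMm2))))
  print(table(status = ob$status[!duplicated(ob$animalId)]))
})

setMethod("show", "CohortResult", function(object) {
  cat(sprintf("CohortResult %s / %s: take rate %d%% (%d/%d)\n",
              object@tissue, object@cellLine, object@takeRatePct,
              object@nEngrafted, object@nImplanted))
  print(object@growth, row.names = FALSE)
})

setMethod("show", "StatsResult", function(object) {
  cat(sprintf("RM-ANOVA: F(%.3g, %.3g) = %.4g, p = %.4g%s\n",
              object@df1, object@df2, object@F, object@p,
              if (!object@sphericityApplied)
                sprintf("  [Greenhouse-Geisser, eps = %.3f]", object@epsilonGG)
              else ""))
  if (!is.na(object@mauchlyW))
    cat(sprintf("  Mauchly W = %.4g, p = %.4g\n",
                object@mauchlyW, object@mauchlyP))
  if (nrow(object@posthoc)) {
    cat("  Bonferroni post-tests:\n")
    print(object@posthoc, row.names = FALSE)
  }
})
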