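#' Monte-Carlo growth recovery study
#'
#' Runs the full image-based growth pipeline on seeded replicate cohorts of
#' one preset: generate a cohort, render every observed tumor area as a
#' synthetic frame, re-segment it, compute per-animal relative growth on the
#' measured areas, and record per-day means. Used to check that the pipeline
#' recovers the preset's growth trajectory under measurement noise.
#'
#' @param preset a [GrowthPreset-class].
#' @param nReplicates number of replicate cohorts.
#' @param baseSeed replicate r uses seed `baseSeed + r`.
#' @param pixelSize,dim,noiseSd rendering parameters (see
#'   [renderTumorFrame()]).
#' @return data.frame with one row per replicate and day: `replicate`,
#'   `day`, `meanRel` (mean relative area, %), `meanAbs` (mean absolute
#'   measured area, mm^2), `n` (animals contributing).
#' @examples
#' \donttest{
#' st <- growthRecoveryStudy(growthPreset("FW", "LnCap"), nReplicates = 3)
#' aggregate(meanRel ~ day, st, mean)
#' }
#' @export
growthRecoveryStudy <- function(preset, nReplicates = 200, baseSeed = 0,
                                pixelSize = 32, dim = c(128L, 128L),
                                noiseSd = 0.02) {
  out <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    co <- generateCohort(preset, seed = baseSeed + r)
    meas <- measureCohortAreas(co, pixelSize = pixelSize, dim = dim,
                               noiseSd = noiseSd)
    ob <- meas@observations
    ob <- ob[ob$status != "excluded_no_engraftment" &
               ob$status != "excluded_infection", , drop = FALSE]
    ob <- relativeGrowth(ob)
    days <- sort(unique(ob$day))
    out[[r]] <- do.call(rbind, lapply(days, function(d) {
      rel <- ob$relativeArea[ob$day == d & !is.na(ob$relativeArea)]
      ab <- ob$areaMm2[ob$day == d & !is.na(ob$areaMm2)]
      data.frame(replicate = r, day = d, meanRel = mean(rel),
                 meanAbs = mean(ab), n = length(rel))
    }))
  }
  do.call(rbind, out)
}
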