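#' Segment tumor area from a single-channel frame
#'
#' Applies Otsu thresholding to the (rescaled) tumor-channel image, fills
#' holes, and returns the area of the largest connected above-threshold
#' component converted to mm^2 via the pixel calibration. Frames without a
#' clear foreground (flat images, or images where the putative foreground is
#' not separated from the background by at least `contrastSd` background
#' standard deviations) return 0 with a warning.
#'
#' @param image numeric matrix, single-channel calibrated frame.
#' @param pixelSize um per pixel; must be a positive scalar.
#' @param contrastSd minimum foreground/background separation in background
#'   SD units below which the frame is declared empty.
#' @return Tumor area in mm^2.
#' @examples
#' img <- renderTumorFrame(1.0, noiseSd = 0)
#' segmentTumorArea(img, pixelSize = 32)
#' @export
segmentTumorArea <- function(image, pixelSize, contrastSd = 6) {
  if (missing(pixelSize) || !is.numeric(pixelSize) || length(pixelSize) != 1 ||
      is.na(pixelSize) || pixelSize <= 0)
    stop("pixelSize must be a positive scalar (um/pixel calibration)")
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (diff(rng) < 1e-12) {
    warning("empty frame: no intensity variation; returning area 0")
    return(0)
  }
  z <- (image - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(z))
  mask <- z > th
  bgSd <- stats::sd(image[!mask])
  sep <- mean(image[mask]) - mean(image[!mask])
  if (!any(mask) || (is.finite(bgSd) && bgSd > 0 && sep < contrastSd * bgSd)) {
    warning("no tumor signal above background; returning area 0")
    return(0)
  }
  lab <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(mask)))
  counts <- tabulate(as.integer(lab[lab > 0]))
  max(counts) * pixelSize^2 / 1e6       # px -> um^2 -> mm^2
}

#' Fill per-animal relative growth
#'
#' Normalizes every animal's area series to its own day-7 value
#' (`relativeArea = 100 * area(day) / area(7)`), the convention under which
#' day 7 is defined as 100%. Animals without a positive day-7 area get `NA`
#' relative areas.
#'
#' @param observations data.frame with columns `animalId`, `day`, `areaMm2`.
#' @return The data.frame with a `relativeArea` column added.
#' @examples
#' df <- data.frame(animalId = "a", day = c(7, 21), areaMm2 = c(1.0, 7.3))
#' relativeGrowth(df)$relativeArea
#' @export
relativeGrowth <- function(observations) {
  stopifnot(all(c("animalId", "day", "areaMm2") %in% names(observations)))
  observations$relativeArea <- rep(NA_real_, nrow(observations))
  for (id in unique(observations$animalId)) {
    sel <- observations$animalId == id
    d7 <- observations$areaMm2[sel & observations$day == 7]
    if (length(d7) != 1 || is.na(d7) || d7 <= 0) next
    observations$relativeArea[sel] <- 100 * observations$areaMm2[sel] / d7
  }
  observations
}

#' Tumor take rate
#'
#' Fraction of implanted chambers with detectable engraftment at day 7,
#' in percent. The exact value is returned together with the integer-rounded
#' percentage used for reporting.
#'
#' @param nImplanted number of chambers implanted (> 0).
#' @param nEngrafted number with day-7 engraftment (0..nImplanted).
#' @return list with `exact` (percent) and `percent` (nearest integer).
#' @examples
#' takeRate(15, 14)$percent  # 93
#' takeRate(20, 9)$percent   # 45
#' @export
takeRate <- function(nImplanted, nEngrafted) {
  if (nImplanted <= 0) stop("take rate undefined for nImplanted = 0")
  if (nEngrafted < 0 || nEngrafted > nImplanted)
    stop("nEngrafted must lie in [0, nImplanted]")
  exact <- 100 * nEngrafted / nImplanted
  list(exact = exact, percent = as.integer(round(exact)))
}

#' Apply the experimental protocol's exclusion and censoring rules
#'
#' Animals without day-7 engraftment or with postoperative infection are
#' excluded from growth statistics (their rows are removed) while remaining
#' countable in take-rate denominators. Fracture-censored animals keep their
#' observed rows (they contribute to per-day means up to their last observed
#' day); no imputation is performed. Every removal or censoring note is
#' recorded in an audit log.
#'
#' @param observations data.frame with columns `animalId`, `day`, `status`.
#' @return list with `included` (rows entering growth statistics), `audit`
#'   (data.frame `animalId`, `rule`, `detail`), and `nImplanted` /
#'   `nEngrafted` counts for take-rate computation.
#' @export
applyProtocolRules <- function(observations) {
  stopifnot(all(c("animalId", "day", "status") %in% names(observations)))
  audit <- data.frame(animalId = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE)
  excludedIds <- character()
  for (id in unique(observations$animalId)) {
    st <- observations$status[observations$animalId == id]
    if (any(st == "excluded_no_engraftment")) {
      excludedIds <- c(excludedIds, id)
      audit <- rbind(audit, data.frame(
        animalId = id, rule = "exclude_no_engraftment",
        detail = "no tumor engraftment on day 7", stringsAsFactors = FALSE))
    } else if (any(st == "excluded_infection")) {
      excludedIds <- c(excludedIds, id)
      audit <- rbind(audit, data.frame(
        animalId = id, rule = "exclude_infection",
        detail = "clinical signs of postoperative infection",
        stringsAsFactors = FALSE))
    } else if (any(st == "censored_fracture")) {
      lastDay <- max(observations$day[observations$animalId == id])
      audit <- rbind(audit, data.frame(
        animalId = id, rule = "censor_fracture",
        detail = sprintf("femur fracture; observed through day %g", lastDay),
        stringsAsFactors = FALSE))
    }
  }
  included <- observations[!observations$animalId %in% excludedIds, ,
                           drop = FALSE]
  nAll <- length(unique(observations$animalId))
  list(included = included, audit = audit, nImplanted = nAll,
       nEngrafted = nAll - length(excludedIds))
}

#' Summarize a cohort: take rate and relative growth
#'
#' Applies the protocol rules, fills relative growth, and aggregates the
#' per-day mean and SD of relative area (mean-of-ratios: each tumor is
#' normalized to its own day-7 area before averaging) together with the
#' per-day number of contributing animals.
#'
#' @param cohort a [TumorCohort-class] or a raw observations data.frame with
#'   the columns produced by [generateCohort()].
#' @return A [CohortResult-class].
#' @examples
#' co <- generateCohort(growthPreset("FW", "Du145", noiseSigma = 0), seed = 2)
#' summarizeCohort(co)
#' @export
summarizeCohort <- function(cohort) {
  ob <- if (is(cohort, "TumorCohort")) cohort@observations else cohort
  pr <- applyProtocolRules(ob)
  inc <- relativeGrowth(pr$included)
  days <- sort(unique(inc$day))
  growth <- do.call(rbind, lapply(days, function(d) {
    v <- inc$relativeArea[inc$day == d & !is.na(inc$relativeArea)]
    data.frame(day = d, meanRel = mean(v),
               sdRel = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))
  }))
  if (is.null(growth))
    growth <- data.frame(day = numeric(), meanRel = numeric(),
                         sdRel = numeric(), n = integer())
  tr <- takeRate(pr$nImplanted, pr$nEngrafted)
  new("CohortResult",
      tissue = ob$tissue[1], cellLine = ob$cellLine[1],
      nImplanted = as.integer(pr$nImplanted),
      nEngrafted = as.integer(pr$nEngrafted),
      takeRate = tr$exact, takeRatePct = tr$percent,
      growth = growth)
}
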