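# Clip the infinite line through p0 with unit direction u to the rectangle
# [0,w] x [0,h]; returns c(t0, t1) parameter range or NULL when it misses.
clipLineToRect <- function(p0, u, w, h) {
  t0 <- -Inf; t1 <- Inf
  for (ax in 1:2) {
    lim <- if (ax == 1) w else h
    if (abs(u[ax]) < 1e-12) {
      if (p0[ax] < 0 || p0[ax] > lim) return(NULL)
    } else {
      ta <- (0 - p0[ax]) / u[ax]; tb <- (lim - p0[ax]) / u[ax]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) return(NULL)
  c(t0, t1)
}

# Minimum distance between two straight segments, each given as (p, u, t0, t1),
# approximated by dense sampling along the shorter one.
segmentMinDist <- function(a, b) {
  ts <- seq(a$t0, a$t1, length.out = 50)
  pts <- cbind(a$p[1] + ts * a$u[1], a$p[2] + ts * a$u[2])
  tb <- pmin(pmax((pts[, 1] - b$p[1]) * b$u[1] +
                  (pts[, 2] - b$p[2]) * b$u[2], b$t0), b$t1)
  qx <- b$p[1] + tb * b$u[1]; qy <- b$p[2] + tb * b$u[2]
  sqrt(min((pts[, 1] - qx)^2 + (pts[, 2] - qy)^2))
}

#' Generate a synthetic microvessel field of view
#'
#' Renders straight vessel tubes with Gaussian cross-section (FWHM equal to
#' the true diameter) on a uniform background, over a time-lapse stack.
#' Perfused tubes carry dark erythrocyte gaps -- local intensity dips --
#' advected along the tube at the true centerline velocity; unperfused tubes
#' carry a frozen gap pattern. Tubes span the full field (their ends lie
#' outside the rendered area) and are placed with a minimum mutual clearance
#' so that each ground-truth segment maps to one recoverable centerline.
#'
#' @param params a [VesselFieldParams-class].
#' @param seed integer seed; identical `(params, seed)` give bit-identical
#'   stacks.
#' @param segments optional explicit geometry overriding random placement: a
#'   data.frame with columns `x0`, `y0`, `x1`, `y1` (um; the segment is
#'   extended to the field boundary), `diameterUm`, `velocityUmS`,
#'   `perfused`.
#' @param roiLabel ROI label stored in the result.
#' @return A [FieldOfView-class] with ground truth (clipped in-field
#'   endpoints, length, diameter, velocity, perfusion flag) per segment.
#' @examples
#' fov <- generateVesselField(vesselFieldParams(nSegments = 2,
#'   fieldSize = c(100, 100), duration = 10, frameRate = 10), seed = 1)
#' groundTruth(fov)
#' @export
generateVesselField <- function(params, seed, segments = NULL,
                                roiLabel = "") {
  validObject(params)
  set.seed(as.integer(seed))
  px <- params@pixelSize
  w <- params@fieldSize[1]; h <- params@fieldSize[2]
  dims <- round(params@fieldSize / px)
  nf <- max(1L, round(params@frameRate * params@duration))

  geom <- list()
  if (!is.null(segments)) {
    for (i in seq_len(nrow(segments))) {
      p0 <- c(segments$x0[i], segments$y0[i])
      u <- c(segments$x1[i] - segments$x0[i], segments$y1[i] - segments$y0[i])
      u <- u / sqrt(sum(u^2))
      tr <- clipLineToRect(p0, u, w, h)
      if (is.null(tr)) stop("segment ", i, " does not intersect the field")
      geom[[i]] <- list(p = p0, u = u, t0 = tr[1], t1 = tr[2],
                        D = segments$diameterUm[i],
                        v = segments$velocityUmS[i],
                        perfused = segments$perfused[i])
    }
  } else if (params@nSegments > 0L) {
    minLen <- min(60, 0.5 * min(w, h))
    # near-parallel bundle (capillary-field geometry): a common base
    # orientation with per-vessel jitter keeps full-field tubes from crossing
    baseTheta <- stats::runif(1, 0, pi)
    for (i in seq_len(params@nSegments)) {
      D <- stats::runif(1, params@diameterRange[1], params@diameterRange[2])
      perfused <- stats::runif(1) < params@perfusedFraction
      v <- if (perfused)
        stats::runif(1, params@velocityRange[1], params@velocityRange[2])
      else 0
      placed <- FALSE
      for (try in 1:300) {
        p0 <- c(stats::runif(1, 0.05 * w, 0.95 * w),
                stats::runif(1, 0.05 * h, 0.95 * h))
        th <- baseTheta + stats::runif(1, -0.15, 0.15)
        u <- c(cos(th), sin(th))
        tr <- clipLineToRect(p0, u, w, h)
        if (is.null(tr) || diff(tr) < minLen) next
        cand <- list(p = p0, u = u, t0 = tr[1], t1 = tr[2], D = D, v = v,
                     perfused = perfused)
        clear <- TRUE
        for (g in geom) {
          if (segmentMinDist(cand, g) < 1.3 * (D + g$D)) { clear <- FALSE; break }
        }
        if (clear) { geom[[length(geom) + 1]] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stop("field too small to place segment ", i,
             " with the requested clearance")
    }
  }

  arr <- array(params@backgroundLevel, c(dims[1], dims[2], nf))
  xs <- (seq_len(dims[1]) - 0.5) * px
  ys <- (seq_len(dims[2]) - 0.5) * px
  gx <- matrix(xs, dims[1], dims[2])
  gy <- matrix(ys, dims[1], dims[2], byrow = TRUE)

  gt <- data.frame(segmentId = integer(), x0 = numeric(), y0 = numeric(),
                   x1 = numeric(), y1 = numeric(), lengthUm = numeric(),
                   diameterUm = numeric(), velocityUmS = numeric(),
                   perfused = logical())
  for (i in seq_along(geom)) {
    g <- geom[[i]]
    sig <- g$D / (2 * sqrt(2 * log(2)))
    # static geometry: per-pixel distance to centerline and arclength
    tpar <- (gx - g$p[1]) * g$u[1] + (gy - g$p[2]) * g$u[2]
    # distance to the clipped segment, not the infinite line: tubes end in
    # rounded caps at the field border instead of bleeding past their
    # ground-truth extent
    tcl <- pmin(pmax(tpar, g$t0), g$t1)
    dx <- gx - (g$p[1] + tcl * g$u[1])
    dy <- gy - (g$p[2] + tcl * g$u[2])
    d2 <- dx^2 + dy^2
    keep <- which(d2 < (4 * sig)^2)
    base <- params@vesselLevel * exp(-d2[keep] / (2 * sig^2))
    svals <- tcl[keep]
    # gap train along arclength, drawn over the range swept during recording
    sweep <- abs(g$v) * params@duration
    lo <- g$t0 - sweep - 3 * params@gapWidthUm
    hi <- g$t1 + 3 * params@gapWidthUm
    nGaps <- stats::rpois(1, (hi - lo) / params@gapSpacingUm)
    centers <- sort(stats::runif(nGaps, lo, hi))
    sGrid <- seq(min(svals), max(svals), by = px / 2)
    sIdx <- findInterval(svals, sGrid, all.inside = TRUE)
    for (t in seq_len(nf)) {
      tt <- (t - 1) / params@frameRate
      pos <- centers + g$v * tt
      near <- pos[pos > sGrid[1] - 3 * params@gapWidthUm &
                    pos < sGrid[length(sGrid)] + 3 * params@gapWidthUm]
      gFac <- rep(1, length(sGrid))
      if (length(near)) {
        dd <- outer(sGrid, near, "-")
        gFac <- 1 - params@gapDepth *
          pmin(1, rowSums(exp(-dd^2 / (2 * params@gapWidthUm^2))))
      }
      slice <- arr[, , t]
      slice[keep] <- slice[keep] + base * gFac[sIdx]
      arr[, , t] <- slice
    }
    e0 <- g$p + g$t0 * g$u; e1 <- g$p + g$t1 * g$u
    gt <- rbind(gt, data.frame(
      segmentId = i, x0 = e0[1], y0 = e0[2], x1 = e1[1], y1 = e1[2],
      lengthUm = g$t1 - g$t0, diameterUm = g$D, velocityUmS = abs(g$v),
      perfused = g$perfused))
  }
  if (params@noiseSd > 0)
    arr <- arr + array(stats::rnorm(length(arr), 0, params@noiseSd), dim(arr))

  new("FieldOfView", frames = arr, pixelSize = px,
      frameRate = params@frameRate, roiLabel = roiLabel, groundTruth = gt)
}
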