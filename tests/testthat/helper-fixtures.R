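# Shared fixture builders and independent oracle implementations.

# A single straight tube crossing the field, specified in um.
straightTubeField <- function(x0, y0, x1, y1, diameterUm, velocityUmS = 0,
                              fieldSize = c(200, 100), pixelSize = 0.5,
                              frameRate = 20, duration = 10, noiseSd = 0,
                              seed = 1) {
  params <- vesselFieldParams(
    fieldSize = fieldSize, pixelSize = pixelSize, nSegments = 1L,
    diameterRange = c(max(2 * pixelSize, diameterUm - 1), diameterUm + 1),
    velocityRange = if (velocityUmS > 0) c(velocityUmS, velocityUmS)
                    else c(0, 0),
    frameRate = frameRate,
    duration = if (velocityUmS > 0) max(10, duration) else duration,
    noiseSd = noiseSd)
  generateVesselField(
    params, seed = seed,
    segments = data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                          diameterUm = diameterUm,
                          velocityUmS = velocityUmS,
                          perfused = velocityUmS > 0))
}

# Brute-force blood flow reference: explicit, independent of the package's
# vectorized implementation.
bruteBfr <- function(d, v) {
  radius <- d / 2
  areaUm2 <- pi * radius * radius
  flowUm3 <- areaUm2 * v / 1.6
  flowUm3 / 1000
}

# Brute-force one-way repeated-measures sums of squares on a wide matrix,
# written with explicit loops as an independent oracle.
bruteRmAnovaF <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ssTime <- 0
  for (j in seq_len(k)) ssTime <- ssTime + n * (mean(Y[, j]) - grand)^2
  ssErr <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ssErr <- ssErr + (Y[i, j] - mean(Y[i, ]) - mean(Y[, j]) + grand)^2
  }
  Fv <- (ssTime / (k - 1)) / (ssErr / ((n - 1) * (k - 1)))
  list(F = Fv, p = pf(Fv, k - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

longFromWide <- function(Y) {
  data.frame(subject = rep(seq_len(nrow(Y)), ncol(Y)),
             time = rep(seq_len(ncol(Y)), each = nrow(Y)),
             value = as.vector(Y))
}

# FWHM of a sampled profile by linear interpolation (independent oracle).
profileFwhm <- function(x, y) {
  bg <- min(y)
  y <- y - bg
  half <- max(y) / 2
  pk <- which.max(y)
  li <- pk; while (li > 1 && y[li] > half) li <- li - 1
  ri <- pk; while (ri < length(y) && y[ri] > half) ri <- ri + 1
  xl <- x[li] + (x[li + 1] - x[li]) * (half - y[li]) / (y[li + 1] - y[li])
  xr <- x[ri - 1] + (x[ri] - x[ri - 1]) * (y[ri - 1] - half) /
    (y[ri - 1] - y[ri])
  xr - xl
}
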