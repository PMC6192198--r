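#' Generate a synthetic extravasation intensity trace
#'
#' Inverts the effective-permeability model: for a prescribed true
#' permeability `P` the whole-image intensity follows the linear ramp
#' `I(t) = I0 + (I0 - Ib) * (P / ((1 - HT) * V/S) - 1/K) * t`
#' with `P` converted from cm/s to um/s (1 um/s = 1e-4 cm/s) so that units
#' match `V/S` in um and `K` in s. Gaussian noise may be added to each
#' sample. When `P = (1 - HT) * (V/S) / K` the ramp slope is exactly zero:
#' extravasation then just balances plasma clearance.
#'
#' @param P true effective permeability (cm/s), non-negative.
#' @param I0 intensity immediately after vessel filling.
#' @param Ib background intensity (`I0 > Ib`).
#' @param vsRatio vessel volume-to-surface ratio V/S (um).
#' @param HT microvascular hematocrit fraction (default 0.19).
#' @param K plasma clearance time constant (s, default 9100).
#' @param sampleInterval s between successive readings (default 30 s).
#' @param duration total observation time (s, default 600 = 10 min).
#' @param noiseSd additive Gaussian noise SD on intensities.
#' @param seed integer seed for the noise draw.
#' @return A [PermeabilityTrace-class].
#' @examples
#' tr <- generatePermeabilityTrace(4e-7, I0 = 100, Ib = 10, vsRatio = 2.5,
#'                                 seed = 1)
#' estimatePermeability(tr)$P
#' @export
generatePermeabilityTrace <- function(P, I0, Ib, vsRatio, HT = 0.19,
                                      K = 9.1e3, sampleInterval = 30,
                                      duration = 600, noiseSd = 0,
                                      seed = 1) {
  if (K <= 0) stop("K must be positive")
  if (vsRatio <= 0) stop("vsRatio must be positive")
  if (!(I0 > Ib)) stop("I0 must exceed Ib")
  if (duration < 2 * sampleInterval)
    stop("duration must cover at least two sampling intervals")
  set.seed(as.integer(seed))
  times <- seq(0, duration, by = sampleInterval)
  pUmS <- P * 1e4                       # cm/s -> um/s
  slope <- (I0 - Ib) * (pUmS / ((1 - HT) * vsRatio) - 1 / K)
  I <- I0 + slope * times
  if (noiseSd > 0) I <- I + stats::rnorm(length(I), 0, noiseSd)
  new("PermeabilityTrace", times = times, intensity = I, I0 = I0, Ib = Ib,
      HT = HT, K = K, vsRatio = vsRatio)
}
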