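#' Ordinary least-squares slope of an intensity trace
#'
#' Fits `I ~ t` over the full observation window and returns the slope, its
#' standard error, the intercept, and the residual SD.
#'
#' @param trace a [PermeabilityTrace-class], or any object with numeric
#'   `times`/`intensity` content accessible via [sampleTimes()] and
#'   [intensities()].
#' @return list with `slope`, `se`, `intercept`, `residSd`, `n`.
#' @examples
#' tr <- generatePermeabilityTrace(1e-7, 100, 10, vsRatio = 2.5)
#' fitSlope(tr)$slope
#' @export
fitSlope <- function(trace) {
  t <- sampleTimes(trace); I <- intensities(trace)
  if (length(t) < 3) stop("insufficient data: at least 3 samples required")
  fit <- stats::lm(I ~ t)
  sm <- suppressWarnings(summary(fit))  # noise-free ramps fit perfectly
  list(slope = unname(stats::coef(fit)[2]),
       se = unname(sm$coefficients[2, 2]),
       intercept = unname(stats::coef(fit)[1]),
       residSd = sm$sigma, n = length(t))
}

#' Effective vascular permeability from an extravasation trace
#'
#' Computes `P = (1 - HT) * (V/S) * (dI/dt / (I0 - Ib) + 1/K)`, where
#' `dI/dt` is the OLS slope of the whole-image intensity over the
#' observation window, `I0` the intensity immediately after filling of all
#' vessels, `Ib` the background intensity, `HT` the microvascular hematocrit
#' (default 0.19), `K` the plasma clearance time constant of albumin
#' (default 9.1e3 s) and `V/S` the vessel volume-to-surface ratio in um.
#' The result is converted from um/s to cm/s (factor 1e-4). A negative
#' computed permeability is returned as-is with a quality flag rather than
#' clipped.
#'
#' @param trace a [PermeabilityTrace-class].
#' @return list with `P` (cm/s), `slope`, `slopeSe`, and `flag` (`"ok"` or
#'   `"negative"`).
#' @examples
#' tr <- generatePermeabilityTrace(4e-7, 100, 10, vsRatio = 2.5)
#' estimatePermeability(tr)$P
#' @export
estimatePermeability <- function(trace) {
  validObject(trace)
  if (trace@I0 == trace@Ib) stop("I0 equals Ib: permeability undefined")
  fs <- fitSlope(trace)
  pUmS <- (1 - trace@HT) * trace@vsRatio *
    (fs$slope / (trace@I0 - trace@Ib) + 1 / trace@K)
  P <- pUmS * 1e-4                      # um/s -> cm/s
  list(P = P, slope = fs$slope, slopeSe = fs$se,
       flag = if (P < 0) "negative" else "ok")
}

#' Vessel volume-to-surface ratio from segment geometry
#'
#' Models each segment as a cylinder of its measured diameter and length:
#' `V/S = sum(pi (D_i/2)^2 L_i) / sum(pi D_i L_i)`, which reduces to `D/4`
#' when all diameters are equal. Used to supply the `V/S` constant of the
#' permeability model from the vessel quantification of the same field.
#'
#' @param diameterUm per-segment diameters (um), positive.
#' @param lengthUm per-segment lengths (um); equal lengths by default.
#' @return V/S in um.
#' @examples
#' vsRatioFromGeometry(10)          # 2.5
#' vsRatioFromGeometry(c(8, 16))    # 10/3
#' @export
vsRatioFromGeometry <- function(diameterUm, lengthUm = rep(1, length(diameterUm))) {
  if (!length(diameterUm)) stop("no segments: V/S undefined")
  if (any(diameterUm <= 0) || any(lengthUm <= 0))
    stop("diameters and lengths must be positive")
  sum(diameterUm^2 * lengthUm) / (4 * sum(diameterUm * lengthUm))
}
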