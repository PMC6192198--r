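# Greenhouse-Geisser epsilon from the sample covariance of the time points.
ggEpsilonFromCov <- function(S) {
  k <- ncol(S)
  C <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  unname(sum(diag(C))^2 / ((k - 1) * sum(C^2)))
}

# Mauchly's sphericity test on the covariance of k repeated measures from n
# subjects, using orthonormal contrasts and the chi-square approximation with
# Anderson's second-order correction term.
mauchlyFromCov <- function(S, n) {
  k <- ncol(S)
  if (k < 3) return(list(W = NA_real_, p = NA_real_))
  M <- qr.Q(qr(stats::contr.helmert(k)))       # k x (k-1), orthonormal
  A <- t(M) %*% S %*% M
  pp <- k - 1
  logW <- determinant(A, logarithm = TRUE)$modulus -
    pp * log(sum(diag(A)) / pp)
  nu <- n - 1
  rho <- 1 - (2 * pp^2 + pp + 2) / (6 * pp * nu)
  w2 <- (pp + 2) * (pp - 1) * (pp - 2) * (2 * pp^3 + 6 * pp^2 + 3 * pp + 2) /
    (288 * (nu * pp * rho)^2)
  z <- -nu * rho * as.numeric(logW)
  f <- pp * (pp + 1) / 2 - 1
  pr1 <- stats::pchisq(z, f, lower.tail = FALSE)
  pr2 <- stats::pchisq(z, f + 4, lower.tail = FALSE)
  list(W = exp(as.numeric(logW)), p = pr1 + w2 * (pr2 - pr1))
}

# Long-format table -> complete-case wide matrix (subjects x times).
toWideMatrix <- function(table, subject = "subject", time = "time",
                         value = "value") {
  stopifnot(all(c(subject, time, value) %in% names(table)))
  if (anyDuplicated(table[, c(subject, time)]))
    stop("each (subject, time) pair may appear at most once")
  times <- sort(unique(table[[time]]))
  subjects <- unique(table[[subject]])
  Y <- matrix(NA_real_, length(subjects), length(times),
              dimnames = list(as.character(subjects), as.character(times)))
  Y[cbind(match(table[[subject]], subjects),
          match(table[[time]], times))] <- table[[value]]
  complete <- stats::complete.cases(Y)
  Y[complete, , drop = FALSE]
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical within-subject ANOVA over a time factor: the F statistic is
#' formed from the time and subject-by-time sums of squares after listwise
#' deletion of subjects with incomplete series (e.g. fracture-censored
#' animals). Mauchly's test assesses sphericity of the time-point
#' covariance; when it is rejected at `sphericityAlpha`, both degrees of
#' freedom are multiplied by the Greenhouse-Geisser epsilon before the
#' p-value is computed. With two time points sphericity holds trivially and
#' no adjustment is made. When the omnibus test is significant at
#' `posthocAlpha`, Bonferroni-adjusted pairwise paired t-tests between time
#' points are run.
#'
#' @param table long-format data.frame.
#' @param subject,time,value column names.
#' @param sphericityAlpha Mauchly decision threshold (default 0.05).
#' @param posthocAlpha omnibus threshold gating post-tests (default 0.05).
#' @return A [StatsResult-class].
#' @examples
#' d <- expand.grid(subject = 1:8, time = c(7, 14, 21))
#' d$value <- rnorm(nrow(d)) + d$time / 10
#' rmAnova(d)
#' @export
rmAnova <- function(table, subject = "subject", time = "time",
                    value = "value", sphericityAlpha = 0.05,
                    posthocAlpha = 0.05) {
  Y <- toWideMatrix(table, subject, time, value)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2) stop("insufficient data: fewer than 2 complete subjects")
  if (k < 2) stop("insufficient data: fewer than 2 time points")
  mt <- colMeans(Y); mi <- rowMeans(Y); m <- mean(Y)
  ssTime <- n * sum((mt - m)^2)
  ssErr <- sum((Y - outer(mi, mt, "+") + m)^2)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  Fv <- (ssTime / df1) / (ssErr / df2)
  S <- stats::cov(Y)
  eps <- if (k > 2) ggEpsilonFromCov(S) else 1
  mau <- mauchlyFromCov(S, n)
  adjust <- k > 2 && !is.na(mau$p) && mau$p < sphericityAlpha
  d1 <- if (adjust) eps * df1 else df1
  d2 <- if (adjust) eps * df2 else df2
  p <- stats::pf(Fv, d1, d2, lower.tail = FALSE)
  pUnc <- stats::pf(Fv, df1, df2, lower.tail = FALSE)

  summ <- data.frame(time = as.numeric(colnames(Y)), mean = mt,
                     sd = apply(Y, 2, stats::sd), n = n, row.names = NULL)

  posthoc <- data.frame(timeA = numeric(), timeB = numeric(),
                        pRaw = numeric(), pAdj = numeric())
  if (p < posthocAlpha && k >= 2) {
    prs <- utils::combn(k, 2)
    pRaw <- apply(prs, 2, function(ij)
      stats::t.test(Y[, ij[1]], Y[, ij[2]], paired = TRUE)$p.value)
    posthoc <- data.frame(
      timeA = as.numeric(colnames(Y))[prs[1, ]],
      timeB = as.numeric(colnames(Y))[prs[2, ]],
      pRaw = pRaw, pAdj = bonferroni(pRaw, ncol(prs)))
  }

  new("StatsResult", F = Fv, df1 = d1, df2 = d2, epsilonGG = eps,
      mauchlyW = mau$W, mauchlyP = mau$p, sphericityApplied = !adjust,
      p = p, pUncorrected = pUnc, nSubjects = as.integer(n),
      nTimes = as.integer(k), posthoc = posthoc, summary = summ)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p_raw)` for each raw p-value; with `m = 1` the
#' adjustment is the identity. Monotone and order-preserving.
#'
#' @param p numeric vector of raw p-values.
#' @param m number of comparisons (defaults to `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 3)  # 0.03, 1
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stop("m must be at least 1")
  pmin(1, m * p)
}

#' Mean +/- SD summary per group and day
#'
#' Per-cell mean, sample SD (n - 1 denominator) and n, with a significance
#' star column when per-cell p-values are supplied. Cells with a single
#' value report `NA` SD.
#'
#' @param table data.frame.
#' @param value value column name.
#' @param by character vector of grouping column names.
#' @param p optional named numeric of per-cell p-values (names matching the
#'   interaction of the grouping columns) used to add stars at p < 0.05.
#' @return data.frame with one row per group cell.
#' @examples
#' statSummary(data.frame(g = "a", v = c(100, 200, 300)), value = "v",
#'             by = "g")
#' @export
statSummary <- function(table, value = "value", by = c("group", "time"),
                        p = NULL) {
  stopifnot(nrow(table) > 0, all(c(value, by) %in% names(table)))
  key <- interaction(table[by], drop = TRUE, sep = ":")
  cells <- split(table[[value]], key)
  out <- data.frame(cell = names(cells),
                    mean = vapply(cells, mean, numeric(1)),
                    sd = vapply(cells, function(v)
                      if (length(v) > 1) stats::sd(v) else NA_real_,
                      numeric(1)),
                    n = vapply(cells, length, integer(1)),
                    row.names = NULL)
  if (!is.null(p))
    out$sig <- ifelse(!is.na(p[out$cell]) & p[out$cell] < 0.05, "*", "")
  out
}
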