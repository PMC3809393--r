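## Inference of the spontaneous DSB rate per cell division from microcolony
## traces, efficiency correction, legacy frequency conversion, and the
## generation-dependence test.

.finalCounts <- function(trace) {
  fr <- frames(trace)
  last <- fr[nrow(fr), ]
  c(foci = last$cum_foci, divisions = last$cum_divisions)
}

#' Foci per cell division across microcolonies
#'
#' Per colony, the final cumulative focus count over the final cumulative
#' division count; the estimate is the colony-level mean with SEM across
#' colonies (matching mean +/- SEM over microcolonies as the headline
#' summary). Colonies whose founder never divided carry no information about
#' a per-division rate and are excluded with a warning.
#'
#' @param traces a [MicrocolonyTrace-class] or list of them.
#' @return list with `f` (mean foci/division), `fSem`, `perColony` (numeric
#'   vector of per-colony ratios), `totalFoci`, `totalDivisions`,
#'   `nColonies` (used), `nExcluded`.
#' @examples
#' trs <- lapply(1:5, function(s)
#'   simulateMicrocolony(SimParams(r = 0.2, p = 1), tEnd = 7, seed = s))
#' fociPerDivision(trs)
#' @export
fociPerDivision <- function(traces) {
  if (is(traces, "MicrocolonyTrace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, is, TRUE, "MicrocolonyTrace")))
  counts <- vapply(traces, .finalCounts, numeric(2))
  ok <- counts["divisions", ] >= 1
  if (!all(ok)) {
    warning(sum(!ok), " colony(ies) with zero divisions excluded")
  }
  if (!any(ok)) stop("no colony with at least one division")
  foci <- counts["foci", ok]
  divs <- counts["divisions", ok]
  fi <- foci / divs
  n <- sum(ok)
  list(f = mean(fi),
       fSem = if (n > 1L) stats::sd(fi) / sqrt(n) else 0,
       perColony = fi,
       totalFoci = sum(foci),
       totalDivisions = sum(divs),
       nColonies = as.integer(n),
       nExcluded = as.integer(sum(!ok)))
}

#' Efficiency-correct a foci-per-division rate
#'
#' Converts a foci-per-division mean into a DSB rate per division,
#' `r = f / p`. By default the uncertainty of the detection efficiency is
#' excluded (`rSem = fSem / p`); supplying `pSem` with
#' `propagateEfficiency = TRUE` adds it by the delta method,
#' `rSem^2 = (fSem/p)^2 + (f * pSem / p^2)^2`.
#'
#' @param f foci per division.
#' @param fSem its standard error (default 0).
#' @param p detection efficiency in (0, 1\].
#' @param pSem standard error of the efficiency (used only when propagating).
#' @param propagateEfficiency logical, include efficiency uncertainty.
#' @param nColonies,totalFoci,totalDivisions optional bookkeeping; when total
#'   counts are given the pooled proportion and its Wilson 95% interval are
#'   filled in.
#' @return A [RateEstimate-class].
#' @examples
#' correctRate(0.0145, 0.006, p = 0.71)   # r = 0.0204, rSem = 0.00845
#' @export
correctRate <- function(f, fSem = 0, p, pSem = 0, propagateEfficiency = FALSE,
                        nColonies = NA_integer_, totalFoci = NA_real_,
                        totalDivisions = NA_real_) {
  .checkNumber(f, "f", lo = 0)
  .checkNumber(fSem, "fSem", lo = 0)
  if (!is.finite(p) || p <= 0 || p > 1) stop("'p' must lie in (0, 1]")
  r <- f / p
  rSem <- if (propagateEfficiency) {
    sqrt((fSem / p)^2 + (f * pSem / p^2)^2)
  } else {
    fSem / p
  }
  pooledQ <- NA_real_
  qCI <- c(NA_real_, NA_real_)
  if (is.finite(totalFoci) && is.finite(totalDivisions) && totalDivisions >= 1) {
    pooledQ <- totalFoci / totalDivisions
    qCI <- wilsonInterval(totalFoci, totalDivisions)
  }
  RateEstimate(f = f, fSem = fSem, p = p, r = r, rSem = rSem,
               nColonies = as.integer(nColonies), pooledQ = pooledQ, qCI = qCI)
}

#' Convert a legacy cells-with-breaks frequency into a DSB rate
#'
#' Older flow-cytometric assays measured the rate `F` at which cells acquire
#' one or more DSBs per generation, without resolving how many breaks each
#' carries. Multiplying by the mean foci per focus-carrying cell
#' (`totalFoci / focusCells`) converts it to DSBs per cell division.
#'
#' @param F rate of cells acquiring >= 1 DSB per generation.
#' @param totalFoci total foci counted.
#' @param focusCells number of focus-carrying cells counted (> 0).
#' @return numeric(1), DSBs per cell division.
#' @examples
#' frequencyToRate(0.01, 108, 98)   # 0.01102
#' @export
frequencyToRate <- function(F, totalFoci, focusCells) {
  .checkNumber(F, "F", lo = 0)
  .checkNumber(totalFoci, "totalFoci", lo = 0)
  if (!is.finite(focusCells) || focusCells <= 0) {
    stop("'focusCells' must be > 0")
  }
  F * totalFoci / focusCells
}

#' Test generation-dependence of focus accrual across division-rate regimes
#'
#' Splits traces at the supplied time boundaries (e.g. the moment glucose was
#' withdrawn), computes per-regime foci per division and foci per hour
#' (events pooled over traces; elapsed time summed over traces), and
#' contrasts each later regime against the first by the ratio of
#' per-division rates (binomial, log-scale interval) and of per-hour rates
#' (Poisson, log-scale interval). Generation-dependence is supported when the
#' per-division ratio is compatible with 1 while the per-hour ratio is not.
#'
#' @param traces a [MicrocolonyTrace-class] or list of them.
#' @param boundaries strictly increasing interior time boundaries (hours)
#'   partitioning the observation span.
#' @param conf confidence level for the ratio intervals.
#' @return list with `regimes` (data.frame: `start_h`, `end_h`, `foci`,
#'   `divisions`, `hours`, `perDivision`, `perHour`, `flagged` — TRUE when a
#'   regime has no divisions so its per-division rate is undefined),
#'   `perDivisionRatio` and `perHourRatio` (data.frames of est/lo/hi vs
#'   regime 1), and `supported` (logical or NA when undecidable).
#' @examples
#' p <- SimParams(r = 0.3, p = 1,
#'                tauSchedule = data.frame(start_h = c(0, 6), tau_h = c(1, 4)))
#' trs <- lapply(1:10, function(s) simulateMicrocolony(p, 12, seed = s))
#' generationDependence(trs, boundaries = 6)
#' @export
generationDependence <- function(traces, boundaries, conf = 0.95) {
  if (is(traces, "MicrocolonyTrace")) traces <- list(traces)
  stopifnot(all(vapply(traces, is, TRUE, "MicrocolonyTrace")))
  tMax <- max(vapply(traces, function(tr) max(frames(tr)$time_h), 0))
  if (any(boundaries <= 0) || any(boundaries >= tMax) ||
      is.unsorted(boundaries, strictly = TRUE)) {
    stop("'boundaries' must be strictly increasing interior times")
  }
  edges <- c(0, boundaries, tMax)
  k <- length(edges) - 1L
  foci <- divs <- hours <- numeric(k)
  for (tr in traces) {
    ev <- events(tr)
    tEnd <- max(frames(tr)$time_h)
    for (i in seq_len(k)) {
      lo <- edges[i]
      hi <- edges[i + 1L]
      inReg <- ev$time_h > lo & ev$time_h <= hi
      foci[i] <- foci[i] + sum(inReg & ev$kind == "focus")
      divs[i] <- divs[i] + sum(inReg & ev$kind == "division")
      hours[i] <- hours[i] + max(0, min(hi, tEnd) - lo)
    }
  }
  flagged <- divs == 0
  regimes <- data.frame(
    start_h = edges[-(k + 1L)], end_h = edges[-1L],
    foci = foci, divisions = divs, hours = hours,
    perDivision = ifelse(flagged, NA_real_, foci / divs),
    perHour = ifelse(hours > 0, foci / hours, NA_real_),
    flagged = flagged
  )
  pdr <- phr <- NULL
  if (k >= 2L) {
    pdr <- t(vapply(2:k, function(i)
      .propRatioCI(foci[1L], divs[1L], foci[i], divs[i], conf), numeric(3)))
    phr <- t(vapply(2:k, function(i)
      .rateRatioCI(foci[1L], hours[1L], foci[i], hours[i], conf), numeric(3)))
    pdr <- data.frame(regime = 2:k, pdr)
    phr <- data.frame(regime = 2:k, phr)
  }
  supported <- NA
  if (!is.null(pdr) && all(is.finite(as.matrix(pdr[, c("lo", "hi")]))) &&
      all(is.finite(as.matrix(phr[, c("lo", "hi")])))) {
    supported <- all(pdr$lo <= 1 & pdr$hi >= 1) &&
      all(phr$lo > 1 | phr$hi < 1)
  }
  list(regimes = regimes, perDivisionRatio = pdr, perHourRatio = phr,
       supported = supported)
}

#' Welch comparison of per-cell focus levels between two samples
#'
#' Two-sample comparison used for exposure controls (e.g. repeatedly
#' fluorescence-pulsed vs previously unexposed microcolonies): difference of
#' means with a Welch-style interval that does not assume equal variances.
#'
#' @param a,b numeric vectors of per-cell (or per-colony) focus levels, each
#'   of length >= 2.
#' @param conf confidence level.
#' @return list with `difference` (mean(b) - mean(a)), `ci`, `p`, and
#'   `flagged` (TRUE when both samples are degenerate with unequal means, in
#'   which case the interval is undefined).
#' @examples
#' exposureControlCompare(rbinom(500, 1, 0.016), rbinom(500, 1, 0.018))
#' @export
exposureControlCompare <- function(a, b, conf = 0.95) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  diffMean <- mean(b) - mean(a)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (diffMean == 0) {
      return(list(difference = 0, ci = c(0, 0), p = 1, flagged = FALSE))
    }
    return(list(difference = diffMean, ci = c(NA_real_, NA_real_),
                p = NA_real_, flagged = TRUE))
  }
  tt <- stats::t.test(b, a, conf.level = conf)
  list(difference = diffMean, ci = unname(tt$conf.int),
       p = tt$p.value, flagged = FALSE)
}
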