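## Detection-efficiency calibration from a gamma-ray dose-response: focus
## formation is linear in dose, and the slope over a known DSBs-per-Gy yield
## gives the probability that a true break is scored as a focus.

.checkDoseTable <- function(table) {
  need <- c("dose_Gy", "mean_foci")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("dose-response table needs columns dose_Gy and mean_foci ",
         "(and ideally sd_foci, n)")
  }
  if (anyDuplicated(table$dose_Gy)) stop("doses must be distinct")
  if (any(table$dose_Gy < 0)) stop("doses must be >= 0")
  invisible(table)
}

## closed-form OLS slope/intercept on (x, y); optional weights
.olsFit <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  b <- sum(w * (x - xb) * (y - yb)) / sxx
  a <- yb - b * xb
  list(slope = b, intercept = a, sxx = sxx, xb = xb, yb = yb, w = w)
}

#' Fit the focus-per-cell vs dose regression
#'
#' Ordinary least squares of per-dose mean foci per cell on dose (unweighted
#' by default; `weighted = TRUE` uses inverse-variance weights `n / sd^2`).
#' With exactly two dose points the slope reduces to the difference quotient
#' and `r2` is undefined (reported as `NA`). When `yield` is supplied the
#' detection efficiency `slope / yield` is filled in via
#' [estimateEfficiency()].
#'
#' @param table data.frame with columns `dose_Gy`, `mean_foci` and optionally
#'   `sd_foci`, `n` (see [simulateDoseResponse()]); >= 2 distinct doses.
#' @param yield assumed true DSBs per cell per Gy (> 0), or `NA` to fit the
#'   line only.
#' @param weighted logical, inverse-variance weighting of dose points.
#' @return A [CalibrationResult-class].
#' @examples
#' ## the printed two-point calibration: 0.043 foci/cell at 0 Gy,
#' ## 3.12 at 140 Gy, against a yield of 0.031 DSBs/cell/Gy
#' tab <- data.frame(dose_Gy = c(0, 140), mean_foci = c(0.043, 3.12))
#' fitDoseResponse(tab, yield = 0.031)
#' @export
fitDoseResponse <- function(table, yield = NA_real_, weighted = FALSE) {
  .checkDoseTable(table)
  n <- nrow(table)
  if (n < 2L) stop("at least two distinct dose points are required")
  w <- NULL
  if (weighted) {
    if (!all(c("sd_foci", "n") %in% names(table)) ||
        any(!is.finite(table$sd_foci)) || any(table$sd_foci <= 0)) {
      stop("weighted fit needs finite positive sd_foci and n columns")
    }
    w <- table$n / table$sd_foci^2
  }
  fit <- .olsFit(table$dose_Gy, table$mean_foci, w)
  resid <- table$mean_foci - fit$intercept - fit$slope * table$dose_Gy
  if (n >= 3L) {
    ww <- fit$w
    rss <- sum(ww * resid^2)
    tss <- sum(ww * (table$mean_foci - fit$yb)^2)
    r2 <- if (tss > 0) 1 - rss / tss else NA_real_
    slopeSe <- sqrt(rss / (n - 2L) / fit$sxx)
  } else {
    r2 <- NA_real_
    slopeSe <- NA_real_
  }
  eff <- NA_real_
  effSe <- NA_real_
  if (is.finite(yield)) {
    eff <- estimateEfficiency(fit$slope, yield)
    effSe <- if (is.finite(slopeSe)) slopeSe / yield else NA_real_
  }
  CalibrationResult(slope = fit$slope, slopeSe = slopeSe,
                    intercept = fit$intercept, r2 = r2, yield = yield,
                    efficiency = eff, efficiencySe = effSe)
}

#' Net radiation-induced foci per cell at a dose
#'
#' Mean foci per cell at `dose` minus the mean at zero dose: the direct
#' background subtraction, kept separate from the fitted intercept.
#'
#' @param table dose-response table containing both `dose` and a zero-dose
#'   row.
#' @param dose the dose of interest, Gy.
#' @return numeric(1), net induced foci per cell.
#' @examples
#' tab <- data.frame(dose_Gy = c(0, 140), mean_foci = c(0.043, 3.12))
#' netInducedFoci(tab, 140)   # 3.077
#' @export
netInducedFoci <- function(table, dose) {
  .checkDoseTable(table)
  i <- match(dose, table$dose_Gy)
  i0 <- match(0, table$dose_Gy)
  if (is.na(i) || is.na(i0)) {
    stop("table must contain rows for dose ", dose, " Gy and 0 Gy")
  }
  table$mean_foci[i] - table$mean_foci[i0]
}

#' Convert a dose-response slope into a detection efficiency
#'
#' `efficiency = slope / yield`. Values above 1 are physically suspect (the
#' assumed yield is then too low); they are returned unclamped with a
#' warning.
#'
#' @param slope foci per cell per Gy.
#' @param yield true DSBs per cell per Gy (> 0).
#' @return numeric(1) detection efficiency.
#' @examples
#' estimateEfficiency(0.022, 0.031)   # 0.7097
#' @export
estimateEfficiency <- function(slope, yield) {
  .checkNumber(slope, "slope")
  if (!is.finite(yield) || yield <= 0) stop("'yield' must be > 0")
  eff <- slope / yield
  if (eff > 1) warning("estimated efficiency exceeds 1 (slope > yield)")
  eff
}

#' Bootstrap confidence interval for the detection efficiency
#'
#' Percentile 95% interval over refits of the dose-response line. The summary
#' table carries only per-dose (mean, sd, n), so each bootstrap replicate
#' redraws every per-dose mean from its estimated sampling distribution
#' (`mean + sd/sqrt(n) * N(0,1)`) and refits; a degenerate zero-variance
#' table yields a zero-width interval at the point estimate. Seeded and
#' reproducible; the interval scales as 1/yield, so doubling the yield
#' halves both endpoints.
#'
#' @param table dose-response table with `dose_Gy`, `mean_foci`, `sd_foci`,
#'   `n`.
#' @param yield true DSBs per cell per Gy (> 0).
#' @param nBoot number of bootstrap replicates (>= 100).
#' @param seed optional integer seed.
#' @param conf confidence level (default 0.95).
#' @return numeric(2), lower and upper efficiency bounds.
#' @examples
#' tab <- simulateDoseResponse(SimParams(), doses = c(0, 40, 80, 140),
#'                             nCells = 2000, seed = 3)
#' bootstrapEfficiencyCI(tab, yield = 0.031, nBoot = 500, seed = 1)
#' @export
bootstrapEfficiencyCI <- function(table, yield, nBoot = 2000, seed = NULL,
                                  conf = 0.95) {
  .checkDoseTable(table)
  if (!all(c("sd_foci", "n") %in% names(table))) {
    stop("bootstrap needs per-dose sd_foci and n columns")
  }
  if (!is.finite(yield) || yield <= 0) stop("'yield' must be > 0")
  if (!is.finite(nBoot) || nBoot < 100) {
    stop("'nBoot' must be at least 100")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(table)
  se <- table$sd_foci / sqrt(table$n)
  se[!is.finite(se)] <- 0
  x <- table$dose_Gy
  xb <- mean(x)
  sxx <- sum((x - xb)^2)
  ## nBoot x d matrix of resampled means; vectorized slope refit
  noise <- matrix(stats::rnorm(nBoot * d), nBoot, d)
  means <- matrix(table$mean_foci, nBoot, d, byrow = TRUE) +
    noise * matrix(se, nBoot, d, byrow = TRUE)
  slopes <- as.numeric(means %*% (x - xb)) / sxx
  eff <- slopes / yield
  alpha <- (1 - conf) / 2
  unname(stats::quantile(eff, c(alpha, 1 - alpha), type = 7))
}
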