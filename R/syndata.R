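## Synthetic-data generators: every input the downstream pipeline consumes can
## be produced here under the generative model the analyses assume, so the
## whole pipeline is testable with known ground truth.

## waiting time to the next division for a cell idle from t0, under a
## piecewise-constant hazard 1/tau(t); Inf when divisions have halted for good
.divisionWait <- function(t0, sched) {
  E <- stats::rexp(1)
  k <- findInterval(t0, sched$start_h)
  t <- t0
  n <- nrow(sched)
  repeat {
    tau <- sched$tau_h[k]
    end <- if (k < n) sched$start_h[k + 1L] else Inf
    if (is.infinite(tau)) {
      if (is.infinite(end)) return(Inf)
    } else {
      cap <- (end - t) / tau
      if (E <= cap) return(t + E * tau - t0)
      E <- E - cap
    }
    t <- end
    k <- k + 1L
  }
}

#' Simulate one microcolony under the per-division breakage model
#'
#' Event-driven branching-process simulation of a single founder cell growing
#' into a microcolony. Interdivision times are exponential with the
#' regime-specific mean from `tauSchedule(params)` (piecewise-constant hazard,
#' so regime switches such as glucose withdrawal act immediately on waiting
#' cells). Each division event independently yields a detected focus with
#' probability `q = r * p` (one Bernoulli trial per division — spontaneous
#' breaks arise from replication, hence are tied to divisions); the focus is
#' assigned to one of the two daughter cells at random, and when
#' `arrestOnFocus` is set that cell never divides again (absorbing state).
#'
#' As an alternative hypothesis generator, `focusModel = "time"` detaches foci
#' from divisions: each non-arrested cell instead accrues foci as a Poisson
#' process at `fociPerHour`, which breaks the generation-dependence that the
#' per-division model has by construction.
#'
#' @param params a [SimParams-class] object.
#' @param tEnd end of observation, hours (> 0).
#' @param frameDt frame cadence in hours (default 1, matching time-lapse use).
#' @param colonyId identifier stored in the trace.
#' @param focusModel `"division"` (default) or `"time"`.
#' @param fociPerHour Poisson focus rate per cell per hour for
#'   `focusModel = "time"`.
#' @param stopAtCells optional colony-size cutoff: observation ends as soon
#'   as the colony reaches this many cells (time-lapse experiments follow
#'   microcolonies to a target size, e.g. ~100 cells), or at `tEnd`,
#'   whichever comes first.
#' @param seed optional integer seed; a fixed seed gives identical output.
#' @return A [MicrocolonyTrace-class].
#' @examples
#' tr <- simulateMicrocolony(SimParams(r = 0.1, p = 1), tEnd = 6, seed = 1)
#' tr
#' @export
simulateMicrocolony <- function(params, tEnd, frameDt = 1,
                                colonyId = "colony1",
                                focusModel = c("division", "time"),
                                fociPerHour = 0, stopAtCells = NULL,
                                seed = NULL) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  focusModel <- match.arg(focusModel)
  .checkNumber(tEnd, "tEnd", lo = 1e-9)
  .checkNumber(frameDt, "frameDt", lo = 1e-9)
  .checkNumber(fociPerHour, "fociPerHour", lo = 0)
  if (!is.null(seed)) set.seed(seed)

  sched <- params@tauSchedule
  q <- params@r * params@p
  timeModel <- focusModel == "time"

  ## per-cell state (grown as needed)
  cap <- 64L
  tDiv <- rep(Inf, cap)           # absolute time of next division
  tFoc <- rep(Inf, cap)           # absolute time of next focus (time model)
  nCells <- 1L
  tDiv[1L] <- .divisionWait(0, sched)
  if (timeModel && fociPerHour > 0) tFoc[1L] <- stats::rexp(1, fociPerHour)

  evTime <- numeric(0)
  evKind <- character(0)
  evCell <- integer(0)
  tObs <- tEnd

  repeat {
    if (!is.null(stopAtCells) && nCells >= stopAtCells) {
      tObs <- if (length(evTime)) evTime[length(evTime)] else 0
      break
    }
    live <- seq_len(nCells)
    iDiv <- live[which.min(tDiv[live])]
    tD <- tDiv[iDiv]
    tF <- Inf
    if (timeModel) {
      iFoc <- live[which.min(tFoc[live])]
      tF <- tFoc[iFoc]
    }
    tNext <- min(tD, tF)
    if (tNext > tEnd) break

    if (tD <= tF) {
      ## division: cell iDiv splits; new daughter gets a fresh id
      nCells <- nCells + 1L
      if (nCells > cap) {
        cap <- cap * 2L
        length(tDiv) <- cap; tDiv[is.na(tDiv)] <- Inf
        length(tFoc) <- cap; tFoc[is.na(tFoc)] <- Inf
      }
      j <- nCells
      evTime <- c(evTime, tD); evKind <- c(evKind, "division")
      evCell <- c(evCell, iDiv)   # the cell that divided
      tDiv[iDiv] <- tD + .divisionWait(tD, sched)
      tDiv[j] <- tD + .divisionWait(tD, sched)
      tFoc[j] <- if (timeModel && fociPerHour > 0) {
        tD + stats::rexp(1, fociPerHour)
      } else Inf
      if (!timeModel && q > 0 && stats::runif(1) < q) {
        hit <- if (stats::runif(1) < 0.5) iDiv else j
        evTime <- c(evTime, tD); evKind <- c(evKind, "focus")
        evCell <- c(evCell, hit)
        if (params@arrestOnFocus) {
          tDiv[hit] <- Inf
          tFoc[hit] <- Inf
        }
      }
    } else {
      ## asynchronous focus (time model)
      evTime <- c(evTime, tF); evKind <- c(evKind, "focus")
      evCell <- c(evCell, iFoc)
      if (params@arrestOnFocus) {
        tDiv[iFoc] <- Inf
        tFoc[iFoc] <- Inf
      } else {
        tFoc[iFoc] <- tF + stats::rexp(1, fociPerHour)
      }
    }
  }

  frameTimes <- seq(0, tObs, by = frameDt)
  if (frameTimes[length(frameTimes)] < tObs) frameTimes <- c(frameTimes, tObs)
  isDiv <- evKind == "division"
  fr <- data.frame(
    time_h = frameTimes,
    n_cells = 1L + vapply(frameTimes, function(t) sum(isDiv & evTime <= t), 0L),
    cum_divisions = vapply(frameTimes, function(t) sum(isDiv & evTime <= t), 0L),
    cum_foci = vapply(frameTimes, function(t) sum(!isDiv & evTime <= t), 0L)
  )
  ev <- data.frame(time_h = evTime, kind = evKind, cell_id = evCell)
  MicrocolonyTrace(colonyId = colonyId, frames = fr, events = ev)
}

#' Simulate a gamma-ray dose-response table
#'
#' Per cell and dose D, true breaks are Poisson with mean `y * D`, each
#' detected as a focus with probability `p` (binomial thinning), plus a
#' spontaneous background focus drawn Bernoulli(`b`) per cell. Returns the
#' per-dose summary table consumed by [fitDoseResponse()].
#'
#' @param params a [SimParams-class]; uses slots `y`, `p`, `b`.
#' @param doses numeric vector of doses in Gy (>= 0, non-empty).
#' @param nCells cells scored per dose (>= 1).
#' @param seed optional integer seed.
#' @return data.frame with columns `dose_Gy`, `mean_foci`, `sd_foci`, `n`.
#' @examples
#' simulateDoseResponse(SimParams(), doses = c(0, 70, 140), nCells = 1000,
#'                      seed = 1)
#' @export
simulateDoseResponse <- function(params, doses, nCells, seed = NULL) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  if (!length(doses)) stop("'doses' must be a non-empty numeric vector")
  if (any(!is.finite(doses)) || any(doses < 0)) {
    stop("all doses must be finite and >= 0")
  }
  .checkNumber(nCells, "nCells", lo = 1)
  if (params@b > 1) stop("background b must be <= 1 for the Bernoulli model")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(doses, function(D) {
    breaks <- stats::rpois(nCells, params@y * D)
    detected <- stats::rbinom(nCells, breaks, params@p)
    bg <- stats::rbinom(nCells, 1L, params@b)
    foci <- detected + bg
    data.frame(dose_Gy = D, mean_foci = mean(foci), sd_foci = stats::sd(foci),
               n = as.integer(nCells))
  })
  do.call(rbind, rows)
}

#' Simulate per-cell focus counts after site-specific cutting
#'
#' Each cell draws its number of cut-site copies from a [CopyModel-class];
#' each copy is cleaved with `cutProb(model)` and each cleavage detected as a
#' focus with probability `p`. Detected counts are therefore binomial with
#' per-copy success `cutProb * p`.
#'
#' @param model a [CopyModel-class].
#' @param p detection efficiency in \[0, 1\].
#' @param nCells number of cells (>= 1).
#' @param seed optional integer seed.
#' @return integer vector of per-cell focus counts, length `nCells`.
#' @examples
#' cm <- CopyModel(copies = c(2L, 4L), prob = c(0.5, 0.5), cutProb = 0.8)
#' table(simulateCutFoci(cm, p = 0.8, nCells = 1000, seed = 1))
#' @export
simulateCutFoci <- function(model, p, nCells, seed = NULL) {
  stopifnot(is(model, "CopyModel"))
  validObject(model)
  .checkNumber(p, "p", lo = 0, hi = 1)
  .checkNumber(nCells, "nCells", lo = 1)
  if (!is.null(seed)) set.seed(seed)
  copies <- model@copies[sample.int(length(model@copies), nCells,
                                    replace = TRUE, prob = model@prob)]
  stats::rbinom(nCells, copies, model@cutProb * p)
}

#' Simulate two-channel focus pairs at a given genomic separation
#'
#' Each cell receives one red focus (fixed chromosomal marker) at a random
#' position within a cell-sized field and one green focus (break site)
#' displaced in a uniformly random direction by a distance drawn from a
#' Rayleigh distribution whose mean follows a saturating exponential of
#' genomic distance:
#' `mean(d) = plateau * (1 - exp(-d / scaleKb))`.
#' At genomic distance 0 the displacement is exactly 0, so all pairs overlap
#' at any positive threshold; at large separation the mean plateaus
#' (physical distance in the folded nucleoid stops growing with genomic
#' distance).
#'
#' @param genomicDistanceKb genomic separation in kilobases (>= 0).
#' @param nCells number of cells.
#' @param plateau plateau of the mean physical distance, micrometres
#'   (default 0.57).
#' @param scaleKb saturation scale in kb (default 35).
#' @param cellDim numeric(2), field for the red focus placement in
#'   micrometres (default `c(3, 1)`, a rod-shaped cell).
#' @param seed optional integer seed.
#' @return data.frame of focus calls: `cell_id`, `channel` ("green"/"red"),
#'   `x_um`, `y_um`, `intensity`.
#' @examples
#' fp <- simulateFocusPairs(55, nCells = 100, seed = 1)
#' head(fp)
#' @export
simulateFocusPairs <- function(genomicDistanceKb, nCells, plateau = 0.57,
                               scaleKb = 35, cellDim = c(3, 1), seed = NULL) {
  .checkNumber(genomicDistanceKb, "genomicDistanceKb", lo = 0)
  .checkNumber(nCells, "nCells", lo = 1)
  .checkNumber(plateau, "plateau", lo = 0)
  .checkNumber(scaleKb, "scaleKb", lo = 1e-9)
  if (!is.null(seed)) set.seed(seed)
  mu <- plateau * (1 - exp(-genomicDistanceKb / scaleKb))
  xr <- stats::runif(nCells, 0, cellDim[1L])
  yr <- stats::runif(nCells, 0, cellDim[2L])
  ## Rayleigh magnitude with mean mu: sigma = mu * sqrt(2/pi)
  sig <- mu * sqrt(2 / pi)
  mag <- if (sig > 0) sig * sqrt(-2 * log(stats::runif(nCells))) else
    numeric(nCells)
  ang <- stats::runif(nCells, 0, 2 * pi)
  xg <- xr + mag * cos(ang)
  yg <- yr + mag * sin(ang)
  rbind(
    data.frame(cell_id = seq_len(nCells), channel = "red", x_um = xr,
               y_um = yr, intensity = 1),
    data.frame(cell_id = seq_len(nCells), channel = "green", x_um = xg,
               y_um = yg, intensity = 1)
  )
}

#' Render a synthetic fluorescence image with Poisson noise
#'
#' The expected value of each pixel is the scene background plus the sum of
#' two-dimensional Gaussian spot profiles evaluated at the pixel centre
#' (amplitude = expected photons at the peak); the returned image is a
#' Poisson draw around that expectation, so the total photon count over many
#' renders averages `background * n_pixels + sum(amplitude * 2 * pi *
#' (sigma/pixelSize)^2)`.
#'
#' @param scene an [ImageScene-class]; spots must lie inside the field.
#' @param seed optional integer seed (fixed seed gives an identical image).
#' @return numeric matrix `shape(scene)` of photon counts.
#' @examples
#' sc <- ImageScene(shape = c(32L, 32L), pixelSize = 0.1,
#'                  spots = data.frame(x_um = 1.5, y_um = 1.5,
#'                                     amplitude = 200, sigma_um = 0.1),
#'                  background = 5)
#' img <- renderImage(sc, seed = 1)
#' @export
renderImage <- function(scene, seed = NULL) {
  stopifnot(is(scene, "ImageScene"))
  validObject(scene)
  if (!is.null(seed)) set.seed(seed)
  nr <- scene@shape[1L]
  nc <- scene@shape[2L]
  px <- scene@pixelSize
  lambda <- matrix(scene@background, nr, nc)
  if (nrow(scene@spots)) {
    ycent <- (seq_len(nr) - 1L) * px
    xcent <- (seq_len(nc) - 1L) * px
    for (i in seq_len(nrow(scene@spots))) {
      s <- scene@spots[i, ]
      gy <- exp(-((ycent - s$y_um)^2) / (2 * s$sigma_um^2))
      gx <- exp(-((xcent - s$x_um)^2) / (2 * s$sigma_um^2))
      lambda <- lambda + s$amplitude * outer(gy, gx)
    }
  }
  matrix(stats::rpois(nr * nc, lambda), nr, nc)
}
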