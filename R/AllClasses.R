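#' @import methods
NULL

## ---------------------------------------------------------------------------
## SimParams
## ---------------------------------------------------------------------------

#' Parameters of the spontaneous-breakage simulation model
#'
#' `SimParams` bundles the parameters of the generative model used throughout
#' the package: a per-division double-strand-break (DSB) probability, a
#' detection efficiency thinning true breaks into visible foci, a spontaneous
#' background focus level, the literature radiation yield used for dose-response
#' simulation, the arrest-on-focus behaviour of focus-bearing cells, and a
#' piecewise interdivision-time schedule describing growth-medium regimes
#' (e.g. glucose followed by glucose withdrawal).
#'
#' @slot r numeric(1), probability a cell division produces a true DSB (in
#'   \[0, 1\]).
#' @slot p numeric(1), probability a true DSB is detected as a focus (in
#'   \[0, 1\]).
#' @slot b numeric(1), spontaneous background foci per cell at zero dose
#'   (per-cell Bernoulli probability; all calibrated regimes have b < 1).
#' @slot y numeric(1), true DSBs per cell per gray of ionizing radiation.
#' @slot arrestOnFocus logical(1), whether a cell stops dividing once it
#'   carries a focus (absorbing state).
#' @slot tauSchedule data.frame with columns `start_h` and `tau_h`: from time
#'   `start_h` (hours) onwards the mean interdivision time is `tau_h` (hours,
#'   `Inf` = divisions halted). Rows sorted, first row starts at 0.
#'
#' @param r,p,b,y,arrestOnFocus,tauSchedule see slot descriptions. Defaults
#'   are the calibrated study conditions: r = 0.021 DSBs per division,
#'   p = 0.71 detection, b = 0.043 background foci/cell, y = 0.031
#'   DSBs/cell/Gy, arrest on focus, and a mean interdivision time of 1.95 h
#'   for the first 9 h (a founder reaches ~100 cells, the observed
#'   microcolony size, since the memoryless branching process grows as
#'   `exp(t/tau)`) followed by starvation (tau = 26 h).
#' @return A `SimParams` object.
#' @examples
#' SimParams()
#' SimParams(r = 0.5, p = 1, tauSchedule = data.frame(start_h = 0, tau_h = 1))
#' @export SimParams
#' @exportClass SimParams
SimParams <- setClass("SimParams",
  slots = c(
    r = "numeric", p = "numeric", b = "numeric", y = "numeric",
    arrestOnFocus = "logical", tauSchedule = "data.frame"
  ),
  prototype = list(
    r = 0.021, p = 0.71, b = 0.043, y = 0.031, arrestOnFocus = TRUE,
    tauSchedule = data.frame(start_h = c(0, 9), tau_h = c(1.95, 26))
  )
)

setValidity("SimParams", function(object) {
  msg <- character(0)
  chk1 <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x)) paste0(nm, " must be a single finite number")
    else character(0)
  }
  msg <- c(msg, chk1(object@r, "r"), chk1(object@p, "p"),
           chk1(object@b, "b"), chk1(object@y, "y"))
  if (!length(msg)) {
    if (object@r < 0 || object@r > 1) msg <- c(msg, "r must lie in [0, 1]")
    if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
    if (object@b < 0) msg <- c(msg, "b must be non-negative")
    if (object@y < 0) msg <- c(msg, "y must be non-negative")
  }
  ts <- object@tauSchedule
  if (!all(c("start_h", "tau_h") %in% names(ts))) {
    msg <- c(msg, "tauSchedule needs columns start_h and tau_h")
  } else {
    if (nrow(ts) < 1L || ts$start_h[1L] != 0) {
      msg <- c(msg, "tauSchedule must start at time 0")
    }
    if (is.unsorted(ts$start_h, strictly = TRUE)) {
      msg <- c(msg, "tauSchedule start_h must be strictly increasing")
    }
    if (any(!(ts$tau_h > 0))) msg <- c(msg, "all tau_h must be strictly positive")
  }
  if (length(object@arrestOnFocus) != 1L || is.na(object@arrestOnFocus)) {
    msg <- c(msg, "arrestOnFocus must be TRUE or FALSE")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SimParams compact display
#' @param object a `SimParams` object
#' @export
setMethod("show", "SimParams", function(object) {
  cat("SimParams: r =", object@r, " p =", object@p,
      " (q = r*p =", signif(object@r * object@p, 4), ")\n")
  cat("  background b =", object@b, " yield y =", object@y, "DSB/cell/Gy\n")
  cat("  arrestOnFocus:", object@arrestOnFocus, "\n")
  cat("  tau schedule:",
      paste(sprintf("[%g h -> tau %g h]", object@tauSchedule$start_h,
                    object@tauSchedule$tau_h), collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## MicrocolonyTrace
## ---------------------------------------------------------------------------

#' Time-lapse record of one growing microcolony
#'
#' Lineage/time record of division and focus-appearance events in a single
#' microcolony growing from one founder cell, together with regularly sampled
#' frames of cumulative counts. Every frame satisfies
#' `n_cells == 1 + cum_divisions` (cells never die; they at most arrest), and
#' cumulative counts are non-decreasing. When the generating model arrests
#' focus-bearing cells, no cell divides after its focus event.
#'
#' @slot colonyId character(1) identifier.
#' @slot frames data.frame with columns `time_h`, `n_cells`, `cum_divisions`,
#'   `cum_foci`.
#' @slot events data.frame with columns `time_h`, `kind` ("division" or
#'   "focus") and `cell_id` (integer; for a division, the newborn cell).
#'
#' @param colonyId,frames,events see slots.
#' @return A `MicrocolonyTrace`.
#' @seealso [simulateMicrocolony()], [fociPerDivision()]
#' @export MicrocolonyTrace
#' @exportClass MicrocolonyTrace
MicrocolonyTrace <- setClass("MicrocolonyTrace",
  slots = c(colonyId = "character", frames = "data.frame", events = "data.frame"),
  prototype = list(
    colonyId = "colony",
    frames = data.frame(time_h = 0, n_cells = 1L, cum_divisions = 0L, cum_foci = 0L),
    events = data.frame(time_h = numeric(0), kind = character(0),
                        cell_id = integer(0))
  )
)

setValidity("MicrocolonyTrace", function(object) {
  msg <- character(0)
  fr <- object@frames
  ev <- object@events
  need <- c("time_h", "n_cells", "cum_divisions", "cum_foci")
  if (!all(need %in% names(fr))) {
    return(paste("frames needs columns", paste(need, collapse = ", ")))
  }
  if (!all(c("time_h", "kind", "cell_id") %in% names(ev))) {
    return("events needs columns time_h, kind, cell_id")
  }
  if (nrow(fr) < 1L) msg <- c(msg, "at least one frame required")
  if (is.unsorted(fr$time_h)) msg <- c(msg, "frame times must be non-decreasing")
  if (any(diff(fr$cum_divisions) < 0) || any(diff(fr$cum_foci) < 0)) {
    msg <- c(msg, "cumulative counts must be non-decreasing")
  }
  if (any(fr$n_cells != 1L + fr$cum_divisions)) {
    msg <- c(msg, "n_cells must equal 1 + cum_divisions in every frame")
  }
  if (nrow(ev) && !all(ev$kind %in% c("division", "focus"))) {
    msg <- c(msg, "event kind must be 'division' or 'focus'")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MicrocolonyTrace compact display
#' @param object a `MicrocolonyTrace`
#' @export
setMethod("show", "MicrocolonyTrace", function(object) {
  fr <- object@frames
  last <- fr[nrow(fr), ]
  cat("MicrocolonyTrace", object@colonyId, "\n")
  cat(sprintf("  %d frames over %g h; final: %d cells, %d divisions, %d foci\n",
              nrow(fr), last$time_h, last$n_cells, last$cum_divisions,
              last$cum_foci))
})

## ---------------------------------------------------------------------------
## CopyModel
## ---------------------------------------------------------------------------

#' Locus copy-number and cleavage model
#'
#' Distribution of chromosomal copies of a cut site per cell (replicating
#' cells hold more origin-proximal than terminus-proximal copies), with a
#' per-copy cleavage probability. Used to simulate and predict multi-focus
#' cell fractions after site-specific cutting.
#'
#' @slot copies integer vector of distinct copy numbers (support, all >= 1).
#' @slot prob numeric vector of probabilities, same length, summing to 1.
#' @slot cutProb numeric(1), per-copy cleavage probability in \[0, 1\].
#'
#' @param copies,prob,cutProb see slots.
#' @return A `CopyModel`.
#' @examples
#' ## log-phase ori-proximal site: some cells with 2, some with 4 copies
#' CopyModel(copies = c(2L, 4L), prob = c(0.5, 0.5), cutProb = 0.8)
#' @export CopyModel
#' @exportClass CopyModel
CopyModel <- setClass("CopyModel",
  slots = c(copies = "integer", prob = "numeric", cutProb = "numeric"),
  prototype = list(copies = 1L, prob = 1, cutProb = 1)
)

setValidity("CopyModel", function(object) {
  msg <- character(0)
  if (length(object@copies) != length(object@prob) || !length(object@copies)) {
    msg <- c(msg, "copies and prob must be non-empty and of equal length")
  }
  if (any(object@copies < 1L)) msg <- c(msg, "copy-number support must be >= 1")
  if (any(object@prob < 0) || abs(sum(object@prob) - 1) > 1e-8) {
    msg <- c(msg, "prob must be non-negative and sum to 1")
  }
  if (length(object@cutProb) != 1L || is.na(object@cutProb) ||
      object@cutProb < 0 || object@cutProb > 1) {
    msg <- c(msg, "cutProb must be a single value in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ImageScene
## ---------------------------------------------------------------------------

#' Ground-truth description of a synthetic fluorescence field
#'
#' Describes a single-channel field of diffraction-limited spots: image shape,
#' physical pixel size, a table of Gaussian spots (position in micrometres,
#' peak amplitude in expected photons, width sigma in micrometres) and a
#' uniform expected background per pixel. Rendering adds Poisson shot noise.
#' Coordinates are 0-based with the physical position of a pixel at its
#' centre; x runs along columns, y along rows.
#'
#' @slot shape integer(2), image rows and columns in pixels.
#' @slot pixelSize numeric(1), micrometres per pixel.
#' @slot spots data.frame with columns `x_um`, `y_um`, `amplitude`, `sigma_um`.
#' @slot background numeric(1), expected photons per pixel, >= 0.
#'
#' @param shape,pixelSize,spots,background see slots.
#' @return An `ImageScene`.
#' @seealso [renderImage()], [detectFoci()]
#' @export ImageScene
#' @exportClass ImageScene
ImageScene <- setClass("ImageScene",
  slots = c(shape = "integer", pixelSize = "numeric", spots = "data.frame",
            background = "numeric"),
  prototype = list(
    shape = c(32L, 32L), pixelSize = 0.1,
    spots = data.frame(x_um = numeric(0), y_um = numeric(0),
                       amplitude = numeric(0), sigma_um = numeric(0)),
    background = 0
  )
)

#' @describeIn ImageScene constructor coercion: `shape` may be given as
#'   plain numbers
#' @param .Object,... standard initialize arguments
#' @export
setMethod("initialize", "ImageScene", function(.Object, ..., shape = NULL) {
  if (!is.null(shape)) {
    callNextMethod(.Object, ..., shape = as.integer(shape))
  } else {
    callNextMethod(.Object, ...)
  }
})

setValidity("ImageScene", function(object) {
  msg <- character(0)
  if (length(object@shape) != 2L || any(object@shape < 1L)) {
    msg <- c(msg, "shape must be two positive integers (rows, cols)")
  }
  if (length(object@pixelSize) != 1L || !(object@pixelSize > 0)) {
    msg <- c(msg, "pixelSize must be a single positive number")
  }
  sp <- object@spots
  if (!all(c("x_um", "y_um", "amplitude", "sigma_um") %in% names(sp))) {
    msg <- c(msg, "spots needs columns x_um, y_um, amplitude, sigma_um")
  } else if (nrow(sp)) {
    xmax <- (object@shape[2L] - 1L) * object@pixelSize
    ymax <- (object@shape[1L] - 1L) * object@pixelSize
    if (any(sp$x_um < 0 | sp$x_um > xmax | sp$y_um < 0 | sp$y_um > ymax)) {
      msg <- c(msg, "all spots must lie inside the field")
    }
    if (any(sp$amplitude < 0) || any(!(sp$sigma_um > 0))) {
      msg <- c(msg, "spot amplitudes must be >= 0 and sigmas > 0")
    }
  }
  if (length(object@background) != 1L || object@background < 0) {
    msg <- c(msg, "background must be a single number >= 0")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CalibrationResult
## ---------------------------------------------------------------------------

#' Dose-response calibration of focus-detection efficiency
#'
#' Result of regressing mean foci per cell on radiation dose and dividing the
#' slope by a known break yield. `efficiency = slope / yield` exactly; `r2` is
#' reported only for three or more dose points (NA otherwise).
#'
#' @slot slope foci per cell per Gy.
#' @slot slopeSe standard error of the slope (NA for a two-point fit).
#' @slot intercept foci per cell at zero dose (fitted, not forced).
#' @slot r2 coefficient of determination, NA unless >= 3 dose points.
#' @slot yield assumed true DSBs per cell per Gy (NA if not supplied).
#' @slot efficiency slope/yield; may exceed 1 (flagged by warning, not clamped).
#' @slot efficiencySe delta-method standard error of the efficiency.
#' @slot efficiencyCI numeric(2) percentile bootstrap interval (NA until
#'   [bootstrapEfficiencyCI()] is run).
#' @seealso [fitDoseResponse()], [estimateEfficiency()],
#'   [bootstrapEfficiencyCI()]
#' @export
#' @exportClass CalibrationResult
CalibrationResult <- setClass("CalibrationResult",
  slots = c(slope = "numeric", slopeSe = "numeric", intercept = "numeric",
            r2 = "numeric", yield = "numeric", efficiency = "numeric",
            efficiencySe = "numeric", efficiencyCI = "numeric"),
  prototype = list(slope = NA_real_, slopeSe = NA_real_, intercept = NA_real_,
                   r2 = NA_real_, yield = NA_real_, efficiency = NA_real_,
                   efficiencySe = NA_real_, efficiencyCI = c(NA_real_, NA_real_))
)

setValidity("CalibrationResult", function(object) {
  msg <- character(0)
  if (length(object@efficiencyCI) != 2L) {
    msg <- c(msg, "efficiencyCI must have length 2")
  }
  if (is.finite(object@r2) && (object@r2 < 0 || object@r2 > 1)) {
    msg <- c(msg, "r2 must lie in [0, 1]")
  }
  if (is.finite(object@efficiency) && is.finite(object@slope) &&
      is.finite(object@yield) && object@yield > 0 &&
      abs(object@efficiency - object@slope / object@yield) > 1e-12) {
    msg <- c(msg, "efficiency must equal slope/yield")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CalibrationResult compact display
#' @param object a `CalibrationResult`
#' @export
setMethod("show", "CalibrationResult", function(object) {
  cat("CalibrationResult\n")
  cat(sprintf("  slope     : %s foci/cell/Gy (se %s)\n",
              signif(object@slope, 3), signif(object@slopeSe, 3)))
  cat(sprintf("  intercept : %s foci/cell\n", signif(object@intercept, 3)))
  cat(sprintf("  r2        : %s\n",
              if (is.na(object@r2)) "NA (two-point fit)" else signif(object@r2, 3)))
  if (is.finite(object@yield)) {
    cat(sprintf("  yield     : %s DSB/cell/Gy\n", signif(object@yield, 3)))
    cat(sprintf("  efficiency: %s", signif(object@efficiency, 3)))
    if (all(is.finite(object@efficiencyCI))) {
      cat(sprintf(" (95%% CI %s-%s)", signif(object@efficiencyCI[1L], 3),
                  signif(object@efficiencyCI[2L], 3)))
    }
    cat("\n")
  }
})

## ---------------------------------------------------------------------------
## RateEstimate
## ---------------------------------------------------------------------------

#' Spontaneous DSB rate per cell division
#'
#' Foci-per-division estimate over microcolonies with its efficiency-corrected
#' DSB rate. The headline estimator is the colony-level mean with SEM across
#' colonies; a pooled Wilson binomial interval on total foci over total
#' divisions is reported alongside. `r = f/p` exactly; by default `rSem`
#' excludes the efficiency's own uncertainty (`rSem = fSem/p`).
#'
#' @slot f foci per division (mean over colonies).
#' @slot fSem standard error of the mean of `f` across colonies.
#' @slot p detection efficiency used for the correction.
#' @slot r DSBs per division, `f/p`.
#' @slot rSem propagated standard error of `r`.
#' @slot nColonies number of colonies contributing.
#' @slot pooledQ pooled total foci / total divisions (NA when built from
#'   summary numbers only).
#' @slot qCI numeric(2) Wilson 95% interval on the pooled proportion.
#' @seealso [fociPerDivision()], [correctRate()]
#' @export
#' @exportClass RateEstimate
RateEstimate <- setClass("RateEstimate",
  slots = c(f = "numeric", fSem = "numeric", p = "numeric", r = "numeric",
            rSem = "numeric", nColonies = "integer", pooledQ = "numeric",
            qCI = "numeric"),
  prototype = list(f = NA_real_, fSem = NA_real_, p = NA_real_, r = NA_real_,
                   rSem = NA_real_, nColonies = NA_integer_, pooledQ = NA_real_,
                   qCI = c(NA_real_, NA_real_))
)

setValidity("RateEstimate", function(object) {
  msg <- character(0)
  if (is.finite(object@r) && is.finite(object@f) && is.finite(object@p) &&
      object@p > 0 && abs(object@r - object@f / object@p) > 1e-12) {
    msg <- c(msg, "r must equal f/p")
  }
  if (is.finite(object@fSem) && object@fSem < 0) msg <- c(msg, "fSem must be >= 0")
  if (is.finite(object@rSem) && object@rSem < 0) msg <- c(msg, "rSem must be >= 0")
  if (length(object@qCI) != 2L) msg <- c(msg, "qCI must have length 2")
  if (length(msg)) msg else TRUE
})

#' @describeIn RateEstimate compact display
#' @param object a `RateEstimate`
#' @export
setMethod("show", "RateEstimate", function(object) {
  cat("RateEstimate\n")
  cat(sprintf("  foci/division f : %s +/- %s (SEM, %s colonies)\n",
              signif(object@f, 3), signif(object@fSem, 3), object@nColonies))
  cat(sprintf("  efficiency p    : %s\n", signif(object@p, 3)))
  cat(sprintf("  DSB/division r  : %s +/- %s\n",
              signif(object@r, 3), signif(object@rSem, 3)))
  if (all(is.finite(object@qCI))) {
    cat(sprintf("  pooled q        : %s (Wilson 95%% %s-%s)\n",
                signif(object@pooledQ, 3), signif(object@qCI[1L], 3),
                signif(object@qCI[2L], 3)))
  }
})
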