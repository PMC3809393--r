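#' Accessors for calibration and rate objects
#'
#' Slot accessors so downstream code never touches `@` directly.
#'
#' @param x a [CalibrationResult-class], [RateEstimate-class] or
#'   [MicrocolonyTrace-class] object, as appropriate.
#' @return `slope`, `efficiency`, `dsbRate`, `fociRate` return a single
#'   numeric; `efficiencyCI` a numeric(2); `colonyId` a character(1);
#'   `frames` and `events` the corresponding data.frame.
#' @examples
#' cal <- fitDoseResponse(
#'   data.frame(dose_Gy = c(0, 140), mean_foci = c(0.043, 3.12),
#'              sd_foci = c(NA, NA), n = c(1000, 1000)),
#'   yield = 0.031)
#' slope(cal)
#' efficiency(cal)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("slope", function(x) standardGeneric("slope"))

#' @rdname accessors
#' @export
setMethod("slope", "CalibrationResult", function(x) x@slope)

#' @rdname accessors
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))

#' @rdname accessors
#' @export
setMethod("efficiency", "CalibrationResult", function(x) x@efficiency)

#' @rdname accessors
#' @export
setGeneric("efficiencyCI", function(x) standardGeneric("efficiencyCI"))

#' @rdname accessors
#' @export
setMethod("efficiencyCI", "CalibrationResult", function(x) x@efficiencyCI)

#' @rdname accessors
#' @export
setGeneric("dsbRate", function(x) standardGeneric("dsbRate"))

#' @rdname accessors
#' @export
setMethod("dsbRate", "RateEstimate", function(x) x@r)

#' @rdname accessors
#' @export
setGeneric("fociRate", function(x) standardGeneric("fociRate"))

#' @rdname accessors
#' @export
setMethod("fociRate", "RateEstimate", function(x) x@f)

#' @rdname accessors
#' @export
setGeneric("colonyId", function(x) standardGeneric("colonyId"))

#' @rdname accessors
#' @export
setMethod("colonyId", "MicrocolonyTrace", function(x) x@colonyId)

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setMethod("frames", "MicrocolonyTrace", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setMethod("events", "MicrocolonyTrace", function(x) x@events)
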