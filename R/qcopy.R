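## qPCR delta-Ct relative copy number and the forward model linking locus
## copy number to multi-focus cell fractions.

#' Relative ori:ter copy number by the delta-Ct method
#'
#' For each sample, `deltaCt = mean Ct(ter locus) - mean Ct(ori locus)`
#' (replicates averaged on the Ct scale); the ratio is
#' `E ^ (deltaCt_sample - deltaCt_reference)` where the reference sample
#' (stationary phase) is assumed to hold equal ori and ter copies. With the
#' default per-cycle amplification `E = 2`, a delta-delta-Ct of 1 is a
#' two-fold ratio. A per-sample constant added to all Ct values (pipetting
#' offset) cancels in the difference.
#'
#' @param table data.frame with columns `sample`, `locus`, `ct` (cycles,
#'   > 0); at least one replicate per locus per sample.
#' @param reference the reference sample label.
#' @param E amplification efficiency, fold per cycle (> 1, default 2).
#' @param ori,ter locus labels (defaults `"oriC"`, `"terC"`).
#' @return data.frame with one row per sample: `sample`, `delta_ct`,
#'   `ratio` (ori:ter copies relative to the reference).
#' @examples
#' tab <- data.frame(
#'   sample = rep(c("stat", "log"), each = 4),
#'   locus = rep(c("oriC", "terC"), 4),
#'   ct = c(20, 20, 20, 20, 18, 19.585, 18, 19.585))
#' relativeCopyNumber(tab, reference = "stat")   # log ratio ~ 3
#' @export
relativeCopyNumber <- function(table, reference, E = 2, ori = "oriC",
                               ter = "terC") {
  need <- c("sample", "locus", "ct")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("Ct table needs columns ", paste(need, collapse = ", "))
  }
  if (!is.finite(E) || E <= 1) stop("'E' must be > 1 (fold per cycle)")
  if (any(!is.finite(table$ct)) || any(table$ct <= 0)) {
    stop("all Ct values must be finite and > 0")
  }
  samples <- unique(table$sample)
  if (!reference %in% samples) stop("reference sample '", reference,
                                    "' not present")
  deltaCt <- vapply(samples, function(s) {
    sub <- table[table$sample == s, , drop = FALSE]
    ctOri <- sub$ct[sub$locus == ori]
    ctTer <- sub$ct[sub$locus == ter]
    if (!length(ctOri) || !length(ctTer)) {
      stop("sample '", s, "' is missing locus ",
           if (!length(ctOri)) ori else ter)
    }
    mean(ctTer) - mean(ctOri)
  }, numeric(1))
  ddCt <- deltaCt - deltaCt[match(reference, samples)]
  data.frame(sample = samples, delta_ct = unname(deltaCt),
             ratio = unname(E^ddCt))
}

#' Expected fraction of cells with more than one focus
#'
#' Exact forward model: a cell with `k` cut-site copies (drawn from the
#' [CopyModel-class] distribution) shows a number of foci that is binomial
#' with `k` trials and per-copy success `cutProb * p`, so
#' `P(> 1 focus) = sum_k w_k * (1 - P0_k - P1_k)`. Monotone non-decreasing
#' in mean copy number, in `cutProb` and in `p`: more copies or more
#' efficient cutting/detection can only raise the multi-focus fraction.
#'
#' @param model a [CopyModel-class].
#' @param p detection efficiency in \[0, 1\].
#' @return numeric(1), probability of more than one focus per cell.
#' @examples
#' cm <- CopyModel(copies = c(2L, 4L), prob = c(0.5, 0.5), cutProb = 0.8)
#' expectedMultifocusFraction(cm, p = 0.8)
#' @export
expectedMultifocusFraction <- function(model, p) {
  stopifnot(is(model, "CopyModel"))
  validObject(model)
  .checkNumber(p, "p", lo = 0, hi = 1)
  pc <- model@cutProb * p
  sum(model@prob * (1 - stats::dbinom(0, model@copies, pc) -
                      stats::dbinom(1, model@copies, pc)))
}
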