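#' Derive a reproducible sub-seed from a global seed and a stream label
#'
#' A single run seed fans out to per-module random streams by stable string
#' labels, so adding a pipeline stage never shifts the draws of existing
#' stages. The derived seed is a deterministic function of `(seed, label)` and
#' always fits a 32-bit integer.
#'
#' @param seed non-negative integer, the global run seed.
#' @param label character(1) stream name, e.g. `"traces"`.
#' @return integer(1) sub-seed in \[0, 2^31).
#' @examples
#' seedStream(1, "traces")
#' seedStream(1, "dose")
#' @export
seedStream <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), seed >= 0,
            is.character(label), length(label) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) %% 1048573 * 1048573 + h * 7919 + seed %% 7919) %%
               2147483587)
}

#' Wilson 95% confidence interval for a binomial proportion
#'
#' Score (Wilson) interval, without continuity correction; well behaved at
#' small counts, used for the pooled foci-per-division proportion.
#'
#' @param x number of successes.
#' @param n number of trials (> 0).
#' @param conf confidence level, default 0.95.
#' @return numeric(2), lower and upper bounds.
#' @examples
#' wilsonInterval(29, 2000)
#' @export
wilsonInterval <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  den <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / den
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

## single finite-number argument check with a parameter error
.checkNumber <- function(x, nm, lo = -Inf, hi = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < lo || x > hi) {
    stop("parameter '", nm, "' must be a single finite number in [",
         lo, ", ", hi, "]", call. = FALSE)
  }
  invisible(x)
}

## log-scale ratio CI between two binomial proportions x1/n1 and x2/n2
## (relative risk); returns c(est, lo, hi) or NAs when undefined.
.propRatioCI <- function(x1, n1, x2, n2, conf = 0.95) {
  if (n1 <= 0 || n2 <= 0 || x1 <= 0 || x2 <= 0) {
    return(c(est = if (n1 > 0 && n2 > 0 && x1 > 0) 0 else NA_real_,
             lo = NA_real_, hi = NA_real_))
  }
  est <- (x2 / n2) / (x1 / n1)
  se <- sqrt(max(0, 1 / x1 - 1 / n1) + max(0, 1 / x2 - 1 / n2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(est = est, lo = est * exp(-z * se), hi = est * exp(z * se))
}

## Poisson rate-ratio CI between counts x1 in time T1 and x2 in T2.
.rateRatioCI <- function(x1, t1, x2, t2, conf = 0.95) {
  if (t1 <= 0 || t2 <= 0 || x1 <= 0 || x2 <= 0) {
    return(c(est = if (t1 > 0 && t2 > 0 && x1 > 0) 0 else NA_real_,
             lo = NA_real_, hi = NA_real_))
  }
  est <- (x2 / t2) / (x1 / t1)
  se <- sqrt(1 / x1 + 1 / x2)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(est = est, lo = est * exp(-z * se), hi = est * exp(z * se))
}
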