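## Two-channel focus geometry: per-cell matching of green (break) and red
## (chromosomal marker) foci, overlap classification, near/far interfocal
## distances, per-focus category counting, and the green-per-red efficiency
## ratio.

## exact minimum-total-distance assignment of rows (s) to columns (l >= s)
## of a cost matrix, by depth-first branch and bound; deterministic: the
## first-found optimum in row-major order wins ties, so pre-sorted input
## gives reproducible matchings. Returns the column index for each row.
.assignExact <- function(D) {
  s <- nrow(D)
  l <- ncol(D)
  best <- Inf
  bestSel <- integer(s)
  used <- logical(l)
  sel <- integer(s)
  rec <- function(i, cost) {
    if (cost >= best) return(invisible())
    if (i > s) {
      best <<- cost
      bestSel <<- sel
      return(invisible())
    }
    for (j in seq_len(l)) {
      if (!used[j]) {
        used[j] <<- TRUE
        sel[i] <<- j
        rec(i + 1L, cost + D[i, j])
        used[j] <<- FALSE
      }
    }
  }
  rec(1L, 0)
  bestSel
}

## greedy fallback for large cells: repeatedly match the globally nearest
## unmatched pair
.assignGreedy <- function(D) {
  s <- nrow(D)
  sel <- integer(s)
  usedR <- logical(s)
  usedC <- logical(ncol(D))
  for (k in seq_len(s)) {
    Dm <- D
    Dm[usedR, ] <- Inf
    Dm[, usedC] <- Inf
    ij <- which(Dm == min(Dm), arr.ind = TRUE)[1L, ]
    sel[ij[1L]] <- ij[2L]
    usedR[ij[1L]] <- TRUE
    usedC[ij[2L]] <- TRUE
  }
  sel
}

.sortCalls <- function(df) df[order(df$x_um, df$y_um), , drop = FALSE]

#' Match green and red foci within each cell
#'
#' Pairs the two channels per cell by minimum-total Euclidean distance
#' (exact branch-and-bound assignment up to 8 foci per channel, greedy
#' global-nearest above that; within a channel calls are first sorted by
#' (x, y) so ties resolve by call order deterministically). Cells are
#' classified by their channel counts: `1:1` (one green, one red), `1:2`
#' (one green, two red — contributing a near and a far distance to the
#' single green focus), or `other`. Cells with an empty channel are excluded
#' from pairing but counted.
#'
#' @param calls data.frame of focus calls with columns `cell_id`, `channel`
#'   (values `green`/`red`, or any two labels via `channels`), `x_um`,
#'   `y_um`.
#' @param channels character(2), which labels to treat as (green, red).
#' @return list with
#'   `pairs` (data.frame: `cell_id`, `ratio_class`, `distance_um` for every
#'   matched pair), `cells` (data.frame: `cell_id`, `n_green`, `n_red`,
#'   `ratio_class`, and `near_um`/`far_um` filled for 1:2 cells),
#'   `nExcluded` (cells with an empty channel).
#' @examples
#' fp <- simulateFocusPairs(55, nCells = 50, seed = 1)
#' m <- matchFoci(fp)
#' head(m$pairs)
#' @export
matchFoci <- function(calls, channels = c("green", "red")) {
  need <- c("cell_id", "channel", "x_um", "y_um")
  if (!is.data.frame(calls) || !all(need %in% names(calls))) {
    stop("'calls' needs columns ", paste(need, collapse = ", "))
  }
  cellIds <- unique(calls$cell_id)
  pairRows <- list()
  cellRows <- list()
  nExcluded <- 0L
  for (cid in cellIds) {
    sub <- calls[calls$cell_id == cid, , drop = FALSE]
    g <- .sortCalls(sub[sub$channel == channels[1L], , drop = FALSE])
    r <- .sortCalls(sub[sub$channel == channels[2L], , drop = FALSE])
    ng <- nrow(g)
    nr <- nrow(r)
    if (ng == 0L || nr == 0L) {
      nExcluded <- nExcluded + 1L
      next
    }
    cls <- if (ng == 1L && nr == 1L) "1:1"
           else if (ng == 1L && nr == 2L) "1:2"
           else "other"
    ## distance matrix with green on the smaller side convention: rows =
    ## smaller channel
    D <- outer(seq_len(ng), seq_len(nr), function(i, j)
      sqrt((g$x_um[i] - r$x_um[j])^2 + (g$y_um[i] - r$y_um[j])^2))
    if (ng <= nr) {
      sel <- if (ng <= 8L && nr <= 8L) .assignExact(D) else .assignGreedy(D)
      d <- D[cbind(seq_len(ng), sel)]
    } else {
      Dt <- t(D)
      sel <- if (ng <= 8L && nr <= 8L) .assignExact(Dt) else .assignGreedy(Dt)
      d <- Dt[cbind(seq_len(nr), sel)]
    }
    pairRows[[length(pairRows) + 1L]] <- data.frame(
      cell_id = cid, ratio_class = cls, distance_um = d)
    nearFar <- c(NA_real_, NA_real_)
    if (cls == "1:2") nearFar <- c(min(D[1L, ]), max(D[1L, ]))
    cellRows[[length(cellRows) + 1L]] <- data.frame(
      cell_id = cid, n_green = ng, n_red = nr, ratio_class = cls,
      near_um = nearFar[1L], far_um = nearFar[2L])
  }
  list(pairs = if (length(pairRows)) do.call(rbind, pairRows) else
         data.frame(cell_id = character(0), ratio_class = character(0),
                    distance_um = numeric(0)),
       cells = if (length(cellRows)) do.call(rbind, cellRows) else
         data.frame(cell_id = character(0), n_green = integer(0),
                    n_red = integer(0), ratio_class = character(0),
                    near_um = numeric(0), far_um = numeric(0)),
       nExcluded = nExcluded)
}

#' Fraction of cells with overlapping two-channel foci
#'
#' Among 1:1 cells, the percentage whose pair distance is at or below the
#' overlap threshold (the operational definition of a "yellow" focus). With
#' experiment labels the SEM is taken across experiment-level percentages;
#' without, a binomial SEM over cells is reported. Monotone non-decreasing
#' in the threshold.
#'
#' @param match result of [matchFoci()].
#' @param thresholdUm overlap threshold in micrometres (default 0.2,
#'   approximately the diffraction limit).
#' @param experiment optional vector of experiment labels, parallel to the
#'   1:1 rows of `match$cells`.
#' @return list with `pct` (percent overlapped), `sem`, `nCells` (1:1 cells
#'   used).
#' @examples
#' fp <- simulateFocusPairs(10, nCells = 200, seed = 2)
#' colocalizationFraction(matchFoci(fp))
#' @export
colocalizationFraction <- function(match, thresholdUm = 0.2,
                                   experiment = NULL) {
  if (!is.finite(thresholdUm) || thresholdUm <= 0) {
    stop("'thresholdUm' must be > 0")
  }
  one <- match$pairs[match$pairs$ratio_class == "1:1", , drop = FALSE]
  n <- nrow(one)
  if (!n) stop("no 1:1 cells to classify")
  hit <- one$distance_um <= thresholdUm
  pct <- 100 * mean(hit)
  if (!is.null(experiment)) {
    stopifnot(length(experiment) == n)
    per <- tapply(hit, experiment, function(z) 100 * mean(z))
    sem <- if (length(per) > 1L) stats::sd(per) / sqrt(length(per)) else 0
  } else {
    sem <- 100 * sqrt(mean(hit) * (1 - mean(hit)) / n)
  }
  list(pct = pct, sem = sem, nCells = n)
}

#' Mean interfocal distances by ratio class
#'
#' Means of the matched pair distances, computed separately for the 1:1
#' population and for the near and far distances of 1:2 cells. Empty classes
#' are reported as absent (`NA`), never as zero.
#'
#' @param match result of [matchFoci()].
#' @return list with `mean_1to1_um`, `mean_near_um`, `mean_far_um` and the
#'   per-class cell counts `n_1to1`, `n_1to2`.
#' @examples
#' fp <- simulateFocusPairs(2400, nCells = 200, seed = 3)
#' interfocalSummary(matchFoci(fp))
#' @export
interfocalSummary <- function(match) {
  one <- match$pairs[match$pairs$ratio_class == "1:1", , drop = FALSE]
  two <- match$cells[match$cells$ratio_class == "1:2", , drop = FALSE]
  list(
    mean_1to1_um = if (nrow(one)) mean(one$distance_um) else NA_real_,
    mean_near_um = if (nrow(two)) mean(two$near_um) else NA_real_,
    mean_far_um = if (nrow(two)) mean(two$far_um) else NA_real_,
    n_1to1 = nrow(one),
    n_1to2 = nrow(two)
  )
}

#' Count single- and double-marker focus categories
#'
#' Per-focus (not per-cell) classification of two marker channels in a
#' shared coordinate frame: foci within `thresholdUm` of a focus in the
#' other channel are matched greedily by global nearest distance, each focus
#' at most once, and counted as "both"; the remainder are single-channel.
#' With `denominator = "pairs"` (default) each matched pair counts once, so
#' percentages are of `nBoth + nAonly + nBonly`; `denominator = "foci"`
#' instead counts matched foci individually over all foci.
#'
#' @param callsA,callsB data.frames with columns `x_um`, `y_um`.
#' @param thresholdUm match threshold in micrometres.
#' @param denominator `"pairs"` or `"foci"`.
#' @return list with counts `nBoth`, `nAonly`, `nBonly` and percentages
#'   `pctBoth`, `pctAonly`, `pctBonly` (summing to 100).
#' @examples
#' a <- data.frame(x_um = c(0, 1, 2), y_um = 0)
#' b <- data.frame(x_um = c(0.05, 5), y_um = 0)
#' categoryCounts(a, b, thresholdUm = 0.2)
#' @export
categoryCounts <- function(callsA, callsB, thresholdUm = 0.2,
                           denominator = c("pairs", "foci")) {
  denominator <- match.arg(denominator)
  if (!nrow(callsA) && !nrow(callsB)) stop("both channels are empty")
  if (!is.finite(thresholdUm) || thresholdUm <= 0) {
    stop("'thresholdUm' must be > 0")
  }
  a <- .sortCalls(callsA)
  b <- .sortCalls(callsB)
  nA <- nrow(a)
  nB <- nrow(b)
  nBoth <- 0L
  if (nA && nB) {
    D <- outer(seq_len(nA), seq_len(nB), function(i, j)
      sqrt((a$x_um[i] - b$x_um[j])^2 + (a$y_um[i] - b$y_um[j])^2))
    usedA <- logical(nA)
    usedB <- logical(nB)
    repeat {
      Dm <- D
      Dm[usedA, ] <- Inf
      Dm[, usedB] <- Inf
      m <- min(Dm)
      if (!is.finite(m) || m > thresholdUm) break
      ij <- which(Dm == m, arr.ind = TRUE)[1L, ]
      usedA[ij[1L]] <- TRUE
      usedB[ij[2L]] <- TRUE
      nBoth <- nBoth + 1L
    }
  }
  nAonly <- nA - nBoth
  nBonly <- nB - nBoth
  total <- if (denominator == "pairs") nBoth + nAonly + nBonly else nA + nB
  bothCount <- if (denominator == "pairs") nBoth else 2L * nBoth
  list(nBoth = nBoth, nAonly = nAonly, nBonly = nBonly,
       pctBoth = 100 * bothCount / total,
       pctAonly = 100 * nAonly / total,
       pctBonly = 100 * nBonly / total)
}

#' Green foci per red focus
#'
#' Total green (break-marking) foci over total red (chromosome-marking) foci
#' across cells, restricted to cells with at least one red focus: a rough
#' per-chromosome detection efficiency when every red-marked chromosome is
#' cut.
#'
#' @param greenCounts,redCounts integer vectors of per-cell focus counts,
#'   equal length.
#' @return numeric(1), the ratio.
#' @examples
#' greenPerRed(c(1, 0, 1), c(1, 1, 1))
#' @export
greenPerRed <- function(greenCounts, redCounts) {
  stopifnot(length(greenCounts) == length(redCounts))
  inc <- redCounts > 0
  if (!any(inc)) stop("no cells with red foci")
  sum(greenCounts[inc]) / sum(redCounts[inc])
}
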