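## Independent oracles used across tests. These deliberately re-derive
## expectations by brute force / closed form, separate from the package's
## own code paths.

## exhaustive minimum-total-distance assignment cost by permutation
## enumeration (rows of D assigned to distinct columns, nrow(D) <= ncol(D))
bruteAssignCost <- function(D) {
  s <- nrow(D)
  best <- Inf
  rec <- function(i, avail, acc) {
    if (i > s) {
      best <<- min(best, acc)
      return(invisible())
    }
    for (j in avail) rec(i + 1L, setdiff(avail, j), acc + D[i, j])
  }
  rec(1L, seq_len(ncol(D)), 0)
  best
}

## pairwise Euclidean distance matrix between two coordinate data.frames
distMat <- function(a, b) {
  outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
    sqrt((a$x_um[i] - b$x_um[j])^2 + (a$y_um[i] - b$y_um[j])^2))
}

## minimal trace with given final counts (for estimator arithmetic tests)
makeTrace <- function(foci, divisions, id = "t") {
  MicrocolonyTrace(
    colonyId = id,
    frames = data.frame(
      time_h = c(0, 10),
      n_cells = as.integer(c(1, 1 + divisions)),
      cum_divisions = as.integer(c(0, divisions)),
      cum_foci = as.integer(c(0, foci))),
    events = data.frame(time_h = numeric(0), kind = character(0),
                        cell_id = integer(0)))
}

## greedy one-to-one matching of called spots to planted truth within a
## distance tolerance; returns true/false positives and false negatives
scoreCalls <- function(truth, calls, tolUm) {
  nT <- nrow(truth)
  nC <- nrow(calls)
  if (nT == 0L || nC == 0L) {
    return(list(tp = 0L, fp = nC, fn = nT))
  }
  D <- distMat(truth, calls)
  usedT <- logical(nT)
  usedC <- logical(nC)
  tp <- 0L
  repeat {
    Dm <- D
    Dm[usedT, ] <- Inf
    Dm[, usedC] <- Inf
    m <- min(Dm)
    if (!is.finite(m) || m > tolUm) break
    ij <- which(Dm == m, arr.ind = TRUE)[1L, ]
    usedT[ij[1L]] <- TRUE
    usedC[ij[2L]] <- TRUE
    tp <- tp + 1L
  }
  list(tp = tp, fp = nC - tp, fn = nT - tp)
}

## grid of square cell masks: k x k cells, each cellPx x cellPx pixels
gridMasks <- function(k, cellPx) {
  row0 <- rep(seq_len(k), each = cellPx)
  m <- outer(row0, row0, function(i, j) (i - 1L) * k + j)
  matrix(as.integer(m), k * cellPx, k * cellPx)
}
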