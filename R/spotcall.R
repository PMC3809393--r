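## Spot calling on single-channel fluorescence images: difference-of-Gaussians
## band-pass at the optical scale, robust thresholding, local maxima with a
## deterministic tie-break, and sub-pixel centroiding.

## shift a matrix by (dr, dc), padding with `fill`
.shiftMat <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  okr <- rs >= 1L & rs <= nr
  okc <- cs >= 1L & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

#' Detect fluorescent foci in a single-channel image
#'
#' Band-pass filters the image with a difference of Gaussians at the optical
#' scale (`psfSigma` and `1.6 * psfSigma`), estimates a robust background on
#' the filtered image (median) and spread (1.4826 x MAD), and reports local
#' maxima exceeding `median + kSigma * spread`. A pixel is a local maximum
#' over its 8-neighbourhood; ties between adjacent equal maxima are resolved
#' in favour of the lowest (row, col) index. Sub-pixel centres are
#' intensity-weighted centroids over the 3x3 window of the
#' background-subtracted raw image. Because the band-pass annihilates any
#' constant offset and the threshold is robust, detection counts are
#' invariant under addition of a constant to the whole image.
#'
#' Coordinates follow the package convention: 0-based pixel indices, physical
#' position at the pixel centre, x along columns, y along rows.
#'
#' @param image 2-D non-negative numeric matrix.
#' @param pixelSize micrometres per pixel.
#' @param psfSigma point-spread-function sigma in micrometres (> 0).
#' @param kSigma detection threshold in robust standard deviations above the
#'   filtered background (default 5; stable on sparse-spot images).
#' @return data.frame of calls: `x_um`, `y_um`, `intensity` (background-
#'   subtracted 3x3 integral), `row`, `col` (1-based peak pixel indices).
#' @seealso [renderImage()] for matched synthetic ground truth,
#'   [countFociPerCell()]
#' @examples
#' sc <- ImageScene(shape = c(32L, 32L), pixelSize = 0.1,
#'                  spots = data.frame(x_um = 1.5, y_um = 1.5,
#'                                     amplitude = 300, sigma_um = 0.1),
#'                  background = 10)
#' detectFoci(renderImage(sc, seed = 1), pixelSize = 0.1, psfSigma = 0.1)
#' @export
detectFoci <- function(image, pixelSize, psfSigma, kSigma = 5) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be a 2-D numeric matrix")
  }
  .checkNumber(pixelSize, "pixelSize", lo = 1e-12)
  .checkNumber(psfSigma, "psfSigma", lo = 1e-12)
  .checkNumber(kSigma, "kSigma", lo = 1e-12)

  s1 <- psfSigma / pixelSize
  s2 <- 1.6 * s1
  dog <- as.matrix(EBImage::gblur(image, sigma = s1)) -
    as.matrix(EBImage::gblur(image, sigma = s2))

  thr <- stats::median(dog) + kSigma * stats::mad(dog)

  ## local maxima: strictly greater than earlier-raster neighbours, >= later,
  ## so the lowest (row, col) pixel of an equal-valued plateau wins
  earlier <- list(c(-1L, -1L), c(0L, -1L), c(1L, -1L), c(-1L, 0L))
  later <- list(c(-1L, 1L), c(0L, 1L), c(1L, 1L), c(1L, 0L))
  peak <- dog > thr
  for (d in earlier) peak <- peak & (dog > .shiftMat(dog, d[1L], d[2L]))
  for (d in later) peak <- peak & (dog >= .shiftMat(dog, d[1L], d[2L]))

  idx <- which(peak, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), row = integer(0),
                      col = integer(0)))
  }
  ## deterministic output order: raster (row within col-major handled below)
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]

  bg <- stats::median(image)
  sub <- pmax(image - bg, 0)
  nr <- nrow(image); nc <- ncol(image)
  n <- nrow(idx)
  x_um <- y_um <- intensity <- numeric(n)
  for (k in seq_len(n)) {
    r <- idx[k, 1L]; cc <- idx[k, 2L]
    rr <- max(1L, r - 1L):min(nr, r + 1L)
    cs <- max(1L, cc - 1L):min(nc, cc + 1L)
    w <- sub[rr, cs, drop = FALSE]
    tot <- sum(w)
    if (tot > 0) {
      rcent <- sum(rowSums(w) * rr) / tot
      ccent <- sum(colSums(w) * cs) / tot
    } else {
      rcent <- r; ccent <- cc
    }
    x_um[k] <- (ccent - 1) * pixelSize
    y_um[k] <- (rcent - 1) * pixelSize
    intensity[k] <- tot
  }
  data.frame(x_um = x_um, y_um = y_um, intensity = intensity,
             row = idx[, 1L], col = idx[, 2L])
}

#' Count detected foci per cell from a labelled mask
#'
#' Assigns each call to the cell whose mask label covers its peak pixel.
#' Calls over background (label 0) are reported separately as unassigned,
#' never silently dropped.
#'
#' @param calls data.frame from [detectFoci()] (needs `row`, `col`).
#' @param masks integer matrix of the same shape as the image; 0 =
#'   background, positive labels = cells.
#' @return data.frame with one row per mask label: `cell_id`, `n_foci`;
#'   attribute `"unassigned"` holds the number of calls outside every mask.
#' @examples
#' m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 1L; m[5:7, 5:7] <- 2L
#' calls <- data.frame(x_um = 0, y_um = 0, intensity = 1,
#'                     row = c(3L, 6L, 6L), col = c(3L, 6L, 5L))
#' countFociPerCell(calls, m)
#' @export
countFociPerCell <- function(calls, masks) {
  if (!is.matrix(masks)) stop("'masks' must be an integer matrix")
  labels <- sort(unique(masks[masks > 0]))
  out <- data.frame(cell_id = as.integer(labels),
                    n_foci = integer(length(labels)))
  unassigned <- 0L
  if (nrow(calls)) {
    lab <- masks[cbind(calls$row, calls$col)]
    unassigned <- sum(lab == 0L)
    tab <- table(factor(lab[lab > 0L], levels = labels))
    out$n_foci <- as.integer(tab)
  }
  attr(out, "unassigned") <- unassigned
  out
}
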