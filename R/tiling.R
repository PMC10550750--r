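#' Otsu threshold of an 8-bit histogram
#'
#' Computes the threshold `t` maximizing the between-class variance of the
#' split `{0..t-1}` vs `{t..255}`, so that "intensity < t" selects the dark
#' class exactly. Histology background is bright, tissue dark, which is why
#' downstream masking marks tissue where luminance falls below the
#' threshold. Ties are broken by the smallest maximizing threshold.
#'
#' @param histogram 256 non-negative counts for intensity bins 0..255.
#' @return Integer threshold in `[1, 255]`.
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256L)
    stop("histogram must have exactly 256 bins")
  h <- as.numeric(histogram)
  if (anyNA(h) || any(h < 0)) stop("histogram counts must be non-negative")
  n <- sum(h)
  if (n <= 0) stop("histogram must contain at least one count")
  if (sum(h > 0) == 1L)
    stop("degenerate histogram: all mass in a single bin")
  v <- 0:255
  # candidate thresholds t = 1..255 split into {0..t-1} and {t..255}
  w0 <- cumsum(h)[1:255]              # mass of the dark class for each t
  m0 <- cumsum(h * v)[1:255]          # its first moment
  w1 <- n - w0
  m1 <- sum(h * v) - m0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (m0[valid] / w0[valid] - m1[valid] / w1[valid])^2 *
    w0[valid] * w1[valid]
  as.integer(which.max(bcv))          # which.max returns the first maximum
}

#' Tissue mask of a slide by Otsu thresholding
#'
#' Builds a thumbnail by area-averaging `downsample x downsample` blocks,
#' converts it to 8-bit luminance (0.299 R + 0.587 G + 0.114 B), applies
#' [otsu_threshold()], and marks tissue where luminance is strictly below
#' the threshold (tissue is darker than the bright background whitespace).
#'
#' @param slide a `pcead_slide`.
#' @param downsample integer thumbnail downsample factor (>= 1).
#' @param invert if `TRUE`, flip the polarity (tissue = bright class).
#' @return A `pcead_tissue_mask`: logical matrix `mask` of dimensions
#'   `ceiling(slide dims / downsample)`, plus `threshold`, `downsample` and
#'   `invert`.
#' @export
compute_tissue_mask <- function(slide, downsample = 32L, invert = FALSE) {
  stopifnot(downsample >= 1)
  lum <- 0.299 * slide$image[, , 1] + 0.587 * slide$image[, , 2] +
    0.114 * slide$image[, , 3]
  thumb <- block_reduce(lum, as.integer(downsample))
  lum8 <- pmin(pmax(as.integer(round(thumb * 255)), 0L), 255L)
  histo <- tabulate(as.vector(lum8) + 1L, nbins = 256L)
  thr <- otsu_threshold(histo)
  m <- matrix(lum8 < thr, nrow = nrow(thumb))
  if (invert) m <- !m
  structure(list(mask = m, threshold = thr,
                 downsample = as.integer(downsample), invert = invert),
            class = "pcead_tissue_mask")
}

# Area-average a matrix over d x d blocks; ragged right/bottom blocks are
# averaged over the pixels they actually contain.
block_reduce <- function(m, d) {
  if (d == 1L) return(m)
  h <- nrow(m); w <- ncol(m)
  ri <- (seq_len(h) - 1L) %/% d + 1L
  ci <- (seq_len(w) - 1L) %/% d + 1L
  s <- rowsum(m, ri)                 # sum rows into blocks
  s <- t(rowsum(t(s), ci))           # then columns
  cnt <- outer(tabulate(ri), tabulate(ci))
  s / cnt
}

#' Level-0 bounding box of the tissue in a mask
#'
#' @param mask a `pcead_tissue_mask`.
#' @param slide optional slide used to clamp the box to the slide bounds.
#' @return `c(x0, y0, x1, y1)` half-open level-0 rectangle, or `NULL` when
#'   the mask contains no tissue.
#' @export
tissue_bbox <- function(mask, slide = NULL) {
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  d <- mask$downsample
  box <- c((min(idx[, 2]) - 1L) * d, (min(idx[, 1]) - 1L) * d,
           max(idx[, 2]) * d, max(idx[, 1]) * d)
  if (!is.null(slide))
    box <- c(box[1:2], min(box[3], slide_width(slide)),
             min(box[4], slide_height(slide)))
  as.integer(box)
}

#' Extract grid-aligned tissue patches from a slide
#'
#' Tiles the slide with a non-overlapping grid of `patch_size` squares
#' anchored at (0, 0) and yields, in row-major order, every grid cell whose
#' tissue coverage under `mask` is at least `min_tissue_fraction`. Coverage
#' is computed exactly under the model that the mask value is constant over
#' each thumbnail pixel's level-0 footprint.
#'
#' @param slide a `pcead_slide`.
#' @param mask a `pcead_tissue_mask` for the same slide.
#' @param patch_size patch side in level-0 pixels.
#' @param min_tissue_fraction minimum tissue coverage in `[0, 1]`.
#' @return List of `pcead_patch` objects (empty, with a warning, when the
#'   patch size exceeds the slide).
#' @export
extract_patches <- function(slide, mask, patch_size,
                            min_tissue_fraction = 0.5) {
  stopifnot(min_tissue_fraction >= 0, min_tissue_fraction <= 1)
  W <- slide_width(slide); H <- slide_height(slide)
  nx <- W %/% patch_size; ny <- H %/% patch_size
  if (nx == 0L || ny == 0L) {
    warning("patch_size larger than slide; no patches extracted")
    return(list())
  }
  frac <- cell_tissue_fraction(mask, patch_size, nx, ny)
  out <- vector("list", nx * ny)
  k <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      if (frac[iy, ix] >= min_tissue_fraction) {
        x0 <- (ix - 1L) * patch_size; y0 <- (iy - 1L) * patch_size
        k <- k + 1L
        out[[k]] <- new_patch(
          slide_region(slide, x0, y0, patch_size, patch_size),
          slide = slide$id, x = x0, y = y0, span = patch_size)
      }
    }
  }
  out[seq_len(k)]
}

# Tissue fraction of every grid cell, by area-weighted overlap with the
# thumbnail mask pixels (each mask pixel covers a d x d level-0 footprint).
cell_tissue_fraction <- function(mask, ps, nx, ny) {
  d <- mask$downsample
  m <- mask$mask
  frac <- matrix(0, ny, nx)
  wts <- function(c0, c1, n) {
    # overlap length of [c0, c1) with each footprint [(i-1)d, id), i = 1..n
    i0 <- c0 %/% d + 1L
    i1 <- min((c1 - 1L) %/% d + 1L, n)
    idx <- i0:i1
    lo <- pmax((idx - 1L) * d, c0); hi <- pmin(idx * d, c1)
    list(idx = idx, w = as.numeric(hi - lo))
  }
  for (iy in seq_len(ny)) {
    wy <- wts((iy - 1L) * ps, iy * ps, nrow(m))
    for (ix in seq_len(nx)) {
      wx <- wts((ix - 1L) * ps, ix * ps, ncol(m))
      sub <- m[wy$idx, wx$idx, drop = FALSE]
      frac[iy, ix] <- as.numeric(wy$w %*% sub %*% wx$w) / (ps * ps)
    }
  }
  frac
}

#' Tissue mask of a single patch at its own resolution
#'
#' Applies the slide-level Otsu luminance threshold to the patch pixels,
#' marking tissue where 8-bit luminance falls strictly below it. Used to
#' keep bright whitespace pixels inside tissue patches out of the error
#' model and out of the predictions: anomaly detection is defined on
#' tissue only.
#'
#' @param patch a `pcead_patch`.
#' @param threshold 8-bit luminance threshold (from
#'   [compute_tissue_mask()]).
#' @return Logical matrix of the patch's dimensions.
#' @export
patch_tissue_mask <- function(patch, threshold) {
  lum <- 0.299 * patch$image[, , 1] + 0.587 * patch$image[, , 2] +
    0.114 * patch$image[, , 3]
  matrix(round(lum * 255) < threshold, nrow = patch$size)
}

#' Multi-resolution pyramid of a patch
#'
#' Downsamples a power-of-two patch by successive factor-2 reductions down
#' to `min_size`, returning the full ladder largest to smallest (e.g. 64,
#' 32, 16, 8, 4). The default reduction is 2x2 area averaging, matching the
#' average-pooling convention of the discriminator; `method = "nearest"`
#' takes the top-left pixel of each block instead.
#'
#' @param patch a `pcead_patch` whose side is a power of two >= `min_size`.
#' @param min_size smallest level side (power of two, default 4).
#' @param method `"average"` (default) or `"nearest"`.
#' @return List of `pcead_patch`, ordered largest to smallest; origins,
#'   spans and slide identifiers are preserved.
#' @export
build_resolution_pyramid <- function(patch, min_size = 4L,
                                     method = c("average", "nearest")) {
  method <- match.arg(method)
  s <- patch$size
  if (!is_pow2(s) || !is_pow2(min_size) || min_size < 4L || s < min_size)
    stop("patch side must be a power of two >= min_size (>= 4)")
  levels <- list(patch)
  img <- patch$image
  while (dim(img)[1] > min_size) {
    img <- downsample2(img, method)
    levels[[length(levels) + 1L]] <-
      new_patch(img, patch$slide, patch$x, patch$y, span = patch$span)
  }
  levels
}

# Factor-2 reduction of an H x W x C array.
downsample2 <- function(img, method = "average") {
  h <- dim(img)[1]; w <- dim(img)[2]
  o <- seq(1L, h, 2L); e <- seq(2L, h, 2L)
  oc <- seq(1L, w, 2L); ec <- seq(2L, w, 2L)
  if (method == "nearest") return(img[o, oc, , drop = FALSE])
  (img[o, oc, , drop = FALSE] + img[e, oc, , drop = FALSE] +
     img[o, ec, , drop = FALSE] + img[e, ec, , drop = FALSE]) / 4
}
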