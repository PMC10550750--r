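#' Per-pixel absolute reconstruction error
#'
#' @param input,recon two `pcead_patch` of identical shape and level.
#' @return A `pcead_errors` object: the `H x W x 3` array of elementwise
#'   absolute differences plus provenance (`slide`, `x`, `y`, `span`).
#' @export
reconstruction_error <- function(input, recon) {
  if (!identical(dim(input$image), dim(recon$image)))
    stop("input and reconstruction shapes differ")
  structure(list(err = abs(input$image - recon$image),
                 slide = input$slide, x = input$x, y = input$y,
                 span = input$span),
            class = "pcead_errors")
}

#' Streaming accumulator for the normal error reference distribution
#'
#' Pooled first and second moments over RGB error vectors, updatable in
#' chunks (Chan et al. parallel combination) so Phase 2 never materialises
#' all errors at once.
#'
#' @return An empty accumulator (`pcead_nerd_acc`).
#' @export
nerd_accumulator <- function() {
  structure(list(n = 0, mean = numeric(3), M2 = matrix(0, 3, 3)),
            class = "pcead_nerd_acc")
}

#' @rdname nerd_accumulator
#' @param acc a `pcead_nerd_acc`.
#' @param errors a `pcead_errors` object, or an `n x 3` matrix of error
#'   vectors.
#' @export
nerd_update <- function(acc, errors) {
  E <- if (inherits(errors, "pcead_errors"))
    matrix(errors$err, ncol = 3L) else as.matrix(errors)
  m <- as.numeric(nrow(E))
  if (m == 0L) return(acc)
  mu_b <- colMeans(E)
  Ec <- sweep(E, 2L, mu_b)
  M2_b <- crossprod(Ec)
  if (acc$n == 0) {
    acc$n <- m; acc$mean <- mu_b; acc$M2 <- M2_b
    return(acc)
  }
  delta <- mu_b - acc$mean
  ntot <- acc$n + m
  acc$M2 <- acc$M2 + M2_b + tcrossprod(delta) * (acc$n * m / ntot)
  acc$mean <- acc$mean + delta * (m / ntot)
  acc$n <- ntot
  acc
}

#' Fit the normal error reference distribution (NERD)
#'
#' Pools all pixels of all error tensors and fits a single 3-variate
#' Gaussian over the RGB error channels: `mu` is the per-channel mean and
#' `sigma` the 3x3 sample covariance (denominator `n - 1`). A ridge
#' `eps` is added to the diagonal whenever the covariance is inverted so
#' degenerate fits (e.g. constant errors) remain usable.
#'
#' @param errors list of `pcead_errors` (or matrices), or a
#'   `pcead_nerd_acc` already accumulated.
#' @param eps diagonal regularisation (default `1e-6`).
#' @return A `pcead_nerd` with fields `mu`, `sigma`, `eps`, `n`.
#' @export
fit_nerd <- function(errors, eps = 1e-6) {
  acc <- if (inherits(errors, "pcead_nerd_acc")) errors else {
    a <- nerd_accumulator()
    for (e in errors) a <- nerd_update(a, e)
    a
  }
  if (acc$n < 2) stop("insufficient data: NERD needs at least 2 pixels")
  structure(list(mu = as.numeric(acc$mean),
                 sigma = acc$M2 / (acc$n - 1),
                 eps = eps, n = acc$n),
            class = "pcead_nerd")
}

#' @export
print.pcead_nerd <- function(x, ...) {
  cat(sprintf("<pcead_nerd n = %g, mu = (%.4g, %.4g, %.4g)>\n",
              x$n, x$mu[1], x$mu[2], x$mu[3]))
  invisible(x)
}

#' Pixel-level Mahalanobis distance map
#'
#' For every pixel error vector `e`, computes
#' `sqrt((e - mu)' (sigma + eps I)^{-1} (e - mu))` under the NERD.
#'
#' @param errors a `pcead_errors` object (or `H x W x 3` array).
#' @param nerd a `pcead_nerd`.
#' @return `H x W` matrix of non-negative distances (a distance map).
#' @export
mahalanobis_map <- function(errors, nerd) {
  arr <- if (inherits(errors, "pcead_errors")) errors$err else errors
  d <- dim(arr)
  E <- matrix(arr, ncol = 3L)
  S <- nerd$sigma + diag(nerd$eps, 3L)
  A <- tryCatch(solve(S), error = function(e)
    stop("regularised NERD covariance is not invertible"))
  C <- sweep(E, 2L, nerd$mu)
  d2 <- rowSums((C %*% A) * C)
  d2[d2 < 0] <- 0                     # guard tiny negative round-off
  matrix(sqrt(d2), nrow = d[1], ncol = d[2])
}

#' Calibrate the cut-off Mahalanobis threshold (Phase 3)
#'
#' The threshold is the empirical `(1 - q)` nearest-rank quantile of the
#' pooled Mahalanobis distances observed on held-out normal slides, so
#' that a fraction `q` of normal pixels is allowed to exceed it. With
#' `q = 0` the threshold is the maximum observed distance.
#'
#' @param normal_distances numeric vector of distances from normal tissue.
#' @param q allowed normal-pixel exceedance fraction, `0 <= q < 1`.
#' @return A `pcead_threshold` with fields `tau`, `q`, `n`.
#' @export
calibrate_threshold <- function(normal_distances, q = 0.05) {
  v <- as.numeric(normal_distances)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no distance values to calibrate on")
  stopifnot(q >= 0, q < 1)
  tau <- if (q == 0) max(v) else sort(v)[ceiling((1 - q) * length(v))]
  structure(list(tau = tau, q = q, n = length(v)),
            class = "pcead_threshold")
}

#' @export
print.pcead_threshold <- function(x, ...) {
  cat(sprintf("<pcead_threshold tau = %.4g (q = %g, n = %g)>\n",
              x$tau, x$q, x$n))
  invisible(x)
}

#' Binarize a distance map into an anomaly mask
#'
#' A pixel is anomalous iff its Mahalanobis distance is strictly higher
#' than the threshold.
#'
#' @param dmap `H x W` distance matrix.
#' @param tau a `pcead_threshold` or a single numeric threshold.
#' @return Logical `H x W` matrix.
#' @export
binarize <- function(dmap, tau) {
  t0 <- if (inherits(tau, "pcead_threshold")) tau$tau else tau
  dmap > t0
}

#' Serialise / read NERD and threshold parameters as JSON
#'
#' @param nerd a `pcead_nerd`.
#' @param path JSON path.
#' @param tau optional `pcead_threshold` stored alongside.
#' @return `write_nerd()` returns `path` invisibly; `read_nerd()` a list
#'   with elements `nerd` and (when present) `tau`.
#' @export
write_nerd <- function(nerd, path, tau = NULL) {
  doc <- list(mu = nerd$mu, sigma = nerd$sigma, eps = nerd$eps, n = nerd$n)
  if (!is.null(tau))
    doc$threshold <- list(tau = tau$tau, q = tau$q, n = tau$n)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_nerd
#' @export
read_nerd <- function(path) {
  doc <- jsonlite::fromJSON(path)
  nerd <- structure(list(mu = as.numeric(doc$mu),
                         sigma = matrix(as.numeric(doc$sigma), 3L, 3L),
                         eps = doc$eps, n = doc$n),
                    class = "pcead_nerd")
  out <- list(nerd = nerd)
  if (!is.null(doc$threshold))
    out$tau <- structure(list(tau = doc$threshold$tau, q = doc$threshold$q,
                              n = doc$threshold$n),
                         class = "pcead_threshold")
  out
}
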