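# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately written as naive scalar loops / exhaustive searches, never
# reusing the package's vectorised implementations.

# Exhaustive between-class-variance search over all candidate thresholds.
brute_otsu <- function(h) {
  v <- 0:255
  n <- sum(h)
  best <- -Inf; bt <- NA_integer_
  for (t in 1:255) {
    w0 <- sum(h[1:t]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:t] * v[1:t]) / w0
    m1 <- sum(h[(t + 1):256] * v[(t + 1):256]) / w1
    b <- w0 * w1 * (m0 - m1)^2
    if (b > best * (1 + 1e-12) && b > best) { best <- b; bt <- t }
  }
  bt
}

# Naive queue-based flood fill, 4-connectivity.
flood_label <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!m[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- p[1] + d[1]; jj <- p[2] + d[2]
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
            m[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Scalar-loop Mahalanobis distances via an explicit matrix inverse.
loop_mahalanobis <- function(arr, mu, sigma, eps) {
  Sinv <- solve(sigma + diag(eps, 3))
  h <- dim(arr)[1]; w <- dim(arr)[2]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    e <- arr[i, j, ] - mu
    out[i, j] <- sqrt(drop(t(e) %*% Sinv %*% e))
  }
  out
}

# A random lattice-aligned rectangle polygon set inside [0, w) x [0, h).
random_rect_polyset <- function(w, h, slide = "s", role = "predicted") {
  x0 <- sample(0:(w - 2), 1); x1 <- sample((x0 + 1):(w - 1), 1) + 1
  y0 <- sample(0:(h - 2), 1); y1 <- sample((y0 + 1):(h - 1), 1) + 1
  ring <- cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  p <- list(exterior = ring, holes = list(),
            area = (x1 - x0) * (y1 - y0))
  polygon_set(list(p), slide = slide, role = role)
}

# Shared, lazily-built fixtures (normal training patches are expensive).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

normal_patches_64 <- function(n = 200) {
  fixture("normal64", function() {
    out <- list()
    s <- 0L
    while (length(out) < 220) {
      s <- s + 1L
      sl <- generate_slide(synthetic_slide_spec(
        size = 256, id = paste0("trn", s), seed = 4000 + s))
      m <- compute_tissue_mask(sl$slide, 16)
      out <- c(out, extract_patches(sl$slide, m, 64, 1))
    }
    out
  })[seq_len(n)]
}
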