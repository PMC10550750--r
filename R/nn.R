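# Minimal convolutional-network primitives on H x W x C x N arrays.
# Convolutions are evaluated as im2col matrix products; every layer returns
# the forward value plus the cache its backward pass needs. All operations
# are deterministic given the R RNG state.

nn_init_conv <- function(k, cin, cout, gain = sqrt(2)) {
  # He-style fan-in scaling
  sd <- gain / sqrt(k * k * cin)
  list(W = matrix(stats::rnorm(k * k * cin * cout, sd = sd),
                  nrow = k * k * cin, ncol = cout),
       b = numeric(cout))
}

nn_init_dense <- function(nin, nout, gain = 1) {
  list(W = matrix(stats::rnorm(nin * nout, sd = gain / sqrt(nin)),
                  nrow = nin, ncol = nout),
       b = numeric(nout))
}

# im2col for a 3x3 convolution with zero padding 1.
im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- array(0, c(H + 2L, W + 2L, C, N))
  xp[2:(H + 1L), 2:(W + 1L), , ] <- x
  out <- array(0, c(H, W, N, 9L * C))
  k <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      k <- k + 1L
      slab <- xp[(1L + dy):(H + dy), (1L + dx):(W + dx), , , drop = FALSE]
      out[, , , ((k - 1L) * C + 1L):(k * C)] <- aperm(slab, c(1, 2, 4, 3))
    }
  }
  dim(out) <- c(H * W * N, 9L * C)
  out
}

col2im3 <- function(dXm, H, W, C, N) {
  dim(dXm) <- c(H, W, N, 9L * C)
  dxp <- array(0, c(H + 2L, W + 2L, C, N))
  k <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      k <- k + 1L
      slab <- aperm(dXm[, , , ((k - 1L) * C + 1L):(k * C), drop = FALSE],
                    c(1, 2, 4, 3))
      dxp[(1L + dy):(H + dy), (1L + dx):(W + dx), , ] <-
        dxp[(1L + dy):(H + dy), (1L + dx):(W + dx), , , drop = FALSE] + slab
    }
  }
  dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
}

conv3_fwd <- function(par, x) {
  d <- dim(x)
  X <- im2col3(x)
  Y <- X %*% par$W
  Y <- sweep(Y, 2L, par$b, "+")
  cout <- ncol(par$W)
  dim(Y) <- c(d[1], d[2], d[4], cout)
  list(y = aperm(Y, c(1, 2, 4, 3)), X = X, din = d)
}

conv3_bwd <- function(par, cache, dy) {
  d <- cache$din
  dYm <- aperm(dy, c(1, 2, 4, 3))
  dim(dYm) <- c(d[1] * d[2] * d[4], ncol(par$W))
  dW <- crossprod(cache$X, dYm)
  db <- colSums(dYm)
  dX <- col2im3(dYm %*% t(par$W), d[1], d[2], d[3], d[4])
  list(dx = dX, dW = dW, db = db)
}

conv1_fwd <- function(par, x) {
  d <- dim(x)
  Xm <- aperm(x, c(1, 2, 4, 3))
  dim(Xm) <- c(d[1] * d[2] * d[4], d[3])
  Y <- sweep(Xm %*% par$W, 2L, par$b, "+")
  cout <- ncol(par$W)
  dim(Y) <- c(d[1], d[2], d[4], cout)
  list(y = aperm(Y, c(1, 2, 4, 3)), X = Xm, din = d)
}

conv1_bwd <- function(par, cache, dy) {
  d <- cache$din
  dYm <- aperm(dy, c(1, 2, 4, 3))
  dim(dYm) <- c(d[1] * d[2] * d[4], ncol(par$W))
  dW <- crossprod(cache$X, dYm)
  db <- colSums(dYm)
  dXm <- dYm %*% t(par$W)
  dim(dXm) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dXm, c(1, 2, 4, 3)), dW = dW, db = db)
}

lrelu_fwd <- function(x, slope = 0.2) {
  neg <- x < 0
  y <- x
  y[neg] <- slope * x[neg]
  list(y = y, neg = neg, slope = slope)
}

lrelu_bwd <- function(cache, dy) {
  dy[cache$neg] <- cache$slope * dy[cache$neg]
  dy
}

avgpool2_fwd <- function(x) {
  d <- dim(x)
  o <- seq(1L, d[1], 2L); e <- seq(2L, d[1], 2L)
  oc <- seq(1L, d[2], 2L); ec <- seq(2L, d[2], 2L)
  y <- (x[o, oc, , , drop = FALSE] + x[e, oc, , , drop = FALSE] +
          x[o, ec, , , drop = FALSE] + x[e, ec, , , drop = FALSE]) / 4
  list(y = y, din = d)
}

avgpool2_bwd <- function(cache, dy) {
  upsample2_fwd(dy)$y / 4
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
         drop = FALSE]
  list(y = y, din = d)
}

upsample2_bwd <- function(cache, dy) {
  d <- dim(dy)
  o <- seq(1L, d[1], 2L); e <- seq(2L, d[1], 2L)
  oc <- seq(1L, d[2], 2L); ec <- seq(2L, d[2], 2L)
  dy[o, oc, , , drop = FALSE] + dy[e, oc, , , drop = FALSE] +
    dy[o, ec, , , drop = FALSE] + dy[e, ec, , , drop = FALSE]
}

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y)
}

sigmoid_bwd <- function(cache, dy) dy * cache$y * (1 - cache$y)

dense_fwd <- function(par, x) {
  d <- dim(x)
  Xm <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
  Y <- sweep(crossprod(Xm, par$W), 2L, par$b, "+")   # N x out
  list(y = Y, X = Xm, din = d)
}

dense_bwd <- function(par, cache, dy) {
  dW <- cache$X %*% dy
  db <- colSums(dy)
  dXm <- par$W %*% t(dy)
  list(dx = array(dXm, cache$din), dW = dW, db = db)
}

# Recursive Adam over nested parameter lists.
adam_state <- function(params) {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else array(0, dim(p) %||% length(p))
  }
  list(m = walk(params), v = walk(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 2e-3, beta1 = 0.5,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (k in names(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scale a gradient pytree so its global L2 norm is at most max_norm;
# guards against the occasional adversarial-loss spike destabilising
# training at small batch sizes.
clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm) || max_norm <= 0) return(grads)
  ss <- 0
  walk_sum <- function(g) {
    if (is.list(g)) lapply(g, walk_sum) else ss <<- ss + sum(g * g)
    invisible(NULL)
  }
  walk_sum(grads)
  nrm <- sqrt(ss)
  if (nrm <= max_norm) return(grads)
  scl <- max_norm / nrm
  walk_mul <- function(g) if (is.list(g)) lapply(g, walk_mul) else g * scl
  walk_mul(grads)
}

zero_like <- function(params) {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else array(0, dim(p) %||% length(p))
  }
  walk(params)
}
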