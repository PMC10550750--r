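#' Progressive GAN configuration
#'
#' Hyperparameters of the inpainting generator/discriminator pair. The
#' networks grow from 4x4 to `max_resolution` by doubling; at each growth
#' step new layers are faded in with a weight `alpha` ramped linearly in
#' images seen, nearest-neighbor upsampling on the way up and 2x2 average
#' pooling on the way down. The training loss is
#' `lambda_rec * L1(input, output) + lambda_adv * least-squares adversarial
#' term`; L1 is used because downstream anomaly scoring works on absolute
#' reconstruction errors.
#'
#' @param max_resolution final resolution (power of two, 4..1024).
#' @param channels named numeric vector mapping each level (4, 8, ...) to
#'   its channel width; defaults to a desk-scale schedule.
#' @param lambda_rec,lambda_adv loss weights.
#' @param lr Adam learning rate (beta1 = 0.5).
#' @param batch_size minibatch size.
#' @param inpaint_fraction side of the centered inpainting square as a
#'   fraction of the patch side.
#' @param inpaint_fill fill colour for masked pixels: an RGB triple, a
#'   scalar, or `NULL` to use the training-set mean colour.
#' @param fade_fraction fraction of each level's image budget spent in the
#'   fade-in sub-phase (the rest stabilises at `alpha = 1`).
#' @param clip_norm global L2 gradient-norm ceiling per update (generator
#'   and discriminator separately); `Inf` disables clipping.
#' @param error_scope `"full"` to score reconstruction errors over the whole
#'   patch, `"masked"` to restrict to the inpainted square.
#' @return An object of class `pcead_config`.
#' @export
network_config <- function(max_resolution = 16L, channels = NULL,
                           lambda_rec = 1, lambda_adv = 0.05,
                           lr = 2e-3, batch_size = 8L,
                           inpaint_fraction = 0.5, inpaint_fill = NULL,
                           fade_fraction = 0.5, clip_norm = 1,
                           error_scope = c("full", "masked")) {
  if (!is_pow2(max_resolution) || max_resolution < 4L ||
      max_resolution > 1024L)
    stop("max_resolution must be a power of two in [4, 1024]")
  lv <- ladder_levels(max_resolution)
  if (is.null(channels)) channels <- default_channels(max_resolution)
  channels <- channels[as.character(lv)]
  if (anyNA(channels))
    stop("channels must be defined for every level 4..max_resolution")
  stopifnot(inpaint_fraction > 0, inpaint_fraction <= 1)
  structure(list(max_resolution = as.integer(max_resolution),
                 channels = channels, lambda_rec = lambda_rec,
                 lambda_adv = lambda_adv, lr = lr,
                 batch_size = as.integer(batch_size),
                 inpaint_fraction = inpaint_fraction,
                 inpaint_fill = inpaint_fill,
                 fade_fraction = fade_fraction,
                 clip_norm = clip_norm,
                 error_scope = match.arg(error_scope)),
            class = "pcead_config")
}

ladder_levels <- function(max_resolution) {
  2L^(2:as.integer(log2(max_resolution)))
}

default_channels <- function(max_resolution) {
  lv <- ladder_levels(max_resolution)
  ch <- c(`4` = 32, `8` = 24, `16` = 16, `32` = 12)
  out <- ifelse(as.character(lv) %in% names(ch),
                ch[as.character(lv)], 8)
  names(out) <- as.character(lv)
  out
}

# Parameter initialisation (uses the current RNG state).
init_network <- function(config) {
  ch <- config$channels
  lv <- as.integer(names(ch))
  g <- list(from = list(), to = list(), enc = list(), dec = list(),
            bneck = nn_init_conv(3L, ch[["4"]], ch[["4"]]))
  d <- list(from = list(), block = list(),
            conv4 = nn_init_conv(3L, ch[["4"]], ch[["4"]]),
            out = nn_init_dense(16L * ch[["4"]], 1L))
  for (l in lv) {
    k <- as.character(l)
    g$from[[k]] <- nn_init_conv(1L, 3L, ch[[k]])
    g$to[[k]] <- nn_init_conv(1L, ch[[k]], 3L, gain = 1)
    d$from[[k]] <- nn_init_conv(1L, 3L, ch[[k]])
    if (l >= 8L) {
      half <- as.character(l %/% 2L)
      g$enc[[k]] <- nn_init_conv(3L, ch[[k]], ch[[half]])
      g$dec[[k]] <- nn_init_conv(3L, ch[[half]], ch[[k]])
      d$block[[k]] <- nn_init_conv(3L, ch[[k]], ch[[half]])
    }
  }
  list(g = g, d = d)
}

# ---- generator -------------------------------------------------------------

gen_forward <- function(p, x, level, alpha = 1) {
  L <- as.integer(level)
  cache <- list(level = L, alpha = alpha)
  if (L == 4L) {
    cache$f1 <- conv1_fwd(p$from[["4"]], x)
    cache$a1 <- lrelu_fwd(cache$f1$y)
    cache$bn <- conv3_fwd(p$bneck, cache$a1$y)
    cache$a2 <- lrelu_fwd(cache$bn$y)
    cache$to <- conv1_fwd(p$to[["4"]], cache$a2$y)
    cache$sg <- sigmoid_fwd(cache$to$y)
    return(list(y = cache$sg$y, cache = cache))
  }
  half <- as.character(L %/% 2L)
  # encoder entry with fade-in
  cache$nf <- conv1_fwd(p$from[[as.character(L)]], x)
  cache$na <- lrelu_fwd(cache$nf$y)
  cache$nc <- conv3_fwd(p$enc[[as.character(L)]], cache$na$y)
  cache$nca <- lrelu_fwd(cache$nc$y)
  cache$np <- avgpool2_fwd(cache$nca$y)
  if (alpha < 1) {
    cache$opool <- avgpool2_fwd(x)
    cache$of <- conv1_fwd(p$from[[half]], cache$opool$y)
    cache$oa <- lrelu_fwd(cache$of$y)
    e <- (1 - alpha) * cache$oa$y + alpha * cache$np$y
  } else {
    e <- cache$np$y
  }
  # deeper encoder
  dn <- L %/% 2L
  cache$down <- list()
  while (dn >= 8L) {
    k <- as.character(dn)
    st <- list()
    st$c <- conv3_fwd(p$enc[[k]], e)
    st$a <- lrelu_fwd(st$c$y)
    st$p <- avgpool2_fwd(st$a$y)
    e <- st$p$y
    cache$down[[k]] <- st
    dn <- dn %/% 2L
  }
  cache$bn <- conv3_fwd(p$bneck, e)
  cache$ba <- lrelu_fwd(cache$bn$y)
  d <- cache$ba$y
  # decoder up to L/2
  up <- 8L
  cache$up <- list()
  while (up <= L %/% 2L) {
    k <- as.character(up)
    st <- list()
    st$u <- upsample2_fwd(d)
    st$c <- conv3_fwd(p$dec[[k]], st$u$y)
    st$a <- lrelu_fwd(st$c$y)
    d <- st$a$y
    cache$up[[k]] <- st
    up <- up * 2L
  }
  # output with fade-in
  cache$du <- upsample2_fwd(d)
  cache$dc <- conv3_fwd(p$dec[[as.character(L)]], cache$du$y)
  cache$da <- lrelu_fwd(cache$dc$y)
  cache$nto <- conv1_fwd(p$to[[as.character(L)]], cache$da$y)
  if (alpha < 1) {
    cache$oto <- conv1_fwd(p$to[[half]], d)
    cache$oup <- upsample2_fwd(cache$oto$y)
    rgb <- (1 - alpha) * cache$oup$y + alpha * cache$nto$y
  } else {
    rgb <- cache$nto$y
  }
  cache$sg <- sigmoid_fwd(rgb)
  list(y = cache$sg$y, cache = cache)
}

gen_backward <- function(p, cache, dy) {
  grads <- zero_like(p)
  add <- function(path, r) {
    grads[[c(path, "W")]] <<- grads[[c(path, "W")]] + r$dW
    grads[[c(path, "b")]] <<- grads[[c(path, "b")]] + r$db
  }
  L <- cache$level
  alpha <- cache$alpha
  drgb <- sigmoid_bwd(cache$sg, dy)
  if (L == 4L) {
    r <- conv1_bwd(p$to[["4"]], cache$to, drgb); add(c("to", "4"), r)
    da <- lrelu_bwd(cache$a2, r$dx)
    r <- conv3_bwd(p$bneck, cache$bn, da); add("bneck", r)
    da <- lrelu_bwd(cache$a1, r$dx)
    r <- conv1_bwd(p$from[["4"]], cache$f1, da); add(c("from", "4"), r)
    return(list(grads = grads, dx = r$dx))
  }
  half <- as.character(L %/% 2L)
  # output side
  dnew <- if (alpha < 1) alpha * drgb else drgb
  r <- conv1_bwd(p$to[[as.character(L)]], cache$nto, dnew)
  add(c("to", as.character(L)), r)
  dda <- lrelu_bwd(cache$da, r$dx)
  r <- conv3_bwd(p$dec[[as.character(L)]], cache$dc, dda)
  add(c("dec", as.character(L)), r)
  dd <- upsample2_bwd(cache$du, r$dx)
  if (alpha < 1) {
    dold <- (1 - alpha) * drgb
    dto_old <- upsample2_bwd(cache$oup, dold)
    r <- conv1_bwd(p$to[[half]], cache$oto, dto_old)
    add(c("to", half), r)
    dd <- dd + r$dx
  }
  # decoder
  ups <- rev(names(cache$up))
  for (k in ups) {
    st <- cache$up[[k]]
    da <- lrelu_bwd(st$a, dd)
    r <- conv3_bwd(p$dec[[k]], st$c, da); add(c("dec", k), r)
    dd <- upsample2_bwd(st$u, r$dx)
  }
  # bottleneck
  da <- lrelu_bwd(cache$ba, dd)
  r <- conv3_bwd(p$bneck, cache$bn, da); add("bneck", r)
  de <- r$dx
  # deeper encoder
  downs <- rev(names(cache$down))
  for (k in downs) {
    st <- cache$down[[k]]
    dp <- avgpool2_bwd(st$p, de)
    da <- lrelu_bwd(st$a, dp)
    r <- conv3_bwd(p$enc[[k]], st$c, da); add(c("enc", k), r)
    de <- r$dx
  }
  # encoder entry
  dnew_e <- if (alpha < 1) alpha * de else de
  dp <- avgpool2_bwd(cache$np, dnew_e)
  da <- lrelu_bwd(cache$nca, dp)
  r <- conv3_bwd(p$enc[[as.character(L)]], cache$nc, da)
  add(c("enc", as.character(L)), r)
  da <- lrelu_bwd(cache$na, r$dx)
  r <- conv1_bwd(p$from[[as.character(L)]], cache$nf, da)
  add(c("from", as.character(L)), r)
  dx <- r$dx
  if (alpha < 1) {
    dold_e <- (1 - alpha) * de
    da <- lrelu_bwd(cache$oa, dold_e)
    r <- conv1_bwd(p$from[[half]], cache$of, da)
    add(c("from", half), r)
    dx <- dx + avgpool2_bwd(cache$opool, r$dx)
  }
  list(grads = grads, dx = dx)
}

# ---- discriminator ---------------------------------------------------------

disc_forward <- function(p, x, level, alpha = 1) {
  L <- as.integer(level)
  cache <- list(level = L, alpha = alpha)
  if (L == 4L) {
    cache$f1 <- conv1_fwd(p$from[["4"]], x)
    cache$a1 <- lrelu_fwd(cache$f1$y)
    f <- cache$a1$y
  } else {
    half <- as.character(L %/% 2L)
    cache$nf <- conv1_fwd(p$from[[as.character(L)]], x)
    cache$na <- lrelu_fwd(cache$nf$y)
    cache$nc <- conv3_fwd(p$block[[as.character(L)]], cache$na$y)
    cache$nca <- lrelu_fwd(cache$nc$y)
    cache$np <- avgpool2_fwd(cache$nca$y)
    if (alpha < 1) {
      cache$opool <- avgpool2_fwd(x)
      cache$of <- conv1_fwd(p$from[[half]], cache$opool$y)
      cache$oa <- lrelu_fwd(cache$of$y)
      f <- (1 - alpha) * cache$oa$y + alpha * cache$np$y
    } else {
      f <- cache$np$y
    }
    dn <- L %/% 2L
    cache$down <- list()
    while (dn >= 8L) {
      k <- as.character(dn)
      st <- list()
      st$c <- conv3_fwd(p$block[[k]], f)
      st$a <- lrelu_fwd(st$c$y)
      st$p <- avgpool2_fwd(st$a$y)
      f <- st$p$y
      cache$down[[k]] <- st
      dn <- dn %/% 2L
    }
  }
  cache$c4 <- conv3_fwd(p$conv4, f)
  cache$a4 <- lrelu_fwd(cache$c4$y)
  cache$out <- dense_fwd(p$out, cache$a4$y)
  list(score = cache$out$y, cache = cache)
}

disc_backward <- function(p, cache, dscore) {
  grads <- zero_like(p)
  add <- function(path, r) {
    grads[[c(path, "W")]] <<- grads[[c(path, "W")]] + r$dW
    grads[[c(path, "b")]] <<- grads[[c(path, "b")]] + r$db
  }
  L <- cache$level
  alpha <- cache$alpha
  r <- dense_bwd(p$out, cache$out, dscore); add("out", r)
  da <- lrelu_bwd(cache$a4, r$dx)
  r <- conv3_bwd(p$conv4, cache$c4, da); add("conv4", r)
  df <- r$dx
  if (L == 4L) {
    da <- lrelu_bwd(cache$a1, df)
    r <- conv1_bwd(p$from[["4"]], cache$f1, da); add(c("from", "4"), r)
    return(list(grads = grads, dx = r$dx))
  }
  half <- as.character(L %/% 2L)
  downs <- rev(names(cache$down))
  for (k in downs) {
    st <- cache$down[[k]]
    dp <- avgpool2_bwd(st$p, df)
    da <- lrelu_bwd(st$a, dp)
    r <- conv3_bwd(p$block[[k]], st$c, da); add(c("block", k), r)
    df <- r$dx
  }
  dnew <- if (alpha < 1) alpha * df else df
  dp <- avgpool2_bwd(cache$np, dnew)
  da <- lrelu_bwd(cache$nca, dp)
  r <- conv3_bwd(p$block[[as.character(L)]], cache$nc, da)
  add(c("block", as.character(L)), r)
  da <- lrelu_bwd(cache$na, r$dx)
  r <- conv1_bwd(p$from[[as.character(L)]], cache$nf, da)
  add(c("from", as.character(L)), r)
  dx <- r$dx
  if (alpha < 1) {
    dold <- (1 - alpha) * df
    da <- lrelu_bwd(cache$oa, dold)
    r <- conv1_bwd(p$from[[half]], cache$of, da)
    add(c("from", half), r)
    dx <- dx + avgpool2_bwd(cache$opool, r$dx)
  }
  list(grads = grads, dx = dx)
}

# ---- public operations -----------------------------------------------------

#' Fade-in blend of two feature maps
#'
#' During progressive growth the output of the previous (upsampled) stage
#' and the new stage are blended as `(1 - alpha) * prev + alpha * new`,
#' with `alpha` ramped linearly from 0 to 1 in images seen.
#'
#' @param prev,new arrays of identical shape.
#' @param alpha blend weight in `[0, 1]`.
#' @return The elementwise blend.
#' @export
fade_in_blend <- function(prev, new, alpha) {
  if (!isTRUE(all.equal(dim(prev) %||% length(prev),
                        dim(new) %||% length(new))))
    stop("fade_in_blend inputs must have the same shape")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  (1 - alpha) * prev + alpha * new
}

#' Instantiate a generator function at a growth state
#'
#' Returns a closure mapping a (masked) square RGB array at the state's
#' resolution to the generator output at the same resolution. At
#' `alpha = 0` the grown generator reproduces the previous level's output
#' upsampled by nearest neighbor, which is the defining property of the
#' fade-in growth rule.
#'
#' @param params network parameters as produced by training (the `g`
#'   component of a model) .
#' @param config the `pcead_config` the parameters were built under.
#' @param state list with `level` (power of two) and `alpha` in `[0, 1]`.
#' @return `function(image_array) -> image_array` operating on
#'   `s x s x 3` (or `s x s x 3 x n`) arrays.
#' @export
grow_generator <- function(params, config, state) {
  L <- as.integer(state$level)
  if (!is_pow2(L) || L > config$max_resolution)
    stop("growth level above the configured maximum resolution")
  alpha <- state$alpha %||% 1
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  function(x) {
    single <- length(dim(x)) == 3L
    if (single) dim(x) <- c(dim(x), 1L)
    y <- gen_forward(params, x, L, alpha)$y
    if (single) dim(y) <- dim(y)[1:3]
    y
  }
}

#' Apply a centered inpainting mask to a patch
#'
#' Sets the centered square of side `round(fraction * patch side)` to the
#' fill colour; returns the masked patch and the boolean mask.
#'
#' @param patch a `pcead_patch`.
#' @param spec list with `fraction` in `(0, 1]` and `fill` (RGB triple or
#'   scalar; default 0.5).
#' @return List with `patch` (masked) and `mask` (logical `s x s` matrix).
#' @export
apply_inpaint_mask <- function(patch, spec = list(fraction = 0.5,
                                                  fill = 0.5)) {
  s <- patch$size
  f <- spec$fraction %||% 0.5
  stopifnot(f > 0, f <= 1)
  fill <- spec$fill %||% 0.5
  if (length(fill) == 1L) fill <- rep(fill, 3L)
  m <- as.integer(round(f * s))
  mask <- matrix(FALSE, s, s)
  img <- patch$image
  if (m > 0L) {
    start <- (s - m) %/% 2L
    idx <- (start + 1L):(start + m)
    mask[idx, idx] <- TRUE
    for (c in 1:3) {
      ch <- img[, , c]
      ch[mask] <- fill[c]
      img[, , c] <- ch
    }
  }
  list(patch = new_patch(img, patch$slide, patch$x, patch$y, patch$span),
       mask = mask)
}

#' Train the inpainting progressive GAN on normal patches (Phase 1)
#'
#' Runs the progressive loop over the resolution ladder: at each level
#' above 4 a fade-in sub-phase ramps `alpha` linearly from 0 to 1 over
#' `fade_fraction` of the level's image budget, followed by a
#' stabilisation sub-phase at `alpha = 1`. Each step minimises
#' `lambda_rec * mean|x - G(masked x)| + lambda_adv * LSGAN terms` with
#' Adam. All layers remain trainable throughout. After the loop the
#' weights are frozen into the returned model.
#'
#' @param records directory of record shards, or a character vector of
#'   shard paths; must contain patches at every ladder level.
#' @param config a `pcead_config`.
#' @param schedule image budget per level: a single count applied to every
#'   level or a named vector by level.
#' @param seed integer seed; two runs with the same seed, data and
#'   single-threaded backend produce identical parameters.
#' @param verbose print per-level loss summaries.
#' @return A frozen `pcead_model`.
#' @export
train_phase1 <- function(records, config, schedule, seed = 1L,
                         verbose = FALSE) {
  paths <- if (length(records) == 1L && dir.exists(records))
    list_record_shards(records) else records
  lv <- ladder_levels(config$max_resolution)
  sched <- if (length(schedule) == 1L && is.null(names(schedule)))
    stats::setNames(rep(schedule, length(lv)), as.character(lv))
  else schedule
  if (any(!as.character(lv) %in% names(sched)))
    stop("schedule must provide an image budget for every level")
  if (any(sched[as.character(lv)] <= 0))
    stop("training error: non-positive image budget for a level")

  local_seed(seed)
  params <- init_network(config)
  sg <- adam_state(params$g)
  sd_ <- adam_state(params$d)

  data <- list()
  for (l in lv) {
    pl <- read_record_shards(paths, level = l)
    if (length(pl) == 0L)
      stop("record store is missing patches at level ", l)
    arr <- array(0, c(l, l, 3L, length(pl)))
    for (i in seq_along(pl)) arr[, , , i] <- pl[[i]]$image
    data[[as.character(l)]] <- arr
  }
  fill <- config$inpaint_fill
  if (is.null(fill)) {
    top <- data[[as.character(config$max_resolution)]]
    fill <- c(mean(top[, , 1, ]), mean(top[, , 2, ]), mean(top[, , 3, ]))
  }
  if (length(fill) == 1L) fill <- rep(fill, 3L)
  inpaint <- list(fraction = config$inpaint_fraction, fill = fill)

  bs <- config$batch_size
  total_images <- 0L
  for (l in lv) {
    k <- as.character(l)
    arr <- data[[k]]
    n <- dim(arr)[4]
    budget <- sched[[k]]
    fade_images <- if (l == 4L) 0 else round(config$fade_fraction * budget)
    seen <- 0
    mask <- apply_inpaint_mask(
      new_patch(array(0.5, c(l, l, 3L))), list(fraction = inpaint$fraction,
                                               fill = 0))$mask
    mvol <- array(rep(mask, 3L), c(l, l, 3L))
    fillimg <- array(rep(fill, each = l * l), c(l, l, 3L))
    fillvals <- fillimg[mvol]
    losses <- c()
    while (seen < budget) {
      nb <- min(bs, budget - seen)
      alpha <- if (fade_images > 0 && seen < fade_images)
        seen / fade_images else 1
      idx <- sample.int(n, nb, replace = TRUE)
      x <- arr[, , , idx, drop = FALSE]
      xm <- x
      xm[array(mvol, dim(xm))] <- rep(fillvals, times = nb)
      # generator step
      gf <- gen_forward(params$g, xm, l, alpha)
      y <- gf$y
      rec_loss <- mean(abs(x - y))
      drec <- -sign(x - y) * (config$lambda_rec / length(x))
      dfk <- disc_forward(params$d, y, l, alpha)
      sc <- dfk$score
      dsc_g <- matrix((sc - 1) * (config$lambda_adv / nb), ncol = 1L)
      dadv <- disc_backward(params$d, dfk$cache, dsc_g)$dx
      gb <- gen_backward(params$g, gf$cache, drec + dadv)
      up <- adam_step(params$g, clip_grads(gb$grads, config$clip_norm),
                      sg, lr = config$lr)
      params$g <- up$params; sg <- up$state
      # discriminator step (fake detached, old D cache reused)
      dfr <- disc_forward(params$d, x, l, alpha)
      dsr <- matrix((dfr$score - 1) / nb, ncol = 1L)
      dsf <- matrix(sc / nb, ncol = 1L)
      gr <- disc_backward(params$d, dfr$cache, dsr)$grads
      gf2 <- disc_backward(params$d, dfk$cache, dsf)$grads
      gd <- clip_grads(add_grads(gr, gf2), config$clip_norm)
      up <- adam_step(params$d, gd, sd_, lr = config$lr)
      params$d <- up$params; sd_ <- up$state
      if (!is.finite(rec_loss) || !is.finite(mean(sc)))
        stop(sprintf(
          "training diverged (non-finite loss) at level %d after %d images",
          l, seen))
      losses <- c(losses, rec_loss)
      seen <- seen + nb
    }
    total_images <- total_images + seen
    if (verbose)
      message(sprintf("level %4d: %6d images, final L1 %.4f",
                      l, seen, mean(utils::tail(losses, 20))))
  }
  structure(list(g = params$g, d = params$d, config = config,
                 growth = list(level = config$max_resolution, alpha = 1,
                               images = total_images),
                 inpaint = inpaint, seed = as.integer(seed)),
            class = "pcead_model")
}

add_grads <- function(a, b) {
  if (is.list(a)) {
    for (k in names(a)) a[[k]] <- add_grads(a[[k]], b[[k]])
    a
  } else a + b
}

#' Construct an untrained (randomly initialised) frozen model
#'
#' Useful as the baseline against which training progress is measured.
#'
#' @param config a `pcead_config`.
#' @param seed integer seed for the weight initialisation.
#' @param inpaint_fill fill colour for the inpainting mask.
#' @return A `pcead_model` with random weights.
#' @export
init_model <- function(config, seed = 1L, inpaint_fill = 0.5) {
  local_seed(seed)
  params <- init_network(config)
  fill <- inpaint_fill
  if (length(fill) == 1L) fill <- rep(fill, 3L)
  structure(list(g = params$g, d = params$d, config = config,
                 growth = list(level = config$max_resolution, alpha = 1,
                               images = 0L),
                 inpaint = list(fraction = config$inpaint_fraction,
                                fill = fill),
                 seed = as.integer(seed)),
            class = "pcead_model")
}

#' Reconstruct a patch with a frozen model
#'
#' Applies the model's inpainting mask, runs the generator, and composites
#' the result: pixels outside the mask are taken from the input unchanged,
#' pixels inside from the generator output. Repeated calls on the same
#' input are identical.
#'
#' @param model a frozen `pcead_model` (or any reconstructor implementing
#'   this generic, such as [oracle_reconstructor()]).
#' @param patch a `pcead_patch` whose side is a ladder level of the model.
#' @param ... passed to methods.
#' @return The reconstructed `pcead_patch`.
#' @export
reconstruct <- function(model, patch, ...) UseMethod("reconstruct")

#' @export
reconstruct.pcead_model <- function(model, patch, ...) {
  s <- patch$size
  if (s > model$config$max_resolution || !is_pow2(s))
    stop(sprintf("patch level %d not supported by a model of max %d",
                 s, model$config$max_resolution))
  masked <- apply_inpaint_mask(patch, model$inpaint)
  x <- masked$patch$image
  dim(x) <- c(s, s, 3L, 1L)
  y <- gen_forward(model$g, x, s, 1)$y
  dim(y) <- c(s, s, 3L)
  out <- patch$image
  for (c in 1:3) {
    ch <- out[, , c]; yc <- y[, , c]
    ch[masked$mask] <- yc[masked$mask]
    out[, , c] <- ch
  }
  out <- pmin(pmax(out, 0), 1)
  new_patch(out, patch$slide, patch$x, patch$y, patch$span)
}

#' @export
print.pcead_model <- function(x, ...) {
  cat(sprintf(
    "<pcead_model max %d px, %d images seen, seed %d>\n",
    x$config$max_resolution, x$growth$images, x$seed))
  invisible(x)
}

#' Save / load a frozen model checkpoint
#'
#' The checkpoint is a single RDS archive holding parameters, the network
#' configuration, the growth state, the inpainting spec and the training
#' seed (format version tagged).
#'
#' @param model a `pcead_model`.
#' @param path checkpoint path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "pcead-ckpt-1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pcead-ckpt-1"))
    stop("not a recognised model checkpoint: ", path)
  obj$model
}

# Evaluate mean absolute reconstruction error of a model over patches.
#' Mean absolute reconstruction error over a set of patches
#'
#' @param model a reconstructor (frozen model or oracle).
#' @param patches list of `pcead_patch`.
#' @param scope `"full"` (whole patch) or `"masked"` (inpainted square
#'   only, models only).
#' @return Mean absolute error, a single number.
#' @export
mean_reconstruction_error <- function(model, patches,
                                      scope = c("full", "masked")) {
  scope <- match.arg(scope)
  tot <- 0; n <- 0
  for (p in patches) {
    r <- reconstruct(model, p)
    e <- abs(p$image - r$image)
    if (scope == "masked" && inherits(model, "pcead_model")) {
      m <- apply_inpaint_mask(p, model$inpaint)$mask
      e <- e[array(rep(m, 3L), dim(e))]
    }
    tot <- tot + sum(e); n <- n + length(e)
  }
  tot / n
}

# Set the RNG locally, restoring the caller's state when the calling
# frame exits.
local_seed <- function(seed, env = parent.frame()) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, envir = env)
  set.seed(seed)
  invisible(seed)
}
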