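test_that("fade-in blend is linear with exact endpoints", {
  A <- array(stats::runif(48), c(4, 4, 3))
  B <- array(stats::runif(48), c(4, 4, 3))
  expect_identical(fade_in_blend(A, B, 0), A)
  expect_identical(fade_in_blend(A, B, 1), B)
  expect_equal(fade_in_blend(A, B, 0.5), (A + B) / 2)
  expect_error(fade_in_blend(A, B, 1.2), "\\[0, 1\\]")
  expect_error(fade_in_blend(A, B[, 1:2, ], 0.5), "same shape")
})

test_that("inpainting mask geometry follows the fraction", {
  p <- new_patch(array(0.3, c(64, 64, 3)), "s", 0L, 0L)
  r <- apply_inpaint_mask(p, list(fraction = 0.5, fill = 0.9))
  expect_identical(sum(r$mask), 1024L)
  expect_true(all(r$mask[17:48, 17:48]))
  expect_true(all(!r$mask[1:16, ]) && all(!r$mask[, 49:64]))
  expect_true(all(r$patch$image[17:48, 17:48, ] == 0.9))
  expect_true(all(r$patch$image[1:16, , ] == 0.3))
  # degenerate fraction: identity; full fraction: everything filled
  tiny <- apply_inpaint_mask(new_patch(array(0.3, c(64, 64, 3))),
                             list(fraction = 0.001, fill = 0))
  expect_false(any(tiny$mask))
  expect_identical(tiny$patch$image, p$image)
  full <- apply_inpaint_mask(p, list(fraction = 1, fill = 0.1))
  expect_true(all(full$mask) && all(full$patch$image == 0.1))
})

test_that("the grown generator at alpha 0 is the previous level upsampled", {
  cfg <- network_config(max_resolution = 32)
  m <- init_model(cfg, seed = 3)
  withr::local_seed(8)
  for (L in c(8L, 16L, 32L)) {
    x <- array(stats::runif(L * L * 3), c(L, L, 3))
    gL <- grow_generator(m$g, cfg, list(level = L, alpha = 0))
    gH <- grow_generator(m$g, cfg, list(level = L %/% 2L, alpha = 1))
    ylo <- gH(pcead:::downsample2(x, "average"))
    up <- ylo[rep(seq_len(L %/% 2L), each = 2), rep(seq_len(L %/% 2L), each = 2), ]
    expect_lt(max(abs(gL(x) - up)), 1e-5)
    # at alpha 1 the new convolutional block changes the output
    g1 <- grow_generator(m$g, cfg, list(level = L, alpha = 1))
    expect_gt(max(abs(g1(x) - up)), 1e-4)
    # shape and range contract
    y <- g1(x)
    expect_identical(dim(y), c(L, L, 3L))
    expect_true(all(y > 0 & y < 1))
  }
  expect_error(grow_generator(m$g, cfg, list(level = 64, alpha = 0)),
               "above")
})

test_that("the discriminator fade-in path has the same identity", {
  cfg <- network_config(max_resolution = 16)
  m <- init_model(cfg, seed = 4)
  withr::local_seed(9)
  x <- array(stats::runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  s16 <- pcead:::disc_forward(m$d, x, 16, alpha = 0)$score
  x8 <- pcead:::avgpool2_fwd(x)$y
  s8 <- pcead:::disc_forward(m$d, x8, 8, alpha = 1)$score
  expect_lt(max(abs(s16 - s8)), 1e-5)
})

test_that("backpropagation matches finite differences", {
  withr::local_seed(21)
  p <- pcead:::init_network(network_config(
    max_resolution = 8, channels = c(`4` = 5, `8` = 4)))
  x <- array(stats::runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  tgt <- array(stats::runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  loss <- function(pp) sum((pcead:::gen_forward(pp, x, 8, 0.4)$y - tgt)^2) / 2
  fw <- pcead:::gen_forward(p$g, x, 8, 0.4)
  gb <- pcead:::gen_backward(p$g, fw$cache, fw$y - tgt)
  eps <- 1e-5
  for (path in list(c("from", "8"), c("from", "4"), c("enc", "8"),
                    "bneck", c("dec", "8"), c("to", "8"), c("to", "4"))) {
    i <- sample(length(p$g[[path]]$W), 1)
    p1 <- p$g; p1[[path]]$W[i] <- p1[[path]]$W[i] + eps
    p2 <- p$g; p2[[path]]$W[i] <- p2[[path]]$W[i] - eps
    expect_equal(gb$grads[[path]]$W[i], (loss(p1) - loss(p2)) / (2 * eps),
                 tolerance = 1e-5)
  }
  # discriminator: parameter and input gradients
  ds <- matrix(c(0.4, -0.6), ncol = 1)
  df <- pcead:::disc_forward(p$d, x, 8, 0.4)
  db <- pcead:::disc_backward(p$d, df$cache, ds)
  dloss <- function(pd, xx = x)
    sum(pcead:::disc_forward(pd, xx, 8, 0.4)$score * ds)
  for (path in list(c("from", "8"), c("block", "8"), "conv4", "out")) {
    i <- sample(length(p$d[[path]]$W), 1)
    p1 <- p$d; p1[[path]]$W[i] <- p1[[path]]$W[i] + eps
    p2 <- p$d; p2[[path]]$W[i] <- p2[[path]]$W[i] - eps
    expect_equal(db$grads[[path]]$W[i], (dloss(p1) - dloss(p2)) / (2 * eps),
                 tolerance = 1e-5)
  }
  x1 <- x; x1[5, 2, 3, 1] <- x1[5, 2, 3, 1] + eps
  x2 <- x; x2[5, 2, 3, 1] <- x2[5, 2, 3, 1] - eps
  expect_equal(db$dx[5, 2, 3, 1], (dloss(p$d, x1) - dloss(p$d, x2)) /
                 (2 * eps), tolerance = 1e-5)
})

test_that("reconstruction composites exactly and is frozen", {
  cfg <- network_config(max_resolution = 8)
  m <- init_model(cfg, seed = 12, inpaint_fill = 0.5)
  withr::local_seed(13)
  p <- new_patch(array(stats::runif(8 * 8 * 3), c(8, 8, 3)), "s", 0L, 0L)
  r1 <- reconstruct(m, p)
  r2 <- reconstruct(m, p)
  expect_identical(r1$image, r2$image)
  msk <- apply_inpaint_mask(p, m$inpaint)$mask
  out <- array(rep(!msk, 3), dim(p$image))
  expect_identical(r1$image[out], p$image[out])
  expect_true(any(r1$image[array(rep(msk, 3), dim(p$image))] !=
                    p$image[array(rep(msk, 3), dim(p$image))]))
  expect_true(all(r1$image >= 0 & r1$image <= 1))
  expect_error(reconstruct(m, new_patch(array(0.5, c(16, 16, 3)))),
               "level")
  # the oracle reconstructor is substitutable through the same generic
  o <- oracle_reconstructor(base_color = c(0.5, 0.5, 0.5))
  ro <- reconstruct(o, p)
  expect_s3_class(ro, "pcead_patch")
  expect_identical(ro$size, p$size)
})

test_that("training budgets and record levels are validated", {
  cfg <- network_config(max_resolution = 8)
  dir <- withr::local_tempdir()
  p4 <- lapply(1:4, function(i) new_patch(array(0.5, c(4, 4, 3)), "s", 0L, 0L))
  paths <- write_record_shards(p4, dir)
  expect_error(train_phase1(dir, cfg, schedule = 0, seed = 1),
               "budget")
  expect_error(train_phase1(dir, cfg, schedule = 10, seed = 1),
               "missing patches at level 8")
})

test_that("training is deterministic given the seed", {
  pts <- normal_patches_64(24)
  lv <- unlist(lapply(pts, function(p)
    build_resolution_pyramid(p, min_size = 4)[3:5]), recursive = FALSE)
  dir <- withr::local_tempdir()
  write_record_shards(lv, dir)
  cfg <- network_config(max_resolution = 16)
  m1 <- train_phase1(dir, cfg, schedule = 120, seed = 33)
  m2 <- train_phase1(dir, cfg, schedule = 120, seed = 33)
  expect_identical(m1$g, m2$g)
  expect_identical(m1$d, m2$d)
  expect_identical(m1$growth$level, 16L)
  # checkpoint round trip
  ck <- withr::local_tempfile(fileext = ".rds")
  save_model(m1, ck)
  m3 <- load_model(ck)
  p16 <- build_resolution_pyramid(pts[[1]], min_size = 16)
  p16 <- p16[[length(p16)]]
  expect_identical(reconstruct(m3, p16)$image, reconstruct(m1, p16)$image)
})

test_that("a trivially learnable texture is driven far below the untrained error", {
  cp <- lapply(1:40, function(i) new_patch(
    array(rep(c(0.7, 0.4, 0.6), each = 64), c(8, 8, 3)), "c", 0L, 0L))
  lv <- unlist(lapply(cp, build_resolution_pyramid), recursive = FALSE)
  dir <- withr::local_tempdir()
  write_record_shards(lv, dir)
  cfg <- network_config(max_resolution = 8)
  m <- train_phase1(dir, cfg, schedule = 2500, seed = 5)
  base <- init_model(cfg, seed = 5, inpaint_fill = m$inpaint$fill)
  held <- cp[1:5]
  ratio <- mean_reconstruction_error(m, held) /
    mean_reconstruction_error(base, held)
  expect_lt(ratio, 0.1)
})
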