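test_that("reconstruction errors are elementwise absolute differences", {
  withr::local_seed(31)
  a <- new_patch(array(stats::runif(192), c(8, 8, 3)), "s", 0L, 0L)
  b <- new_patch(array(stats::runif(192), c(8, 8, 3)), "s", 0L, 0L)
  e <- reconstruction_error(a, b)
  expect_s3_class(e, "pcead_errors")
  for (i in sample(192, 20)) {
    expect_identical(e$err[i], abs(a$image[i] - b$image[i]))
  }
  expect_true(all(reconstruction_error(a, a)$err == 0))
  c1 <- new_patch(array(0.8, c(4, 4, 3))); c2 <- new_patch(array(0.5, c(4, 4, 3)))
  expect_true(all(abs(reconstruction_error(c1, c2)$err - 0.3) < 1e-15))
  expect_error(reconstruction_error(a, new_patch(array(0.1, c(4, 4, 3)))),
               "shapes differ")
})

test_that("NERD pooling matches hand computations and degenerate cases", {
  # two pixels (0,0,0) and (2,2,2): mu = 1s, covariance all 2s (n-1)
  n2 <- fit_nerd(list(rbind(c(0, 0, 0), c(2, 2, 2))), eps = 1e-6)
  expect_equal(n2$mu, c(1, 1, 1))
  expect_equal(n2$sigma, matrix(2, 3, 3))
  expect_identical(n2$n, 2)
  # constant errors: zero covariance but still invertible via eps
  cst <- structure(list(err = array(0.2, c(4, 4, 3)), slide = "s",
                        x = 0L, y = 0L, span = 4L),
                   class = "pcead_errors")
  nc <- fit_nerd(list(cst))
  expect_equal(nc$mu, rep(0.2, 3))
  expect_true(all(nc$sigma == 0))
  dm <- mahalanobis_map(cst, nc)
  expect_true(all(is.finite(dm)) && all(dm == 0))
  expect_error(fit_nerd(list(matrix(c(1, 2, 3), 1, 3))), "at least 2")
})

test_that("streaming, batch and permuted fits agree to 1e-10", {
  withr::local_seed(32)
  chunks <- lapply(1:6, function(i) matrix(stats::rnorm(3000, 0.1, 0.05),
                                           ncol = 3))
  batch <- fit_nerd(list(do.call(rbind, chunks)), eps = 0)
  acc <- nerd_accumulator()
  for (ch in chunks) acc <- nerd_update(acc, ch)
  stream <- fit_nerd(acc, eps = 0)
  perm <- fit_nerd(chunks[sample(6)], eps = 0)
  expect_lt(max(abs(batch$mu - stream$mu)), 1e-10)
  expect_lt(max(abs(batch$sigma - stream$sigma)), 1e-10)
  expect_lt(max(abs(batch$sigma - perm$sigma)), 1e-10)
})

random_nerd <- function() {
  A <- matrix(stats::rnorm(9, sd = 0.5), 3, 3)
  structure(list(mu = stats::rnorm(3, 0.1, 0.05),
                 sigma = crossprod(A) + diag(0.01, 3),
                 eps = 0, n = 100),
            class = "pcead_nerd")
}

test_that("Mahalanobis maps match the scalar oracle and reduce to Euclid", {
  withr::local_seed(33)
  for (rep in 1:10) {
    nerd <- random_nerd()
    arr <- array(abs(stats::rnorm(6 * 5 * 3, 0.1, 0.2)), c(6, 5, 3))
    expect_lt(max(abs(mahalanobis_map(arr, nerd) -
                        loop_mahalanobis(arr, nerd$mu, nerd$sigma, 0))),
              1e-8)
  }
  iden <- structure(list(mu = c(0, 0, 0), sigma = diag(3), eps = 0, n = 10),
                    class = "pcead_nerd")
  arr <- array(0, c(1, 1, 3)); arr[1, 1, ] <- c(3, 4, 0)
  expect_equal(mahalanobis_map(arr, iden)[1, 1], 5)
  # distance at the mean is zero
  nerd <- random_nerd()
  at_mu <- array(rep(nerd$mu, each = 4), c(2, 2, 3))
  expect_true(all(mahalanobis_map(at_mu, nerd) < 1e-12))
})

test_that("Mahalanobis distances are affine invariant", {
  withr::local_seed(34)
  nerd <- random_nerd()
  arr <- array(abs(stats::rnorm(8 * 8 * 3, 0.1, 0.2)), c(8, 8, 3))
  d0 <- mahalanobis_map(arr, nerd)
  A <- matrix(c(2, 0.3, 0, -0.5, 1.5, 0.2, 0.1, 0, 0.8), 3, 3)
  b <- c(0.4, -0.2, 1)
  E <- matrix(arr, ncol = 3) %*% t(A)
  E <- sweep(E, 2, b, "+")
  arr2 <- array(E, dim(arr))
  nerd2 <- structure(list(mu = as.numeric(A %*% nerd$mu + b),
                          sigma = A %*% nerd$sigma %*% t(A),
                          eps = 0, n = nerd$n),
                     class = "pcead_nerd")
  expect_lt(max(abs(mahalanobis_map(arr2, nerd2) - d0)), 1e-8)
})

test_that("threshold calibration uses the nearest-rank quantile", {
  expect_equal(calibrate_threshold(1:100, 0.5)$tau, 50)
  expect_equal(calibrate_threshold(c(3, 9, 1), 0)$tau, 9)
  expect_error(calibrate_threshold(numeric(0), 0.05), "no distance")
  expect_error(calibrate_threshold(1:10, 1), "q < 1")
  # self-calibration: exceedance equals q within 3 binomial SEs
  withr::local_seed(35)
  d <- sqrt(stats::rchisq(2e5, df = 3))
  tau <- calibrate_threshold(d, 0.05)
  rate <- mean(d > tau$tau)
  se <- sqrt(0.05 * 0.95 / 2e5)
  expect_lt(abs(rate - 0.05), 3 * se)
  # chi-square-3 closed form for Gaussian errors
  expect_equal(tau$tau, sqrt(stats::qchisq(0.95, 3)), tolerance = 0.02)
})

test_that("binarization is strict and matches a scalar loop", {
  dmap <- matrix(c(0.5, 1, 1.5, 2), 2, 2)
  tau <- structure(list(tau = 1, q = 0, n = 4), class = "pcead_threshold")
  expect_identical(binarize(dmap, tau), dmap > 1)
  expect_false(any(binarize(matrix(1, 3, 3), tau)))   # equality -> normal
  expect_true(all(binarize(matrix(0.1, 2, 2),
                           structure(list(tau = 0), class = "pcead_threshold"))))
  withr::local_seed(36)
  dm <- matrix(stats::runif(64, 0, 4), 8, 8)
  got <- binarize(dm, 2)
  for (i in 1:8) for (j in 1:8) expect_identical(got[i, j], dm[i, j] > 2)
})

test_that("squared distances under the NERD follow chi-square with 3 df", {
  withr::local_seed(37)
  A <- matrix(c(0.04, 0.01, 0, 0, 0.05, 0.02, 0, 0, 0.03), 3, 3)
  X <- matrix(stats::rnorm(3e4), ncol = 3) %*% A
  X <- sweep(X, 2, c(0.1, 0.12, 0.08), "+")
  nerd <- fit_nerd(list(X), eps = 0)
  # distributional shape check at fixed seed (not a gate on p-values)
  d2 <- sort(mahalanobis_map(array(X[1:5000, ], c(5000, 1, 3)), nerd)^2)
  ks <- max(abs(stats::pchisq(d2, 3) - seq_along(d2) / length(d2)))
  expect_lt(ks, 0.03)
})

test_that("NERD and threshold serialise through JSON losslessly", {
  withr::local_seed(38)
  nerd <- random_nerd()
  tau <- calibrate_threshold(stats::runif(100), 0.1)
  f <- withr::local_tempfile(fileext = ".json")
  write_nerd(nerd, f, tau = tau)
  back <- read_nerd(f)
  expect_equal(back$nerd$mu, nerd$mu)
  expect_equal(back$nerd$sigma, nerd$sigma)
  expect_equal(back$tau$tau, tau$tau)
  expect_equal(back$tau$q, 0.1)
})
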