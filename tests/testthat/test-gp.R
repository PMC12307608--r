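# Independent dense-matrix GP oracle used to check the Cholesky path.
oracle_gp <- function(X, y, Xq, ell, s2m, v, noise, nu = 2.5) {
  mat_k <- function(A, B) {
    D <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), `+`) -
                     2 * A %*% t(B), 0))
    z <- sqrt(5) * D / ell
    s2m * (1 + z + z^2 / 3) * exp(-z)
  }
  m <- mean(y); s <- sd(y)
  ys <- (y - m) / s
  K <- mat_k(X, X) + v * X %*% t(X) + diag(noise, nrow(X))
  Kq <- mat_k(Xq, X) + v * Xq %*% t(X)
  kss <- s2m + v * rowSums(Xq^2)
  Kinv <- solve(K)
  mu <- m + s * as.numeric(Kq %*% Kinv %*% ys)
  var_s <- pmax(kss - diag(Kq %*% Kinv %*% t(Kq)), 0)
  list(mu = mu, sigma = s * sqrt(var_s))
}

test_that("a noise-free GP interpolates its training data", {
  withr::with_seed(21, {
    X <- matrix(rnorm(15L), nrow = 5L)
    y <- rnorm(5L, sd = 2)
  })
  fit <- gp_fit(X, y, kernel_config(noise_variance = 0), seed = 1L)
  p <- predict(fit, X)
  expect_lt(max(abs(p$mu - y) / pmax(abs(y), 1)), 1e-6)
  expect_lt(max(p$sigma), 1e-4)

  # minimal two-point case
  X2 <- matrix(c(0, 1), ncol = 1L)
  y2 <- c(3, -1)
  fit2 <- gp_fit(X2, y2, kernel_config(noise_variance = 0,
                                       matern_lengthscale = 1), seed = 1L)
  expect_equal(predict(fit2, X2)$mu, y2, tolerance = 1e-6)
})

test_that("a constant target yields a constant predictive mean", {
  X <- matrix(seq_len(8L), ncol = 1L)
  fit <- gp_fit(X, rep(4.2, 8L), kernel_config(), seed = 1L)
  p <- predict(fit, matrix(c(-5, 0.5, 20), ncol = 1L))
  expect_equal(p$mu, rep(4.2, 3L), tolerance = 1e-6)
})

test_that("a linear-kernel GP on a line matches the least-squares fit", {
  x <- seq(-2, 2, length.out = 5L)       # centered by construction
  y <- 1 + 2 * x
  X <- matrix(x, ncol = 1L)
  fit <- gp_fit(X, y, kernel_config(matern_variance = 0,
                                    matern_lengthscale = 1,
                                    linear_variance = 1,
                                    noise_variance = 0), seed = 1L)
  xq <- c(-1.3, 0.4, 3)
  lmfit <- lm(y ~ x)
  expect_equal(predict(fit, matrix(xq, ncol = 1L))$mu,
               unname(predict(lmfit, data.frame(x = xq))),
               tolerance = 1e-4)
})

test_that("deviation vanishes at data, reaches the prior far away, never exceeds it", {
  withr::with_seed(5, {
    X <- matrix(rnorm(30L), nrow = 10L)
    y <- rnorm(10L)
  })
  cfg <- kernel_config(matern_lengthscale = 1, matern_variance = 2,
                       linear_variance = 0, noise_variance = 1e-8)
  fit <- gp_fit(X, y, cfg, seed = 1L)
  prior_sd <- fit$y_sd * sqrt(2)
  far <- matrix(rnorm(3L) + 100, nrow = 1L)
  expect_equal(predict(fit, far)$sigma, prior_sd, tolerance = 1e-3)
  expect_true(all(predict(fit, X)$sigma <= prior_sd + 1e-12))
  expect_lt(max(predict(fit, X)$sigma), 1e-3)
})

test_that("Cholesky predictions match the dense-matrix oracle on n = 50", {
  withr::with_seed(8, {
    X <- matrix(rnorm(250L), nrow = 50L)
    y <- rowSums(X) + rnorm(50L, sd = 0.3)
    Xq <- matrix(rnorm(40L), nrow = 8L)
  })
  ell <- 2; s2m <- 1.5; v <- 0.2; noise <- 0.05
  fit <- gp_fit(X, y, kernel_config(matern_lengthscale = ell,
                                    matern_variance = s2m,
                                    linear_variance = v,
                                    noise_variance = noise), seed = 1L)
  p <- predict(fit, Xq)
  o <- oracle_gp(X, y, Xq, ell, s2m, v, noise)
  expect_equal(p$mu, o$mu, tolerance = 1e-8)
  expect_equal(p$sigma, o$sigma, tolerance = 1e-8)
})

test_that("the sum kernel degenerates to Matern-only as linear variance vanishes", {
  withr::with_seed(9, {
    X <- matrix(rnorm(24L), nrow = 8L)
    y <- rnorm(8L)
    Xq <- matrix(rnorm(9L), nrow = 3L)
  })
  base <- list(matern_lengthscale = 1.5, matern_variance = 1,
               noise_variance = 0.01)
  lim <- gp_fit(X, y, do.call(kernel_config,
                              c(base, linear_variance = 1e-8)), seed = 1L)
  pure <- gp_fit(X, y, do.call(kernel_config,
                               c(base, linear_variance = 0)), seed = 1L)
  expect_equal(predict(lim, Xq)$mu, predict(pure, Xq)$mu, tolerance = 1e-6)
  expect_equal(predict(lim, Xq)$sigma, predict(pure, Xq)$sigma,
               tolerance = 1e-6)
})

test_that("observing a point reduces the deviation there", {
  withr::with_seed(10, {
    X <- matrix(rnorm(20L), nrow = 10L)
    y <- rnorm(10L)
  })
  xq <- matrix(rnorm(2L) + 3, nrow = 1L)
  cfg <- kernel_config(matern_lengthscale = 1, matern_variance = 1,
                       linear_variance = 0, noise_variance = 1e-6)
  s_before <- predict(gp_fit(X, y, cfg, seed = 1L), xq)$sigma
  s_after <- predict(gp_fit(rbind(X, xq), c(y, 0.5), cfg, seed = 1L),
                     xq)$sigma
  expect_lt(s_after, s_before)
})

test_that("gp_fit validates its inputs", {
  expect_error(gp_fit(matrix(1, 1, 1), 1, kernel_config()), "at least 2")
  expect_error(gp_fit(matrix(1:4, 2), 1:3, kernel_config()), "length")
  fit <- gp_fit(matrix(1:4, 2), c(1, 2), kernel_config())
  expect_error(predict(fit, matrix(1, 1, 3)), "dimension")
})

test_that("cross-validation recovers a noiseless linear signal", {
  withr::with_seed(31, {
    X <- matrix(rnorm(60L * 3L), nrow = 60L)
    y <- 2 * X[, 1L]
  })
  cv <- cross_validate(X, y, kernel_config(), folds = 5L, seed = 2L)
  expect_gte(cv$pearson, 0.99)
  expect_lt(cv$rmse, 0.5)
})

test_that("cross-validation finds no signal in pure noise on average", {
  cfg <- kernel_config(matern_lengthscale = 2, matern_variance = 1,
                       linear_variance = 0.1, noise_variance = 0.5)
  rs <- vapply(1:20, function(s) {
    withr::with_seed(1000L + s, {
      X <- matrix(rnorm(200L * 2L), nrow = 200L)
      y <- rnorm(200L)
    })
    cross_validate(X, y, cfg, folds = 5L, seed = s)$pearson
  }, numeric(1L))
  expect_lt(mean(abs(rs)), 0.2)
})

test_that("cross-validation metrics are invariant to row order", {
  withr::with_seed(12, {
    X <- matrix(rnorm(40L * 2L), nrow = 40L)
    y <- X[, 1L] + rnorm(40L, sd = 0.2)
    perm <- sample(40L)
  })
  cfg <- kernel_config(matern_lengthscale = 1, matern_variance = 1,
                       linear_variance = 0.5, noise_variance = 0.1)
  a <- cross_validate(X, y, cfg, folds = 4L, seed = 3L)
  b <- cross_validate(X[perm, ], y[perm], cfg, folds = 4L, seed = 3L)
  expect_equal(a$pearson, b$pearson, tolerance = 1e-10)
  expect_equal(a$rmse, b$rmse, tolerance = 1e-10)
  expect_error(cross_validate(X, y, cfg, folds = 1L), "folds")
})
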