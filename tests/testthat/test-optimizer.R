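test_that("GP posterior matches the dense closed-form oracle", {
  X <- rbind(c(2, 4), c(7, 10), c(4, 15), c(9, 3), c(1, 9))
  y <- c(1.2, 0.7, 0.9, 1.5, 1.1)
  sur <- fit_surrogate(X, y, restarts = 3, seed = 0)
  Xq <- rbind(c(5, 8), c(1, 2), c(10, 16))
  pred <- predict_surrogate(sur, Xq)
  # oracle: explicit kernel matrix inversion with the fitted hyperparameters
  scale01 <- function(M) cbind((M[, 1] - 1) / 9, (M[, 2] - 2) / 14)
  Xs <- scale01(X); Qs <- scale01(Xq)
  k <- function(A, B) {
    sur$output_scale^2 *
      exp(-0.5 * (outer(A[, 1], B[, 1], "-")^2 / sur$length_scales[1]^2 +
                    outer(A[, 2], B[, 2], "-")^2 / sur$length_scales[2]^2))
  }
  K <- k(Xs, Xs) + diag(sur$noise + 1e-10, nrow(X))
  Ki <- solve(K)
  mu_o <- mean(y) + k(Qs, Xs) %*% Ki %*% (y - mean(y))
  var_o <- sur$output_scale^2 - diag(k(Qs, Xs) %*% Ki %*% t(k(Qs, Xs)))
  expect_equal(pred$mean, as.numeric(mu_o), tolerance = 1e-8)
  expect_equal(pred$sd^2, pmax(var_o, 0), tolerance = 1e-8)
})

test_that("GP limits: constant data, interpolation, prior reversion", {
  # constant targets -> posterior mean equals the constant everywhere
  Xc <- rbind(c(2, 4), c(7, 10), c(4, 15))
  surc <- fit_surrogate(Xc, c(0.8, 0.8, 0.8), seed = 0)
  predc <- predict_surrogate(surc, pattern_box())
  expect_lt(max(abs(predc$mean - 0.8)), 1e-6)
  # near-noiseless posterior interpolates the training targets
  X <- rbind(c(2, 4), c(8, 12), c(5, 7), c(3, 14))
  y <- c(1.0, 0.5, 0.8, 1.2)
  sur <- fit_surrogate(X, y, restarts = 5, seed = 1)
  at_train <- predict_surrogate(sur, X)
  expect_lt(max(abs(at_train$mean - y)), 1e-2)
  # far from all data the posterior reverts to the prior variance: build a
  # surrogate with known hyperparameters and query >= 10 length scales away
  sur2 <- stereomire:::new_surrogate(X, y, stereomire:::scale_to_unit(X),
                                     mean(y),
                                     list(output_scale = 0.4,
                                          length_scales = c(0.05, 0.05),
                                          noise = 1e-8))
  far <- predict_surrogate(sur2, matrix(c(10, 16), 1))
  expect_equal(far$sd^2, 0.4^2, tolerance = 0.01 * 0.4^2)
  expect_equal(far$mean, mean(y), tolerance = 1e-3)
})

test_that("expected improvement matches a Monte-Carlo oracle and its edge cases", {
  mu <- c(0.5, 0.9, 1.4, 0.2, 1.0)
  sd <- c(0.3, 0.05, 0.2, 0.4, 0.0)
  best <- 0.8
  ei <- expected_improvement(mu, sd, best)
  expect_true(all(ei >= 0))
  # sigma = 0: EI = max(best - mu, 0)
  expect_identical(ei[5], 0)
  expect_equal(expected_improvement(0.5, 0, best), 0.3)
  # 1e6-draw Monte-Carlo oracle
  withr::with_seed(123, {
    for (i in 1:4) {
      draws <- rnorm(1e6, mu[i], sd[i])
      mc <- mean(pmax(best - draws, 0))
      expect_equal(ei[i], mc, tolerance = 1e-3)
    }
  })
})

test_that("proposals scan the grid, break ties low and detect exhaustion", {
  grid <- stereomire:::pattern_box()
  # surrogate trained on 149 of the 150 grid points -> the single hole
  hole <- c(6, 9)
  keep <- !(grid[, 1] == hole[1] & grid[, 2] == hole[2])
  sur <- fit_surrogate(grid[keep, ], rowSums(grid[keep, ]) / 10,
                       restarts = 1, seed = 0)
  p <- propose_next(sur)
  expect_identical(c(p$dot_distance_d, p$dot_size_s), c(6L, 9L))
  # all 150 evaluated -> exhaustion error
  sur_all <- fit_surrogate(grid, rowSums(grid) / 10, restarts = 1, seed = 0)
  expect_error(propose_next(sur_all), "exhausted")
  # zero-EI tie rule: a zero-variance surrogate with mu >= best everywhere
  # falls back to the smallest unevaluated (d, s)
  sur0 <- stereomire:::new_surrogate(matrix(c(5, 5), 1), 1,
                                     stereomire:::scale_to_unit(matrix(c(5, 5), 1)),
                                     1, list(output_scale = 1e-12,
                                             length_scales = c(0.3, 0.3),
                                             noise = 1e-12))
  p0 <- propose_next(sur0, best_y = 0.5)
  expect_identical(c(p0$dot_distance_d, p0$dot_size_s), c(1L, 2L))
})

test_that("optimizer follows the 10-random + EI protocol and finds the optimum", {
  f <- function(p) (p$dot_distance_d - 4)^2 + (p$dot_size_s - 9)^2
  # exhaustive-grid oracle: (4, 9) is the unique minimum
  grid <- stereomire:::pattern_box()
  vals <- (grid[, 1] - 4)^2 + (grid[, 2] - 9)^2
  expect_identical(unname(grid[which.min(vals), ]), c(4L, 9L))
  expect_identical(sum(vals == min(vals)), 1L)

  hits <- 0L
  for (seed in 0:19) {
    res <- optimize_pattern(f, n_init = 10, n_iter = 15, seed = seed,
                            restarts = 2)
    h <- res$history
    expect_identical(nrow(h), 25L)
    expect_identical(h$phase[1:10], rep("init", 10)) # 10 random inits first
    expect_identical(h$phase[11:25], rep("acquisition", 15))
    expect_false(any(duplicated(h[, c("d", "s")]))) # no repeated evaluations
    # incumbent error trace is non-increasing
    expect_true(all(diff(cummin(h$error)) <= 0))
    expect_equal(res$best_error, min(h$error))
    if (res$best_params$dot_distance_d == 4L &&
        res$best_params$dot_size_s == 9L) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("optimizer survives failing evaluations and constant objectives", {
  # evaluator that errors on a subregion: failures become +Inf, run continues
  f_bad <- function(p) {
    if (p$dot_distance_d <= 2) stop("hardware glitch")
    (p$dot_distance_d - 6)^2 + (p$dot_size_s - 10)^2
  }
  res <- suppressWarnings(optimize_pattern(f_bad, n_init = 10, n_iter = 10,
                                           seed = 3, restarts = 1))
  expect_identical(nrow(res$history), 20L)
  expect_true(is.finite(res$best_error))
  expect_gt(res$best_params$dot_distance_d, 2L)
  # constant evaluator
  resc <- optimize_pattern(function(p) 2.5, n_init = 5, n_iter = 3, seed = 0,
                           restarts = 1)
  expect_equal(resc$best_error, 2.5)
  # determinism of the whole loop
  res1 <- optimize_pattern(function(p) p$dot_distance_d + p$dot_size_s / 2,
                           n_init = 6, n_iter = 4, seed = 9, restarts = 2)
  res2 <- optimize_pattern(function(p) p$dot_distance_d + p$dot_size_s / 2,
                           n_init = 6, n_iter = 4, seed = 9, restarts = 2)
  expect_identical(res1$history, res2$history)
  # tidy/glance accessors
  td <- tidy(res1)
  expect_identical(td$best_so_far, cummin(td$error))
  gl <- glance(res1)
  expect_identical(gl$n_evals, 10L)
  expect_identical(gl$n_init, 6L)
})

test_that("guided search beats pure random search on synthetic objectives", {
  f <- function(p) {
    0.4 + 0.05 * (p$dot_distance_d - 3)^2 + 0.02 * (p$dot_size_s - 11)^2 +
      0.1 * sin(p$dot_size_s)
  }
  grid <- stereomire:::pattern_box()
  bo <- numeric(0); rnd <- numeric(0)
  for (seed in 0:9) { # scaled down from 20 seeds for test-time budget
    res <- optimize_pattern(f, n_init = 10, n_iter = 15, seed = seed,
                            restarts = 1)
    bo <- c(bo, res$best_error)
    idx <- withr::with_seed(seed, sample.int(nrow(grid), 25))
    rnd <- c(rnd, min(vapply(idx, function(i) {
      f(pattern_params(grid[i, 1], grid[i, 2]))
    }, numeric(1))))
  }
  expect_lte(median(bo), median(rnd))
})
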