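# Gaussian-process surrogate (RBF kernel with an output scale, i.e.
# "RBF + scaling") over the integer pattern box d in [1,10] x s in [2,16],
# expected-improvement acquisition maximized by exhaustive grid scan, and the
# Bayesian optimization loop: 10 random initial evaluations, then
# fit -> propose -> evaluate.

pattern_box <- function() {
  grid <- expand.grid(d = 1:10, s = 2:16) # ordered by d fastest? see below
  grid <- grid[order(grid$d, grid$s), ]
  rownames(grid) <- NULL
  as.matrix(grid)
}

scale_to_unit <- function(X) {
  cbind((X[, 1] - 1) / 9, (X[, 2] - 2) / 14)
}

rbf_kernel <- function(A, B, output_scale, length_scales) {
  d1 <- outer(A[, 1], B[, 1], "-") / length_scales[1]
  d2 <- outer(A[, 2], B[, 2], "-") / length_scales[2]
  output_scale^2 * exp(-0.5 * (d1^2 + d2^2))
}

#' Fit the Gaussian-process surrogate of the reconstruction error
#'
#' Kernel `k(a, b) = s_f^2 * exp(-1/2 * sum_j (a_j - b_j)^2 / l_j^2)` plus a
#' noise term on the diagonal, over inputs scaled to the unit square and
#' mean-centered targets. Hyperparameters (output scale, two length scales,
#' noise level) maximize the log marginal likelihood by multi-start L-BFGS-B
#' on log parameters; a deterministic seed fixes the restart draws. Duplicate
#' inputs with conflicting targets are absorbed by a numerical jitter rather
#' than failing.
#'
#' @param X n x 2 matrix (or data frame) of (d, s) pattern parameters.
#' @param y Numeric vector of observed errors (mm), length n (non-finite
#'   entries are dropped with their rows).
#' @param restarts Number of random restarts for hyperparameter fitting.
#' @param seed Integer seed for the restarts.
#' @return A `gp_surrogate`.
#' @export
fit_surrogate <- function(X, y, restarts = 5L, seed = 0L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), ncol(X) == 2)
  keep <- is.finite(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X)
  if (n < 1) stop("no finite observations to fit", call. = FALSE)
  Xs <- scale_to_unit(X)
  y_mean <- mean(y)
  yc <- y - y_mean
  y_sd <- stats::sd(y)
  if (n < 2 || !is.finite(y_sd) || y_sd < 1e-12) {
    # prior-only / degenerate surrogate: flat mean, prior variance
    hyp <- list(output_scale = max(y_sd, 1e-6, na.rm = TRUE),
                length_scales = c(0.3, 0.3), noise = 1e-6)
    return(new_surrogate(X, y, Xs, y_mean, hyp))
  }

  nll <- function(logp) {
    os <- exp(logp[1]); ls <- exp(logp[2:3]); nv <- exp(logp[4])
    K <- rbf_kernel(Xs, Xs, os, ls)
    diag(K) <- diag(K) + nv + 1e-10
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), yc))
    as.numeric(0.5 * sum(yc * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi))
  }

  local_seed(derive_seed(seed, 505))
  start0 <- log(c(y_sd, 0.3, 0.3, max(1e-4 * y_sd, 1e-8)))
  lower <- log(c(1e-6 * y_sd, 0.02, 0.02, 1e-10))
  upper <- log(c(1e3 * y_sd, 10, 10, y_sd^2 + 1e-8))
  starts <- list(start0)
  if (restarts > 1) {
    for (r in seq_len(restarts - 1)) {
      starts[[r + 1]] <- stats::runif(4, lower, upper)
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) best <- list(par = start0, value = nll(start0))
  hyp <- list(output_scale = exp(best$par[1]),
              length_scales = exp(best$par[2:3]),
              noise = exp(best$par[4]))
  new_surrogate(X, y, Xs, y_mean, hyp)
}

new_surrogate <- function(X, y, Xs, y_mean, hyp) {
  n <- nrow(X)
  K <- rbf_kernel(Xs, Xs, hyp$output_scale, hyp$length_scales)
  diag(K) <- diag(K) + hyp$noise + 1e-10
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y - y_mean))
  structure(list(X = X, y = y, Xs = Xs, y_mean = y_mean,
                 output_scale = hyp$output_scale,
                 length_scales = hyp$length_scales, noise = hyp$noise,
                 L = L, alpha = alpha, fitted = TRUE),
            class = "gp_surrogate")
}

#' @export
print.gp_surrogate <- function(x, ...) {
  cat(sprintf(paste0("<gp_surrogate> %d observations; output_scale %.4g, ",
                     "length scales (%.3g, %.3g), noise %.3g\n"),
              nrow(x$X), x$output_scale, x$length_scales[1],
              x$length_scales[2], x$noise))
  invisible(x)
}

#' Posterior mean and standard deviation of the surrogate
#'
#' @param surrogate A `gp_surrogate`.
#' @param Xnew m x 2 matrix of (d, s) query points.
#' @return Tibble with columns `d`, `s`, `mean`, `sd` (noise-free posterior).
#' @export
predict_surrogate <- function(surrogate, Xnew) {
  Xnew <- as.matrix(Xnew)
  Qs <- scale_to_unit(Xnew)
  Ks <- rbf_kernel(Qs, surrogate$Xs, surrogate$output_scale,
                   surrogate$length_scales)
  mu <- surrogate$y_mean + as.numeric(Ks %*% surrogate$alpha)
  V <- forwardsolve(t(surrogate$L), t(Ks))
  var <- surrogate$output_scale^2 - colSums(V^2)
  var[var < 0] <- 0
  tibble::tibble(d = Xnew[, 1], s = Xnew[, 2], mean = mu, sd = sqrt(var))
}

#' Closed-form expected improvement (minimization)
#'
#' `EI(x) = (best_y - mu) * Phi(z) + sigma * phi(z)` with
#' `z = (best_y - mu) / sigma`; where `sigma = 0`, EI equals
#' `max(best_y - mu, 0)`.
#'
#' @param mu,sd Posterior mean and sd vectors.
#' @param best_y Incumbent best (smallest) observed value.
#' @return Numeric vector of non-negative EI values.
#' @export
expected_improvement <- function(mu, sd, best_y) {
  imp <- best_y - mu
  out <- pmax(imp, 0)
  pos <- sd > 0
  z <- imp[pos] / sd[pos]
  out[pos] <- imp[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  out
}

#' Propose the next pattern to evaluate
#'
#' Evaluates the expected improvement at every point of the 10 x 15 integer
#' grid (d in 1..10, s in 2..16), excludes already-evaluated points, and
#' returns the argmax; exact ties break toward smaller d, then smaller s.
#'
#' @param surrogate A fitted `gp_surrogate`.
#' @param best_y Incumbent best observed error (defaults to the surrogate's
#'   own minimum target).
#' @param exclude Optional extra k x 2 matrix of (d, s) points to exclude in
#'   addition to the surrogate's training points.
#' @return A [pattern_params()] object with attribute `ei`.
#' @export
propose_next <- function(surrogate, best_y = min(surrogate$y),
                         exclude = NULL) {
  stopifnot(inherits(surrogate, "gp_surrogate"), isTRUE(surrogate$fitted))
  grid <- pattern_box()
  seen <- rbind(surrogate$X, exclude)
  if (!is.null(seen) && nrow(seen) > 0) {
    key <- paste(grid[, 1], grid[, 2])
    seen_key <- paste(seen[, 1], seen[, 2])
    grid <- grid[!key %in% seen_key, , drop = FALSE]
  }
  if (nrow(grid) == 0) stop("search space exhausted", call. = FALSE)
  pred <- predict_surrogate(surrogate, grid)
  ei <- expected_improvement(pred$mean, pred$sd, best_y)
  # grid is sorted by (d, s); the first strict maximum realizes the tie-break
  i <- which.max(ei)
  out <- pattern_params(grid[i, 1], grid[i, 2])
  attr(out, "ei") <- ei[i]
  out
}

#' Bayesian optimization of the pattern parameters
#'
#' The protocol of the adaptive pattern generator: `n_init` distinct
#' uniformly random grid points are evaluated first, then `n_iter` rounds of
#' surrogate fitting and expected-improvement proposals. An evaluator error
#' records `Inf` for that point and the run continues (hardware-style
#' failures must not kill an optimization). The incumbent best is tracked
#' over the full history.
#'
#' @param evaluator Function `pattern_params -> error (mm)`; deterministic or
#'   externally seeded.
#' @param n_init Random initial evaluations (default 10).
#' @param n_iter Surrogate-guided evaluations after initialization
#'   (default 15).
#' @param seed Integer seed (initial design + surrogate restarts).
#' @param restarts Hyperparameter restarts per surrogate fit.
#' @return An `opt_result`: tibble `history` (d, s, error, phase, eval),
#'   `best_params`, `best_error`, `seed`.
#' @export
optimize_pattern <- function(evaluator, n_init = 10L, n_iter = 15L, seed = 0L,
                             restarts = 3L) {
  grid <- pattern_box()
  n_init <- min(n_init, nrow(grid))
  local_seed(derive_seed(seed, 606))
  init_idx <- sample.int(nrow(grid), n_init)

  evaluate <- function(params) {
    val <- tryCatch(evaluator(params), error = function(e) {
      warning("evaluation failed at (d=", params$dot_distance_d, ", s=",
              params$dot_size_s, "): ", conditionMessage(e), call. = FALSE)
      Inf
    })
    if (!is.finite(val)) Inf else as.numeric(val)
  }

  hist_d <- integer(0); hist_s <- integer(0)
  hist_e <- numeric(0); hist_phase <- character(0)
  for (i in init_idx) {
    p <- pattern_params(grid[i, 1], grid[i, 2])
    hist_d <- c(hist_d, p$dot_distance_d); hist_s <- c(hist_s, p$dot_size_s)
    hist_e <- c(hist_e, evaluate(p)); hist_phase <- c(hist_phase, "init")
  }

  for (it in seq_len(n_iter)) {
    evaluated <- cbind(hist_d, hist_s)
    if (nrow(evaluated) >= nrow(grid)) break
    finite <- is.finite(hist_e)
    p_next <- if (sum(finite) >= 2) {
      sur <- fit_surrogate(evaluated[finite, , drop = FALSE], hist_e[finite],
                           restarts = restarts, seed = derive_seed(seed, 700, it))
      tryCatch(propose_next(sur, best_y = min(hist_e[finite]),
                            exclude = evaluated[!finite, , drop = FALSE]),
               error = function(e) NULL)
    } else NULL
    if (is.null(p_next)) {
      # not enough signal yet (or exhausted): fall back to a random unseen point
      key <- paste(grid[, 1], grid[, 2])
      left <- which(!key %in% paste(hist_d, hist_s))
      if (length(left) == 0) break
      local_seed(derive_seed(seed, 800, it))
      i <- left[sample.int(length(left), 1)]
      p_next <- pattern_params(grid[i, 1], grid[i, 2])
    }
    hist_d <- c(hist_d, p_next$dot_distance_d)
    hist_s <- c(hist_s, p_next$dot_size_s)
    hist_e <- c(hist_e, evaluate(p_next))
    hist_phase <- c(hist_phase, "acquisition")
  }

  history <- tibble::tibble(d = hist_d, s = hist_s, error = hist_e,
                            phase = hist_phase, eval = seq_along(hist_e))
  ib <- which.min(hist_e)
  structure(list(history = history,
                 best_params = pattern_params(hist_d[ib], hist_s[ib]),
                 best_error = hist_e[ib], seed = as.integer(seed)),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result> %d evaluations; best (d=%d, s=%d), error %.4f mm\n",
              nrow(x$history), x$best_params$dot_distance_d,
              x$best_params$dot_size_s, x$best_error))
  invisible(x)
}

#' Tidy the optimization history
#' @param x An `opt_result`.
#' @param ... Ignored.
#' @return Tibble with one row per evaluation, including the running
#'   incumbent `best_so_far`.
#' @export
tidy.opt_result <- function(x, ...) {
  dplyr::mutate(x$history, best_so_far = cummin(.data$error))
}

#' One-row summary of an optimization run
#' @param x An `opt_result`.
#' @param ... Ignored.
#' @return One-row tibble: best d, s, error, evaluation counts.
#' @export
glance.opt_result <- function(x, ...) {
  tibble::tibble(best_d = x$best_params$dot_distance_d,
                 best_s = x$best_params$dot_size_s,
                 best_error = x$best_error,
                 n_evals = nrow(x$history),
                 n_init = sum(x$history$phase == "init"),
                 n_failed = sum(!is.finite(x$history$error)),
                 seed = x$seed)
}

#' Plot the optimization trace
#' @param object An `opt_result`.
#' @param ... Ignored.
#' @return A ggplot of error per evaluation and the running best.
#' @export
autoplot.opt_result <- function(object, ...) {
  df <- tidy.opt_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eval)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$error, color = .data$phase),
                        na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_so_far)) +
    ggplot2::labs(x = "evaluation", y = "reconstruction error (mm)",
                  color = NULL)
}
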