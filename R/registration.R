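#' Horn's closed-form absolute orientation
#'
#' Least-squares rigid alignment of two corresponded point sets using the
#' unit-quaternion eigen solution: the rotation maximizing the trace of the
#' cross-covariance is the largest eigenvector of the 4x4 quaternion matrix;
#' translation aligns the centroids. The result is always a proper rotation
#' (det = +1); reflections are never fitted.
#'
#' @param src N x 3 source points (N >= 3, non-collinear), mm.
#' @param dst N x 3 destination points (same count), mm.
#' @return A [rigid_transform()] minimizing `sum |R src + t - dst|^2`, with
#'   attribute `rms` (fiducial registration RMS in mm).
#' @examples
#' src <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' tr <- horn_align(src, src)
#' attr(tr, "rms") # 0
#' @export
horn_align <- function(src, dst) {
  src <- as_points_matrix(src)
  dst <- as_points_matrix(dst)
  if (nrow(src) != nrow(dst)) stop("point count mismatch", call. = FALSE)
  if (nrow(src) < 3) stop("need at least 3 correspondences", call. = FALSE)
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  A <- sweep(src, 2, mu_s)
  B <- sweep(dst, 2, mu_d)
  if (svd(A, nu = 0, nv = 0)$d[2] < 1e-9 * max(1, svd(A, nu = 0, nv = 0)$d[1])) {
    stop("source points are collinear; rotation is not unique", call. = FALSE)
  }
  M <- crossprod(A, B) # sum over points of a_i b_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  eig <- eigen(N, symmetric = TRUE)
  q <- eig$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
  # orthonormalize against rounding
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  t_ <- mu_d - as.numeric(R %*% mu_s)
  tr <- rigid_transform(R, t_)
  resid <- transform_points(tr, src) - dst
  attr(tr, "rms") <- sqrt(mean(rowSums(resid^2)))
  tr
}

#' Nearest-neighbor distances between point clouds
#'
#' Euclidean distance from each query point to its closest reference point.
#' The default uniform-grid spatial index returns exactly the same distances
#' as the brute-force all-pairs scan (`method = "brute"`), which serves as
#' its oracle.
#'
#' @param query A [point_cloud()] or N x 3 matrix.
#' @param reference A non-empty [point_cloud()] or M x 3 matrix.
#' @param method `"grid"` (indexed, default) or `"brute"` (O(N*M)).
#' @return Numeric vector of distances, mm (length N).
#' @export
nearest_neighbor_distances <- function(query, reference,
                                       method = c("grid", "brute")) {
  method <- match.arg(method)
  q <- as_points_matrix(query)
  r <- as_points_matrix(reference)
  if (nrow(r) == 0) stop("reference cloud is empty", call. = FALSE)
  if (nrow(q) == 0) return(numeric(0))
  if (method == "grid") cpp_nn_grid(q, r) else cpp_nn_brute(q, r)
}

#' Localize the fiducial targets in a reconstructed cloud
#'
#' For each marker, the reconstructed points near its predicted top-center
#' are segmented; when the cloud carries intensities the bright marker disc
#' is isolated by thresholding, otherwise all points within the marker's
#' footprint are used (geometric fallback). A plane is fitted to the
#' segment, its normal oriented toward the camera, and the registration
#' target is the disc centroid offset 1 mm along the inward normal (away
#' from the camera, into the holder) — the camera-frame counterpart of the
#' sub-surface targets returned by [fiducial_target_points()].
#'
#' @param cloud Reconstructed [point_cloud()] in the camera frame, ideally
#'   with intensities.
#' @param scene The `phantom_scene` (provides marker geometry priors).
#' @param pose The [rigid_transform()] placing the scene in the camera frame
#'   (the simulation's marker-detection prior).
#' @param search_radius_factor Search ball radius as a multiple of each
#'   marker's half side (default 1.6).
#' @param min_points Minimum segmented points per marker (default 10); fewer
#'   raises an error naming the marker.
#' @return 4 x 3 matrix of camera-frame target estimates (mm), in marker
#'   order.
#' @export
localize_fiducials_3d <- function(cloud, scene, pose = default_scene_pose(),
                                  search_radius_factor = 1.6,
                                  min_points = 10L) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(scene, "phantom_scene"))
  pts <- cloud$points
  out <- matrix(NA_real_, 4, 3)
  for (i in seq_along(scene$fiducials$markers)) {
    m <- scene$fiducials$markers[[i]]
    top_cam <- as.numeric(transform_points(pose, matrix(m$top_center, 1)))
    r <- search_radius_factor * m$half_side
    d2 <- (pts[, 1] - top_cam[1])^2 + (pts[, 2] - top_cam[2])^2 +
      (pts[, 3] - top_cam[3])^2
    sel <- which(d2 <= r^2)
    if (length(sel) >= min_points && !is.null(cloud$intensity)) {
      # the disc is the bright face: threshold between bulk and peak
      ints <- cloud$intensity[sel]
      thr <- 0.5 * (stats::median(ints) + stats::quantile(ints, 0.98, names = FALSE))
      bright <- sel[ints >= thr]
      if (length(bright) >= min_points) sel <- bright
    }
    if (length(sel) < min_points) {
      stop(sprintf("marker %d: only %d reconstructed points (need >= %d)",
                   i, length(sel), min_points), call. = FALSE)
    }
    P <- pts[sel, , drop = FALSE]
    disc_r <- 0.75 * m$half_side + 0.5
    n <- c(0, 0, -1); ctr <- colMeans(P)
    for (pass in 1:3) {
      ctr <- colMeans(P)
      sv <- svd(sweep(P, 2, ctr), nu = 0)
      n <- sv$v[, 3]
      if (pass == 1) {
        # drop gross off-plane outliers (matching artifacts)
        resid <- abs(sweep(P, 2, ctr) %*% n)
        keep <- resid <= pmax(2.5 * stats::mad(resid), 0.5)
        if (sum(keep) >= min_points) P <- P[keep, , drop = FALSE]
      } else if (pass == 2) {
        # recentre in-plane on the disc: drop holder-wall/rim contamination
        centered <- sweep(P, 2, ctr)
        in_plane <- centered - (centered %*% n) %*% t(n)
        keep <- sqrt(rowSums(in_plane^2)) <= disc_r
        if (sum(keep) >= min_points) P <- P[keep, , drop = FALSE]
      }
    }
    if (sum(n * ctr) > 0) n <- -n # orient toward the camera (origin)
    out[i, ] <- ctr - 1.0 * n     # 1 mm into the holder, away from the camera
  }
  out
}

#' Closest-point reconstruction error inside the ROI
#'
#' Applies the registration transform to the reconstruction, crops to the
#' ROI cuboid (defined in the ground-truth frame), draws a seeded random
#' subset of at most `n_samples` points (without replacement, after a
#' canonical lexicographic ordering so the draw is independent of upstream
#' point order), and scores nearest-neighbor distances to the ground-truth
#' cloud. Both the root-mean-square distance (`rmse`, the headline metric)
#' and the mean absolute distance (`mean_abs`) are recorded.
#'
#' @param mire Reconstructed [point_cloud()] in the camera frame.
#' @param ct Ground-truth [point_cloud()] (ground-truth frame).
#' @param transform [rigid_transform()] from camera to ground-truth frame
#'   (e.g. from [horn_align()]).
#' @param roi List with `lower`, `upper` cuboid corners, mm.
#' @param n_samples Subset size (default 5000).
#' @param seed Integer sampling seed.
#' @return An `rmse_result`: rmse, mean_abs (mm), n_samples, n_cropped, seed.
#' @export
reconstruction_error <- function(mire, ct, transform, roi,
                                 n_samples = 5000L, seed = 0L) {
  stopifnot(inherits(mire, "point_cloud"), inherits(ct, "point_cloud"))
  moved <- transform_points(transform, mire$points)
  inside <- moved[, 1] >= roi$lower[1] & moved[, 1] <= roi$upper[1] &
    moved[, 2] >= roi$lower[2] & moved[, 2] <= roi$upper[2] &
    moved[, 3] >= roi$lower[3] & moved[, 3] <= roi$upper[3]
  cropped <- moved[inside, , drop = FALSE]
  n_cropped <- nrow(cropped)
  if (n_cropped == 0) stop("reconstruction missed the ROI", call. = FALSE)
  ord <- order(cropped[, 1], cropped[, 2], cropped[, 3])
  cropped <- cropped[ord, , drop = FALSE]
  n_take <- min(n_samples, n_cropped)
  local_seed(derive_seed(seed, 404))
  take <- sample.int(n_cropped, n_take, replace = FALSE)
  d <- nearest_neighbor_distances(cropped[take, , drop = FALSE], ct$points)
  structure(list(rmse = sqrt(mean(d^2)), mean_abs = mean(d),
                 n_samples = n_take, n_cropped = n_cropped,
                 seed = as.integer(seed)),
            class = "rmse_result")
}

#' @export
print.rmse_result <- function(x, ...) {
  cat(sprintf("<rmse_result> rmse %.4f mm, mean |d| %.4f mm (%d of %d ROI points)\n",
              x$rmse, x$mean_abs, x$n_samples, x$n_cropped))
  invisible(x)
}

#' Z-direction difference heat map
#'
#' Bins both clouds on a common (x, y) grid and reports, per cell, the
#' median reconstructed height minus the median ground-truth height; cells
#' lacking either cloud are masked invalid. Visualizes where depth structure
#' is recovered and where it is missing.
#'
#' @param mire_in_ct Reconstruction transformed into the ground-truth frame.
#' @param ct Ground-truth [point_cloud()].
#' @param grid_mm Cell size in mm (> 0).
#' @return A `z_heatmap`: `values` (signed mm, NA where masked), `mask`
#'   (TRUE = valid), `x_breaks`, `y_breaks`.
#' @export
z_difference_heatmap <- function(mire_in_ct, ct, grid_mm = 1) {
  if (grid_mm <= 0) stop("grid_mm must be positive", call. = FALSE)
  a <- as_points_matrix(mire_in_ct)
  b <- as_points_matrix(ct)
  lo <- pmin(apply(a[, 1:2, drop = FALSE], 2, min), apply(b[, 1:2, drop = FALSE], 2, min))
  hi <- pmax(apply(a[, 1:2, drop = FALSE], 2, max), apply(b[, 1:2, drop = FALSE], 2, max))
  x_breaks <- seq(floor(lo[1]), ceiling(hi[1]) + grid_mm, by = grid_mm)
  y_breaks <- seq(floor(lo[2]), ceiling(hi[2]) + grid_mm, by = grid_mm)
  nx <- length(x_breaks) - 1; ny <- length(y_breaks) - 1
  cell_median <- function(p) {
    ix <- findInterval(p[, 1], x_breaks, rightmost.closed = TRUE)
    iy <- findInterval(p[, 2], y_breaks, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    key <- (ix[ok] - 1) * ny + iy[ok] # column-major index into (ny, nx)
    med <- tapply(p[ok, 3], key, stats::median)
    m <- matrix(NA_real_, ny, nx)
    m[as.integer(names(med))] <- med
    m
  }
  za <- cell_median(a)
  zb <- cell_median(b)
  vals <- za - zb
  structure(list(values = vals, mask = is.finite(vals),
                 x_breaks = x_breaks, y_breaks = y_breaks, grid_mm = grid_mm),
            class = "z_heatmap")
}

#' Plot a Z-difference heat map
#'
#' Diverging color scale symmetric about zero; masked cells are transparent.
#'
#' @param object A `z_heatmap`.
#' @param limit Optional symmetric color limit in mm (default: data-driven).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.z_heatmap <- function(object, limit = NULL, ...) {
  xc <- (object$x_breaks[-1] + object$x_breaks[-length(object$x_breaks)]) / 2
  yc <- (object$y_breaks[-1] + object$y_breaks[-length(object$y_breaks)]) / 2
  df <- tibble::tibble(
    x = rep(xc, each = length(yc)),
    y = rep(yc, times = length(xc)),
    dz = as.vector(object$values)
  )
  limit <- limit %||% max(abs(df$dz), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$dz)) +
    ggplot2::geom_raster(na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  limits = c(-limit, limit), na.value = NA,
                                  name = "dz (mm)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}
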