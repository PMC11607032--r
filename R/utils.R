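# internal helpers: seeded RNG scopes, rotations, small linear algebra

local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
}

# deterministic per-task seed derivation, kept below 2^31
derive_seed <- function(master_seed, ...) {
  idx <- c(...)
  h <- as.double(master_seed) %% 2147483629
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483629
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rodrigues rotation vector (axis * angle, radians) -> 3x3 rotation matrix
rodrigues_to_matrix <- function(om) {
  theta <- sqrt(sum(om^2))
  if (theta < 1e-12) {
    K <- skew3(om)
    return(diag(3) + K) # first-order for tiny angles
  }
  k <- om / theta
  K <- skew3(k)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# 3x3 rotation matrix -> Rodrigues vector
matrix_to_rodrigues <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    # near pi: axis from R + I
    A <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(A), 0))
    # fix signs using off-diagonals
    i <- which.max(axis)
    if (i == 1) {
      axis[2] <- A[1, 2] / axis[1]; axis[3] <- A[1, 3] / axis[1]
    } else if (i == 2) {
      axis[1] <- A[1, 2] / axis[2]; axis[3] <- A[2, 3] / axis[2]
    } else {
      axis[1] <- A[1, 3] / axis[3]; axis[2] <- A[2, 3] / axis[3]
    }
    axis <- axis / sqrt(sum(axis^2))
    return(axis * theta)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  axis * theta
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

# uniformly random unit axis + given angle -> rotation matrix
random_rotation <- function(max_angle_deg) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, -max_angle_deg, max_angle_deg) * pi / 180
  rodrigues_to_matrix(ax * ang)
}

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 proper rotation matrix (det = +1, orthonormal within
#'   1e-9). No scale, no reflection.
#' @param translation Length-3 numeric, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!is_rotation_matrix(rotation, tol = 1e-7)) {
    stop("rotation must be a proper orthonormal 3x3 matrix", call. = FALSE)
  }
  stopifnot(length(translation) == 3)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- sqrt(sum(matrix_to_rodrigues(x$rotation)^2)) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points N x 3 numeric matrix (mm).
#' @return N x 3 matrix of transformed points.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  points <- as_points_matrix(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

# compose: first a, then b  => (b %t% a)(x) = b(a(x))
compose_transforms <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

invert_transform <- function(tr) {
  rigid_transform(t(tr$rotation), -as.numeric(t(tr$rotation) %*% tr$translation))
}

as_points_matrix <- function(points) {
  if (inherits(points, "point_cloud")) points <- points$points
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3)
  points
}
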