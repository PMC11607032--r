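# shared fixtures: ideal parallel test rig, textured plane scenes, and small
# R oracles kept independent of the implementation paths they check

# ideal parallel rig: identical pinholes, pure x baseline, no vergence,
# no distortion -> rectification is exactly the identity
ideal_parallel_rig <- function(f = 800, baseline = 24, width = 320L,
                               height = 240L, zoom = 1) {
  cx <- (width - 1) / 2
  cy <- (height - 1) / 2
  K <- matrix(c(f, 0, 0, 0, f, 0, cx, cy, 1), 3, 3)
  structure(list(
    left = list(K = K, dist = rep(0, 5)),
    right = list(K = K, dist = rep(0, 5)),
    R = diag(3), T = c(-baseline, 0, 0),
    image_size = c(width, height), zoom = zoom,
    config = rig_config("desk", f_base_px = f, baseline_mm = baseline)
  ), class = "stereo_rig")
}

# fronto-parallel plane mesh at depth z spanning the field of view of `rig`;
# x_shift moves the plane so its image keeps full stereo overlap (away from
# the left band where correspondences leave the right frame)
plane_scene <- function(rig, z = 200, margin = 1.4, step = 4, albedo = 0.65,
                        x_shift = 0) {
  half_x <- margin * rig$image_size[1] / 2 / rig$left$K[1, 1] * z
  half_y <- margin * rig$image_size[2] / 2 / rig$left$K[2, 2] * z
  xs <- x_shift + seq(-half_x, half_x, by = step)
  ys <- seq(-half_y, half_y, by = step)
  nx <- length(xs); ny <- length(ys)
  V <- cbind(rep(xs, each = ny), rep(ys, times = nx), 0)
  F <- stereomire:::heightfield_faces(ny, nx)
  list(vertices = V, faces = F, albedo = rep(albedo, nrow(V)), z = z)
}

# identity pose placing a z=0 plane scene at depth z without flipping
plane_pose <- function(z) rigid_transform(diag(3), c(0, 0, z))

# brute-force O(N*M) nearest-neighbor oracle in plain R
nn_oracle <- function(query, ref) {
  vapply(seq_len(nrow(query)), function(i) {
    dx <- ref[, 1] - query[i, 1]
    dy <- ref[, 2] - query[i, 2]
    dz <- ref[, 3] - query[i, 3]
    sqrt(min(dx * dx + dy * dy + dz * dz))
  }, numeric(1))
}

# random proper rotation matrix from a seeded draw
random_rotation_oracle <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, -pi, pi)
  stereomire:::rodrigues_to_matrix(ax * ang)
}

# direct rasterization oracle for the adaptive dot pattern: a pixel at
# 0-based (x, y) is lit iff both coordinates fall in the first s cells of
# their pitch-p period
dot_pattern_oracle <- function(d, s, width, height) {
  p <- d + s
  lit <- 0L
  img <- matrix(0L, height, width)
  for (y in 0:(height - 1)) {
    for (x in 0:(width - 1)) {
      if ((x %% p) < s && (y %% p) < s) {
        img[y + 1, x + 1] <- 255L
        lit <- lit + 1L
      }
    }
  }
  list(pixels = img, lit = lit)
}

# single-path (left-to-right) SGM aggregation oracle in plain R, operating on
# a raw cost volume C[y, x, d]
sgm_single_path_oracle <- function(C, P1, P2) {
  H <- dim(C)[1]; W <- dim(C)[2]; D <- dim(C)[3]
  L <- array(0, dim(C))
  for (y in seq_len(H)) {
    L[y, 1, ] <- C[y, 1, ]
    for (x in 2:W) {
      prev <- L[y, x - 1, ]
      mp <- min(prev)
      for (d in seq_len(D)) {
        cand <- prev[d]
        if (d > 1) cand <- min(cand, prev[d - 1] + P1)
        if (d < D) cand <- min(cand, prev[d + 1] + P1)
        cand <- min(cand, mp + P2)
        L[y, x, d] <- C[y, x, d] + cand - mp
      }
    }
  }
  L
}
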