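#' Stereo rig configuration
#'
#' Describes the zoom-independent geometry of the simulated stereo operating
#' microscope: two verged pinhole cameras over a beam-splitter-style baseline.
#' The left camera defines the rig frame (origin at its center, +z into the
#' scene). The right camera sits `baseline_mm` along +x and is rotated about
#' its y axis to aim at the working point on the left optical axis at
#' `aim_distance_mm`, so the working volume stays centred in both views at
#' every zoom (principal points and the relative pose are zoom-invariant).
#'
#' Two resolution profiles exist: `"full"` is the 2456 x 2054 sensor of the
#' physical cameras; `"desk"` is the quarter-scale 614 x 514 profile used for
#' fast simulation (focal lengths scale with the profile so the field of view
#' is identical).
#'
#' @param profile `"desk"` or `"full"`.
#' @param f_base_px Base focal length at zoom 1.0 for the desk profile
#'   (scaled x4 for full). Default 750 px: the 90 mm phantom fills ~80% of the
#'   desk frame at zoom 1.5 and stays fully visible (with its markers) at all
#'   five default zooms.
#' @param baseline_mm Stereo baseline (default 24).
#' @param aim_distance_mm Vergence working distance (default 200, the 20 cm
#'   objective-to-scene distance).
#' @param distortion Length-5 (k1, k2, p1, p2, k3) applied to both cameras.
#' @return A `rig_config` list.
#' @export
rig_config <- function(profile = c("full", "desk"), f_base_px = 750,
                       baseline_mm = 24, aim_distance_mm = 200,
                       distortion = c(0, 0, 0, 0, 0)) {
  profile <- match.arg(profile)
  scale <- if (profile == "full") 4 else 1
  list(profile = profile,
       image_size = if (profile == "full") c(2456L, 2054L) else c(614L, 514L),
       f_base_px = f_base_px * scale,
       baseline_mm = baseline_mm,
       aim_distance_mm = aim_distance_mm,
       distortion = as.numeric(distortion))
}

#' Build the stereo rig at a zoom level
#'
#' Focal length scales linearly with zoom (`f = f_base * zoom`); principal
#' points and the relative camera pose do not depend on zoom. The five default
#' zoom levels of the simulated microscope are 1.1-1.5 in steps of 0.1.
#'
#' @param zoom Zoom factor (> 0); the default supported range is
#'   \[1.1, 1.5\].
#' @param config A [rig_config()].
#' @return A `stereo_rig`: per-side intrinsics `K` (3x3), `dist` (k1,k2,p1,p2,k3),
#'   relative pose `R`, `T` mapping left-camera coordinates to right-camera
#'   coordinates (baseline = |T|), `image_size`, `zoom`.
#' @examples
#' rig <- make_zoom_rig(1.3, rig_config("desk"))
#' rig$left$K[1, 1] / make_zoom_rig(1.1, rig_config("desk"))$left$K[1, 1] # 1.3/1.1
#' @export
make_zoom_rig <- function(zoom, config = rig_config()) {
  if (zoom <= 0) stop("zoom must be positive", call. = FALSE)
  f <- config$f_base_px * zoom
  w <- config$image_size[1]; h <- config$image_size[2]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  K <- matrix(c(f, 0, 0, 0, f, 0, cx, cy, 1), 3, 3)
  b <- config$baseline_mm
  # right camera center at (b, 0, 0), aimed at (0, 0, aim_distance)
  alpha <- atan2(-b, config$aim_distance_mm)
  R_wr <- rodrigues_to_matrix(c(0, alpha, 0)) # right cam orientation in left frame
  R_rel <- t(R_wr)
  T_rel <- as.numeric(-R_rel %*% c(b, 0, 0))
  structure(list(
    left = list(K = K, dist = config$distortion),
    right = list(K = K, dist = config$distortion),
    R = R_rel, T = T_rel,
    image_size = c(w, h), zoom = zoom, config = config
  ), class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf("<stereo_rig> zoom %.2f, f = %.1f px, %d x %d px, baseline %.2f mm\n",
              x$zoom, x$left$K[1, 1], x$image_size[1], x$image_size[2],
              sqrt(sum(x$T^2))))
  invisible(x)
}

#' Baseline of a stereo rig (mm)
#' @param rig A `stereo_rig`.
#' @return Scalar baseline length.
#' @export
rig_baseline <- function(rig) sqrt(sum(rig$T^2))

# transform rig-frame (left-camera-frame) points into a given side's camera frame
points_to_side <- function(rig, side, points) {
  points <- as_points_matrix(points)
  if (side == "left") points
  else sweep(points %*% t(rig$R), 2, rig$T, "+")
}

# pinhole + radial/tangential distortion projection of camera-frame points
project_camera_frame <- function(K, dist, pts, on_behind = "error") {
  z <- pts[, 3]
  bad <- z <= 1e-9
  if (any(bad)) {
    if (on_behind == "error") {
      stop("point at or behind the camera plane", call. = FALSE)
    }
  }
  x <- pts[, 1] / z; y <- pts[, 2] / z
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  r2 <- x^2 + y^2
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- x * radial + 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
  yd <- y * radial + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  u <- K[1, 1] * xd + K[1, 3]
  v <- K[2, 2] * yd + K[2, 3]
  out <- cbind(u = u, v = v)
  out[bad, ] <- NA
  out
}

#' Project 3-D points through one camera of the rig
#'
#' Full pinhole model with radial (k1, k2, k3) and tangential (p1, p2)
#' distortion. Coordinates are 0-based with pixel centers at integers.
#'
#' @param rig A `stereo_rig`.
#' @param side `"left"` or `"right"`.
#' @param points N x 3 matrix in the rig (left-camera) frame, mm.
#' @param on_behind `"error"` (default) or `"na"`: behaviour for points at or
#'   behind the camera plane.
#' @return N x 2 matrix of pixel coordinates (u, v).
#' @export
project_points <- function(rig, side = c("left", "right"), points,
                           on_behind = c("error", "na")) {
  side <- match.arg(side)
  on_behind <- match.arg(on_behind)
  cam <- rig[[side]]
  pts <- points_to_side(rig, side, points)
  project_camera_frame(cam$K, cam$dist, pts, on_behind = on_behind)
}

#' Pattern projector model
#'
#' A third pinhole device that throws the binary dot pattern onto the scene.
#' By default it sits 40 mm above the left camera (image "up" is -y) and aims
#' at the working point on the left optical axis; its 800 x 600 micromirror
#' panel and focal length are chosen so the projected field covers the phantom
#' at the working distance.
#'
#' @param height_mm Offset above the left camera along -y (default 40).
#' @param aim_distance_mm Working point distance on the left optical axis.
#' @param f_px Projector focal length in projector pixels (default 1450).
#' @param resolution Projector panel size (default c(800, 600)).
#' @return A `projector_model`: `K`, `R`, `T` (left-camera frame -> projector
#'   frame), `resolution`.
#' @export
projector_model <- function(height_mm = 40, aim_distance_mm = 200,
                            f_px = 1450, resolution = c(800L, 600L)) {
  w <- resolution[1]; h <- resolution[2]
  K <- matrix(c(f_px, 0, 0, 0, f_px, 0, (w - 1) / 2, (h - 1) / 2, 1), 3, 3)
  # projector center at (0, -height, 0), aimed at (0, 0, aim_distance)
  beta <- atan2(height_mm, aim_distance_mm)
  R_wp <- rodrigues_to_matrix(c(-beta, 0, 0)) # projector orientation in left frame
  C <- c(0, -height_mm, 0)
  R <- t(R_wp)
  T_ <- as.numeric(-R %*% C)
  structure(list(K = K, R = R, T = T_, resolution = as.integer(resolution)),
            class = "projector_model")
}
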