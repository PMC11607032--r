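#' Illumination configuration for the simulator
#'
#' The four regimes compared in the experiments, mirroring an operating-room
#' setting: diffuse environmental light, the microscope's own coaxial spot
#' (deliberately driven into specular saturation), and two projected-pattern
#' modes (uncontrolled random speckle and the optimized adaptive dot grid).
#' In pattern modes a `pattern_image` is mandatory and the pattern term is
#' applied by projective texturing with a projector-side shadow test.
#'
#' @param mode One of `"environmental"`, `"microscope_spot"`,
#'   `"random_pattern"`, `"adaptive_pattern"`.
#' @param ambient Ambient light level, 8-bit counts.
#' @param spot_direction Unit direction the spot light travels (scene-ward).
#' @param spot_power Diffuse spot strength, counts.
#' @param specular_power Phong specular strength, counts.
#' @param specular_exponent Phong exponent.
#' @param pattern_gain Pattern brightness added on lit surface, counts.
#' @param noise_sigma Additive Gaussian sensor noise sd, counts.
#' @param pattern Optional [generate_dot_pattern()] / [generate_random_pattern()]
#'   image (required in pattern modes).
#' @param projector Optional [projector_model()] (default model used if NULL
#'   in pattern modes).
#' @return An `illumination_config` list.
#' @export
illumination_config <- function(mode = c("environmental", "microscope_spot",
                                         "random_pattern", "adaptive_pattern"),
                                ambient = NULL, spot_direction = NULL,
                                spot_power = NULL, specular_power = NULL,
                                specular_exponent = 40, pattern_gain = NULL,
                                noise_sigma = 2, pattern = NULL,
                                projector = NULL) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    environmental = list(ambient = 110, spot_direction = c(0.25, -0.35, 1),
                         spot_power = 40, specular_power = 0, pattern_gain = 0),
    # spot_power/specular_power chosen so >= 10% of foreground pixels
    # saturate at 255 (the deliberate over-illumination failure mode)
    microscope_spot = list(ambient = 30, spot_direction = c(0, 0, 1),
                           spot_power = 240, specular_power = 140,
                           pattern_gain = 0),
    random_pattern = list(ambient = 60, spot_direction = c(0, 0, 1),
                          spot_power = 0, specular_power = 0,
                          pattern_gain = 150),
    adaptive_pattern = list(ambient = 60, spot_direction = c(0, 0, 1),
                            spot_power = 0, specular_power = 0,
                            pattern_gain = 150)
  )
  is_pattern_mode <- mode %in% c("random_pattern", "adaptive_pattern")
  if (is_pattern_mode) {
    if (is.null(pattern)) stop("mode '", mode, "' requires a pattern", call. = FALSE)
    projector <- projector %||% projector_model()
  } else if (!is.null(pattern)) {
    stop("pattern supplied for non-pattern mode '", mode, "'", call. = FALSE)
  }
  structure(list(
    mode = mode,
    ambient = ambient %||% defaults$ambient,
    spot_direction = spot_direction %||% defaults$spot_direction,
    spot_power = spot_power %||% defaults$spot_power,
    specular_power = specular_power %||% defaults$specular_power,
    specular_exponent = specular_exponent,
    pattern_gain = pattern_gain %||% defaults$pattern_gain,
    noise_sigma = noise_sigma,
    pattern = pattern, projector = projector
  ), class = "illumination_config")
}

#' Default placement of the phantom in front of the microscope
#'
#' The phantom's relief (+z in the ground-truth frame) is turned to face the
#' camera and its base plane is placed at the working distance on the left
#' optical axis.
#'
#' @param working_distance_mm Distance from the left camera to the phantom
#'   base plane (default 200 mm, the 20 cm table-to-objective distance).
#' @return A [rigid_transform()] mapping ground-truth frame to camera frame.
#' @export
default_scene_pose <- function(working_distance_mm = 200) {
  Rx <- diag(c(1, -1, -1)) # 180 deg about x: relief faces the camera
  rigid_transform(Rx, c(0, 0, working_distance_mm))
}

mesh_of <- function(scene) {
  if (inherits(scene, "phantom_scene")) scene$mesh else scene
}

#' Render a monochrome stereo pair of the scene
#'
#' Z-buffer rasterization through both rig cameras, with per-pixel shading
#' (ambient + Lambertian spot + Phong specular), projective pattern texturing
#' with a projector-side shadow map in pattern modes, additive Gaussian sensor
#' noise, and 8-bit quantization. Ground-truth depth maps (z of the nearest
#' surface, 0 for background) are returned alongside.
#'
#' @param scene A `phantom_scene` or a bare mesh list (vertices, faces, albedo).
#' @param rig A [make_zoom_rig()] rig.
#' @param illum An [illumination_config()].
#' @param seed Integer seed governing sensor noise only.
#' @param pose [rigid_transform()] ground-truth -> left-camera frame
#'   (default [default_scene_pose()]).
#' @return List `left`, `right` (integer matrices, 0-255), `left_depth`,
#'   `right_depth` (mm, 0 = background).
#' @export
render_stereo_pair <- function(scene, rig, illum, seed = 0L,
                               pose = default_scene_pose()) {
  stopifnot(inherits(rig, "stereo_rig"), inherits(illum, "illumination_config"))
  mesh <- mesh_of(scene)
  V_cam <- transform_points(pose, mesh$vertices)
  F <- mesh$faces
  albedo <- mesh$albedo %||% rep(0.65, nrow(V_cam))

  is_pattern_mode <- illum$mode %in% c("random_pattern", "adaptive_pattern")
  pattern <- NULL; proj <- NULL; proj_depth <- NULL
  if (is_pattern_mode) {
    if (is.null(illum$pattern)) stop("missing pattern for pattern mode", call. = FALSE)
    pattern <- illum$pattern$pixels
    proj <- illum$projector
    V_proj <- sweep(V_cam %*% t(proj$R), 2, proj$T, "+")
    proj_depth <- cpp_render(V_proj, F, albedo,
                             proj$K[1, 1], proj$K[2, 2], proj$K[1, 3], proj$K[2, 3],
                             proj$resolution[1], proj$resolution[2],
                             list(ambient = 0, spot_power = 0,
                                  spot_direction = c(0, 0, 1), specular_power = 0,
                                  specular_exponent = 1, pattern_gain = 0),
                             NULL, NULL, NULL, TRUE)$depth
  }
  shading <- list(ambient = illum$ambient, spot_power = illum$spot_power,
                  spot_direction = illum$spot_direction,
                  specular_power = illum$specular_power,
                  specular_exponent = illum$specular_exponent,
                  pattern_gain = illum$pattern_gain)

  render_one <- function(V_side, proj_side) {
    cpp_render(V_side, F, albedo,
               rig$left$K[1, 1], rig$left$K[2, 2], rig$left$K[1, 3], rig$left$K[2, 3],
               rig$image_size[1], rig$image_size[2], shading,
               if (is_pattern_mode) pattern else NULL,
               proj_side, proj_depth, FALSE)
  }

  left_raw <- render_one(V_cam, if (is_pattern_mode) {
    list(K = proj$K, R = proj$R, T = proj$T)
  } else NULL)

  V_right <- sweep(V_cam %*% t(rig$R), 2, rig$T, "+")
  proj_right <- NULL
  if (is_pattern_mode) {
    # projector pose relative to the right camera frame
    Rr <- proj$R %*% t(rig$R)
    Tr <- proj$T - as.numeric(Rr %*% rig$T)
    proj_right <- list(K = proj$K, R = Rr, T = Tr)
  }
  right_raw <- render_one(V_right, proj_right)

  quantize <- function(img, seed_k) {
    if (illum$noise_sigma > 0) {
      local_seed(seed_k)
      img <- img + matrix(stats::rnorm(length(img), 0, illum$noise_sigma),
                          nrow(img), ncol(img))
    }
    # epsilon absorbs float jitter in shading sums straddling half-integers,
    # keeping noiseless renders exactly piecewise-constant
    matrix(as.integer(pmin(255, pmax(0, round(img + 1e-6)))),
           nrow(img), ncol(img))
  }
  list(left = quantize(left_raw$image, derive_seed(seed, 1)),
       right = quantize(right_raw$image, derive_seed(seed, 2)),
       left_depth = left_raw$depth,
       right_depth = right_raw$depth)
}

#' Checkerboard specification
#'
#' @param inner_corners Inner-corner grid, columns x rows (default 9 x 5).
#' @param square_mm Square side length in mm (default 3).
#' @return A `board_spec` with the board-frame corner coordinates (z = 0,
#'   centered on the board origin).
#' @export
board_spec <- function(inner_corners = c(9L, 5L), square_mm = 3) {
  nx <- inner_corners[1]; ny <- inner_corners[2]
  xs <- (seq_len(nx) - (nx + 1) / 2) * square_mm
  ys <- (seq_len(ny) - (ny + 1) / 2) * square_mm
  corners <- cbind(x = rep(xs, times = ny), y = rep(ys, each = nx), z = 0)
  structure(list(inner_corners = as.integer(inner_corners),
                 square_mm = square_mm, corners = corners),
            class = "board_spec")
}

#' Generate synthetic calibration observations
#'
#' Draws board poses with tilt uniform in \[-60, +60\] degrees about random
#' axes and translations that keep every corner visible in both views, then
#' records the exact projections of the inner corners through both cameras
#' plus Gaussian corner noise. This isolates the calibration math from corner
#' detection quality; 19 pose pairs per zoom is the default protocol.
#'
#' @param rig A `stereo_rig`.
#' @param board A [board_spec()].
#' @param n_poses Number of board poses (>= 3; default 19).
#' @param seed Integer seed for poses and corner noise.
#' @param corner_noise_px Corner noise sd in pixels.
#' @return A `calibration_set`: list of poses, each with `left`, `right`
#'   (N x 2 pixel corners), `board` (N x 3 board-frame mm), and the true pose
#'   `R`, `T` (board -> left camera) kept for diagnostics.
#' @export
render_calibration_set <- function(rig, board = board_spec(), n_poses = 19L,
                                   seed = 0L, corner_noise_px = 0) {
  stopifnot(inherits(rig, "stereo_rig"))
  if (n_poses < 3) stop("need at least 3 poses", call. = FALSE)
  local_seed(derive_seed(seed, 303))
  wd <- rig$config$aim_distance_mm
  margin <- 5
  w <- rig$image_size[1]; h <- rig$image_size[2]
  poses <- vector("list", n_poses)
  k <- 0L; attempts <- 0L
  while (k < n_poses) {
    attempts <- attempts + 1L
    if (attempts > 300L * n_poses) {
      stop("could not place the board inside both camera frusta", call. = FALSE)
    }
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, -60, 60) * pi / 180
    R <- rodrigues_to_matrix(ax * ang)
    # spread board centers over the shared field of view
    z <- stats::runif(1, 0.88 * wd, 1.12 * wd)
    half_x <- 0.30 * w / rig$left$K[1, 1] * z
    half_y <- 0.30 * h / rig$left$K[2, 2] * z
    centre <- c(stats::runif(1, -half_x, half_x),
                stats::runif(1, -half_y, half_y), z)
    pts <- sweep(board$corners %*% t(R), 2, centre, "+")
    uv_l <- project_points(rig, "left", pts, on_behind = "na")
    uv_r <- project_points(rig, "right", pts, on_behind = "na")
    ok <- function(uv) {
      all(is.finite(uv)) &&
        all(uv[, 1] >= margin & uv[, 1] <= w - 1 - margin &
              uv[, 2] >= margin & uv[, 2] <= h - 1 - margin)
    }
    if (!ok(uv_l) || !ok(uv_r)) next
    k <- k + 1L
    if (corner_noise_px > 0) {
      uv_l <- uv_l + matrix(stats::rnorm(length(uv_l), 0, corner_noise_px),
                            ncol = 2)
      uv_r <- uv_r + matrix(stats::rnorm(length(uv_r), 0, corner_noise_px),
                            ncol = 2)
    }
    poses[[k]] <- list(left = uv_l, right = uv_r, board = board$corners,
                       R = R, T = centre)
  }
  structure(list(poses = poses, board = board, image_size = rig$image_size,
                 corner_noise_px = corner_noise_px),
            class = "calibration_set")
}
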