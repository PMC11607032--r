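test_that("zoom scales focal length linearly and leaves the rest invariant", {
  cfg <- rig_config("desk")
  r15 <- make_zoom_rig(1.5, cfg)
  r11 <- make_zoom_rig(1.1, cfg)
  expect_equal(r15$left$K[1, 1] / r11$left$K[1, 1], 1.5 / 1.1, tolerance = 1e-12)
  expect_equal(r15$left$K[1, 3], r11$left$K[1, 3])
  expect_equal(r15$R, r11$R)
  expect_equal(r15$T, r11$T)
  expect_error(make_zoom_rig(0, cfg), "zoom")
  # resolution profiles
  expect_identical(make_zoom_rig(1.3, rig_config("full"))$image_size,
                   c(2456L, 2054L))
  expect_identical(make_zoom_rig(1.3, rig_config("desk"))$image_size,
                   c(614L, 514L))
  # both cameras see the working point at the image center at all 5 zooms
  for (z in c(1.1, 1.2, 1.3, 1.4, 1.5)) {
    rig <- make_zoom_rig(z, cfg)
    aim <- matrix(c(0, 0, cfg$aim_distance_mm), 1)
    expect_equal(as.numeric(project_points(rig, "left", aim)),
                 c(rig$left$K[1, 3], rig$left$K[2, 3]), tolerance = 1e-9)
    expect_equal(as.numeric(project_points(rig, "right", aim)),
                 c(rig$right$K[1, 3], rig$right$K[2, 3]), tolerance = 1e-9)
  }
})

test_that("projection follows the closed-form pinhole with and without distortion", {
  rig <- ideal_parallel_rig(f = 800)
  K <- rig$left$K
  # axis point lands on the principal point at any depth
  for (z in c(50, 200, 1000)) {
    expect_equal(as.numeric(project_points(rig, "left", c(0, 0, z))),
                 c(K[1, 3], K[2, 3]), tolerance = 1e-12)
  }
  # off-axis point: x = cx + f X / Z
  expect_equal(as.numeric(project_points(rig, "left", c(10, 0, 200)))[1],
               K[1, 3] + 800 * 10 / 200, tolerance = 1e-12)
  # behind-camera handling
  expect_error(project_points(rig, "left", c(0, 0, -5)), "behind")
  expect_true(all(is.na(project_points(rig, "left", c(0, 0, -5), on_behind = "na"))))
  # radial distortion bends off-axis points by the polynomial factor
  rig$left$dist <- c(-0.1, 0.02, 0, 0, 0)
  pt <- c(30, -20, 150)
  x <- pt[1] / pt[3]; y <- pt[2] / pt[3]; r2 <- x^2 + y^2
  rad <- 1 - 0.1 * r2 + 0.02 * r2^2
  expect_equal(as.numeric(project_points(rig, "left", pt)),
               c(K[1, 3] + 800 * x * rad, K[2, 3] + 800 * y * rad),
               tolerance = 1e-12)
})

test_that("ambient-only rendering of a flat uniform scene is flat shaded", {
  rig <- ideal_parallel_rig(f = 600, width = 160L, height = 120L)
  sc <- plane_scene(rig, z = 200)
  illum <- illumination_config("environmental", ambient = 100, spot_power = 0,
                               noise_sigma = 0)
  pair <- render_stereo_pair(sc, rig, illum, seed = 0, pose = plane_pose(200))
  fg <- pair$left_depth > 0
  expect_true(all(fg)) # plane covers the full frame
  expect_length(unique(as.vector(pair$left[fg])), 1L)
  expect_equal(unique(as.vector(pair$left[fg])), round(0.65 * 100))
  # true depth equals the plane depth
  expect_equal(max(abs(pair$left_depth[fg] - 200)), 0, tolerance = 1e-9)
})

test_that("rendering is deterministic and independent of face order", {
  rig <- make_zoom_rig(1.3, rig_config("desk"))
  sc <- generate_phantom(0, 1)
  illum <- illumination_config("microscope_spot", noise_sigma = 2)
  a <- render_stereo_pair(sc, rig, illum, seed = 5)
  b <- render_stereo_pair(sc, rig, illum, seed = 5)
  expect_identical(a$left, b$left)
  expect_identical(a$right, b$right)
  # permute faces: images must be bit-identical (z-buffer correctness)
  sc2 <- sc
  perm <- rev(seq_len(nrow(sc$mesh$faces)))
  sc2$mesh$faces <- sc$mesh$faces[perm, , drop = FALSE]
  c_ <- render_stereo_pair(sc2, rig, illum, seed = 5)
  expect_identical(a$left, c_$left)
  expect_identical(a$right, c_$right)
  # a different noise seed changes the image
  d <- render_stereo_pair(sc, rig, illum, seed = 6)
  expect_gt(sum(d$left != a$left), 0)
})

test_that("noiseless pattern rendering of a fronto-parallel plane is bimodal", {
  rig <- ideal_parallel_rig(f = 600, width = 160L, height = 120L)
  sc <- plane_scene(rig, z = 200)
  pat <- generate_dot_pattern(pattern_params(4, 8))
  illum <- illumination_config("adaptive_pattern", pattern = pat,
                               noise_sigma = 0)
  pair <- render_stereo_pair(sc, rig, illum, seed = 0, pose = plane_pose(200))
  fg <- pair$left_depth > 0
  vals <- sort(unique(as.vector(pair$left[fg])))
  expect_length(vals, 2L) # lit vs unlit by the projected pattern
  expect_equal(vals[1], round(0.65 * 60))
  expect_equal(vals[2], round(0.65 * (60 + 150) + 1e-6))
})

test_that("pattern contribution is shadowed where the projector is occluded", {
  rig <- ideal_parallel_rig(f = 600, width = 160L, height = 120L)
  # two-plane occluder: small near plane floating above a large far plane,
  # offset so it blocks the (elevated) projector for part of the far plane
  far <- plane_scene(rig, z = 220, margin = 1.6, step = 4)
  near_half <- 12
  xs <- seq(-near_half, near_half, by = 4)
  ny <- length(xs)
  Vn <- cbind(rep(xs, each = ny), rep(xs - 20, times = ny), -70) # z=150 after pose
  Fn <- stereomire:::heightfield_faces(ny, ny)
  mesh <- list(vertices = rbind(far$vertices, Vn),
               faces = rbind(far$faces, Fn + nrow(far$vertices)),
               albedo = rep(0.65, nrow(far$vertices) + nrow(Vn)))
  illum <- illumination_config("adaptive_pattern",
                               pattern = generate_dot_pattern(pattern_params(2, 6)),
                               noise_sigma = 0)
  pair <- render_stereo_pair(mesh, rig, illum, seed = 0, pose = plane_pose(220))
  img <- pair$left; dep <- pair$left_depth
  lit_val <- round(0.65 * (60 + 150) + 1e-6)
  far_px <- abs(dep - 220) < 1e-6
  # projector sits above (-y); rays grazing the occluder's lower edge
  # (y = -8 at z = 150) land at y ~ +6.9 on the far plane, i.e. the umbra
  # covers the far-plane rows just below the occluder's image (v ~ 28..78);
  # probe its central part
  shadow_band <- far_px & row(img) >= 36 & row(img) <= 68 &
    col(img) >= 50 & col(img) <= 110
  expect_gt(sum(shadow_band), 200)
  expect_true(all(img[shadow_band] < lit_val))
  # far-plane pixels well below the umbra do show lit dots
  open_band <- far_px & row(img) >= 95
  expect_true(any(img[open_band] == lit_val))
})

test_that("rendered depth agrees with analytic projection at vertices", {
  rig <- ideal_parallel_rig(f = 500, width = 200L, height = 160L)
  # gently tilted 10-vertex plane strip: z = 205 + 0.2 x (slope keeps the
  # per-pixel depth footprint ~0.16 mm)
  xs <- seq(-20, 20, length.out = 5)
  V <- cbind(rep(xs, each = 3), rep(c(-10, 0, 10), times = 5),
             205 + 0.2 * rep(xs, each = 3))
  F <- stereomire:::heightfield_faces(3, 5)
  mesh <- list(vertices = V, faces = F, albedo = rep(0.65, nrow(V)))
  illum <- illumination_config("environmental", ambient = 150, spot_power = 0,
                               noise_sigma = 0)
  pair <- render_stereo_pair(mesh, rig, illum, seed = 0,
                             pose = rigid_transform(diag(3), c(0, 0, 0)))
  uv <- project_points(rig, "left", V)
  ok <- 0L
  for (i in which(V[, 2] == 0)) { # interior (middle-row) vertices only
    px <- round(uv[i, 1]) + 1L; py <- round(uv[i, 2]) + 1L
    if (px < 1 || py < 1 || px > 200 || py > 160) next
    z <- pair$left_depth[py, px]
    if (z > 0) {
      expect_equal(z, V[i, 3], tolerance = 0.5 / V[i, 3])
      ok <- ok + 1L
    }
  }
  expect_gt(ok, 3)
})

test_that("calibration target generator follows the acquisition protocol", {
  rig <- make_zoom_rig(1.3, rig_config("desk"))
  b <- board_spec()
  expect_identical(nrow(b$corners), 45L) # 9 x 5 inner corners
  expect_equal(diff(sort(unique(b$corners[, 1]))), rep(3, 8)) # 3 mm squares
  set <- render_calibration_set(rig, b, n_poses = 19, seed = 0,
                                corner_noise_px = 0)
  expect_length(set$poses, 19L)
  w <- rig$image_size[1]; h <- rig$image_size[2]
  for (ps in set$poses) {
    expect_identical(nrow(ps$left), 45L)
    expect_identical(nrow(ps$right), 45L)
    # all corners visible in both views
    for (uv in list(ps$left, ps$right)) {
      expect_true(all(uv[, 1] >= 0 & uv[, 1] <= w - 1 &
                        uv[, 2] >= 0 & uv[, 2] <= h - 1))
    }
    # noiseless corners equal exact projections
    pts <- sweep(ps$board %*% t(ps$R), 2, ps$T, "+")
    expect_equal(ps$left, project_points(rig, "left", pts), tolerance = 1e-9)
    expect_equal(ps$right, project_points(rig, "right", pts), tolerance = 1e-9)
    # tilt stays within the 60 degree protocol bound
    ang <- sqrt(sum(stereomire:::matrix_to_rodrigues(ps$R)^2)) * 180 / pi
    expect_lte(ang, 60 + 1e-9)
  }
  expect_error(render_calibration_set(rig, b, n_poses = 2, seed = 0), "3 poses")
})

test_that("epipolar rows agree after perfect rectification of the true rig", {
  rig <- make_zoom_rig(1.2, rig_config("desk"))
  entry <- calibration_entry_from_rig(rig)
  set.seed(11)
  X <- cbind(runif(50, -30, 30), runif(50, -15, 15), runif(50, 180, 220))
  # rectified projections through P1 (left) and P2 (right)
  Xl <- X %*% t(entry$R1)
  Xr <- sweep(X %*% t(rig$R), 2, rig$T, "+") %*% t(entry$R2)
  vl <- entry$f_rect * Xl[, 2] / Xl[, 3] + entry$c_rect[2]
  vr <- entry$f_rect * Xr[, 2] / Xr[, 3] + entry$c_rect[2]
  expect_lt(max(abs(vl - vr)), 0.1)
  # and disparity follows f * B / z (shifted by the vergence cx offset)
  ul <- entry$f_rect * Xl[, 1] / Xl[, 3] + entry$c_rect[1]
  ur <- entry$f_rect * Xr[, 1] / Xr[, 3] + entry$cx2_rect
  expect_equal(ul - ur, entry$f_rect * entry$baseline / Xl[, 3] + entry$dcx,
               tolerance = 1e-9)
})
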