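test_that("sgbm parameter validation enforces the protocol constraints", {
  expect_identical(sgbm_params()$block_size, 3L) # fixed protocol value
  expect_error(sgbm_params(block_size = 4), "odd")
  expect_error(sgbm_params(num_disparities = 24), "multiple of 16")
  expect_error(sgbm_params(p1 = 10, p2 = 10), "p2 > p1")
  expect_error(sgbm_params(n_paths = 6), "4 or 8")
  # negative minimum disparity is allowed (verged rigs)
  expect_identical(sgbm_params(min_disparity = -32)$min_disparity, -32L)
})

test_that("identical rectified images yield zero disparity on textured pixels", {
  withr::with_seed(5, {
    img <- matrix(sample(0:255, 120 * 90, replace = TRUE), 90, 120)
  })
  disp <- compute_disparity(img, img,
                            sgbm_params(min_disparity = 0, num_disparities = 16,
                                        speckle_window = 0))
  vals <- disp$values[is.finite(disp$values)]
  expect_gt(length(vals), 5000)
  expect_true(all(vals == 0))
  expect_error(compute_disparity(img, img[1:45, ],
                                 sgbm_params(num_disparities = 16)), "mismatch")
})

test_that("disparity on a rendered fronto-parallel plane matches f*B/Z", {
  rig <- ideal_parallel_rig(f = 800, baseline = 24, width = 320L, height = 240L)
  z <- 200
  sc <- plane_scene(rig, z = z, margin = 0.55, step = 2, x_shift = 15)
  illum <- illumination_config("random_pattern", noise_sigma = 0,
                               pattern = generate_random_pattern(density = 0.25,
                                                                 seed = 2))
  pair <- render_stereo_pair(sc, rig, illum, seed = 0, pose = plane_pose(z))
  entry <- calibration_entry_from_rig(rig)
  d_true <- 800 * 24 / z # 96 px
  disp <- compute_disparity(pair$left, pair$right,
                            sgbm_params(min_disparity = 80,
                                        num_disparities = 32, n_paths = 8),
                            entry = entry)
  vals <- disp$values[is.finite(disp$values)]
  expect_gt(length(vals), 1000)
  expect_gte(mean(abs(vals - d_true) <= 0.5), 0.95)
})

test_that("reprojection through Q inverts an exact synthetic disparity", {
  rig <- ideal_parallel_rig(f = 800, baseline = 24, width = 64L, height = 48L)
  entry <- calibration_entry_from_rig(rig)
  z <- 150
  d <- entry$f_rect * entry$baseline / z
  disp <- structure(list(
    values = matrix(d, 48, 64), entry = entry,
    params = sgbm_params(min_disparity = 96, num_disparities = 48),
    valid_fraction = 1), class = "disparity_map")
  cloud <- disparity_to_cloud(disp, entry)
  expect_identical(n_points(cloud), 64L * 48L)
  expect_lt(max(abs(cloud$points[, 3] - z)), 1e-6)
  # round trip through the projection oracle: each point lands on its pixel
  uv <- project_points(rig, "left", cloud$points)
  h <- 48
  idx <- seq_len(n_points(cloud))
  v <- (idx - 1) %% h
  u <- (idx - 1) %/% h
  expect_lt(max(abs(uv[, 1] - u)), 0.5)
  expect_lt(max(abs(uv[, 2] - v)), 0.5)
  # all-invalid map gives an empty cloud, not an error
  disp$values[] <- NA_real_
  empty <- disparity_to_cloud(disp, entry)
  expect_identical(n_points(empty), 0L)
  # mismatched entry is rejected
  other <- calibration_entry_from_rig(ideal_parallel_rig(f = 900, width = 64L,
                                                         height = 48L))
  expect_error(disparity_to_cloud(disp, other), "does not match")
})

test_that("full reconstruction of a noiseless patterned plane is sub-0.1 mm", {
  rig <- ideal_parallel_rig(f = 800, baseline = 24, width = 320L, height = 240L)
  z <- 200
  # keep the plane inside the fully-overlapping stereo region
  sc <- plane_scene(rig, z = z, margin = 0.55, step = 2, x_shift = 15)
  pat <- generate_dot_pattern(pattern_params(3, 4))
  illum <- illumination_config("adaptive_pattern", pattern = pat,
                               noise_sigma = 0)
  pair <- render_stereo_pair(sc, rig, illum, seed = 0, pose = plane_pose(z))
  entry <- calibration_entry_from_rig(rig)
  cloud <- reconstruct_mire(pair$left, pair$right, entry,
                            sgbm_params(min_disparity = 80,
                                        num_disparities = 32, n_paths = 8))
  expect_gt(n_points(cloud), 1000)
  # distance to the true plane z = 200
  rms <- sqrt(mean((cloud$points[, 3] - z)^2))
  expect_lte(rms, 0.1)
  # determinism of the full chain
  cloud2 <- reconstruct_mire(pair$left, pair$right, entry,
                             sgbm_params(min_disparity = 80,
                                         num_disparities = 32, n_paths = 8))
  expect_identical(cloud$points, cloud2$points)
})

test_that("a uniform untextured surface is an (expected) matching failure", {
  rig <- ideal_parallel_rig(f = 800, baseline = 24, width = 320L, height = 240L)
  sc <- plane_scene(rig, z = 200)
  illum <- illumination_config("environmental", spot_power = 0, noise_sigma = 2)
  pair <- render_stereo_pair(sc, rig, illum, seed = 3, pose = plane_pose(200))
  entry <- calibration_entry_from_rig(rig)
  cloud <- reconstruct_mire(pair$left, pair$right, entry,
                            sgbm_params(min_disparity = 80,
                                        num_disparities = 32, n_paths = 4))
  expect_lt(attr(cloud, "valid_fraction"), 0.20)
})

test_that("texture benefit: patterned illumination yields more valid pixels", {
  # paired comparison on the default phantom at one zoom over several seeds
  rig <- make_zoom_rig(1.3, rig_config("desk"))
  sc <- generate_phantom(0, 1)
  entry <- calibration_entry_from_rig(rig)
  rng <- disparity_range(entry, 165, 235)
  sp <- sgbm_params(min_disparity = rng$min_disparity,
                    num_disparities = rng$num_disparities, n_paths = 4)
  pat <- generate_dot_pattern(pattern_params(3, 4))
  vf <- function(illum, seed) {
    pair <- render_stereo_pair(sc, rig, illum, seed = seed)
    attr(reconstruct_mire(pair$left, pair$right, entry, sp), "valid_fraction")
  }
  seeds <- 0:4 # scaled down from 0:9 to stay inside the test-time budget
  vf_adaptive <- vapply(seeds, function(s) {
    vf(illumination_config("adaptive_pattern", pattern = pat), s)
  }, numeric(1))
  vf_env <- vapply(seeds, function(s) {
    vf(illumination_config("environmental"), s)
  }, numeric(1))
  expect_gte(mean(vf_adaptive), mean(vf_env))
})

test_that("aggregated SGM costs match a single-path dynamic-programming oracle", {
  withr::with_seed(9, {
    L <- matrix(sample(0:255, 40 * 24, replace = TRUE), 24, 40)
  })
  # right image = left shifted by 3 px (wrap borders clamped by the matcher)
  R <- cbind(L[, 4:40], L[, 37:39])
  params <- sgbm_params(min_disparity = 0, num_disparities = 16,
                        block_size = 3, n_paths = 4, lr_check_tol = -1,
                        uniqueness_ratio = 0, texture_threshold = 0,
                        speckle_window = 0)
  res <- compute_disparity(L, R, params, return_cost = TRUE)
  # energy sanity: the winner-take-all labeling never exceeds the energy of
  # the constant all-zero-disparity labeling under the aggregated cost
  S <- res$cost
  h <- dim(S)[1]; w <- dim(S)[2]
  lab <- round(res$values) + 1
  lab[!is.finite(lab)] <- 1
  e_wta <- sum(vapply(seq_len(h), function(y) {
    sum(S[cbind(y, seq_len(w), lab[y, ])])
  }, numeric(1)))
  e_const <- sum(S[, , 1])
  expect_lte(e_wta, e_const)

  # single-path aggregation equals the R dynamic-programming oracle exactly
  p1 <- sgbm_params(min_disparity = 0, num_disparities = 16, block_size = 1,
                    p1 = 8L, p2 = 32L, n_paths = 4, lr_check_tol = -1,
                    uniqueness_ratio = 0, texture_threshold = 0,
                    speckle_window = 0)
  crop_l <- L[1:12, 1:20]; crop_r <- R[1:12, 1:20]
  # raw block cost for block 1 is |L - R(shifted)| with clamped borders
  C <- array(0, c(12, 20, 16))
  for (d in 0:15) {
    for (x in 1:20) {
      xr <- x - d
      C[, x, d + 1] <- if (xr >= 1) abs(crop_l[, x] - crop_r[, xr]) else 255
    }
  }
  oracle_L <- sgm_single_path_oracle(C, 8, 32)
  # compare against the compiled path by running with only the left-to-right
  # direction: emulate by a 1-path call through the internal interface
  res1 <- stereomire:::cpp_sgbm(crop_l, crop_r, 0L, 16L, 1L, 8L, 32L, 1L,
                                -1, 0L, 0L, 0L, 1, TRUE)
  expect_equal(as.numeric(res1$cost), as.numeric(oracle_L), tolerance = 0)
})
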