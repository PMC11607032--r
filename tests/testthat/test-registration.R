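test_that("horn alignment is exact on constructed rigid transforms", {
  src <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0), c(0, 0, 6))
  # identity
  tr <- horn_align(src, src)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(attr(tr, "rms"), 0, tolerance = 1e-12)
  # random proper transforms recovered to 1e-9
  withr::with_seed(21, {
    for (k in 1:10) {
      R0 <- random_rotation_oracle()
      t0 <- runif(3, -50, 50)
      dst <- sweep(src %*% t(R0), 2, t0, "+")
      tr <- horn_align(src, dst)
      expect_lt(max(abs(tr$rotation - R0)), 1e-9)
      expect_lt(max(abs(tr$translation - t0)), 1e-9)
      expect_lt(attr(tr, "rms"), 1e-9)
    }
  })
})

test_that("horn alignment never fits a reflection and rejects degenerate input", {
  src <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0), c(0, 0, 6))
  dst <- src %*% diag(c(-1, 1, 1)) # reflected set
  tr <- horn_align(src, dst)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  expect_gt(attr(tr, "rms"), 0.5)
  # collinear source
  line <- cbind(1:4, 2 * (1:4), -1 * (1:4))
  expect_error(horn_align(line, line), "collinear")
  expect_error(horn_align(src[1:3, ], src), "mismatch")
  expect_error(horn_align(src[1:2, ], src[1:2, ]), "at least 3")
})

test_that("horn alignment is left-invariant under a common rotation", {
  withr::with_seed(31, {
    src <- matrix(runif(12, -20, 20), 4, 3)
    R0 <- random_rotation_oracle()
    t0 <- runif(3, -10, 10)
    dst <- sweep(src %*% t(R0), 2, t0, "+") + matrix(rnorm(12, 0, 0.1), 4, 3)
    base <- attr(horn_align(src, dst), "rms")
    for (k in 1:5) {
      Rc <- random_rotation_oracle()
      rms_k <- attr(horn_align(src %*% t(Rc), dst %*% t(Rc)), "rms")
      expect_equal(rms_k, base, tolerance = 1e-9)
    }
  })
})

test_that("nearest-neighbor distances: closed forms and index-vs-brute equality", {
  expect_equal(nearest_neighbor_distances(matrix(c(3, 4, 0), 1),
                                          matrix(c(0, 0, 0), 1)), 5)
  q <- matrix(runif(60, -5, 5), 20, 3)
  expect_equal(nearest_neighbor_distances(q, q), rep(0, 20))
  expect_error(nearest_neighbor_distances(q, matrix(numeric(0), 0, 3)), "empty")
  withr::with_seed(41, {
    query <- matrix(rnorm(300 * 3, sd = 10), 300, 3)
    ref <- matrix(rnorm(200 * 3, sd = 10), 200, 3)
  })
  d_grid <- nearest_neighbor_distances(query, ref, method = "grid")
  d_brut <- nearest_neighbor_distances(query, ref, method = "brute")
  expect_identical(d_grid, d_brut) # bit-exact
  expect_equal(d_brut, nn_oracle(query, ref), tolerance = 1e-12)
  # clustered + outlier geometry exercises the ring search bound
  withr::with_seed(42, {
    ref2 <- rbind(matrix(rnorm(300, sd = 0.1), 100, 3),
                  matrix(rnorm(300, sd = 0.1) + 50, 100, 3))
    query2 <- rbind(matrix(rnorm(150, sd = 30), 50, 3), ref2[7, , drop = FALSE])
  })
  expect_identical(nearest_neighbor_distances(query2, ref2, "grid"),
                   nearest_neighbor_distances(query2, ref2, "brute"))
})

test_that("reconstruction error follows the crop-sort-sample-score contract", {
  sc <- generate_phantom(0, 1)
  gt <- sample_ground_truth_cloud(sc, 30000, seed = 0)
  idt <- rigid_transform(diag(3), c(0, 0, 0))
  # mire == ct inside an all-covering roi -> rmse 0
  roi_all <- list(lower = c(-100, -100, -100), upper = c(100, 100, 100))
  same <- point_cloud(gt$points, frame = "camera")
  r0 <- reconstruction_error(same, gt, idt, roi_all, seed = 1)
  expect_equal(r0$rmse, 0)
  expect_equal(r0$mean_abs, 0)
  expect_identical(r0$n_samples, 5000L) # default subset size
  expect_identical(r0$n_cropped, 30000L)

  # dense plane vs 0.3 mm z-shifted copy -> rmse ~ 0.3
  withr::with_seed(7, {
    plane <- cbind(runif(120000, -20, 20), runif(120000, -20, 20), 0)
  })
  ct <- point_cloud(plane, frame = "ground_truth")
  mire_xy <- plane[seq_len(20000), 1:2] +
    matrix(runif(40000, -0.5, 0.5), ncol = 2)
  mire <- point_cloud(cbind(mire_xy, 0.3), frame = "camera")
  r3 <- reconstruction_error(mire, ct, idt, roi_all, seed = 2)
  expect_equal(r3$rmse, 0.3, tolerance = 0.05)
  expect_gte(r3$rmse, r3$mean_abs) # Jensen
  # empty crop errors
  roi_far <- list(lower = c(500, 500, 500), upper = c(600, 600, 600))
  expect_error(reconstruction_error(mire, ct, idt, roi_far, seed = 0),
               "missed the ROI")
})

test_that("the seeded subset is invariant to point order and rmse >= mean_abs", {
  withr::with_seed(8, {
    pts <- matrix(runif(9000, -10, 10), 3000, 3)
    ref <- matrix(runif(3000, -10, 10), 1000, 3)
  })
  roi <- list(lower = c(-10, -10, -10), upper = c(10, 10, 10))
  idt <- rigid_transform(diag(3), c(0, 0, 0))
  ct <- point_cloud(ref, frame = "ground_truth")
  a <- reconstruction_error(point_cloud(pts, frame = "camera"), ct, idt, roi,
                            n_samples = 500, seed = 3)
  perm <- sample(nrow(pts))
  b <- reconstruction_error(point_cloud(pts[perm, ], frame = "camera"), ct, idt,
                            roi, n_samples = 500, seed = 3)
  expect_identical(a$rmse, b$rmse)
  expect_identical(a$mean_abs, b$mean_abs)
  expect_gte(a$rmse, a$mean_abs)
  # different sampling seed changes the draw (statistically)
  c_ <- reconstruction_error(point_cloud(pts, frame = "camera"), ct, idt, roi,
                             n_samples = 500, seed = 4)
  expect_false(identical(a$rmse, c_$rmse))
})

test_that("fiducial localization recovers the targets from an exact cloud", {
  sc <- generate_phantom(0, 1)
  pose <- default_scene_pose()
  # exact synthetic reconstruction: dense surface samples with intensity
  # proportional to albedo, in the camera frame
  gt <- sample_ground_truth_cloud(sc, 120000, seed = 5)
  # carry albedo-driven intensity: find nearest vertex albedo per sample
  vert <- sc$mesh$vertices
  alb <- sc$mesh$albedo
  nearest_v <- function(p) {
    # height-field: nearest grid vertex in (x, y)
    ix <- pmin(pmax(round((p[, 1] + 45) / sc$grid_step), 0), 90)
    iy <- pmin(pmax(round((p[, 2] + 20) / sc$grid_step), 0), 40)
    ix * 41 + iy + 1
  }
  inten <- 200 * alb[nearest_v(gt$points)]
  cam <- transform_cloud(point_cloud(gt$points, frame = "ground_truth",
                                     intensity = inten),
                         pose, new_frame = "camera")
  est <- localize_fiducials_3d(cam, sc, pose = pose)
  truth <- transform_points(pose, fiducial_target_points(sc))
  err <- sqrt(rowSums((est - truth)^2))
  expect_lt(max(err), 0.2)
  # offset direction: targets sit farther from the camera than the disc tops
  tops <- transform_points(pose, do.call(rbind, lapply(sc$fiducials$markers,
                                                       function(m) m$top_center)))
  expect_true(all(est[, 3] > tops[, 3] - 1e-6))
  # a cloud missing one marker errors, naming it
  keep <- sqrt(rowSums(sweep(cam$points, 2,
                             transform_points(pose, matrix(sc$fiducials$markers[[2]]$top_center, 1)))^2)) > 8
  cropped <- point_cloud(cam$points[keep, ], frame = "camera",
                         intensity = cam$intensity[keep])
  expect_error(localize_fiducials_3d(cropped, sc, pose = pose), "marker 2")
})

test_that("z-difference heat maps bin, difference and mask correctly", {
  withr::with_seed(9, {
    base <- cbind(runif(20000, -10, 10), runif(20000, -10, 10), 0)
  })
  ct <- point_cloud(base, frame = "ground_truth")
  # identical clouds -> all valid cells 0
  hm0 <- z_difference_heatmap(ct, ct, grid_mm = 2)
  expect_true(all(abs(hm0$values[hm0$mask]) < 1e-12))
  # constant +0.5 z shift -> all valid cells 0.5
  up <- point_cloud(cbind(base[, 1:2], 0.5), frame = "ground_truth")
  hm5 <- z_difference_heatmap(up, ct, grid_mm = 2)
  expect_true(all(abs(hm5$values[hm5$mask] - 0.5) < 1e-9))
  # a hole in the reconstruction masks the corresponding cells
  holed <- base[!(abs(base[, 1]) < 3 & abs(base[, 2]) < 3), ]
  hmh <- z_difference_heatmap(point_cloud(holed, frame = "ground_truth"), ct,
                              grid_mm = 2)
  xc <- (hmh$x_breaks[-1] + hmh$x_breaks[-length(hmh$x_breaks)]) / 2
  yc <- (hmh$y_breaks[-1] + hmh$y_breaks[-length(hmh$y_breaks)]) / 2
  hole_cells <- outer(abs(yc) < 2, abs(xc) < 2, FUN = "&")
  expect_true(all(!hmh$mask[hole_cells]))
  expect_error(z_difference_heatmap(ct, ct, grid_mm = 0), "positive")
})
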