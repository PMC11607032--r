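# Stereo calibration from checkerboard corner observations: closed-form
# Zhang initialization (planar homographies -> intrinsics -> per-pose
# extrinsics), joint Levenberg-Marquardt bundle refinement over both cameras
# and the relative pose, then Bouguet-style rectification and the metric
# reprojection matrix Q.

# ---- homography estimation (normalized DLT) --------------------------------

normalise_points_2d <- function(p) {
  mu <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2, mu)^2))
  s <- sqrt(2) / mean(d)
  T_ <- matrix(c(s, 0, 0, 0, s, 0, -s * mu[1], -s * mu[2], 1), 3, 3)
  list(T = T_, p = cbind(s * (p[, 1] - mu[1]), s * (p[, 2] - mu[2])))
}

estimate_homography <- function(xy_board, uv) {
  nb <- normalise_points_2d(xy_board)
  ni <- normalise_points_2d(uv)
  X <- nb$p[, 1]; Y <- nb$p[, 2]
  u <- ni$p[, 1]; v <- ni$p[, 2]
  n <- length(X)
  Z0 <- rep(0, n); O <- rep(1, n)
  A <- rbind(
    cbind(X, Y, O, Z0, Z0, Z0, -u * X, -u * Y, -u),
    cbind(Z0, Z0, Z0, X, Y, O, -v * X, -v * Y, -v)
  )
  h <- svd(A, nu = 0)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(ni$T) %*% H %*% nb$T
  H / H[3, 3]
}

# ---- Zhang closed-form intrinsics ------------------------------------------

zhang_v <- function(H, i, j) {
  c(H[1, i] * H[1, j],
    H[1, i] * H[2, j] + H[2, i] * H[1, j],
    H[2, i] * H[2, j],
    H[3, i] * H[1, j] + H[1, i] * H[3, j],
    H[3, i] * H[2, j] + H[2, i] * H[3, j],
    H[3, i] * H[3, j])
}

zhang_intrinsics <- function(Hs) {
  V <- do.call(rbind, lapply(Hs, function(H) {
    rbind(zhang_v(H, 1, 2), zhang_v(H, 1, 1) - zhang_v(H, 2, 2))
  }))
  sv <- svd(V, nu = 0)
  if (sv$d[5] / sv$d[1] < 1e-10) {
    stop("degenerate pose set: board orientations do not constrain the intrinsics",
         call. = FALSE)
  }
  b <- sv$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  v0 <- (B12 * B13 - B11 * B23) / (B11 * B22 - B12^2)
  lambda <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  alpha2 <- lambda / B11
  beta2 <- lambda * B11 / (B11 * B22 - B12^2)
  if (alpha2 <= 0 || beta2 <= 0) stop("Zhang initialization failed (negative focal^2)",
                                      call. = FALSE)
  alpha <- sqrt(alpha2); beta <- sqrt(beta2)
  gamma <- -B12 * alpha^2 * beta / lambda
  u0 <- gamma * v0 / beta - B13 * alpha^2 / lambda
  K <- matrix(c(alpha, 0, 0, 0, beta, 0, u0, v0, 1), 3, 3) # skew dropped
  K
}

zhang_extrinsics <- function(K, H) {
  Ki <- solve(K)
  h1 <- H[, 1]; h2 <- H[, 2]; h3 <- H[, 3]
  lambda <- 1 / sqrt(sum((Ki %*% h1)^2))
  r1 <- lambda * as.numeric(Ki %*% h1)
  r2 <- lambda * as.numeric(Ki %*% h2)
  t <- lambda * as.numeric(Ki %*% h3)
  if (t[3] < 0) { r1 <- -r1; r2 <- -r2; t <- -t }
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  Rapprox <- cbind(r1, r2, r3)
  sv <- svd(Rapprox)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  list(R = R, t = t)
}

# ---- Levenberg-Marquardt on a generic residual -----------------------------

lm_refine <- function(par, resid_fn, max_iter = 50, tol = 1e-12) {
  r <- resid_fn(par)
  cost <- sum(r^2)
  mu <- NULL
  for (iter in seq_len(max_iter)) {
    np <- length(par)
    J <- matrix(0, length(r), np)
    h <- 1e-7 * (abs(par) + 1e-7)
    for (j in seq_len(np)) {
      pj <- par
      pj[j] <- pj[j] + h[j]
      J[, j] <- (resid_fn(pj) - r) / h[j]
    }
    A <- crossprod(J)
    g <- crossprod(J, r)
    if (is.null(mu)) mu <- 1e-3 * max(diag(A))
    improved <- FALSE
    for (inner in 1:10) {
      step <- tryCatch(solve(A + mu * diag(np), -g), error = function(e) NULL)
      if (!is.null(step)) {
        par_new <- par + as.numeric(step)
        r_new <- resid_fn(par_new)
        cost_new <- sum(r_new^2)
        if (is.finite(cost_new) && cost_new < cost) {
          rel <- (cost - cost_new) / max(cost, 1e-300)
          par <- par_new; r <- r_new; cost <- cost_new
          mu <- mu / 3
          improved <- TRUE
          if (rel < tol) return(list(par = par, resid = r, cost = cost))
          break
        }
      }
      mu <- mu * 4
    }
    if (!improved) break
  }
  list(par = par, resid = r, cost = cost)
}

# ---- parameter packing for the joint stereo bundle -------------------------

pack_stereo_par <- function(Kl, dl, Kr, dr, om, tvec, pose_om, pose_t, n_dist) {
  c(Kl[1, 1], Kl[2, 2], Kl[1, 3], Kl[2, 3], dl[seq_len(n_dist)],
    Kr[1, 1], Kr[2, 2], Kr[1, 3], Kr[2, 3], dr[seq_len(n_dist)],
    om, tvec,
    as.numeric(rbind(do.call(cbind, pose_om), do.call(cbind, pose_t))))
}

unpack_stereo_par <- function(par, n_poses, n_dist) {
  i <- 0L
  take <- function(k) {
    if (k == 0L) return(numeric(0))
    out <- par[(i + 1):(i + k)]
    i <<- i + k
    out
  }
  kl <- take(4); dl <- c(take(n_dist), rep(0, 5 - n_dist))
  kr <- take(4); dr <- c(take(n_dist), rep(0, 5 - n_dist))
  om <- take(3); tvec <- take(3)
  poses <- lapply(seq_len(n_poses), function(j) {
    v <- take(6)
    list(om = v[1:3], t = v[4:6])
  })
  Kl <- matrix(c(kl[1], 0, 0, 0, kl[2], 0, kl[3], kl[4], 1), 3, 3)
  Kr <- matrix(c(kr[1], 0, 0, 0, kr[2], 0, kr[3], kr[4], 1), 3, 3)
  list(Kl = Kl, dl = dl, Kr = Kr, dr = dr, om = om, tvec = tvec, poses = poses)
}

stereo_residuals <- function(par, observations, n_dist) {
  n_poses <- length(observations)
  p <- unpack_stereo_par(par, n_poses, n_dist)
  R_rel <- rodrigues_to_matrix(p$om)
  out <- vector("list", n_poses)
  for (j in seq_len(n_poses)) {
    ob <- observations[[j]]
    Rj <- rodrigues_to_matrix(p$poses[[j]]$om)
    Xl <- sweep(ob$board %*% t(Rj), 2, p$poses[[j]]$t, "+")
    Xr <- sweep(Xl %*% t(R_rel), 2, p$tvec, "+")
    prl <- project_camera_frame(p$Kl, p$dl, Xl, on_behind = "na")
    prr <- project_camera_frame(p$Kr, p$dr, Xr, on_behind = "na")
    rl <- prl - ob$left
    rr <- prr - ob$right
    out[[j]] <- c(rl, rr)
  }
  r <- unlist(out)
  r[!is.finite(r)] <- 1e6
  r
}

#' Stereo calibration from checkerboard observations
#'
#' Zhang's closed-form initialization per camera (planar homographies to
#' intrinsics to per-pose extrinsics) followed by a joint Levenberg-Marquardt
#' bundle refinement of both cameras' intrinsics and distortion, the relative
#' pose, and all board poses, minimizing total reprojection error. The
#' returned entry carries the rectification rotations (R1, R2), rectified
#' projections (P1, P2) and the metric reprojection matrix Q.
#'
#' @param observations A `calibration_set` from [render_calibration_set()]
#'   (or a compatible list of poses with `left`, `right`, `board`).
#' @param board A [board_spec()] (defaults to the set's own board).
#' @param zoom Zoom tag stored in the entry.
#' @param fix_k3 Freeze the 6th-order radial coefficient at 0 (default TRUE;
#'   the synthetic rig has mild distortion at most).
#' @param estimate_distortion If FALSE, all distortion coefficients are frozen
#'   at 0.
#' @return A `calibration_entry`.
#' @export
calibrate_stereo <- function(observations, board = NULL, zoom = NA_real_,
                             fix_k3 = TRUE, estimate_distortion = TRUE) {
  if (inherits(observations, "calibration_set")) {
    board <- board %||% observations$board
    image_size <- observations$image_size
    observations <- observations$poses
  } else {
    image_size <- NULL
  }
  n_poses <- length(observations)
  if (n_poses < 3) {
    stop("need at least 3 poses for calibration, got ", n_poses, call. = FALSE)
  }
  for (ob in observations) {
    if (nrow(ob$left) != nrow(ob$board) || nrow(ob$right) != nrow(ob$board)) {
      stop("every pose must observe the full corner grid in both views",
           call. = FALSE)
    }
  }

  xy <- function(ob) ob$board[, 1:2, drop = FALSE]
  Hl <- lapply(observations, function(ob) estimate_homography(xy(ob), ob$left))
  Hr <- lapply(observations, function(ob) estimate_homography(xy(ob), ob$right))
  Kl <- zhang_intrinsics(Hl)
  Kr <- zhang_intrinsics(Hr)
  el <- lapply(Hl, function(H) zhang_extrinsics(Kl, H))
  er <- lapply(Hr, function(H) zhang_extrinsics(Kr, H))

  # relative pose init: median-free simple average over poses via rotation vecs
  oms <- sapply(seq_len(n_poses), function(j) {
    matrix_to_rodrigues(er[[j]]$R %*% t(el[[j]]$R))
  })
  om0 <- rowMeans(oms)
  R0 <- rodrigues_to_matrix(om0)
  t0 <- rowMeans(sapply(seq_len(n_poses), function(j) {
    er[[j]]$t - as.numeric(R0 %*% el[[j]]$t)
  }))

  n_dist <- if (!estimate_distortion) 0L else if (fix_k3) 4L else 5L
  par0 <- pack_stereo_par(Kl, rep(0, 5), Kr, rep(0, 5), om0, t0,
                          lapply(el, function(e) matrix_to_rodrigues(e$R)),
                          lapply(el, function(e) e$t), n_dist)
  fit <- lm_refine(par0, function(p) stereo_residuals(p, observations, n_dist))
  p <- unpack_stereo_par(fit$par, n_poses, n_dist)

  # rms over corners (both views) = sqrt(mean(du^2 + dv^2))
  n_corners <- sum(vapply(observations, function(ob) nrow(ob$board), 1L)) * 2L
  rms <- sqrt(sum(fit$resid^2) / n_corners)

  R_rel <- rodrigues_to_matrix(p$om)
  rect <- stereo_rectify(p$Kl, p$dl, p$Kr, p$dr, R_rel, p$tvec,
                         image_size %||% c(NA_integer_, NA_integer_))
  new_calibration_entry(zoom = zoom, Kl = p$Kl, dl = p$dl, Kr = p$Kr, dr = p$dr,
                        R = R_rel, T = p$tvec, rect = rect,
                        rms = rms, image_size = image_size,
                        poses = p$poses)
}

# Bouguet-style rectification: common rotation aligning both optical frames
# with the baseline, shared rectified intrinsics, and the reprojection matrix Q
stereo_rectify <- function(Kl, dl, Kr, dr, R, T_, image_size) {
  C_r <- as.numeric(-t(R) %*% T_) # right camera center in left frame
  B <- sqrt(sum(C_r^2))
  e1 <- C_r / B
  if (e1[1] < 0) e1 <- -e1
  z0 <- c(0, 0, 1)
  e2 <- c(z0[2] * e1[3] - z0[3] * e1[2],
          z0[3] * e1[1] - z0[1] * e1[3],
          z0[1] * e1[2] - z0[2] * e1[1]) # cross(z, e1) ~ +y for e1 ~ +x
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R1 <- rbind(e1, e2, e3)
  dimnames(R1) <- NULL
  R2 <- R1 %*% t(R)
  f_new <- mean(c(Kl[1, 1], Kl[2, 2], Kr[1, 1], Kr[2, 2]))
  # per-side rectified principal points keep each camera's optical axis at
  # its image centre; otherwise a verged rig loses the shared field of view
  # after rectification. The cx offset shifts all disparities by
  # dcx = cx1 - cx2 (which is how converged rigs produce small or negative
  # disparities) and is carried in Q.
  centre_px <- function(Rr, w0, h0) {
    dr <- as.numeric(Rr %*% c(0, 0, 1)) # rectified direction of the optical axis
    c(w0 - f_new * dr[1] / dr[3], h0 - f_new * dr[2] / dr[3])
  }
  w0 <- mean(c(Kl[1, 3], Kr[1, 3])) # original principal points as the centre
  h0 <- mean(c(Kl[2, 3], Kr[2, 3]))
  cl <- centre_px(R1, w0, h0)
  cr <- centre_px(R2, w0, h0)
  cy <- mean(c(cl[2], cr[2])) # rows must share one principal row
  cx1 <- cl[1]; cx2 <- cr[1]
  dcx <- cx1 - cx2
  K1 <- matrix(c(f_new, 0, 0, 0, f_new, 0, cx1, cy, 1), 3, 3)
  K2 <- matrix(c(f_new, 0, 0, 0, f_new, 0, cx2, cy, 1), 3, 3)
  P1 <- cbind(K1, c(0, 0, 0))
  P2 <- cbind(K2, K2 %*% c(-B, 0, 0))
  # (u - cx1, v - cy, f, (d - dcx)/B) ~ metric point
  Q <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0,
                0, 0, 0, 1 / B,
                -cx1, -cy, f_new, -dcx / B), 4, 4)
  list(R1 = R1, R2 = R2, P1 = P1, P2 = P2, Q = Q, baseline = B,
       f_rect = f_new, c_rect = c(cx1, cy), cx2_rect = cx2, dcx = dcx)
}

new_calibration_entry <- function(zoom, Kl, dl, Kr, dr, R, T, rect, rms,
                                  image_size, poses = NULL) {
  structure(list(zoom = zoom,
                 left = list(K = Kl, dist = dl),
                 right = list(K = Kr, dist = dr),
                 R = R, T = as.numeric(T),
                 R1 = rect$R1, R2 = rect$R2, P1 = rect$P1, P2 = rect$P2,
                 Q = rect$Q, baseline = rect$baseline,
                 f_rect = rect$f_rect, c_rect = rect$c_rect,
                 cx2_rect = rect$cx2_rect, dcx = rect$dcx,
                 rms_reprojection_error = rms,
                 image_size = image_size, poses = poses,
                 cache = new.env(parent = emptyenv())),
            class = "calibration_entry")
}

#' @export
print.calibration_entry <- function(x, ...) {
  cat(sprintf(paste0("<calibration_entry> zoom %.2f, f_rect %.1f px, baseline %.3f mm, ",
                     "rms %.4f px\n"),
              x$zoom, x$f_rect, x$baseline, x$rms_reprojection_error))
  invisible(x)
}

#' Exact calibration entry from a known rig
#'
#' Builds a `calibration_entry` directly from the true simulated rig geometry
#' (no estimation); useful for isolating reconstruction from calibration
#' error and for identity-rectification tests on ideal parallel rigs.
#'
#' @param rig A `stereo_rig`.
#' @return A `calibration_entry` with zero reported reprojection error.
#' @export
calibration_entry_from_rig <- function(rig) {
  rect <- stereo_rectify(rig$left$K, rig$left$dist, rig$right$K, rig$right$dist,
                         rig$R, rig$T, rig$image_size)
  new_calibration_entry(zoom = rig$zoom, Kl = rig$left$K, dl = rig$left$dist,
                        Kr = rig$right$K, dr = rig$right$dist,
                        R = rig$R, T = rig$T, rect = rect, rms = 0,
                        image_size = rig$image_size)
}

rectify_maps <- function(entry, side = c("left", "right")) {
  side <- match.arg(side)
  w <- entry$image_size[1]; h <- entry$image_size[2]
  Rr <- if (side == "left") entry$R1 else entry$R2
  cam <- entry[[side]]
  u <- rep(0:(w - 1), each = h)
  v <- rep(0:(h - 1), times = w)
  cx_side <- if (side == "left") entry$c_rect[1] else entry$cx2_rect
  x <- (u - cx_side) / entry$f_rect
  y <- (v - entry$c_rect[2]) / entry$f_rect
  dirs <- cbind(x, y, 1) %*% Rr # = t(Rr) applied row-wise
  # project through the original camera including distortion
  uv <- project_camera_frame(cam$K, cam$dist, dirs, on_behind = "na")
  list(mapx = matrix(uv[, 1], h, w), mapy = matrix(uv[, 2], h, w))
}

#' Rectify a stereo pair
#'
#' Resamples both images so that corresponding points share the same row
#' (horizontal epipolar lines), using the entry's rectification rotations and
#' shared rectified intrinsics; bilinear resampling, out-of-source pixels 0.
#'
#' @param left,right Numeric/integer image matrices at the calibrated size.
#' @param entry A `calibration_entry`.
#' @return List with `left`, `right` rectified matrices.
#' @export
rectify_pair <- function(left, right, entry) {
  stopifnot(inherits(entry, "calibration_entry"))
  if (!all(dim(left) == dim(right))) stop("image size mismatch", call. = FALSE)
  if (!is.null(entry$image_size) && !all(is.na(entry$image_size)) &&
      !all(dim(left) == c(entry$image_size[2], entry$image_size[1]))) {
    stop("images do not match the calibrated resolution", call. = FALSE)
  }
  cache <- entry$cache
  if (!is.null(cache) && is.environment(cache)) {
    if (is.null(cache$maps)) {
      cache$maps <- list(left = rectify_maps(entry, "left"),
                         right = rectify_maps(entry, "right"))
    }
    ml <- cache$maps$left
    mr <- cache$maps$right
  } else {
    ml <- rectify_maps(entry, "left")
    mr <- rectify_maps(entry, "right")
  }
  list(left = cpp_remap_bilinear(matrix(as.numeric(left), nrow(left)), ml$mapx, ml$mapy),
       right = cpp_remap_bilinear(matrix(as.numeric(right), nrow(right)), mr$mapx, mr$mapy))
}

# ---- zoom lookup table persistence -----------------------------------------

entry_to_list <- function(e) {
  list(zoom = e$zoom,
       left = list(K = e$left$K, dist = e$left$dist),
       right = list(K = e$right$K, dist = e$right$dist),
       R = e$R, T = e$T, R1 = e$R1, R2 = e$R2, P1 = e$P1, P2 = e$P2,
       Q = e$Q, baseline = e$baseline, f_rect = e$f_rect, c_rect = e$c_rect,
       cx2_rect = e$cx2_rect, dcx = e$dcx,
       rms_reprojection_error = e$rms_reprojection_error,
       image_size = e$image_size)
}

list_to_entry <- function(l) {
  as_m <- function(x) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  structure(list(zoom = num(l$zoom),
                 left = list(K = as_m(l$left$K), dist = as.numeric(l$left$dist)),
                 right = list(K = as_m(l$right$K), dist = as.numeric(l$right$dist)),
                 R = as_m(l$R), T = as.numeric(l$T),
                 R1 = as_m(l$R1), R2 = as_m(l$R2), P1 = as_m(l$P1), P2 = as_m(l$P2),
                 Q = as_m(l$Q), baseline = num(l$baseline), f_rect = num(l$f_rect),
                 c_rect = as.numeric(l$c_rect),
                 cx2_rect = num(l$cx2_rect), dcx = num(l$dcx),
                 rms_reprojection_error = num(l$rms_reprojection_error),
                 image_size = if (is.null(l$image_size)) NULL else as.integer(l$image_size),
                 poses = NULL,
                 cache = new.env(parent = emptyenv())),
            class = "calibration_entry")
}

#' Save a per-zoom calibration lookup table as JSON
#'
#' All matrices are serialized at full double precision so that
#' `load(save(x))` round-trips exactly.
#'
#' @param entries List of `calibration_entry` objects with distinct zooms.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_zoom_lookup <- function(entries, path) {
  if (inherits(entries, "calibration_entry")) entries <- list(entries)
  zooms <- vapply(entries, function(e) e$zoom, 1)
  if (anyDuplicated(zooms)) stop("duplicate zoom keys in lookup table", call. = FALSE)
  payload <- list(schema = "stereomire-zoom-lookup", version = 1L,
                  entries = lapply(entries, entry_to_list))
  # I(17) significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a calibration lookup table saved by [save_zoom_lookup()]
#' @param path JSON path.
#' @return A `zoom_lookup`: list of `calibration_entry`, ordered by zoom.
#' @export
load_zoom_lookup <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                                 simplifyMatrix = TRUE)
  if (!identical(payload$schema, "stereomire-zoom-lookup")) {
    stop("not a zoom lookup table: ", path, call. = FALSE)
  }
  entries <- lapply(payload$entries, list_to_entry)
  zooms <- vapply(entries, function(e) e$zoom, 1)
  structure(entries[order(zooms)], class = "zoom_lookup")
}

#' Retrieve the calibration entry for a zoom level
#'
#' Exact-match lookup; the table stores discrete zoom/focus settings and no
#' interpolation or extrapolation is performed.
#'
#' @param lookup A `zoom_lookup` or plain list of entries.
#' @param zoom Zoom level to fetch.
#' @param tol Numeric match tolerance on the zoom key.
#' @return The matching `calibration_entry`.
#' @export
lookup_zoom <- function(lookup, zoom, tol = 1e-9) {
  zooms <- vapply(lookup, function(e) e$zoom, 1)
  i <- which(abs(zooms - zoom) <= tol)
  if (length(i) != 1) {
    stop(sprintf("no calibration for zoom %.3f; available zooms: %s (nearest %.3f)",
                 zoom, paste(sprintf("%.2f", sort(zooms)), collapse = ", "),
                 zooms[which.min(abs(zooms - zoom))]), call. = FALSE)
  }
  lookup[[i]]
}
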