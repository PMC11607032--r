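#' Semi-global block matching parameters
#'
#' Block matching cost is the sum of absolute differences over a
#' `block_size`^2 window; costs are aggregated along 4 or 8 scanline paths
#' with the usual small-jump (`p1`) and large-jump (`p2`) smoothness
#' penalties. Block size 3 is the fixed protocol value; `p1 = 8 * block^2`
#' and `p2 = 32 * block^2` follow standard semi-global matching practice. A
#' negative `min_disparity` is allowed (verged rigs can produce either sign).
#'
#' @param block_size Odd matching window side, px (default 3).
#' @param min_disparity Smallest disparity considered (may be negative).
#' @param num_disparities Number of disparity levels; must be a multiple
#'   of 16.
#' @param p1,p2 Smoothness penalties (`p2 > p1 >= 0`); defaults scale with
#'   the block area.
#' @param n_paths 4 or 8 aggregation directions (8 default; 4 is the fast
#'   desk-test mode).
#' @param lr_check_tol Left-right consistency tolerance in px (negative
#'   disables the check).
#' @param uniqueness_ratio Winner margin in percent (0 disables).
#' @param texture_threshold Minimum local intensity range (counts) around a
#'   left pixel for it to be matchable; 0 disables. The default 10 is just
#'   above the range pure sensor noise (sd 2 counts) produces over the
#'   window, so "valid" always means signal-backed.
#' @param speckle_window Minimum connected-component size (px) for a valid
#'   disparity patch; smaller speckles are invalidated. 0 disables.
#' @param speckle_range Disparity connectivity tolerance (px) for the
#'   speckle filter.
#' @return An `sgbm_params` list.
#' @export
sgbm_params <- function(block_size = 3L, min_disparity = 0L,
                        num_disparities = 64L,
                        p1 = 8L * block_size^2, p2 = 32L * block_size^2,
                        n_paths = 8L, lr_check_tol = 1,
                        uniqueness_ratio = 5L, texture_threshold = 10L,
                        speckle_window = 100L, speckle_range = 1) {
  block_size <- as.integer(block_size)
  num_disparities <- as.integer(num_disparities)
  if (block_size < 1L || block_size %% 2L == 0L) {
    stop("block_size must be an odd integer >= 1", call. = FALSE)
  }
  if (num_disparities %% 16L != 0L || num_disparities <= 0L) {
    stop("num_disparities must be a positive multiple of 16", call. = FALSE)
  }
  if (!(p2 > p1 && p1 >= 0)) stop("require p2 > p1 >= 0", call. = FALSE)
  if (!n_paths %in% c(4L, 8L)) stop("n_paths must be 4 or 8", call. = FALSE)
  structure(list(block_size = block_size,
                 min_disparity = as.integer(min_disparity),
                 num_disparities = num_disparities,
                 p1 = as.integer(p1), p2 = as.integer(p2),
                 n_paths = as.integer(n_paths),
                 lr_check_tol = lr_check_tol,
                 uniqueness_ratio = as.integer(uniqueness_ratio),
                 texture_threshold = as.integer(texture_threshold),
                 speckle_window = as.integer(speckle_window),
                 speckle_range = speckle_range),
            class = "sgbm_params")
}

#' Disparity search range from scene depth bounds
#'
#' Sizes the disparity search window from the rectified geometry and the
#' simulated working volume: `d = f * B / Z`, with the window rounded up to a
#' multiple of 16 levels.
#'
#' @param entry A `calibration_entry`.
#' @param z_near,z_far Near/far scene depth bounds in mm.
#' @return List with `min_disparity` and `num_disparities`.
#' @export
disparity_range <- function(entry, z_near, z_far) {
  stopifnot(z_far > z_near, z_near > 0)
  fB <- entry$f_rect * entry$baseline
  dcx <- entry$dcx %||% 0 # verged rigs shift all disparities by cx1 - cx2
  d_min <- floor(fB / z_far + dcx) - 1
  d_max <- ceiling(fB / z_near + dcx) + 1
  num <- as.integer(ceiling((d_max - d_min) / 16) * 16)
  list(min_disparity = as.integer(d_min), num_disparities = num)
}

#' Compute a dense disparity map by semi-global block matching
#'
#' @param rect_left,rect_right Rectified grayscale image matrices (equal
#'   size).
#' @param params An [sgbm_params()].
#' @param entry Optional `calibration_entry` the pair was rectified with;
#'   carried on the result for reprojection.
#' @param return_cost Also return the aggregated cost volume (for small
#'   images/diagnostics only).
#' @return A `disparity_map`: list with `values` (matrix, NA = invalid),
#'   `params`, `entry`, `valid_fraction` (and `cost` when requested).
#' @export
compute_disparity <- function(rect_left, rect_right, params = sgbm_params(),
                              entry = NULL, return_cost = FALSE) {
  stopifnot(inherits(params, "sgbm_params"))
  if (!all(dim(rect_left) == dim(rect_right))) {
    stop("rectified pair size mismatch", call. = FALSE)
  }
  to_int <- function(m) {
    matrix(as.integer(round(pmin(255, pmax(0, m)))), nrow(m), ncol(m))
  }
  res <- cpp_sgbm(to_int(rect_left), to_int(rect_right),
                  params$min_disparity, params$num_disparities,
                  params$block_size, params$p1, params$p2, params$n_paths,
                  params$lr_check_tol, params$uniqueness_ratio,
                  params$texture_threshold, params$speckle_window,
                  params$speckle_range, return_cost)
  out <- structure(list(values = res$disparity, params = params, entry = entry,
                        valid_fraction = mean(is.finite(res$disparity))),
                   class = "disparity_map")
  if (return_cost) out$cost <- res$cost
  out
}

#' @export
print.disparity_map <- function(x, ...) {
  cat(sprintf("<disparity_map> %d x %d px, %.1f%% valid, range [%d, %d)\n",
              ncol(x$values), nrow(x$values), 100 * x$valid_fraction,
              x$params$min_disparity,
              x$params$min_disparity + x$params$num_disparities))
  invisible(x)
}

#' Reproject a disparity map to a metric point cloud
#'
#' Valid pixels are mapped through the calibration entry's reprojection
#' matrix Q (homogeneous `(x, y, d, 1)` to mm) and rotated from the rectified
#' frame back into the original left-camera frame. Pixel intensities from the
#' rectified left image are carried along when provided.
#'
#' @param disp A `disparity_map`.
#' @param entry A `calibration_entry` (defaults to the one stored on `disp`;
#'   supplying a different entry than the map was built with is an error).
#' @param intensity Optional rectified left image whose values are attached
#'   to the points.
#' @return A [point_cloud()] in the camera frame.
#' @export
disparity_to_cloud <- function(disp, entry = NULL, intensity = NULL) {
  stopifnot(inherits(disp, "disparity_map"))
  if (is.null(entry)) entry <- disp$entry
  if (is.null(entry)) stop("no calibration entry available", call. = FALSE)
  if (!is.null(disp$entry) &&
      !isTRUE(all.equal(disp$entry$Q, entry$Q, tolerance = 1e-12))) {
    stop("calibration entry does not match the one used for this disparity map",
         call. = FALSE)
  }
  vals <- disp$values
  idx <- which(is.finite(vals))
  if (length(idx) == 0) {
    return(point_cloud(matrix(numeric(0), 0, 3), frame = "camera"))
  }
  h <- nrow(vals)
  v <- (idx - 1) %% h          # 0-based row
  u <- (idx - 1) %/% h         # 0-based col
  d <- vals[idx]
  hom <- cbind(u, v, d, 1) %*% t(entry$Q)
  pts <- hom[, 1:3] / hom[, 4]
  # rectified-left frame -> original left camera frame
  pts <- pts %*% entry$R1 # == t(R1) applied to each point
  keep <- is.finite(rowSums(pts))
  inten <- NULL
  if (!is.null(intensity)) inten <- intensity[idx][keep]
  point_cloud(pts[keep, , drop = FALSE], frame = "camera", intensity = inten)
}

#' Full reconstruction of one stereo pair (the "MiRe")
#'
#' Rectify, match (semi-global block matching) and triangulate to a metric
#' point cloud in the left-camera frame. The fraction of pixels with a valid
#' disparity is recorded on the result.
#'
#' @param left,right Grayscale stereo images at the calibrated resolution.
#' @param entry A `calibration_entry`.
#' @param params An [sgbm_params()].
#' @return A [point_cloud()] (camera frame, with intensities) carrying
#'   attribute `valid_fraction`.
#' @export
reconstruct_mire <- function(left, right, entry, params = sgbm_params()) {
  rect <- rectify_pair(left, right, entry)
  disp <- compute_disparity(rect$left, rect$right, params, entry = entry)
  cloud <- disparity_to_cloud(disp, entry, intensity = rect$left)
  attr(cloud, "valid_fraction") <- disp$valid_fraction
  cloud
}
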