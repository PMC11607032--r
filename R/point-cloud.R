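#' Point cloud container
#'
#' A set of 3-D points in millimetres, tagged with the frame it lives in
#' (`"camera"` for reconstructions in the left-camera frame, `"ground_truth"`
#' for the phantom/CT frame). Points must be finite. An optional per-point
#' `intensity` vector (8-bit counts from the left rectified image) is carried
#' through reconstruction for intensity-based fiducial segmentation.
#'
#' @param points N x 3 numeric matrix (or data frame with x, y, z), mm.
#' @param frame `"camera"` or `"ground_truth"`.
#' @param intensity Optional numeric vector of length N.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, frame = c("camera", "ground_truth"),
                        intensity = NULL) {
  frame <- match.arg(frame)
  points <- as_points_matrix(points)
  if (nrow(points) > 0 && !all(is.finite(points))) {
    stop("point_cloud requires finite coordinates", call. = FALSE)
  }
  if (!is.null(intensity)) {
    intensity <- as.numeric(intensity)
    stopifnot(length(intensity) == nrow(points))
  }
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, frame = frame, intensity = intensity),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, frame = %s%s\n", nrow(x$points), x$frame,
              if (!is.null(x$intensity)) ", with intensity" else ""))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud A `point_cloud`.
#' @return Integer count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Convert a point cloud to a tibble
#' @param x A `point_cloud`.
#' @param ... Ignored.
#' @return Tibble with columns x, y, z (and intensity when present).
#' @export
as_tibble.point_cloud <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$points))
  if (!is.null(x$intensity)) out$intensity <- x$intensity
  out
}

#' Apply a rigid transform to a point cloud
#'
#' @param cloud A [point_cloud()].
#' @param transform A [rigid_transform()].
#' @param new_frame Frame tag of the result (default: keep).
#' @return A transformed `point_cloud`.
#' @export
transform_cloud <- function(cloud, transform, new_frame = cloud$frame) {
  point_cloud(transform_points(transform, cloud$points), frame = new_frame,
              intensity = cloud$intensity)
}
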