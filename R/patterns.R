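#' Pattern parameters for the adaptive dot pattern
#'
#' The adaptive projected pattern is a regular grid of square dots described by
#' two integers in projector pixels: the dot side length `s` and the
#' edge-to-edge gap `d` between adjacent dots (so the grid pitch is `s + d`).
#' The optimizer searches the integer box d in \[1, 10\], s in \[2, 16\];
#' construction outside that box is an error.
#'
#' @param dot_distance_d Integer gap between dots, projector pixels (1-10).
#' @param dot_size_s Integer dot side length, projector pixels (2-16).
#' @return An object of class `pattern_params` (a named list with
#'   `dot_distance_d` and `dot_size_s`).
#' @examples
#' pattern_params(5, 15)
#' @export
pattern_params <- function(dot_distance_d, dot_size_s) {
  d <- as.integer(dot_distance_d)
  s <- as.integer(dot_size_s)
  if (length(d) != 1L || length(s) != 1L || is.na(d) || is.na(s)) {
    stop("dot_distance_d and dot_size_s must be single integers", call. = FALSE)
  }
  if (d < 1L || d > 10L) {
    stop("dot_distance_d must be in [1, 10], got ", d, call. = FALSE)
  }
  if (s < 2L || s > 16L) {
    stop("dot_size_s must be in [2, 16], got ", s, call. = FALSE)
  }
  structure(list(dot_distance_d = d, dot_size_s = s), class = "pattern_params")
}

#' @export
print.pattern_params <- function(x, ...) {
  cat(sprintf("<pattern_params> d = %d px gap, s = %d px dot, pitch = %d px\n",
              x$dot_distance_d, x$dot_size_s, x$dot_distance_d + x$dot_size_s))
  invisible(x)
}

new_pattern_image <- function(pixels) {
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels,
                 width = ncol(pixels), height = nrow(pixels)),
            class = "pattern_image")
}

#' @export
print.pattern_image <- function(x, ...) {
  cat(sprintf("<pattern_image> %d x %d px, lit fraction %.3f\n",
              x$width, x$height, mean(x$pixels > 0L)))
  invisible(x)
}

#' Rasterize the deterministic adaptive dot pattern
#'
#' Square dots of side `s` on a regular grid with center-to-center pitch
#' `p = s + d`, anchored at pixel (0, 0); dots at the right/bottom border are
#' clipped. The result is binary (0 or 255) and fully deterministic. The
#' default canvas is the projector resolution, 800 x 600.
#'
#' @param params A [pattern_params()] object.
#' @param width,height Canvas size in projector pixels; both must be at least
#'   `dot_size_s`.
#' @return A `pattern_image`: list with `pixels` (height x width integer matrix
#'   of 0/255), `width`, `height`.
#' @examples
#' img <- generate_dot_pattern(pattern_params(1, 2), width = 8, height = 8)
#' sum(img$pixels > 0) # 36 lit pixels
#' @export
generate_dot_pattern <- function(params, width = 800L, height = 600L) {
  stopifnot(inherits(params, "pattern_params"))
  width <- as.integer(width); height <- as.integer(height)
  s <- params$dot_size_s
  if (width < s || height < s) {
    stop("canvas (", width, " x ", height, ") smaller than one dot (s = ", s, ")",
         call. = FALSE)
  }
  p <- s + params$dot_distance_d
  # a pixel with 0-based coordinate k is lit iff (k mod p) < s
  col_on <- (seq_len(width) - 1L) %% p < s
  row_on <- (seq_len(height) - 1L) %% p < s
  pixels <- 255L * (outer(row_on, col_on, "&"))
  new_pattern_image(pixels)
}

#' Rasterize an uncontrolled random dot pattern
#'
#' Emulates a diffractive-style speckle illuminator where neither feature size
#' nor placement can be controlled: circular dots with log-normally distributed
#' radii are stamped at uniformly random centers until the lit-pixel fraction
#' first reaches `density`. Reproducible given `seed`.
#'
#' @param width,height Canvas size in pixels.
#' @param mean_radius Mean dot radius in pixels (>= 1).
#' @param radius_sigma Log-normal sigma of the radius distribution.
#' @param density Target lit-pixel fraction in (0, 1).
#' @param seed Integer seed controlling centers and radii.
#' @return A `pattern_image` (binary 0/255).
#' @export
generate_random_pattern <- function(width = 800L, height = 600L,
                                    mean_radius = 2, radius_sigma = 0.35,
                                    density = 0.2, seed = 0L) {
  width <- as.integer(width); height <- as.integer(height)
  if (!(density > 0 && density < 1)) stop("density must be in (0, 1)", call. = FALSE)
  if (mean_radius < 1) stop("mean_radius must be >= 1", call. = FALSE)
  pixels <- matrix(0L, nrow = height, ncol = width)
  n_px <- width * height
  n_lit <- 0L
  local_seed(seed)
  meanlog <- log(mean_radius) - radius_sigma^2 / 2
  xs <- seq_len(width); ys <- seq_len(height)
  repeat {
    cx <- stats::runif(1, 0.5, width + 0.5)
    cy <- stats::runif(1, 0.5, height + 0.5)
    r <- stats::rlnorm(1, meanlog = meanlog, sdlog = radius_sigma)
    r <- max(r, 1)
    ix <- xs[abs(xs - cx) <= r]
    iy <- ys[abs(ys - cy) <= r]
    if (length(ix) && length(iy)) {
      d2 <- outer((iy - cy)^2, (ix - cx)^2, "+")
      sub <- pixels[iy, ix, drop = FALSE]
      hit <- d2 <= r^2
      n_lit <- n_lit + sum(hit & sub == 0L)
      sub[hit] <- 255L
      pixels[iy, ix] <- sub
    }
    if (n_lit / n_px >= density) break
  }
  new_pattern_image(pixels)
}

#' Lit-pixel fraction of a pattern image
#' @param img A `pattern_image`.
#' @return Fraction of pixels equal to 255, in \[0, 1\].
#' @export
pattern_fill_fraction <- function(img) {
  stopifnot(inherits(img, "pattern_image"))
  mean(img$pixels > 0L)
}

#' Plot a pattern image
#'
#' @param object A `pattern_image`.
#' @param ... Ignored.
#' @return A ggplot object rendering the binary pattern.
#' @export
autoplot.pattern_image <- function(object, ...) {
  df <- tibble::tibble(
    x = rep(seq_len(object$width), each = object$height),
    y = rep(seq_len(object$height), times = object$width),
    on = as.vector(object$pixels) > 0L
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$on)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "black", `TRUE` = "white"),
                               guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "projector x (px)", y = "projector y (px)")
}
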