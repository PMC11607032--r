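#' Synthetic ear-like phantom with fiducial markers
#'
#' Generates the ground-truth scene that stands in for a CT-derived surface
#' model of a real-scale ear print (the physical reference is a 9 x 4 cm
#' plastic ear): a smooth height field carrying helix/concha-like ridges and
#' valleys, four raised square marker holders at distinct heights and tilts,
#' and an axis-aligned region-of-interest (ROI) cuboid over the central
#' anatomy that excludes the holders. Each holder top carries a high-albedo
#' disc (the optical marker face) and a registration target exactly 1 mm below
#' the top center along the top normal, mirroring a radio-opaque sphere hidden
#' under an optical marker.
#'
#' @param seed Integer seed; the surface relief is a seeded random mixture of
#'   ridge/valley features.
#' @param complexity Non-negative scalar scaling the relief amplitude;
#'   `complexity = 0` yields a flat plane with holders.
#' @param grid_step Height-field sampling step in mm (default 1).
#' @return A `phantom_scene`: list with
#'   \describe{
#'     \item{mesh}{list(vertices N x 3 mm, faces M x 3 1-based, albedo length-N)}
#'     \item{fiducials}{`fiducial_set`: per marker top_center, normal (unit),
#'       half_side (mm), target_point (mm)}
#'     \item{roi}{list(lower, upper): the ROI cuboid corners, mm}
#'     \item{albedo}{base surface albedo in (0, 1]}
#'   }
#' @examples
#' scene <- generate_phantom(seed = 0, complexity = 1)
#' range(scene$mesh$vertices[, 3])
#' @export
generate_phantom <- function(seed = 0L, complexity = 1, grid_step = 1) {
  stopifnot(complexity >= 0, grid_step > 0)
  local_seed(derive_seed(seed, 101))

  half_x <- 45; half_y <- 20  # footprint 90 x 40 mm
  xs <- seq(-half_x, half_x, by = grid_step)
  ys <- seq(-half_y, half_y, by = grid_step)
  nx <- length(xs); ny <- length(ys)
  X <- matrix(rep(xs, each = ny), nrow = ny)
  Y <- matrix(rep(ys, times = nx), nrow = ny)

  # ear-like relief: a C-shaped helix ridge, a concha depression, an
  # antihelix ridge and gentle seeded undulation; amplitudes in mm
  Z <- matrix(0, ny, nx)
  if (complexity > 0) {
    jit <- stats::rnorm(6, 0, 0.5)
    a <- (X - jit[1]) / 34; b <- (Y - jit[2]) / 15
    r_ell <- sqrt(a^2 + b^2)
    helix <- 5.0 * exp(-((r_ell - 1) / 0.16)^2)            # outer rim ridge
    ang <- atan2(b, a)
    helix <- helix * (0.6 + 0.4 * cos(ang - 0.4))           # rim asymmetry
    concha <- -3.2 * exp(-(((X - 8 - jit[3]) / 11)^2 + ((Y + 2 - jit[4]) / 7)^2))
    antihelix <- 2.6 * exp(-(((X + 6 - jit[5]) / 16)^2 + ((Y - 3 - jit[6]) / 4.5)^2))
    tragus <- 1.8 * exp(-(((X + 24) / 5)^2 + ((Y + 6) / 4)^2))
    wave <- 0.35 * sin(X / 7 + jit[1]) * cos(Y / 5 - jit[2])
    Z <- complexity * (helix + concha + antihelix + tragus + wave)
    # taper relief to zero at the plate border so holders sit on flat ground
    taper <- pmin(1, pmin((half_x - abs(X)) / 6, (half_y - abs(Y)) / 5))
    Z <- Z * pmax(taper, 0)
  }

  albedo_base <- 0.65
  albedo <- matrix(albedo_base, ny, nx)

  # four marker holders: tilted square plateaus at distinct heights
  holder <- holder_layout()
  fid <- vector("list", 4)
  for (i in seq_len(4)) {
    h <- holder[[i]]
    in_patch <- abs(X - h$cx) <= h$half_side & abs(Y - h$cy) <= h$half_side
    zi <- h$height + h$ax * (X - h$cx) + h$ay * (Y - h$cy)
    Z[in_patch] <- zi[in_patch]
    albedo[in_patch] <- 0.55
    disc <- (X - h$cx)^2 + (Y - h$cy)^2 <= h$disc_radius^2
    albedo[in_patch & disc] <- 0.95
    nrm <- c(-h$ax, -h$ay, 1)
    nrm <- nrm / sqrt(sum(nrm^2))
    top_center <- c(h$cx, h$cy, h$height)
    fid[[i]] <- list(top_center = top_center, normal = nrm,
                     half_side = h$half_side,
                     target_point = top_center - 1.0 * nrm)
  }
  fiducials <- structure(list(markers = fid), class = "fiducial_set")

  vertices <- cbind(x = as.vector(X), y = as.vector(Y), z = as.vector(Z))
  faces <- heightfield_faces(ny, nx)

  relief_z <- Z
  for (i in seq_len(4)) {
    h <- holder[[i]]
    relief_z[abs(X - h$cx) <= h$half_side & abs(Y - h$cy) <= h$half_side] <- NA
  }
  roi <- list(lower = c(-28, -16, min(relief_z, na.rm = TRUE) - 1),
              upper = c(28, 16, max(relief_z, na.rm = TRUE) + 1))

  structure(list(
    mesh = list(vertices = vertices, faces = faces, albedo = as.vector(albedo)),
    fiducials = fiducials,
    roi = roi,
    albedo = albedo_base,
    seed = as.integer(seed), complexity = complexity, grid_step = grid_step
  ), class = "phantom_scene")
}

# fixed holder placement: distinct heights and tilt directions, outside the ROI
holder_layout <- function() {
  list(
    list(cx = -33, cy = -13, height = 6,  ax =  0.10, ay =  0.05,
         half_side = 4, disc_radius = 3),
    list(cx =  33, cy = -13, height = 8,  ax = -0.08, ay =  0.12,
         half_side = 4, disc_radius = 3),
    list(cx = -33, cy =  13, height = 10, ax =  0.05, ay = -0.14,
         half_side = 4, disc_radius = 3),
    list(cx =  33, cy =  13, height = 12, ax = -0.12, ay = -0.06,
         half_side = 4, disc_radius = 3)
  )
}

heightfield_faces <- function(ny, nx) {
  # two triangles per grid cell; vertices are column-major over (ny, nx)
  i <- rep(seq_len(ny - 1), times = nx - 1)
  j <- rep(seq_len(nx - 1), each = ny - 1)
  v00 <- (j - 1) * ny + i
  v01 <- j * ny + i
  v10 <- v00 + 1
  v11 <- v01 + 1
  out <- rbind(cbind(v00, v01, v11), cbind(v00, v11, v10))
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' @export
print.phantom_scene <- function(x, ...) {
  bb <- apply(x$mesh$vertices, 2, range)
  cat(sprintf(paste0("<phantom_scene> %d vertices, %d faces, bbox %.1f x %.1f x %.1f mm, ",
                     "4 fiducials, seed %d\n"),
              nrow(x$mesh$vertices), nrow(x$mesh$faces),
              diff(bb[, 1]), diff(bb[, 2]), diff(bb[, 3]), x$seed))
  invisible(x)
}

#' Area-weighted random samples from the phantom surface
#'
#' Draws `n_points` points uniformly by area over the mesh triangles
#' (triangle chosen with probability proportional to its area, then a uniform
#' barycentric draw). This plays the role of the dense CT-derived reference
#' point set.
#'
#' @param scene A `phantom_scene`.
#' @param n_points Number of samples (>= 1).
#' @param seed Integer seed.
#' @return A [point_cloud()] in the `ground_truth` frame.
#' @export
sample_ground_truth_cloud <- function(scene, n_points, seed = 0L) {
  stopifnot(inherits(scene, "phantom_scene"), n_points >= 1)
  V <- scene$mesh$vertices; F <- scene$mesh$faces
  if (is.null(V) || nrow(V) == 0 || is.null(F) || nrow(F) == 0) {
    stop("empty mesh", call. = FALSE)
  }
  local_seed(derive_seed(seed, 202))
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  cr <- cross_rows(B - A, C - A)
  area <- 0.5 * sqrt(rowSums(cr^2))
  idx <- sample.int(nrow(F), n_points, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n_points)); r2 <- stats::runif(n_points)
  w0 <- 1 - r1; w1 <- r1 * (1 - r2); w2 <- r1 * r2
  pts <- w0 * A[idx, , drop = FALSE] + w1 * B[idx, , drop = FALSE] +
    w2 * C[idx, , drop = FALSE]
  point_cloud(pts, frame = "ground_truth")
}

cross_rows <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Registration target points of a fiducial set
#'
#' Returns the sub-surface target of each marker (1 mm below the marker-top
#' center along the top normal) in fixed marker order — the ground-truth side
#' of the rigid registration correspondence.
#'
#' @param fiducials A `fiducial_set` (or a `phantom_scene`).
#' @return 4 x 3 numeric matrix, mm.
#' @export
fiducial_target_points <- function(fiducials) {
  if (inherits(fiducials, "phantom_scene")) fiducials <- fiducials$fiducials
  stopifnot(inherits(fiducials, "fiducial_set"))
  if (length(fiducials$markers) != 4) stop("expected 4 markers", call. = FALSE)
  do.call(rbind, lapply(fiducials$markers, function(m) m$target_point))
}

#' Save a phantom scene to disk (PLY mesh + JSON sidecar)
#'
#' @param scene A `phantom_scene`.
#' @param dir Output directory (created if missing).
#' @param binary_ply Write the mesh as binary little-endian PLY.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(scene, dir, binary_ply = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ply(scene$mesh$vertices, file.path(dir, "mesh.ply"),
            faces = scene$mesh$faces, binary = binary_ply)
  side <- list(
    fiducials = lapply(scene$fiducials$markers, function(m) {
      list(top_center = m$top_center, normal = m$normal,
           half_side = m$half_side, target_point = m$target_point)
    }),
    roi = scene$roi,
    albedo = scene$albedo,
    vertex_albedo = scene$mesh$albedo,
    seed = scene$seed, complexity = scene$complexity, grid_step = scene$grid_step
  )
  jsonlite::write_json(side, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' Load a phantom scene saved by [write_phantom()]
#' @param dir Directory holding `mesh.ply` and `scene.json`.
#' @return A `phantom_scene`.
#' @export
read_phantom <- function(dir) {
  ply <- read_ply(file.path(dir, "mesh.ply"))
  side <- jsonlite::read_json(file.path(dir, "scene.json"), simplifyVector = FALSE)
  markers <- lapply(side$fiducials, function(m) {
    list(top_center = as.numeric(unlist(m$top_center)),
         normal = as.numeric(unlist(m$normal)),
         half_side = as.numeric(m$half_side),
         target_point = as.numeric(unlist(m$target_point)))
  })
  vertices <- ply$vertices
  colnames(vertices) <- c("x", "y", "z")
  structure(list(
    mesh = list(vertices = vertices, faces = ply$faces,
                albedo = as.numeric(unlist(side$vertex_albedo))),
    fiducials = structure(list(markers = markers), class = "fiducial_set"),
    roi = list(lower = as.numeric(unlist(side$roi$lower)),
               upper = as.numeric(unlist(side$roi$upper))),
    albedo = as.numeric(side$albedo), seed = as.integer(side$seed),
    complexity = as.numeric(side$complexity),
    grid_step = as.numeric(side$grid_step)
  ), class = "phantom_scene")
}
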