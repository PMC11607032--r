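# file I/O: PGM images, PLY meshes/clouds, raw float depth maps with JSON header

#' Write an 8-bit grayscale image as PGM
#'
#' @param pixels Integer matrix (rows = image rows) with values 0-255, or a
#'   `pattern_image`.
#' @param path Output path.
#' @param ascii If TRUE write plain P2, otherwise binary P5.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(pixels, path, ascii = FALSE) {
  if (inherits(pixels, "pattern_image")) pixels <- pixels$pixels
  stopifnot(is.matrix(pixels))
  v <- as.integer(round(pixels))
  if (any(v < 0L | v > 255L)) stop("pixel values must be in [0, 255]", call. = FALSE)
  h <- nrow(pixels); w <- ncol(pixels)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    # row-major raster order
    write(t(pixels), file = con, ncolumns = w)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(as.vector(t(pixels))), con)
  }
  invisible(path)
}

#' Read a PGM image (P2 or P5)
#'
#' @param path File path.
#' @return Integer matrix of pixel values (rows = image rows).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # read header tokens, skipping comments
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop("unexpected end of PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (maxval > 255L) stop("only 8-bit PGM supported")
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a triangle mesh or point cloud as PLY
#'
#' @param vertices N x 3 matrix, mm. Data frames and `point_cloud`s accepted.
#' @param path Output path.
#' @param faces Optional M x 3 integer matrix of 1-based vertex indices.
#' @param binary If TRUE write binary_little_endian 1.0, else ascii 1.0.
#' @return `path`, invisibly.
#' @export
write_ply <- function(vertices, path, faces = NULL, binary = FALSE) {
  vertices <- as_points_matrix(vertices)
  n_v <- nrow(vertices)
  n_f <- if (is.null(faces)) 0L else nrow(faces)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c("ply", paste("format", fmt, "1.0"),
              paste("element vertex", n_v),
              "property float x", "property float y", "property float z")
  if (n_f > 0) {
    header <- c(header, paste("element face", n_f),
                "property list uchar int vertex_indices")
  }
  header <- c(header, "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(t(vertices)), con, size = 4, endian = "little")
    if (n_f > 0) {
      for (j in seq_len(n_f)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(faces[j, ] - 1L), con, size = 4, endian = "little")
      }
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.9g %.9g %.9g", vertices[, 1], vertices[, 2], vertices[, 3]), con)
    if (n_f > 0) {
      writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
    }
  }
  invisible(path)
}

#' Read a PLY mesh or point cloud (ascii or binary_little_endian)
#'
#' Supports float/double x,y,z vertex properties and uchar-counted int face
#' lists, which covers everything this package writes.
#'
#' @param path File path.
#' @return List with `vertices` (N x 3 matrix) and `faces` (M x 3, 1-based,
#'   or NULL).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_line <- function() {
    out <- character(0)
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("unexpected EOF in PLY header")
      if (ch == "\n") break
      out <- c(out, ch)
    }
    sub("\r$", "", paste(out, collapse = ""))
  }
  if (read_line() != "ply") stop("not a PLY file: ", path)
  fmt <- NULL; n_v <- 0L; n_f <- 0L
  v_props <- character(0); cur <- ""
  repeat {
    ln <- read_line()
    if (ln == "end_header") break
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (parts[1] == "format") fmt <- parts[2]
    if (parts[1] == "element") {
      cur <- parts[2]
      if (cur == "vertex") n_v <- as.integer(parts[3])
      if (cur == "face") n_f <- as.integer(parts[3])
    }
    if (parts[1] == "property" && cur == "vertex" && parts[2] != "list") {
      v_props <- c(v_props, parts[3])
    }
  }
  stopifnot(all(c("x", "y", "z") %in% v_props))
  np <- length(v_props)
  if (fmt == "ascii") {
    txt <- readLines(con)
    v_lines <- txt[seq_len(n_v)]
    vm <- matrix(scan(text = v_lines, what = numeric(), quiet = TRUE),
                 nrow = n_v, byrow = TRUE)
    vertices <- vm[, match(c("x", "y", "z"), v_props), drop = FALSE]
    faces <- NULL
    if (n_f > 0) {
      f_lines <- txt[n_v + seq_len(n_f)]
      fm <- matrix(scan(text = f_lines, what = integer(), quiet = TRUE),
                   nrow = n_f, byrow = TRUE)
      stopifnot(all(fm[, 1] == 3L))
      faces <- fm[, 2:4, drop = FALSE] + 1L
    }
  } else if (fmt == "binary_little_endian") {
    vm <- matrix(readBin(con, "numeric", n = n_v * np, size = 4, endian = "little"),
                 nrow = n_v, byrow = TRUE)
    vertices <- vm[, match(c("x", "y", "z"), v_props), drop = FALSE]
    faces <- NULL
    if (n_f > 0) {
      faces <- matrix(0L, n_f, 3)
      for (j in seq_len(n_f)) {
        cnt <- as.integer(readBin(con, "raw", 1))
        stopifnot(cnt == 3L)
        faces[j, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
      }
    }
  } else stop("unsupported PLY format: ", fmt)
  list(vertices = vertices, faces = faces)
}

#' Write a float matrix (depth or disparity map) as raw binary + JSON header
#'
#' @param values Numeric matrix; NA stored as the sentinel given in the header.
#' @param path Output path for the raw data; `<path>.json` holds the header.
#' @param sentinel Value substituted for NA (default -1e30).
#' @return `path`, invisibly.
#' @export
write_float_map <- function(values, path, sentinel = -1e30) {
  stopifnot(is.matrix(values))
  v <- as.numeric(t(values))
  v[is.na(v)] <- sentinel
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = 4, endian = "little")
  header <- list(rows = nrow(values), cols = ncol(values), dtype = "float32",
                 order = "row-major", sentinel = sentinel, version = 1L)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a float map written by [write_float_map()]
#' @param path Raw data path (expects `<path>.json` alongside).
#' @return Numeric matrix with sentinel values restored to NA.
#' @export
read_float_map <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = header$rows * header$cols, size = 4,
               endian = "little")
  # sentinel passed through float32, compare with relative tolerance
  v[abs(v - header$sentinel) <= abs(header$sentinel) * 1e-6] <- NA
  matrix(v, nrow = header$rows, ncol = header$cols, byrow = TRUE)
}
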