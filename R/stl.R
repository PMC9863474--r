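# Minimal STL surface I/O. Triangulated surfaces only, millimetre units
# assumed. Reader accepts ASCII and binary STL; writer emits ASCII.

#' Construct a triangulated surface mesh
#'
#' @param vertices Numeric n x 3 matrix of unique vertex coordinates (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `stl_mesh`.
#' @export
stl_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || nrow(vertices) < 1L) {
    stop("`vertices` must be an n x 3 matrix with n >= 1", call. = FALSE)
  }
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinate", call. = FALSE)
  if (nrow(faces) >= 1L) {
    if (ncol(faces) != 3L) stop("`faces` must be m x 3", call. = FALSE)
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("face index out of range", call. = FALSE)
    }
  }
  colnames(vertices) <- c("x", "y", "z")
  structure(list(vertices = vertices, faces = faces), class = "stl_mesh")
}

#' @export
print.stl_mesh <- function(x, ...) {
  cat(sprintf("<stl_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# collapse per-facet vertex triples into unique vertices + index faces
.index_triangles <- function(tri) {
  key <- apply(tri, 1L, paste, collapse = "\r")
  uk <- !duplicated(key)
  vertices <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  stl_mesh(vertices, faces)
}

#' Read a triangulated surface from an STL file
#'
#' Detects binary vs ASCII STL from the file structure (a binary file's
#' length is exactly 84 + 50 bytes per triangle), not from the header text.
#'
#' @param path Path to an STL file.
#' @return An `stl_mesh` with de-duplicated vertices and 1-based faces.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sz <- file.size(path)
  is_binary <- FALSE
  if (sz >= 84) {
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, 80)
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.numeric(ntri)) {
      is_binary <- TRUE
      if (ntri == 0L) stop("empty mesh: ", path, call. = FALSE)
      raw <- readBin(con, "raw", n = 50L * ntri)
      # per 50-byte record: 12 float32 (normal + 3 vertices) + 2 attr bytes
      payload <- matrix(raw, nrow = 50L)[1:48, , drop = FALSE]
      floats <- matrix(readBin(as.vector(payload), "double", n = 12L * ntri,
                               size = 4L, endian = "little"),
                       nrow = 12L)
      tri <- matrix(0, nrow = 3L * ntri, ncol = 3L)
      for (k in 1:3) tri[seq(k, by = 3L, length.out = ntri), ] <-
        t(floats[(3 * k + 1):(3 * k + 3), , drop = FALSE])
    }
    close(con)
    on.exit()
  }
  if (!is_binary) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^[[:space:]]*vertex[[:space:]]", lines, value = TRUE)
    if (!length(vlines)) stop("no triangles found in STL file: ", path,
                              call. = FALSE)
    if (length(vlines) %% 3L != 0L) {
      stop("malformed ASCII STL (vertex count not a multiple of 3): ", path,
           call. = FALSE)
    }
    tok <- strsplit(trimws(vlines), "[[:space:]]+")
    tri <- t(vapply(tok, function(t) suppressWarnings(as.numeric(t[2:4])),
                    numeric(3)))
    if (any(!is.finite(tri))) stop("non-finite vertex in STL file", call. = FALSE)
  }
  .index_triangles(tri)
}

#' Write a triangulated surface to an ASCII STL file
#'
#' Facet normals are recomputed from the vertex winding.
#'
#' @param mesh An `stl_mesh`.
#' @param path Output path.
#' @param name Solid name written in the header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "papvrscore") {
  stopifnot(inherits(mesh, "stl_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) < 1L) stop("mesh has no faces to write", call. = FALSE)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  fmt <- function(m, i) sprintf("%.9g %.9g %.9g", m[i, 1], m[i, 2], m[i, 3])
  out <- character(2L + 7L * nrow(f))
  out[1] <- paste("solid", name)
  pos <- 2L
  for (i in seq_len(nrow(f))) {
    out[pos:(pos + 6L)] <- c(
      paste("  facet normal", fmt(n, i)),
      "    outer loop",
      paste("      vertex", fmt(a, i)),
      paste("      vertex", fmt(b, i)),
      paste("      vertex", fmt(c_, i)),
      "    endloop",
      "  endfacet"
    )
    pos <- pos + 7L
  }
  out[pos] <- paste("endsolid", name)
  writeLines(out, path)
  invisible(path)
}
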