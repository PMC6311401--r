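#' Read an STL file
#'
#' Reads binary or ASCII stereolithography files, auto-detecting the
#' dialect.  Files beginning with `"solid"` are tentatively parsed as ASCII
#' but fall back to binary if no facet can be parsed (a common malformed
#' convention).  Per-facet vertices are merged with a `1e-6` mm tolerance so
#' downstream slicing sees a connected surface; degenerate faces are
#' dropped.
#'
#' @param path path to the STL file.
#' @return a [triangle_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fsize <- file.size(path)
  if (fsize < 15) stop("not an STL file (only ", fsize, " bytes)")
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = min(512, fsize))
  close(con)
  is_solid <- identical(rawToChar(head_raw[1:5]), "solid")
  mesh <- NULL
  if (is_solid) {
    mesh <- tryCatch(read_stl_ascii(path), error = function(e) NULL)
  }
  if (is.null(mesh)) mesh <- read_stl_binary(path)
  if (nrow(mesh$faces) == 0) stop("empty mesh in ", path)
  mesh
}

read_stl_binary <- function(path) {
  fsize <- file.size(path)
  if (fsize < 84) stop("malformed binary STL: header truncated at byte ",
                       fsize, " (need 84)")
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  count <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(count) || count < 0)
    stop("malformed binary STL: bad facet count at byte offset 80")
  need <- 84 + 50 * as.double(count)
  if (need > fsize)
    stop("malformed binary STL: declared ", count, " facets require ", need,
         " bytes but file ends at byte offset ", fsize)
  if (count == 0) stop("empty mesh (0 facets declared) in ", path)
  body <- readBin(con, "raw", n = 50 * count)
  # each 50-byte record: 12 little-endian float32 (normal + 3 vertices) + 2
  # attribute bytes; strip the attribute bytes then bulk-convert
  sel <- as.vector(outer(1:48, (0:(count - 1)) * 50, "+"))
  vals <- readBin(body[sel], "numeric", n = 12 * count, size = 4,
                  endian = "little")
  m <- matrix(vals, nrow = 12)
  verts <- matrix(as.vector(m[4:12, ]), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3 * count), ncol = 3, byrow = TRUE)
  merge_mesh_vertices(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL: vertex count ", length(vl),
         " is not a multiple of 3")
  parts <- strsplit(trimws(vl), "\\s+")
  coords <- vapply(parts, function(p) as.double(p[2:4]), numeric(3))
  if (any(!is.finite(coords))) stop("malformed ASCII STL: non-numeric vertex")
  verts <- t(coords)
  count <- nrow(verts) / 3
  faces <- matrix(seq_len(3 * count), ncol = 3, byrow = TRUE)
  merge_mesh_vertices(verts, faces)
}

#' Write an STL file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param dialect `"binary"` (default; 32-bit floats, so round-trips
#'   reproduce coordinates to about `1e-5` mm at tooth scale) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh")
  validate_mesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(f)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  len <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-300)
  normals <- cbind(nx, ny, nz) / len

  if (dialect == "binary") {
    rec <- rbind(t(normals),
                 t(v[f[, 1], , drop = FALSE]),
                 t(v[f[, 2], , drop = FALSE]),
                 t(v[f[, 3], , drop = FALSE]))  # 12 x n
    fl <- writeBin(as.double(as.vector(rec)), raw(), size = 4,
                   endian = "little")
    body <- matrix(as.raw(0), nrow = 50, ncol = n)
    body[1:48, ] <- matrix(fl, nrow = 48)
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "rootaxis binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    writeBin(as.vector(body), con)
  } else {
    fmt <- function(p) sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
    lines <- character(7 * n + 2)
    lines[1] <- "solid rootaxis"
    idx <- (seq_len(n) - 1) * 7 + 1
    lines[idx + 1] <- sprintf("  facet normal %.9g %.9g %.9g",
                              normals[, 1], normals[, 2], normals[, 3])
    lines[idx + 2] <- "    outer loop"
    lines[idx + 3] <- fmt(v[f[, 1], , drop = FALSE])
    lines[idx + 4] <- fmt(v[f[, 2], , drop = FALSE])
    lines[idx + 5] <- fmt(v[f[, 3], , drop = FALSE])
    lines[idx + 6] <- "    endloop"
    lines[idx + 7] <- "  endfacet"
    lines[7 * n + 2] <- "endsolid rootaxis"
    writeLines(lines, path)
  }
  invisible(path)
}
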