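#' Intersect a triangle mesh with a plane
#'
#' Computes the cross-section outlines of a mesh: each triangle crossing the
#' plane contributes one segment, and segments are chained into closed
#' loops.  Vertices lying exactly on the plane are perturbed by `+1e-9` mm
#' along the plane normal before intersection so every crossing triangle
#' yields exactly two edge intersections (robustness rule).
#'
#' Open chains (non-watertight meshes at the slice level) are closed by
#' joining their endpoints when the gap is below `0.5` mm, otherwise the
#' chain is discarded with a warning.
#'
#' @param mesh a [triangle_mesh()].
#' @param plane a [plane3d()].
#' @return list of [outline_loop()]s ordered by decreasing enclosed area;
#'   empty list when the plane misses the mesh.
#' @export
plane_mesh_intersection <- function(mesh, plane) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(plane, "plane3d"))
  v <- mesh$vertices
  n <- plane$normal
  d <- as.vector((v - matrix(plane$point, nrow(v), 3, byrow = TRUE)) %*% n)
  if (all(d > 0) || all(d < 0)) return(list())
  d[abs(d) < 1e-12] <- 1e-9

  f <- mesh$faces
  d1 <- d[f[, 1]]; d2 <- d[f[, 2]]; d3 <- d[f[, 3]]
  crossing <- (pmin(d1, d2, d3) < 0) & (pmax(d1, d2, d3) > 0)
  if (!any(crossing)) return(list())
  f <- f[crossing, , drop = FALSE]
  d1 <- d1[crossing]; d2 <- d2[crossing]; d3 <- d3[crossing]

  seg_edge_point <- function(ia, ib, da, db) {
    t <- da / (da - db)
    v[ia, , drop = FALSE] + t * (v[ib, , drop = FALSE] - v[ia, , drop = FALSE])
  }
  nseg <- nrow(f)
  p1 <- matrix(NA_real_, nseg, 3)
  p2 <- matrix(NA_real_, nseg, 3)
  c12 <- (d1 > 0) != (d2 > 0)
  c23 <- (d2 > 0) != (d3 > 0)
  c31 <- (d3 > 0) != (d1 > 0)
  fill <- function(mask, ia, ib, da, db) {
    if (!any(mask)) return(NULL)
    pts <- seg_edge_point(ia[mask], ib[mask], da[mask], db[mask])
    empty1 <- is.na(p1[mask, 1])
    w <- which(mask)
    p1[w[empty1], ] <<- pts[empty1, , drop = FALSE]
    p2[w[!empty1], ] <<- pts[!empty1, , drop = FALSE]
    NULL
  }
  fill(c12, f[, 1], f[, 2], d1, d2)
  fill(c23, f[, 2], f[, 3], d2, d3)
  fill(c31, f[, 3], f[, 1], d3, d1)
  ok <- !is.na(p1[, 1]) & !is.na(p2[, 1])
  p1 <- p1[ok, , drop = FALSE]; p2 <- p2[ok, , drop = FALSE]
  nseg <- nrow(p1)
  if (nseg == 0) return(list())

  # chain segments by matching endpoints (keyed on rounded coordinates)
  keytol <- 1e-7
  key_of <- function(p) paste(round(p[, 1] / keytol), round(p[, 2] / keytol),
                              round(p[, 3] / keytol))
  k1 <- key_of(p1); k2 <- key_of(p2)
  allk <- c(k1, k2)
  ends <- data.frame(key = allk, seg = rep(seq_len(nseg), 2),
                     side = rep(c(1L, 2L), each = nseg),
                     stringsAsFactors = FALSE)
  by_key <- split(seq_len(nrow(ends)), ends$key)

  used <- rep(FALSE, nseg)
  loops <- list()
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    used[s0] <- TRUE
    pts <- list(p1[s0, ], p2[s0, ])
    tail_key <- k2[s0]
    start_key <- k1[s0]
    closed <- FALSE
    repeat {
      cand <- by_key[[tail_key]]
      nxt <- NULL
      for (ei in cand) {
        s <- ends$seg[ei]
        if (used[s]) next
        nxt <- ei; break
      }
      if (is.null(nxt)) break
      s <- ends$seg[nxt]; side <- ends$side[nxt]
      used[s] <- TRUE
      if (side == 1L) { newp <- p2[s, ]; tail_key <- k2[s] }
      else           { newp <- p1[s, ]; tail_key <- k1[s] }
      if (tail_key == start_key) { closed <- TRUE; break }
      pts[[length(pts) + 1]] <- newp
    }
    P <- do.call(rbind, pts)
    if (!closed) {
      gap <- vnorm(P[1, ] - P[nrow(P), ])
      if (gap >= 0.5) {
        warning("discarding open cross-section chain with endpoint gap ",
                signif(gap, 3), " mm")
        next
      }
    }
    P <- P[!duplicated(key_of(P)), , drop = FALSE]
    if (nrow(P) < 3) next
    loops[[length(loops) + 1]] <- outline_loop(P, plane, tol = 1e-5)
  }
  if (length(loops) == 0) return(list())
  areas <- vapply(loops, loop_area, numeric(1))
  loops[order(areas, decreasing = TRUE)]
}

#' Equidistant landmarks along a closed outline
#'
#' Places `k` points at equal arc-length spacing (perimeter / k) along the
#' loop, emulating the equidistant outline landmarks digitized on each root
#' cross-section.  The start point is the loop vertex with the smallest x
#' coordinate (ties broken by smallest y, then z) so the placement is
#' deterministic.
#'
#' @param loop an [outline_loop()].
#' @param k number of landmarks, `k >= 3` (the root-axis workflow uses 4 or
#'   5 per outline).
#' @return k x 3 matrix of points on the outline.
#' @export
equidistant_landmarks <- function(loop, k) {
  k <- as.integer(k)
  if (k < 3) stop("k must be >= 3")
  loop_points_at_fractions(loop, (seq_len(k) - 1) / k)
}

#' Export outline loops to CSV
#'
#' Debug helper: writes one row per outline vertex with a loop id column.
#'
#' @param loops list of [outline_loop()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_outline_csv <- function(loops, path) {
  rows <- do.call(rbind, lapply(seq_along(loops), function(i) {
    p <- loops[[i]]$points
    data.frame(loop = i, x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# Points at arbitrary arc-length fractions along a loop, measured from the
# deterministic min-x start vertex.
loop_points_at_fractions <- function(loop, fracs) {
  stopifnot(inherits(loop, "outline_loop"))
  p <- loop$points
  start <- order(p[, 1], p[, 2], p[, 3])[1]
  if (start > 1) p <- rbind(p[start:nrow(p), , drop = FALSE],
                            p[1:(start - 1), , drop = FALSE])
  q <- rbind(p, p[1, , drop = FALSE])
  seglen <- sqrt(rowSums((q[-1, , drop = FALSE] - q[-nrow(q), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  per <- cum[length(cum)]
  targets <- (fracs %% 1) * per
  out <- matrix(NA_real_, length(targets), 3)
  for (i in seq_along(targets)) {
    s <- targets[i]
    j <- findInterval(s, cum, rightmost.closed = TRUE)
    j <- min(j, length(seglen))
    t <- if (seglen[j] > 0) (s - cum[j]) / seglen[j] else 0
    out[i, ] <- q[j, ] + t * (q[j + 1, ] - q[j, ])
  }
  out
}
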