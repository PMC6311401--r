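# Fixture builders: small meshes constructed in code.

# Axis-aligned cube [0, side]^3 as 12 triangles over 8 vertices.
cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side),
                             z = c(0, side)))
  # faces with outward orientation not required by the tests
  f <- rbind(c(1, 3, 2), c(2, 3, 4),    # z = 0
             c(5, 6, 7), c(6, 8, 7),    # z = side
             c(1, 2, 5), c(2, 6, 5),    # y = 0
             c(3, 7, 4), c(4, 7, 8),    # y = side
             c(1, 5, 3), c(3, 5, 7),    # x = 0
             c(2, 4, 6), c(4, 8, 6))    # x = side
  triangle_mesh(v, f)
}

# Watertight UV sphere centered at the origin.
uv_sphere_mesh <- function(r = 1, n_theta = 24, n_phi = 48) {
  th <- seq(0, pi, length.out = n_theta + 1)[2:n_theta]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[1:n_phi]
  g <- expand.grid(ph = ph, th = th)
  v <- cbind(r * sin(g$th) * cos(g$ph), r * sin(g$th) * sin(g$ph),
             r * cos(g$th))
  np <- nrow(v)
  v <- rbind(v, c(0, 0, r), c(0, 0, -r))
  idx <- function(i, j) (i - 1) * n_phi + ((j - 1) %% n_phi) + 1
  f <- list()
  for (i in 1:(n_theta - 2)) for (j in 1:n_phi) {
    f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  for (j in 1:n_phi) {
    f[[length(f) + 1]] <- c(np + 1, idx(1, j), idx(1, j + 1))
    f[[length(f) + 1]] <- c(np + 2, idx(n_theta - 1, j + 1),
                            idx(n_theta - 1, j))
  }
  triangle_mesh(v, do.call(rbind, f))
}

# Watertight torus: tube radius r about a circle of radius R in the x-y
# plane, central axis = z.
torus_mesh <- function(R = 3, r = 1, n_major = 48, n_minor = 24) {
  u <- 2 * pi * (seq_len(n_major) - 1) / n_major
  w <- 2 * pi * (seq_len(n_minor) - 1) / n_minor
  g <- expand.grid(w = w, u = u)
  v <- cbind((R + r * cos(g$w)) * cos(g$u),
             (R + r * cos(g$w)) * sin(g$u),
             r * sin(g$w))
  idx <- function(i, j) ((i - 1) %% n_major) * n_minor +
    ((j - 1) %% n_minor) + 1
  f <- list()
  for (i in 1:n_major) for (j in 1:n_minor) {
    f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  triangle_mesh(v, do.call(rbind, f))
}

# Circle outline in the z = 0 plane as a fine polygon.
circle_loop <- function(r = 1, n = 7200) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  outline_loop(cbind(r * cos(th), r * sin(th), 0),
               plane3d(c(0, 0, 0), c(0, 0, 1)))
}

# Points on rings of a cylinder about z (balanced placement: exact axis).
cylinder_ring_points <- function(n_levels = 10, per_level = 5, L = 12,
                                 r = 2) {
  z <- seq(-L / 2, L / 2, length.out = n_levels)
  do.call(rbind, lapply(seq_len(n_levels), function(i) {
    phi <- 2 * pi * (seq_len(per_level) - 1) / per_level + 0.1 * i
    cbind(r * cos(phi), r * sin(phi), z[i])
  }))
}

# A small crown arch (predicted frame) used by registration tests.
crown_arch_mesh <- function(labels = c(11, 12, 13, 21, 22, 23)) {
  teeth <- lapply(labels, function(l) generate_tooth(l))
  merged <- mapply(function(t) {
    rootaxis:::transform_mesh(rootaxis:::arch_placement(t$label, 7),
                              t$crown)
  }, teeth, SIMPLIFY = FALSE)
  rootaxis:::merge_meshes(merged)
}

expect_line_close <- function(a, b, tol_deg) {
  expect_lt(angle_between_lines(a, b), tol_deg)
}
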