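# Internal numerical helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

vnorm <- function(x) sqrt(sum(x * x))

normalize <- function(x) {
  n <- vnorm(x)
  if (n < 1e-300) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic sign convention for an undirected direction: between d and -d
# keep the lexicographically larger vector (first non-negligible component
# positive).
canonical_direction <- function(d, tol = 1e-12) {
  for (i in 1:3) {
    if (abs(d[i]) > tol) {
      if (d[i] < 0) d <- -d
      break
    }
  }
  d
}

# Rotation matrix about `axis` by `deg` degrees (Rodrigues).
rotation_about_axis <- function(axis, deg) {
  u <- normalize(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Orthonormal basis (u, v) spanning the plane perpendicular to unit vector w,
# chosen deterministically from w alone.
perp_basis <- function(w) {
  w <- normalize(w)
  e <- diag(3)[, which.min(abs(w))]
  u <- normalize(cross3(w, e))
  v <- cross3(w, u)
  list(u = u, v = v)
}

# Derive a child seed from a base seed and integer tags, staying < 2^31.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed %% 2147483647)
  for (t in tags) x <- (x * 48271 + as.double(t)) %% 2147483647
  as.integer(x + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
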