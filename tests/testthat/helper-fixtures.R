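# Shared fixtures and independent oracles. Heavy generator outputs are
# cached per test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

fixture_quad <- function() cached("quad", gen_quadruplex(quad_spec(), seed = 1))

fixture_traj <- function() cached("traj", {
  gen_trajectory(fixture_quad(), hydration_spec(seed = 3),
                 n_frames_per_state = 300, switch_state = "122D+")
})

# Brute-force minimal cross-pair distance: independent of the vectorized
# implementation (explicit double loop).
brute_min_distance <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt(sum((A[i, ] - B[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# Union-find connected components over a logical adjacency matrix.
union_find_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Brute-force Coulomb potential at a set of points (plain loops).
brute_potential <- function(pts, coords, q) {
  K <- 14.3996
  tot <- 0
  for (a in seq_len(nrow(pts))) {
    s <- 0
    for (k in seq_len(nrow(coords))) {
      r <- sqrt(sum((pts[a, ] - coords[k, ])^2))
      s <- s + q[k] * K / r
    }
    tot <- tot + s
  }
  tot / nrow(pts)
}

# Random rigid-body transform (rotation + translation).
random_rigid <- function() {
  r <- rnorm(3)
  th <- sqrt(sum(r^2)) %% pi
  k <- r / sqrt(sum(r^2))
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  list(R = R, t = rnorm(3, 0, 10))
}

transform_frame <- function(f, rig) {
  f$sites <- lapply(f$sites, function(s) {
    s$atoms <- sweep(s$atoms %*% t(rig$R), 2, -rig$t)
    s$nh <- s$atoms["NE1", ]
    s
  })
  if (nrow(f$waters) > 0)
    f$waters <- sweep(f$waters %*% t(rig$R), 2, -rig$t)
  f$groups <- lapply(f$groups, function(g)
    sweep(g %*% t(rig$R), 2, -rig$t))
  f
}

transform_atoms <- function(atoms, rig) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rig$R), 2, -rig$t)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}
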