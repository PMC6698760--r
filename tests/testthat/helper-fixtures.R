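# Shared fixtures: all built in code at test time.

options(kbdvh.verbose = FALSE)

# Small isotropic grid with voxel centers at integer mm (origin 0).
unit_grid <- function(shape = c(4, 4, 1), spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  volume_grid(shape, spacing, origin)
}

# Single-voxel target in the middle of a 5^3 unit grid.
point_target <- function() {
  g <- unit_grid(c(5, 5, 5))
  occ <- array(FALSE, dim = g$shape)
  occ[3, 3, 3] <- TRUE
  structure_mask(g, occ, "PTV", "target")
}

# Vectorized brute-force nearest-center distances: an independent O(N^2)
# oracle for the separable distance transform.
brute_force_signed_distance <- function(mask) {
  g <- mask$grid
  ax <- grid_axes(g)
  pts <- as.matrix(expand.grid(ax$x, ax$y, ax$z))
  rs <- rowSums(pts^2)
  min_dist_to <- function(sel) {
    sub <- pts[sel, , drop = FALSE]
    d2 <- outer(rs, rowSums(sub^2), "+") - 2 * pts %*% t(sub)
    sqrt(pmax(apply(d2, 1, min), 0))
  }
  occv <- as.vector(mask$occupancy)
  t <- numeric(length(occv))
  t[!occv] <- min_dist_to(occv)[!occv]
  t[occv] <- -min_dist_to(!occv)[occv]
  array(t, dim = g$shape)
}

# Literal double-Gaussian-sum conditional density (reflected at 0): the
# brute-force KDE oracle.
brute_force_conditional <- function(model, t_query, axis) {
  w <- exp(-0.5 * ((t_query - model$train_t) / model$h_t)^2)
  if (sum(w) == 0) {
    t_query <- min(max(t_query, min(model$train_t)), max(model$train_t))
    w <- exp(-0.5 * ((t_query - model$train_t) / model$h_t)^2)
  }
  w <- w / sum(w)
  vapply(axis, function(a)
    sum(w * (stats::dnorm(a, model$train_x, model$h_x) +
             stats::dnorm(-a, model$train_x, model$h_x))), 0.0)
}

# Random blob-like target on an n^3 grid (several fused random ellipsoids),
# for randomized distance-transform checks.
random_target <- function(n = 16, spacing = c(1, 1, 1), seed = 1) {
  g <- volume_grid(c(n, n, n), spacing, -spacing * (n - 1) / 2)
  ax <- grid_axes(g)
  occ <- array(FALSE, dim = g$shape)
  set.seed(seed)
  for (b in seq_len(3)) {
    ctr <- runif(3, -n / 4, n / 4) * spacing
    rad <- runif(3, n / 8, n / 3) * spacing
    q <- outer(outer(((ax$x - ctr[1]) / rad[1])^2,
                     ((ax$y - ctr[2]) / rad[2])^2, "+"),
               ((ax$z - ctr[3]) / rad[3])^2, "+")
    occ <- occ | (q <= 1)
  }
  if (!any(occ)) occ[n %/% 2, n %/% 2, n %/% 2] <- TRUE
  structure_mask(g, occ, "PTV", "target")
}

# A small trained model on synthetic smooth data, reused across KDE tests.
toy_model <- function(n = 120, seed = 3) {
  set.seed(seed)
  tt <- runif(n, -10, 40)
  xx <- pmax(0, 50 / (1 + exp((tt - 10) / 4)) + rnorm(n, 0, 1.5))
  kde_model("toy", tt, xx, h_t = 2.5, h_x = 1.2, x_max = 60)
}
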