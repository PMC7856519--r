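# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Volume of the lens-shaped intersection of two spheres of radii r1, r2 with
# centre distance a (standard closed form; full containment and disjoint
# cases handled).
lens_volume <- function(r1, r2, a) {
  if (a >= r1 + r2) return(0)
  if (a <= abs(r1 - r2)) {
    r <- min(r1, r2)
    return(4 / 3 * pi * r^3)
  }
  pi * (r1 + r2 - a)^2 *
    (a^2 + 2 * a * r2 - 3 * r2^2 + 2 * a * r1 + 6 * r1 * r2 - 3 * r1^2) /
    (12 * a)
}

# Naive per-voxel, per-time-point accumulation: for every voxel centre,
# count the time points at which it lies within diameter/2 of the aperture
# centre (CTV centroid + error). Independent of the engine's bounding-box
# pass; plain loop over voxels.
brute_accumulate <- function(ctv_mask, spacing, origin, errors, diameter) {
  dims <- dim(ctv_mask)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 0.5) * spacing[a])
  idx <- which(ctv_mask, arr.ind = TRUE)
  c0 <- c(
    mean(ax[[1]][idx[, 1]]), mean(ax[[2]][idx[, 2]]), mean(ax[[3]][idx[, 3]])
  )
  r2 <- (diameter / 2)^2
  counts <- array(0L, dims)
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      for (k in seq_len(dims[3])) {
        dx <- ax[[1]][i] - (c0[1] + errors[, 1])
        dy <- ax[[2]][j] - (c0[2] + errors[, 2])
        dz <- ax[[3]][k] - (c0[3] + errors[, 3])
        counts[i, j, k] <- sum(dx^2 + dy^2 + dz^2 <= r2)
      }
    }
  }
  counts
}

# Brute-force Euclidean-distance dilation: output voxel set iff its centre
# is within `margin` of the centre of any set input voxel (same grid).
brute_dilate <- function(mask, spacing, margin) {
  dims <- dim(mask)
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing[a])
  idx <- which(mask, arr.ind = TRUE)
  P <- cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]], ax[[3]][idx[, 3]])
  out <- array(FALSE, dims)
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      for (k in seq_len(dims[3])) {
        d2 <- (P[, 1] - ax[[1]][i])^2 + (P[, 2] - ax[[2]][j])^2 +
          (P[, 3] - ax[[3]][k])^2
        out[i, j, k] <- any(d2 <= margin^2)
      }
    }
  }
  out
}

# Max pairwise distance between surface points by direct double loop.
brute_feret <- function(P) {
  best <- 0
  for (i in seq_len(nrow(P) - 1)) {
    d2 <- (P[-(1:i), 1] - P[i, 1])^2 + (P[-(1:i), 2] - P[i, 2])^2 +
      (P[-(1:i), 3] - P[i, 3])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# Exact two-sided p-value of the Wilcoxon signed-rank statistic by full
# enumeration of the 2^n sign assignments (no ties assumed).
enumerate_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% rk
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  list(V = v_obs, p = min(1, 2 * min(p_low, p_high)))
}

# Spearman rho from the definition: Pearson correlation of midranks.
spearman_direct <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Re-embed a structure mask onto a compatible (larger) grid.
embed_mask_for_test <- function(s, grid) irisopt:::embed_mask(s, grid)

# Small random structure + trace pair for property tests.
random_phantom_trace <- function(seed, spacing = 2) {
  withr::with_seed(seed, {
    semi <- sort(runif(3, 8, 22), decreasing = TRUE)
    ctv <- make_ellipsoid_phantom(semi_axes = semi, spacing = spacing,
                                  label = "CTV")
    trace <- simulate_trace(
      sd = runif(3, 0.3, 2), n_points_per_fraction = 10,
      n_fractions = 3, seed = seed + 1000
    )
    list(ctv = ctv, ptv = expand_margin(ctv, 4), trace = trace)
  })
}
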