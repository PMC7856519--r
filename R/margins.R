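#' Isotropic Euclidean margin expansion
#'
#' Dilates a structure by a Euclidean ball: a voxel is set in the output iff
#' its centre lies within `margin` mm of the centre of any set input voxel.
#' This is the standard clinical margin chain GTV -> CTV (2 mm, microscopic
#' extension) -> PTV (4 mm, delivery uncertainty). If the expanded structure
#' would touch the grid boundary, the grid is first enlarged by
#' `ceiling(margin / spacing) + 1` voxels per face (origin shifted
#' accordingly), so the dilation is never clipped.
#'
#' @param s A [structure_mask()].
#' @param margin Margin in mm (>= 0). `margin = 0` returns the input mask
#'   (possibly relabelled).
#' @param label Label for the expanded structure. Defaults to the next label
#'   in the GTV -> CTV -> PTV chain when applicable, else `"other"`.
#' @return A [structure_mask()] that is a superset of the input.
#' @examples
#' gtv <- make_sphere_phantom(radius = 10, label = "GTV")
#' ctv <- expand_margin(gtv, 2)
#' ptv <- expand_margin(ctv, 4)
#' volume_cm3(ptv) # ~ (4/3) * pi * 1.6^3 cm^3
#' @export
expand_margin <- function(s, margin, label = NULL) {
  stopifnot(inherits(s, "structure_mask"))
  if (!is.numeric(margin) || length(margin) != 1L || !is.finite(margin) ||
      margin < 0) {
    stop("`margin` must be a single non-negative number", call. = FALSE)
  }
  if (is.null(label)) {
    label <- switch(s$label, GTV = "CTV", CTV = "PTV", "other")
  }
  if (margin == 0) return(structure_mask(s$grid, s$mask, label))

  pad <- as.integer(ceiling(margin / s$grid$spacing)) + 1L
  grid <- voxel_grid(
    spacing = s$grid$spacing,
    origin = s$grid$origin - pad * s$grid$spacing,
    dims = s$grid$dims + 2L * pad
  )
  base <- array(FALSE, dim = grid$dims)
  base[
    pad[1] + seq_len(s$grid$dims[1]),
    pad[2] + seq_len(s$grid$dims[2]),
    pad[3] + seq_len(s$grid$dims[3])
  ] <- s$mask

  # Ball structuring element as integer voxel offsets within `margin`.
  off <- lapply(1:3, function(a) {
    r <- floor(margin / s$grid$spacing[a])
    (-r):r
  })
  og <- expand.grid(i = off[[1]], j = off[[2]], k = off[[3]])
  d2 <- (og$i * s$grid$spacing[1])^2 + (og$j * s$grid$spacing[2])^2 +
    (og$k * s$grid$spacing[3])^2
  og <- og[d2 <= margin^2, , drop = FALSE]

  out <- array(FALSE, dim = grid$dims)
  nd <- grid$dims
  for (r in seq_len(nrow(og))) {
    sh <- c(og$i[r], og$j[r], og$k[r])
    dst <- lapply(1:3, function(a) {
      seq_len(nd[a] - abs(sh[a])) + max(sh[a], 0L)
    })
    src <- lapply(1:3, function(a) {
      seq_len(nd[a] - abs(sh[a])) + max(-sh[a], 0L)
    })
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] |
      base[src[[1]], src[[2]], src[[3]]]
  }
  structure_mask(grid, out, label)
}

# Surface voxels: set voxels with an unset 6-neighbour or on the array edge.
surface_coords <- function(s) {
  m <- s$mask
  d <- dim(m)
  interior <- array(TRUE, dim = d)
  shift_and <- function(acc, axis, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    n <- d[axis]
    idx[[axis]] <- seq_len(n - 1L) + (if (by > 0) 0L else 1L)
    src[[axis]] <- idx[[axis]] + by
    nb <- array(FALSE, dim = d)  # edge voxels have an "outside" neighbour
    nb[idx[[1]], idx[[2]], idx[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    acc & nb
  }
  for (axis in 1:3) {
    interior <- shift_and(interior, axis, 1L)
    interior <- shift_and(interior, axis, -1L)
  }
  surf <- m & !interior
  ax <- grid_axes(s$grid)
  idx <- which(surf, arr.ind = TRUE)
  cbind(ax$lr[idx[, 1]], ax$ap[idx[, 2]], ax$si[idx[, 3]])
}

# Max pairwise distance between rows of P (n x 3), with the maximizing pair.
# Blocked so the n x n distance matrix is never fully materialized.
max_pairwise <- function(P, block = 512L) {
  n <- nrow(P)
  nrm <- rowSums(P^2)
  best <- c(d2 = 0, i = 1L, j = 1L)
  for (lo in seq(1L, n, by = block)) {
    hi <- min(lo + block - 1L, n)
    G <- P[lo:hi, , drop = FALSE] %*% t(P)
    D2 <- outer(nrm[lo:hi], nrm, `+`) - 2 * G
    w <- arrayInd(which.max(D2), dim(D2))
    if (D2[w] > best["d2"]) {
      best <- c(d2 = D2[w], i = lo + w[1] - 1L, j = w[2])
    }
  }
  list(dist = sqrt(max(best["d2"], 0)), i = best[["i"]], j = best[["j"]])
}

#' Long- and short-axis lengths of a structure
#'
#' Characterizes a target's extent by two clinically-read lengths: `a_max`,
#' the maximum Feret diameter (largest pairwise distance between surface
#' voxel centres, plus one voxel spacing so a sphere of diameter d measures
#' d rather than d minus one spacing), and `a_min`, the minimum width of the
#' structure's projection onto the plane orthogonal to the long-axis
#' direction (rotating-calipers width over the projected convex hull, plus
#' one voxel spacing). These feed the candidate aperture interval
#' `[0.5 * a_min, a_max + 5]` of the collimator optimizer.
#'
#' A single-voxel structure reports both lengths equal to the voxel spacing
#' (keeping `a_min > 0`). Assumes isotropic spacing (the supported case);
#' with anisotropic spacing the one-voxel padding uses the mean spacing.
#'
#' @param s A non-empty [structure_mask()].
#' @return A one-row tibble with columns `a_max`, `a_min` (mm).
#' @examples
#' axis_lengths(make_ellipsoid_phantom(semi_axes = c(28.4, 18.18, 18.18)))
#' @export
axis_lengths <- function(s) {
  stopifnot(inherits(s, "structure_mask"))
  if (!any(s$mask)) stop("empty mask has no axis lengths", call. = FALSE)
  pad <- mean(s$grid$spacing)
  P <- surface_coords(s)
  if (nrow(P) == 1L) {
    return(tibble(a_max = pad, a_min = pad))
  }
  mp <- max_pairwise(P)
  a_max <- mp$dist + pad

  # Orthonormal basis (v, w) of the plane orthogonal to the long axis.
  u <- (P[mp$i, ] - P[mp$j, ]) / mp$dist
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
  Q <- P %*% cbind(v, w)
  a_min <- projection_min_width(Q) + pad
  tibble(a_max = a_max, a_min = min(a_min, a_max))
}

# Minimal width of a 2D point set: rotating calipers over the convex hull
# (min over hull edges of the max vertex distance from the edge line).
projection_min_width <- function(Q) {
  Q <- unique(Q)
  if (nrow(Q) < 3L) {
    if (nrow(Q) < 2L) return(0)
    return(0)  # collinear after dedup: zero width
  }
  h <- grDevices::chull(Q)
  H <- Q[h, , drop = FALSE]
  nh <- nrow(H)
  if (nh < 3L) return(0)
  widths <- vapply(seq_len(nh), function(e) {
    a <- H[e, ]
    b <- H[if (e == nh) 1L else e + 1L, ]
    ed <- b - a
    len <- sqrt(sum(ed^2))
    if (len < .Machine$double.eps) return(Inf)
    # distance of all hull points from the line through a, b
    max(abs((Q[, 1] - a[1]) * ed[2] - (Q[, 2] - a[2]) * ed[1]) / len)
  }, numeric(1))
  min(widths)
}
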