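#' Accumulate per-voxel coverage and leakage over a motion trace
#'
#' For every imaging time point the collimator field is modelled as a ball of
#' the nominal `diameter` centred on the predicted target position.
#' Accumulation works in the target frame: the CTV stays fixed and the
#' aperture centre is displaced from the CTV centroid by the per-point
#' tracking error `e = pred - true` (only the relative displacement between
#' aperture and target matters for the intersection). A voxel is inside the
#' aperture iff its centre is within `diameter / 2` of the aperture centre
#' (no partial-volume weighting).
#'
#' The coverage possibility of a CTV voxel is the fraction of time points
#' (pooled over all fractions, equal weight) at which it lies inside the
#' aperture; the leakage possibility of a non-CTV voxel is the same fraction
#' on its side of the CTV boundary. The evaluation grid is auto-padded so
#' that the ball at every error offset fits inside it.
#'
#' @param ctv CTV [structure_mask()] (non-empty).
#' @param trace A `motion_trace`.
#' @param diameter Aperture diameter in mm (> 0).
#' @return A list with elements `coverage` (a `coverage_map`: values on CTV
#'   voxels) and `leakage` (a `leakage_map`: values on non-CTV voxels that
#'   entered the aperture at least once). Both carry the padded grid, the
#'   full per-voxel fraction array `values`, a logical `domain` array and
#'   `n_points`.
#' @examples
#' ctv <- make_sphere_phantom(radius = 10, spacing = 2)
#' tr <- simulate_trace(sd = c(1.2, 0.6, 0.9), seed = 1)
#' maps <- accumulate(ctv, tr, diameter = 25)
#' maps$coverage$n_points
#' @export
accumulate <- function(ctv, trace, diameter) {
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0) {
    stop("`diameter` must be a single positive number", call. = FALSE)
  }
  acc <- accumulate_counts(ctv, trace, diameter)
  maps_from_counts(acc, 1L)
}

# Shared multi-diameter accumulation: one pass over the trace computes the
# per-voxel squared distance field per time point and thresholds it at every
# candidate radius, so evaluating the full Iris set costs little more than
# one diameter. Returns grid, ctv mask on the padded grid, integer count
# arrays per diameter, and n_points.
accumulate_counts <- function(ctv, trace, diameters) {
  stopifnot(inherits(ctv, "structure_mask"), inherits(trace, "motion_trace"))
  if (!any(ctv$mask)) stop("CTV mask is empty", call. = FALSE)
  diameters <- sort(as.numeric(diameters))
  E <- trace_errors(trace)
  n_pts <- nrow(E)
  rmax <- max(diameters) / 2

  # Pad so every aperture ball fits: CTV extent + rmax + max |e| + 1 voxel,
  # per axis (the leakage support follows the aperture wherever it lands).
  emax <- apply(abs(E), 2, max)
  pad_mm <- rmax + emax + ctv$grid$spacing
  pad <- as.integer(ceiling(pad_mm / ctv$grid$spacing)) + 1L
  grid <- voxel_grid(
    spacing = ctv$grid$spacing,
    origin = ctv$grid$origin - pad * ctv$grid$spacing,
    dims = ctv$grid$dims + 2L * pad
  )
  cmask <- array(FALSE, dim = grid$dims)
  cmask[
    pad[1] + seq_len(ctv$grid$dims[1]),
    pad[2] + seq_len(ctv$grid$dims[2]),
    pad[3] + seq_len(ctv$grid$dims[3])
  ] <- ctv$mask

  ax <- grid_axes(grid)
  c0 <- mask_centroid(structure_mask(grid, cmask, ctv$label))
  counts <- lapply(diameters, function(d) array(0L, dim = grid$dims))
  r2 <- (diameters / 2)^2

  for (t in seq_len(n_pts)) {
    ctr <- c0 + E[t, ]
    rng <- lapply(1:3, function(a) which(abs(ax[[a]] - ctr[a]) <= rmax))
    if (any(lengths(rng) == 0)) next
    d2 <- outer(
      outer((ax[[1]][rng[[1]]] - ctr[1])^2, (ax[[2]][rng[[2]]] - ctr[2])^2,
            `+`),
      (ax[[3]][rng[[3]]] - ctr[3])^2, `+`
    )
    for (k in seq_along(diameters)) {
      counts[[k]][rng[[1]], rng[[2]], rng[[3]]] <-
        counts[[k]][rng[[1]], rng[[2]], rng[[3]]] + (d2 <= r2[k])
    }
  }
  list(
    grid = grid, ctv_mask = cmask, diameters = diameters,
    counts = counts, n_points = n_pts
  )
}

maps_from_counts <- function(acc, k) {
  values <- acc$counts[[k]] / acc$n_points
  coverage <- structure(
    list(
      grid = acc$grid, values = values, domain = acc$ctv_mask,
      n_points = acc$n_points, diameter = acc$diameters[k]
    ),
    class = "coverage_map"
  )
  leakage <- structure(
    list(
      grid = acc$grid, values = values,
      domain = !acc$ctv_mask & acc$counts[[k]] > 0L,
      n_points = acc$n_points, diameter = acc$diameters[k]
    ),
    class = "leakage_map"
  )
  list(coverage = coverage, leakage = leakage)
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(
    "<coverage_map> diameter ", x$diameter, " mm, ", x$n_points,
    " time points, ", sum(x$domain), " target voxels\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.leakage_map <- function(x, ...) {
  cat(
    "<leakage_map> diameter ", x$diameter, " mm, ", x$n_points,
    " time points, ", sum(x$domain), " support voxels\n",
    sep = ""
  )
  invisible(x)
}

# Embed a structure mask into a (larger) grid with identical spacing and
# voxel-centre alignment; errors out on mismatch.
embed_mask <- function(s, grid) {
  if (max(abs(s$grid$spacing - grid$spacing)) > 1e-9) {
    stop("grid spacing mismatch", call. = FALSE)
  }
  off <- (s$grid$origin - grid$origin) / grid$spacing
  if (max(abs(off - round(off))) > 1e-6) {
    stop("grids are not voxel-aligned", call. = FALSE)
  }
  off <- as.integer(round(off))
  if (any(off < 0L) || any(off + s$grid$dims > grid$dims)) {
    stop("structure does not fit inside the target grid", call. = FALSE)
  }
  out <- array(FALSE, dim = grid$dims)
  out[
    off[1] + seq_len(s$grid$dims[1]),
    off[2] + seq_len(s$grid$dims[2]),
    off[3] + seq_len(s$grid$dims[3])
  ] <- s$mask
  out
}

#' Restrict a coverage map to an evaluation structure
#'
#' Keeps the per-voxel aperture-inclusion fractions only on the voxels of
#' `eval_structure` (e.g. the PTV instead of the CTV). PTV voxels outside
#' the CTV are scored by aperture inclusion alone, so C95/C90 of both CTV
#' and PTV can be read from a single accumulation. The structure must live
#' on a grid with the same spacing and voxel alignment as the map.
#'
#' @param map A `coverage_map`.
#' @param eval_structure A [structure_mask()].
#' @return A `coverage_map` whose domain is `eval_structure`.
#' @export
coverage_on_structure <- function(map, eval_structure) {
  stopifnot(inherits(map, "coverage_map"),
            inherits(eval_structure, "structure_mask"))
  dom <- embed_mask(eval_structure, map$grid)
  structure(
    list(
      grid = map$grid, values = map$values, domain = dom,
      n_points = map$n_points, diameter = map$diameter
    ),
    class = "coverage_map"
  )
}

# Raw possibility values on a map's domain (numeric vector).
map_values <- function(map) map$values[map$domain]
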