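#' Regular voxel grid
#'
#' A regular, axis-aligned 3D voxel grid. The world coordinate (mm) of the
#' centre of voxel `(i, j, k)` (1-based) is `origin + (i - 0.5) * spacing`
#' per axis, i.e. the voxel-centre convention with `origin` at the outer
#' corner of the first voxel. Axes are ordered (LR, AP, SI).
#'
#' @param spacing Voxel edge length in mm; a positive scalar (isotropic) or
#'   length-3 vector.
#' @param origin Corner of the grid in mm (length-3, defaults to the origin).
#' @param dims Number of voxels per axis (length-3 positive integers).
#' @return A `voxel_grid` object.
#' @examples
#' voxel_grid(1, dims = c(64, 64, 64))
#' @export
voxel_grid <- function(spacing, origin = c(0, 0, 0), dims) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  dims <- rep_len(as.integer(dims), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be positive and finite on every axis", call. = FALSE)
  }
  if (any(is.na(dims)) || any(dims < 1L)) {
    stop("`dims` must be positive integers", call. = FALSE)
  }
  structure(
    list(spacing = spacing, origin = origin, dims = dims),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(
    "<voxel_grid> ", paste(x$dims, collapse = " x "),
    " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
    ") mm, origin (", paste(format(x$origin), collapse = ", "), ") mm\n",
    sep = ""
  )
  invisible(x)
}

#' Voxel-centre coordinates of a grid
#'
#' @param grid A [voxel_grid()].
#' @return A list with numeric vectors `lr`, `ap`, `si` of voxel-centre world
#'   coordinates (mm) along each axis.
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  ax <- lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(grid$dims[a]) - 0.5) * grid$spacing[a]
  })
  names(ax) <- .axis_names
  ax
}

#' @rdname grid_axes
#' @return For `voxel_volume_mm3()`, the volume of one voxel in mm^3.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' Binary structure mask on a voxel grid
#'
#' Carries a target structure (GTV, CTV, PTV, ...) as a per-voxel binary
#' indicator. Structures used in coverage evaluation must be non-empty.
#'
#' @param grid A [voxel_grid()].
#' @param mask Logical (or 0/1) array with `dim(mask) == grid$dims`.
#' @param label Structure label; one of `"GTV"`, `"CTV"`, `"PTV"`, `"other"`.
#' @return A `structure_mask` object.
#' @export
structure_mask <- function(grid, mask, label = "other") {
  stopifnot(inherits(grid, "voxel_grid"))
  mask <- array(as.logical(mask), dim = grid$dims)
  if (anyNA(mask)) stop("mask contains missing values", call. = FALSE)
  label <- match.arg(label, c("GTV", "CTV", "PTV", "other"))
  structure(
    list(grid = grid, mask = mask, label = label),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(
    "<structure_mask> ", x$label, ": ", sum(x$mask), " voxels, ",
    format(volume_cm3(x), digits = 4), " cm^3 on ",
    paste(x$grid$dims, collapse = " x "), " grid\n",
    sep = ""
  )
  invisible(x)
}

#' Structure volume in cm^3
#'
#' @param s A [structure_mask()].
#' @return Volume of the set voxels in cm^3.
#' @export
volume_cm3 <- function(s) {
  stopifnot(inherits(s, "structure_mask"))
  sum(s$mask) * voxel_volume_mm3(s$grid) / 1000
}

# Coordinates (n x 3 matrix, mm) of the set voxels of a mask.
mask_coords <- function(s) {
  ax <- grid_axes(s$grid)
  idx <- which(s$mask, arr.ind = TRUE)
  cbind(
    lr = ax$lr[idx[, 1]],
    ap = ax$ap[idx[, 2]],
    si = ax$si[idx[, 3]]
  )
}

# Centroid (mm) of the set voxels.
mask_centroid <- function(s) colMeans(mask_coords(s))

# Default grid tightly enclosing a centred shape of half-extent `half` (mm),
# padded by `pad` mm per face.
auto_grid <- function(center, half, spacing, pad = 2) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  half <- rep_len(as.numeric(half), 3L)
  dims <- pmax(1L, as.integer(ceiling(2 * (half + pad) / spacing)))
  dims <- dims + (dims %% 2L == 0L)  # odd counts put `center` on a voxel centre
  origin <- center - dims / 2 * spacing
  voxel_grid(spacing, origin, dims)
}

#' Spherical and ellipsoidal target phantoms
#'
#' Voxelizes a sphere (or axis-aligned ellipsoid) on a grid: a voxel is set
#' iff its centre lies inside the analytic shape. With `grid = NULL` a tight
#' isotropic grid enclosing the shape (plus a small pad) is built
#' automatically.
#'
#' @param grid A [voxel_grid()], or `NULL` to build one.
#' @param center Shape centre in mm (length-3).
#' @param radius Sphere radius in mm (> 0).
#' @param semi_axes Ellipsoid semi-axis lengths in mm (length-3, all > 0),
#'   ordered (LR, AP, SI).
#' @param spacing Voxel spacing used when `grid = NULL` (mm, default 1).
#' @param label Structure label for the result.
#' @return A [structure_mask()].
#' @examples
#' ctv <- make_sphere_phantom(radius = 10)
#' volume_cm3(ctv)
#' @export
make_sphere_phantom <- function(grid = NULL, center = c(0, 0, 0), radius,
                                spacing = 1, label = "CTV") {
  if (!is.numeric(radius) || radius <= 0) {
    stop("`radius` must be > 0", call. = FALSE)
  }
  make_ellipsoid_phantom(
    grid = grid, center = center, semi_axes = rep(radius, 3),
    spacing = spacing, label = label
  )
}

#' @rdname make_sphere_phantom
#' @export
make_ellipsoid_phantom <- function(grid = NULL, center = c(0, 0, 0), semi_axes,
                                   spacing = 1, label = "CTV") {
  semi_axes <- rep_len(as.numeric(semi_axes), 3L)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0)) {
    stop("all `semi_axes` must be > 0", call. = FALSE)
  }
  center <- rep_len(as.numeric(center), 3L)
  if (is.null(grid)) grid <- auto_grid(center, semi_axes, spacing)
  ax <- grid_axes(grid)
  u2 <- lapply(1:3, function(a) ((ax[[a]] - center[a]) / semi_axes[a])^2)
  q <- outer(outer(u2[[1]], u2[[2]], `+`), u2[[3]], `+`)
  mask <- q <= 1
  if (!any(mask)) {
    stop("shape does not intersect the grid: empty mask", call. = FALSE)
  }
  structure_mask(grid, mask, label)
}
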