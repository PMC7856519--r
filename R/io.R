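#' Read and write structure masks as NIfTI volumes
#'
#' Masks are exchanged as NIfTI-1 images (`.nii` / `.nii.gz`): nonzero voxel
#' values mean "inside"; grid spacing comes from the header `pixdim` and the
#' grid origin from the translation column of the sform/qform, converted to
#' the package's corner-origin voxel-centre convention (NIfTI places the
#' stored translation at the centre of the first voxel).
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param label Structure label assigned on read.
#' @param s A [structure_mask()] to write.
#' @return `read_mask()` returns a [structure_mask()]; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path, label = "other") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D NIfTI volume, got ", length(dim(arr)), "D",
      call. = FALSE
    )
  }
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))  # rotation column norms
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  if (any(diag(xf[1:3, 1:3]) < 0)) {
    stop("flipped/rotated NIfTI orientations are not supported; ",
         "expecting an axis-aligned positive-diagonal transform",
         call. = FALSE)
  }
  center1 <- xf[1:3, 4]  # world position of the first voxel centre
  grid <- voxel_grid(spacing, origin = center1 - spacing / 2, dims = dim(arr))
  structure_mask(grid, arr != 0, label)
}

#' @rdname read_mask
#' @export
write_mask <- function(s, path) {
  stopifnot(inherits(s, "structure_mask"))
  img <- RNifti::asNifti(array(as.integer(s$mask), dim = s$grid$dims))
  sp <- s$grid$spacing
  RNifti::pixdim(img) <- sp
  xf <- diag(c(sp, 1))
  xf[1:3, 4] <- s$grid$origin + sp / 2
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a coverage or leakage map as a NIfTI volume
#'
#' Voxel values are the accumulated coverage/leakage possibilities in
#' \[0, 1\]; voxels outside the map's structure/support are written as 0.
#'
#' @param map A `coverage_map` or `leakage_map` from [accumulate()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, c("coverage_map", "leakage_map")))
  vals <- map$values
  vals[!map$domain] <- 0
  img <- RNifti::asNifti(vals)
  sp <- map$grid$spacing
  RNifti::pixdim(img) <- sp
  xf <- diag(c(sp, 1))
  xf[1:3, 4] <- map$grid$origin + sp / 2
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
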