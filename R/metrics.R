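#' Cumulative coverage- and leakage-volume histograms
#'
#' The CVH is the coverage analogue of a cumulative DVH: for each coverage
#' level c in \[0, 1\], the percent of the evaluation structure's volume
#' whose voxels achieve coverage possibility >= c. The LVH is its leakage
#' counterpart on an absolute scale: the volume in cm^3 of non-target voxels
#' with leakage possibility >= l. Curves are discretized on `n_levels`
#' evenly spaced levels; all scalar metrics ([coverage_at_volume()],
#' [hist_auc()]) are computed from the raw voxel values carried alongside,
#' so they do not depend on the discretization.
#'
#' @param map A `coverage_map` (for `build_cvh`) or `leakage_map` (for
#'   `build_lvh`) from [accumulate()].
#' @param eval_structure Optional [structure_mask()] to restrict the coverage
#'   map to (see [coverage_on_structure()]) before building the CVH.
#' @param n_levels Number of levels on \[0, 1\] (default 1001).
#' @return A tibble with columns `level` and `volume_pct` (CVH, percent of
#'   structure volume) or `volume_cm3` (LVH, absolute volume), classed
#'   `"cvh"` / `"lvh"`, carrying the raw values and voxel volume as
#'   attributes.
#' @examples
#' ctv <- make_sphere_phantom(radius = 10, spacing = 2)
#' tr <- simulate_trace(sd = c(1.2, 0.6, 0.9), seed = 1)
#' maps <- accumulate(ctv, tr, diameter = 25)
#' cvh <- build_cvh(maps$coverage)
#' coverage_at_volume(cvh, 95)
#' @export
build_cvh <- function(map, eval_structure = NULL, n_levels = 1001) {
  stopifnot(inherits(map, "coverage_map"))
  if (!is.null(eval_structure)) {
    map <- coverage_on_structure(map, eval_structure)
  }
  v <- map_values(map)
  if (length(v) == 0) stop("evaluation structure is empty", call. = FALSE)
  level <- seq(0, 1, length.out = n_levels)
  volume_pct <- 100 * (1 - ecdf_left(v, level))
  out <- tibble(level = level, volume_pct = volume_pct)
  structure(
    out,
    class = c("cvh", class(out)),
    values = v,
    voxel_volume_cm3 = voxel_volume_mm3(map$grid) / 1000
  )
}

#' @rdname build_cvh
#' @export
build_lvh <- function(map, n_levels = 1001) {
  stopifnot(inherits(map, "leakage_map"))
  v <- map_values(map)  # may be empty: LVH is then identically 0
  vv <- voxel_volume_mm3(map$grid) / 1000
  level <- seq(0, 1, length.out = n_levels)
  n_ge <- if (length(v) == 0) rep(0, n_levels) else {
    length(v) * (1 - ecdf_left(v, level))
  }
  out <- tibble(level = level, volume_cm3 = vv * n_ge)
  structure(
    out,
    class = c("lvh", class(out)),
    values = v,
    voxel_volume_cm3 = vv
  )
}

# Fraction of x strictly below each level (left-continuous ECDF), so that
# 1 - ecdf_left gives the fraction with x >= level.
ecdf_left <- function(x, level) {
  sx <- sort(x)
  findInterval(level, sx, left.open = TRUE) / length(sx)
}

#' Coverage level achieved by a given volume fraction (C95, C90)
#'
#' The largest coverage level c such that at least `vol_pct` percent of the
#' structure's voxels have coverage >= c — the coverage analogue of the DVH
#' D95/D90, i.e. the `(100 - vol_pct)`-th percentile (order statistic) of
#' the raw voxel values. Returned as a percent.
#'
#' @param h A `"cvh"` from [build_cvh()].
#' @param vol_pct Volume percentage in (0, 100\]; 95 gives C95, 90 gives C90.
#' @return Coverage level in percent.
#' @export
coverage_at_volume <- function(h, vol_pct) {
  stopifnot(inherits(h, "cvh"))
  if (!is.numeric(vol_pct) || vol_pct <= 0 || vol_pct > 100) {
    stop("`vol_pct` must be in (0, 100]", call. = FALSE)
  }
  v <- sort(attr(h, "values"), decreasing = TRUE)
  k <- ceiling(length(v) * vol_pct / 100)
  100 * v[k]
}

#' Area under a CVH/LVH curve (possibility-weighted volume)
#'
#' The integral of the cumulative curve over levels \[0, 1\] equals the mean
#' voxel possibility times the base volume; it is computed exactly from the
#' raw voxel values as `voxel_volume * sum(values)`, in cm^3 (possibility-
#' weighted absolute volume) for both curve kinds, so that the
#' leakage/coverage ratio is dimensionless.
#'
#' @param h A `"cvh"` or `"lvh"`.
#' @return Possibility-weighted volume in cm^3.
#' @export
hist_auc <- function(h) {
  stopifnot(inherits(h, c("cvh", "lvh")))
  sum(attr(h, "values")) * attr(h, "voxel_volume_cm3")
}

#' Evaluate CVH/LVH metrics for a set of candidate diameters
#'
#' Runs one shared accumulation of the motion trace against the CTV and
#' derives, per candidate diameter, the full scalar metric set:
#'
#' * `c95_ctv`, `c90_ctv`: coverage of 95% / 90% of the CTV (%), the
#'   feasibility-threshold quantities;
#' * `c95_ptv`, `c90_ptv`: same on the PTV (reported per plan);
#' * `auc_cov_ptv`: area under the PTV coverage curve (cm^3);
#' * `leakage_volume_cm3`: volume that ever entered the aperture outside the
#'   CTV; `auc_leak`: area under the leakage curve (cm^3);
#' * `mean_leakage`: `auc_leak / leakage_volume` — the mean leakage
#'   possibility of the irradiated normal tissue, in \[0, 1\];
#' * `leak_cov_ratio`: `auc_leak / auc_cov_ptv` (dimensionless);
#' * `phi_over_amin`, `phi_over_amax`: diameter normalized by the PTV short /
#'   long axis.
#'
#' @param ctv,ptv CTV and PTV [structure_mask()]s on spacing-compatible
#'   grids.
#' @param trace A `motion_trace`.
#' @param diameters Candidate aperture diameters in mm.
#' @param axes Optional one-row tibble from [axis_lengths()] for the PTV;
#'   computed from `ptv` when omitted.
#' @return A tibble with one row per diameter and the columns above.
#' @export
evaluate_diameters <- function(ctv, ptv, trace, diameters, axes = NULL) {
  stopifnot(inherits(ctv, "structure_mask"), inherits(ptv, "structure_mask"))
  if (is.null(axes)) axes <- axis_lengths(ptv)
  acc <- accumulate_counts(ctv, trace, diameters)
  purrr::map_dfr(seq_along(acc$diameters), function(k) {
    maps <- maps_from_counts(acc, k)
    cvh_ctv <- build_cvh(maps$coverage)
    cvh_ptv <- build_cvh(maps$coverage, eval_structure = ptv)
    lvh <- build_lvh(maps$leakage)
    auc_leak <- hist_auc(lvh)
    auc_cov_ptv <- hist_auc(cvh_ptv)
    leak_vol <- length(attr(lvh, "values")) * attr(lvh, "voxel_volume_cm3")
    tibble(
      diameter = acc$diameters[k],
      c95_ctv = coverage_at_volume(cvh_ctv, 95),
      c90_ctv = coverage_at_volume(cvh_ctv, 90),
      c95_ptv = coverage_at_volume(cvh_ptv, 95),
      c90_ptv = coverage_at_volume(cvh_ptv, 90),
      auc_cov_ptv = auc_cov_ptv,
      leakage_volume_cm3 = leak_vol,
      auc_leak = auc_leak,
      mean_leakage = if (leak_vol > 0) auc_leak / leak_vol else 0,
      leak_cov_ratio = if (auc_cov_ptv > 0) auc_leak / auc_cov_ptv else
        NA_real_,
      phi_over_amin = acc$diameters[k] / axes$a_min,
      phi_over_amax = acc$diameters[k] / axes$a_max
    )
  })
}
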