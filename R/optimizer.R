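#' Admissible Iris diameters for a target geometry
#'
#' Step 1 of the selection strategy: candidate apertures are the collimator
#' diameters inside `[0.5 * a_min, a_max + 5]` mm, where `a_max` / `a_min`
#' are the PTV long- and short-axis lengths.
#'
#' @param axes One-row tibble from [axis_lengths()] (PTV).
#' @param collimator An [iris_collimator()].
#' @return Increasing numeric vector of admissible diameters (mm); errors if
#'   the interval contains no collimator diameter.
#' @examples
#' candidate_diameters(tibble::tibble(a_max = 56.80, a_min = 36.36))
#' @export
candidate_diameters <- function(axes, collimator = iris_collimator()) {
  stopifnot(inherits(collimator, "iris_collimator"))
  if (!all(c("a_max", "a_min") %in% names(axes))) {
    stop("`axes` must have columns a_max and a_min", call. = FALSE)
  }
  lo <- 0.5 * axes$a_min[1]
  hi <- axes$a_max[1] + 5
  d <- collimator$diameters
  out <- d[d >= lo & d <= hi]
  if (length(out) == 0) {
    stop(
      sprintf(
        "no admissible Iris diameter in [%.2f, %.2f] mm for this geometry",
        lo, hi
      ),
      call. = FALSE
    )
  }
  out
}

#' Coverage-threshold feasibility cascade
#'
#' Step 2: candidates satisfying C95 of CTV >= `min_coverage` are kept; if
#' none do, the cascade degrades to C90 of CTV >= `min_coverage`; if that
#' also fails, no candidate is feasible and the tier is `"none"` (all
#' candidates are passed through for reporting, with a warning). With
#' `threshold = "C90"` the cascade starts (and ends) at the C90 tier — the
#' relaxed-threshold variant used for group comparisons.
#'
#' @param metrics Per-diameter tibble from [evaluate_diameters()] (needs
#'   `diameter`, `c95_ctv`, `c90_ctv`).
#' @param threshold `"C95"` (default: C95 then C90 fallback) or `"C90"`.
#' @param min_coverage Required coverage in percent (default 90).
#' @return A list with `tier` (`"C95"`, `"C90"` or `"none"`) and `feasible`
#'   (diameters, mm).
#' @export
feasibility_cascade <- function(metrics, threshold = c("C95", "C90"),
                                min_coverage = 90) {
  threshold <- match.arg(threshold)
  tiers <- if (threshold == "C95") c("C95", "C90") else "C90"
  for (tier in tiers) {
    col <- if (tier == "C95") metrics$c95_ctv else metrics$c90_ctv
    ok <- metrics$diameter[col >= min_coverage]
    if (length(ok) > 0) return(list(tier = tier, feasible = ok))
  }
  warning(
    "no candidate reaches ", min_coverage, "% coverage at any tier; ",
    "passing all candidates through with tier = \"none\"",
    call. = FALSE
  )
  list(tier = "none", feasible = metrics$diameter)
}

#' Aperture selection cost
#'
#' Step 3 scores each feasible diameter d with
#' `F(d) = w * C95_PTV(d) - mean_leakage(d) / v_lung`,
#' where `C95_PTV` enters as a fraction in \[0, 1\], `mean_leakage` is the
#' dimensionless mean leakage possibility, and `v_lung` is the affected-lung
#' volume in cm^3. The best aperture maximizes F — with the clinical default
#' `w = 0` that is the feasible diameter of minimal mean leakage.
#'
#' @param metrics Per-diameter tibble from [evaluate_diameters()].
#' @param w Coverage weight (>= 0; default 0 — PTV coverage not enforced).
#' @param v_lung Affected-lung volume in cm^3 (> 0).
#' @return `metrics` with an added `cost` column.
#' @export
aperture_cost <- function(metrics, w = 0, v_lung) {
  if (!is.numeric(v_lung) || v_lung <= 0) {
    stop("`v_lung` must be > 0 (cm^3)", call. = FALSE)
  }
  if (!is.numeric(w) || w < 0) stop("`w` must be >= 0", call. = FALSE)
  dplyr::mutate(
    metrics,
    cost = w * .data$c95_ptv / 100 - .data$mean_leakage / v_lung
  )
}

#' Optimize the Iris collimator diameter for one plan
#'
#' Runs the full three-step selection: admissible candidates from the PTV
#' axis lengths, the C95/C90 CTV-coverage feasibility cascade, and
#' cost-based selection among the feasible diameters. Ties are broken toward
#' the smaller diameter (spares more tissue at equal cost). When no
#' candidate is feasible (`tier == "none"`) the result reports all candidate
#' metrics but carries no selection.
#'
#' @inheritParams evaluate_diameters
#' @inheritParams feasibility_cascade
#' @inheritParams aperture_cost
#' @param collimator An [iris_collimator()].
#' @param direction `"maximize"` (default) selects the feasible diameter of
#'   largest `F`; `"minimize"` applies the literal lowest-cost-value rule.
#' @return An `iris_opt` object: `selected_diameter` (mm or `NA`), `tier`,
#'   `feasible`, the per-candidate `candidates` tibble (metrics + cost +
#'   feasibility flag), `axes`, `w`, `v_lung`, `direction`. Use [tidy()] /
#'   [glance()] to extract tibbles.
#' @examples
#' ctv <- make_ellipsoid_phantom(semi_axes = c(20.4, 10.2, 10.2),
#'                               spacing = 2, label = "CTV")
#' ptv <- expand_margin(ctv, 4)
#' tr <- simulate_trace(sd = c(1.21, 0.58, 0.86), seed = 7)
#' fit <- optimize_collimator(ctv, ptv, tr, v_lung = 1500)
#' fit$selected_diameter
#' @export
optimize_collimator <- function(ctv, ptv, trace,
                                collimator = iris_collimator(),
                                w = 0, v_lung = 1500,
                                threshold = c("C95", "C90"),
                                min_coverage = 90,
                                direction = c("maximize", "minimize")) {
  threshold <- match.arg(threshold)
  direction <- match.arg(direction)
  axes <- axis_lengths(ptv)
  cand <- candidate_diameters(axes, collimator)
  metrics <- evaluate_diameters(ctv, ptv, trace, cand, axes = axes)
  metrics <- aperture_cost(metrics, w = w, v_lung = v_lung)
  casc <- feasibility_cascade(metrics, threshold = threshold,
                              min_coverage = min_coverage)
  metrics$feasible <- metrics$diameter %in% casc$feasible
  selected <- select_diameter(metrics, casc$tier, direction)
  structure(
    list(
      selected_diameter = selected, tier = casc$tier,
      feasible = casc$feasible, candidates = metrics, axes = axes,
      w = w, v_lung = v_lung, threshold = threshold, direction = direction
    ),
    class = "iris_opt"
  )
}

# Argbest over the feasible rows of the cost table; ties toward the smaller
# diameter (rows are in increasing diameter order).
select_diameter <- function(metrics, tier, direction) {
  if (tier == "none") return(NA_real_)
  feas <- metrics[metrics$feasible, , drop = FALSE]
  score <- if (direction == "maximize") feas$cost else -feas$cost
  feas$diameter[which.max(score)]
}

#' @export
print.iris_opt <- function(x, ...) {
  cat("<iris_opt> Iris diameter selection\n")
  cat(
    "  PTV axes a_max / a_min: ", format(x$axes$a_max, digits = 4), " / ",
    format(x$axes$a_min, digits = 4), " mm\n",
    sep = ""
  )
  cat("  coverage tier: ", x$tier, "; feasible: ",
    paste(x$feasible, collapse = ", "), " mm\n",
    sep = ""
  )
  if (is.na(x$selected_diameter)) {
    cat("  no feasible diameter; no selection\n")
  } else {
    cat("  selected diameter:", x$selected_diameter, "mm\n")
  }
  invisible(x)
}

#' Tidy an Iris optimization result
#'
#' `tidy()` returns the per-candidate table (one row per diameter with all
#' CVH/LVH metrics, cost and feasibility); `glance()` returns a one-row
#' summary of the selected plan.
#'
#' @param x An `iris_opt` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.iris_opt <- function(x, ...) x$candidates

#' @rdname tidy.iris_opt
#' @export
glance.iris_opt <- function(x, ...) {
  sel <- x$candidates[
    !is.na(x$selected_diameter) &
      x$candidates$diameter == x$selected_diameter, ,
    drop = FALSE
  ]
  tibble(
    selected_diameter = x$selected_diameter,
    tier = x$tier,
    n_feasible = length(x$feasible),
    a_max = x$axes$a_max,
    a_min = x$axes$a_min,
    c95_ptv = if (nrow(sel)) sel$c95_ptv else NA_real_,
    c90_ptv = if (nrow(sel)) sel$c90_ptv else NA_real_,
    mean_leakage = if (nrow(sel)) sel$mean_leakage else NA_real_,
    leak_cov_ratio = if (nrow(sel)) sel$leak_cov_ratio else NA_real_,
    phi_over_amin = if (nrow(sel)) sel$phi_over_amin else NA_real_,
    phi_over_amax = if (nrow(sel)) sel$phi_over_amax else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
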