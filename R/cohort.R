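#' Specification of a synthetic lung-SBRT cohort
#'
#' Distribution parameters emulating the published tracked-lung cohort
#' statistics: PTV long axis 56.80 +/- 17.26 mm and short axis
#' 36.36 +/- 10.44 mm (truncated normals, jointly resampled until
#' `a_max >= a_min`), per-axis delivery-error SDs LR 1.21 +/- 0.81,
#' AP 0.58 +/- 0.31, SI 0.86 +/- 0.52 mm (truncated >= 0), 3-7 fractions
#' around 5.11 +/- 1.73, and a lognormal affected-lung volume (median
#' 1500 cm^3, sigma 0.25 — invented, no lung volumes are published).
#' Patients are ellipsoids, so the PTV volume is implied by the sampled axes
#' (about 39 cm^3 at the mean axes, consistent with the reported
#' 41.15 +/- 30.17 cm^3).
#'
#' @param n_patients Number of synthetic patients (default 37).
#' @param a_max_mean,a_max_sd PTV long-axis distribution (mm).
#' @param a_min_mean,a_min_sd PTV short-axis distribution (mm).
#' @param err_mean,err_sd Length-3 means and SDs of the per-patient per-axis
#'   error SDs (mm), ordered (LR, AP, SI).
#' @param fractions_mean,fractions_sd Fraction-count distribution, rounded
#'   and clipped to `fractions_range`.
#' @param fractions_range Allowed fraction counts (default `c(3, 7)`).
#' @param v_lung_median,v_lung_sigma Lognormal affected-lung volume (cm^3).
#' @param a_min_floor Smallest admissible PTV short axis (mm); keeps the CTV
#'   (PTV eroded by the 4 mm margin on each side) non-degenerate.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 37,
                        a_max_mean = 56.80, a_max_sd = 17.26,
                        a_min_mean = 36.36, a_min_sd = 10.44,
                        err_mean = c(1.21, 0.58, 0.86),
                        err_sd = c(0.81, 0.31, 0.52),
                        fractions_mean = 5.11, fractions_sd = 1.73,
                        fractions_range = c(3L, 7L),
                        v_lung_median = 1500, v_lung_sigma = 0.25,
                        a_min_floor = 14) {
  stopifnot(n_patients >= 1, a_min_floor > 8)
  structure(
    list(
      n_patients = as.integer(n_patients),
      a_max_mean = a_max_mean, a_max_sd = a_max_sd,
      a_min_mean = a_min_mean, a_min_sd = a_min_sd,
      err_mean = rep_len(err_mean, 3L), err_sd = rep_len(err_sd, 3L),
      fractions_mean = fractions_mean, fractions_sd = fractions_sd,
      fractions_range = as.integer(fractions_range),
      v_lung_median = v_lung_median, v_lung_sigma = v_lung_sigma,
      a_min_floor = a_min_floor
    ),
    class = "cohort_spec"
  )
}

#' Sample a synthetic patient cohort
#'
#' Draws per-patient PTV axis lengths, per-axis tracking-error SDs, fraction
#' counts and affected-lung volumes from a [cohort_spec()]. Axis pairs with
#' `a_min > a_max` (the published marginals imply occasional inversions) are
#' jointly resampled, with a retry cap.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the manifest is reproducible for a fixed seed.
#' @return A tibble (the cohort manifest) with one row per patient: columns
#'   `patient`, `a_max`, `a_min`, `sd_lr`, `sd_ap`, `sd_si`, `n_fractions`,
#'   `v_lung`.
#' @examples
#' sample_cohort(cohort_spec(n_patients = 5), seed = 7)
#' @export
sample_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  gen <- function() {
    n <- spec$n_patients
    draw_axes <- function(m) {
      a_max <- rnorm(m, spec$a_max_mean, spec$a_max_sd)
      a_min <- rnorm(m, spec$a_min_mean, spec$a_min_sd)
      cbind(a_max, a_min)
    }
    ax <- draw_axes(n)
    for (try in 1:1000) {
      bad <- ax[, 2] > ax[, 1] | ax[, 2] < spec$a_min_floor
      if (!any(bad)) break
      ax[bad, ] <- draw_axes(sum(bad))
    }
    if (any(ax[, 2] > ax[, 1] | ax[, 2] < spec$a_min_floor)) {
      stop("could not sample consistent axis pairs (retry cap hit)",
        call. = FALSE
      )
    }
    trunc_norm0 <- function(m, mu, s) {
      x <- rnorm(m, mu, s)
      while (any(x < 0)) x[x < 0] <- rnorm(sum(x < 0), mu, s)
      x
    }
    fx <- round(rnorm(n, spec$fractions_mean, spec$fractions_sd))
    fx <- pmin(pmax(fx, spec$fractions_range[1]), spec$fractions_range[2])
    tibble(
      patient = seq_len(n),
      a_max = unname(ax[, 1]), a_min = unname(ax[, 2]),
      sd_lr = trunc_norm0(n, spec$err_mean[1], spec$err_sd[1]),
      sd_ap = trunc_norm0(n, spec$err_mean[2], spec$err_sd[2]),
      sd_si = trunc_norm0(n, spec$err_mean[3], spec$err_sd[3]),
      n_fractions = as.integer(fx),
      v_lung = rlnorm(n, log(spec$v_lung_median), spec$v_lung_sigma)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Build the CTV/PTV pair for one manifest row: the CTV is an ellipsoid whose
# Minkowski dilation by the 4 mm CTV->PTV ball reproduces the sampled PTV
# axis lengths (each axis length grows by exactly 2 * margin).
patient_geometry <- function(row, spacing, margin_ctv_ptv = 4) {
  semi <- c(
    (row$a_max - 2 * margin_ctv_ptv) / 2,
    rep((row$a_min - 2 * margin_ctv_ptv) / 2, 2)
  )
  ctv <- make_ellipsoid_phantom(semi_axes = semi, spacing = spacing,
                                label = "CTV")
  ptv <- expand_margin(ctv, margin_ctv_ptv)
  list(ctv = ctv, ptv = ptv)
}

#' Run the optimization study on a synthetic cohort
#'
#' For each patient: builds the ellipsoidal CTV/PTV pair from the sampled
#' axes, simulates a motion trace from the patient's per-axis error SDs
#' (`n_points_per_fraction` imaging points per fraction), evaluates all
#' admissible Iris diameters once, and selects a diameter under each
#' coverage-threshold variant in `thresholds` (the strict C95-first cascade
#' and/or the relaxed C90-only rule).
#'
#' @param manifest Cohort manifest tibble from [sample_cohort()].
#' @param spacing Evaluation-grid voxel spacing in mm (default 2).
#' @param n_points_per_fraction Imaging points per fraction (default 40).
#' @param thresholds Threshold variants to run (default both).
#' @param w,min_coverage Passed to [optimize_collimator()].
#' @param seed Integer seed for the per-patient trace simulation.
#' @return An `iris_cohort` object whose `results` tibble has one row per
#'   patient x threshold with the selected diameter, tier and the selected
#'   plan's metrics; `manifest` is carried along. All cohort statistics
#'   ([paired_threshold_comparison()], [correlation_analysis()],
#'   [diameter_distribution_table()]) are recomputable from `results`.
#' @examples
#' \donttest{
#' cohort <- run_cohort(sample_cohort(cohort_spec(4), seed = 1), seed = 1)
#' paired_threshold_comparison(cohort$results)
#' }
#' @export
run_cohort <- function(manifest, spacing = 2, n_points_per_fraction = 40,
                       thresholds = c("C95", "C90"), w = 0,
                       min_coverage = 90, seed = 1) {
  stopifnot(nrow(manifest) >= 1)
  thresholds <- match.arg(thresholds, c("C95", "C90"), several.ok = TRUE)
  results <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    geo <- patient_geometry(row, spacing = spacing)
    trace <- simulate_trace(
      sd = c(row$sd_lr, row$sd_ap, row$sd_si),
      n_points_per_fraction = n_points_per_fraction,
      n_fractions = row$n_fractions,
      seed = (seed + row$patient) %% .Machine$integer.max
    )
    purrr::map_dfr(thresholds, function(th) {
      fit <- optimize_collimator(
        geo$ctv, geo$ptv, trace,
        w = w, v_lung = row$v_lung, threshold = th,
        min_coverage = min_coverage
      )
      dplyr::bind_cols(
        tibble(patient = row$patient, threshold = th, v_lung = row$v_lung),
        glance(fit)
      )
    })
  })
  structure(
    list(manifest = manifest, results = results,
         spacing = spacing, n_points_per_fraction = n_points_per_fraction),
    class = "iris_cohort"
  )
}

#' @export
print.iris_cohort <- function(x, ...) {
  cat(
    "<iris_cohort> ", nrow(x$manifest), " synthetic patients, ",
    nrow(x$results), " patient x threshold records\n",
    sep = ""
  )
  invisible(x)
}

# Metric columns compared between threshold groups.
.compared_metrics <- c(
  "c95_ptv", "c90_ptv", "mean_leakage", "leak_cov_ratio",
  "selected_diameter", "phi_over_amin", "phi_over_amax"
)

#' Paired comparison of the C95- and C90-threshold groups
#'
#' Paired, two-tailed Wilcoxon signed-rank tests of each plan metric between
#' the strict (C95) and relaxed (C90) coverage-threshold variants, patient
#' by patient. Zero differences are dropped (Wilcoxon's convention) and
#' ties take midranks, via [stats::wilcox.test()]. Metrics with fewer than
#' two non-zero differences are flagged `NA`.
#'
#' @param results The `results` tibble of an [run_cohort()] object (must
#'   contain both threshold variants).
#' @param metrics Metric columns to compare.
#' @return A tibble with one row per metric: group means, the signed-rank
#'   statistic `V` (rank sum of positive C95-minus-C90 differences),
#'   `p_value`, and `n_nonzero` differences used.
#' @export
paired_threshold_comparison <- function(results,
                                        metrics = .compared_metrics) {
  wide <- results |>
    dplyr::select(dplyr::all_of(c("patient", "threshold", metrics))) |>
    tidyr::pivot_wider(names_from = "threshold",
                       values_from = dplyr::all_of(metrics),
                       names_glue = "{.value}_{threshold}")
  purrr::map_dfr(metrics, function(m) {
    x <- wide[[paste0(m, "_C95")]]
    y <- wide[[paste0(m, "_C90")]]
    keep <- stats::complete.cases(x, y)
    x <- x[keep]
    y <- y[keep]
    nz <- sum(x - y != 0)
    if (nz < 2) {
      return(tibble(
        metric = m, mean_c95 = mean(x), mean_c90 = mean(y),
        statistic = NA_real_, p_value = NA_real_, n_nonzero = nz
      ))
    }
    wt <- suppressWarnings(
      wilcox.test(x, y, paired = TRUE, alternative = "two.sided")
    )
    tibble(
      metric = m, mean_c95 = mean(x), mean_c90 = mean(y),
      statistic = unname(wt$statistic), p_value = wt$p.value, n_nonzero = nz
    )
  })
}

#' Spearman correlations of aperture ratios with leakage metrics
#'
#' Two-tailed Spearman rank correlations of `phi_over_amin` and
#' `phi_over_amax` against `leak_cov_ratio` and `mean_leakage` across
#' patients, with midranks for ties and the t-approximation p-value
#' ([stats::cor.test()], `exact = FALSE`). Constant columns yield `NA` rho,
#' flagged.
#'
#' @param results The `results` tibble of [run_cohort()].
#' @param threshold Which threshold variant's selections to correlate
#'   (default `"C95"`).
#' @return A tibble with columns `x`, `y`, `rho`, `p_value`, `n`.
#' @export
correlation_analysis <- function(results, threshold = "C95") {
  r <- results[results$threshold == threshold &
                 !is.na(results$selected_diameter), , drop = FALSE]
  if (nrow(r) < 4) stop("need at least 4 optimized patients", call. = FALSE)
  pairs <- tidyr::expand_grid(
    x = c("phi_over_amin", "phi_over_amax"),
    y = c("leak_cov_ratio", "mean_leakage")
  )
  purrr::pmap_dfr(pairs, function(x, y) {
    xv <- r[[x]]
    yv <- r[[y]]
    keep <- stats::complete.cases(xv, yv)
    xv <- xv[keep]
    yv <- yv[keep]
    if (length(unique(xv)) < 2 || length(unique(yv)) < 2) {
      return(tibble(x = x, y = y, rho = NA_real_, p_value = NA_real_,
                    n = length(xv)))
    }
    ct <- suppressWarnings(
      cor.test(xv, yv, method = "spearman", exact = FALSE)
    )
    tibble(x = x, y = y, rho = unname(ct$estimate),
           p_value = ct$p.value, n = length(xv))
  })
}

#' Distribution of selected diameters across short-axis ranges
#'
#' Tabulates the optimized collimator diameters against PTV short-axis
#' (`a_min`) bins `< 25`, `25-30`, `30-35`, `35-40`, `40-50` and `50-60` mm
#' (half-open `[lo, hi)`; a final `>= 60` bin catches larger targets), with
#' marginal totals.
#'
#' @inheritParams correlation_analysis
#' @param breaks Bin edges for `a_min` in mm.
#' @return A tibble: one row per selected diameter (plus a `Total` row), one
#'   column per `a_min` bin (plus a `Total` column).
#' @export
diameter_distribution_table <- function(results, threshold = "C95",
                                        breaks = c(-Inf, 25, 30, 35, 40, 50,
                                                   60, Inf)) {
  r <- results[results$threshold == threshold &
                 !is.na(results$selected_diameter), , drop = FALSE]
  labs <- character(length(breaks) - 1)
  for (b in seq_along(labs)) {
    labs[b] <- if (is.infinite(breaks[b])) {
      paste0("<", breaks[b + 1])
    } else if (is.infinite(breaks[b + 1])) {
      paste0(">=", breaks[b])
    } else {
      paste0(breaks[b], "-", breaks[b + 1])
    }
  }
  bin <- cut(r$a_min, breaks = breaks, labels = labs, right = FALSE)
  tab <- table(diameter = r$selected_diameter, a_min_range = bin)
  out <- as_tibble(as.data.frame.matrix(tab), rownames = "diameter")
  out$Total <- rowSums(out[labs])
  totals <- c(diameter = "Total",
              as.list(colSums(out[c(labs, "Total")])))
  dplyr::bind_rows(out, as_tibble(totals[c("diameter", labs, "Total")]))
}
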