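# Construct a synthetic per-candidate metrics table without the engine, so
# cascade/cost/selection can be tested against exhaustive enumeration.
fake_metrics <- function(diameters, c95_ctv, c90_ctv, c95_ptv, mean_leak) {
  tibble::tibble(
    diameter = diameters,
    c95_ctv = c95_ctv, c90_ctv = c90_ctv,
    c95_ptv = c95_ptv, c90_ptv = pmin(100, c95_ptv + 5),
    auc_cov_ptv = 10, leakage_volume_cm3 = 50,
    auc_leak = mean_leak * 50, mean_leakage = mean_leak,
    leak_cov_ratio = mean_leak * 5,
    phi_over_amin = diameters / 30, phi_over_amax = diameters / 50
  )
}

test_that("candidate interval [0.5 a_min, a_max + 5] intersects the Iris set", {
  expect_equal(
    candidate_diameters(tibble::tibble(a_max = 56.80, a_min = 36.36)),
    c(20, 25, 30, 35, 40, 50, 60)
  )
  expect_equal(
    candidate_diameters(tibble::tibble(a_max = 12, a_min = 10)),
    c(5, 7.5, 10, 12.5, 15)
  )
  expect_error(
    candidate_diameters(tibble::tibble(a_max = 160, a_min = 140)),
    "no admissible"
  )
})

test_that("the feasibility cascade prefers the C95 tier and degrades explicitly", {
  d <- c(20, 30, 40, 50)
  # perfect coverage everywhere: C95 tier, all feasible
  m <- fake_metrics(d, rep(100, 4), rep(100, 4), rep(100, 4), rep(0.5, 4))
  casc <- feasibility_cascade(m)
  expect_equal(casc$tier, "C95")
  expect_equal(casc$feasible, d)

  # only the largest reaches C95 >= 90 but all reach C90 >= 90:
  # the C95 tier takes precedence with a singleton set
  m <- fake_metrics(d, c(50, 60, 80, 95), rep(95, 4), rep(90, 4),
                    rep(0.5, 4))
  casc <- feasibility_cascade(m)
  expect_equal(casc$tier, "C95")
  expect_equal(casc$feasible, 50)

  # C95 unreachable, C90 reachable for the top two
  m <- fake_metrics(d, rep(50, 4), c(10, 20, 92, 93), rep(90, 4),
                    rep(0.5, 4))
  casc <- feasibility_cascade(m)
  expect_equal(casc$tier, "C90")
  expect_equal(casc$feasible, c(40, 50))

  # the C90-only variant never consults C95
  casc90 <- feasibility_cascade(
    fake_metrics(d, rep(100, 4), c(10, 20, 92, 93), rep(90, 4), rep(0.5, 4)),
    threshold = "C90"
  )
  expect_equal(casc90$tier, "C90")
  expect_equal(casc90$feasible, c(40, 50))

  # nothing reaches either tier
  m <- fake_metrics(d, rep(10, 4), rep(20, 4), rep(90, 4), rep(0.5, 4))
  expect_warning(casc <- feasibility_cascade(m), "none")
  expect_equal(casc$tier, "none")
  expect_equal(casc$feasible, d)
})

test_that("the cost function follows F = w C95_PTV - mean_leakage / v_lung", {
  m <- fake_metrics(35, 95, 98, 80, 0.56)
  expect_equal(aperture_cost(m, w = 0, v_lung = 1500)$cost,
               -0.56 / 1500) # = -3.733e-4
  expect_equal(aperture_cost(m, w = 2, v_lung = 1500)$cost,
               2 * 0.80 - 0.56 / 1500)
  # equal leakage: larger PTV C95 wins for any w > 0
  m2 <- fake_metrics(c(30, 40), c(95, 95), c(98, 98), c(70, 90),
                     c(0.5, 0.5))
  costs <- aperture_cost(m2, w = 1, v_lung = 1000)$cost
  expect_gt(costs[2], costs[1])
  expect_error(aperture_cost(m, w = 0, v_lung = 0), "v_lung")
})

test_that("selection equals exhaustive argbest over the cost table", {
  d12 <- iris_collimator()$diameters
  for (seed in 1:20) {
    withr::with_seed(seed, {
      m <- fake_metrics(
        d12,
        c95_ctv = runif(12, 60, 100), c90_ctv = runif(12, 70, 100),
        c95_ptv = runif(12, 40, 100), mean_leak = runif(12, 0.2, 0.9)
      )
      w <- sample(c(0, 0, 0.5), 1)
      v_lung <- runif(1, 800, 3000)
    })
    m <- aperture_cost(m, w = w, v_lung = v_lung)
    casc <- suppressWarnings(feasibility_cascade(m))
    m$feasible <- m$diameter %in% casc$feasible
    sel <- irisopt:::select_diameter(m, casc$tier, "maximize")
    # oracle: full enumeration over the feasible cost table
    feas <- m[m$feasible, ]
    best <- max(feas$cost)
    oracle <- min(feas$diameter[feas$cost == best])
    expect_equal(sel, oracle)
    if (w == 0 && casc$tier != "none") {
      # with w = 0 the selected feasible diameter minimizes mean leakage
      expect_equal(
        m$mean_leakage[m$diameter == sel],
        min(feas$mean_leakage)
      )
    }
  }
})

test_that("ties break toward the smaller diameter and singletons select themselves", {
  m <- fake_metrics(c(35, 40), c(95, 95), c(99, 99), c(90, 90),
                    c(0.5, 0.5))
  m <- aperture_cost(m, w = 0, v_lung = 1500)
  m$feasible <- TRUE
  expect_equal(irisopt:::select_diameter(m, "C95", "maximize"), 35)

  m1 <- aperture_cost(fake_metrics(40, 95, 99, 90, 0.5), 0, 1500)
  m1$feasible <- TRUE
  expect_equal(irisopt:::select_diameter(m1, "C95", "maximize"), 40)
})

test_that("scaling v_lung never changes the w = 0 selection", {
  pt <- random_phantom_trace(3)
  f1 <- optimize_collimator(pt$ctv, pt$ptv, pt$trace, v_lung = 500)
  f2 <- optimize_collimator(pt$ctv, pt$ptv, pt$trace, v_lung = 5000)
  expect_equal(f1$selected_diameter, f2$selected_diameter)
  expect_equal(f1$tier, f2$tier)
})

test_that("the selected diameter satisfies the active tier's constraint", {
  for (seed in c(2, 9)) {
    pt <- random_phantom_trace(seed)
    fit <- optimize_collimator(pt$ctv, pt$ptv, pt$trace, v_lung = 1500)
    sel <- fit$candidates[fit$candidates$diameter == fit$selected_diameter, ]
    if (fit$tier == "C95") expect_gte(sel$c95_ctv, 90)
    if (fit$tier == "C90") expect_gte(sel$c90_ctv, 90)
    expect_true(fit$selected_diameter %in% fit$feasible)
  }
})

test_that("an infeasible plan reports tier none and carries no selection", {
  ctv <- make_sphere_phantom(radius = 10, spacing = 2)
  ptv <- expand_margin(ctv, 4)
  # errors far larger than any aperture: no candidate can reach C90 >= 90
  tr <- simulate_trace(sd = c(30, 30, 30), n_points_per_fraction = 15,
                       n_fractions = 2, seed = 5)
  expect_warning(
    fit <- optimize_collimator(ctv, ptv, tr, v_lung = 1500),
    "none"
  )
  expect_equal(fit$tier, "none")
  expect_true(is.na(fit$selected_diameter))
  expect_true(all(is.na(glance(fit)$c95_ptv)))
})

test_that("tidy and glance return the candidate table and plan summary", {
  pt <- random_phantom_trace(4)
  fit <- optimize_collimator(pt$ctv, pt$ptv, pt$trace, v_lung = 1200)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("diameter", "cost", "feasible") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$selected_diameter, fit$selected_diameter)
  expect_equal(gl$phi_over_amin,
               fit$selected_diameter / fit$axes$a_min)
})
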