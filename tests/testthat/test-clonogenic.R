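lq_points <- function(alpha, beta, doses = c(0.5, 1, 2, 4), anchor = TRUE) {
  d <- c(if (anchor) 0, doses)
  tibble::tibble(dose_Gy = d, sf = exp(-alpha * d - beta * d^2))
}

test_that("plating efficiency is colonies over seeded cells, pooled with SE", {
  pe <- plating_efficiency(tibble::tibble(cells_seeded = 200, colonies = 100))
  expect_equal(pe$pe, 0.5)
  expect_error(
    plating_efficiency(tibble::tibble(cells_seeded = 0, colonies = 0)),
    "positive"
  )
  expect_error(
    plating_efficiency(tibble::tibble(cells_seeded = 10, colonies = 11)),
    "cells_seeded"
  )
  # replicates {0.4, 0.5, 0.6}: mean 0.5, SE = sd/sqrt(3) = 0.0577
  tbl <- tibble::tibble(dose_Gy = 1, cells_seeded = 100,
                        colonies = c(40, 50, 60))
  s <- summarise_pe(tbl, dose_Gy)
  expect_equal(s$pe_mean, 0.5)
  expect_equal(s$pe_se, 0.057735, tolerance = 1e-5)
  # a single dish has no replicate spread: SE is missing, not zero
  single <- summarise_pe(tibble::tibble(cells_seeded = 100, colonies = 50))
  expect_true(is.na(single$pe_se))
  # zero colonies give PE 0 (non-fittable downstream, but not an error)
  expect_equal(plating_efficiency(
    tibble::tibble(cells_seeded = 100, colonies = 0))$pe, 0)
})

test_that("surviving fractions propagate errors in quadrature", {
  r <- sf_ratio(0.1, 0.5, 0.01, 0.02)
  expect_equal(r$sf, 0.2)
  expect_equal(r$sf_se, 0.2 * sqrt(0.1^2 + 0.04^2), tolerance = 1e-12)
  expect_equal(r$sf_se, 0.0215, tolerance = 1e-2)
  expect_equal(sf_ratio(0.5, 0.5)$sf, 1)
  expect_error(sf_ratio(0.1, 0), "positive")
})

test_that("surviving fractions are computed against each arm's own control", {
  tbl <- dplyr::bind_rows(
    simulate_clonogenic(alpha = 0.4, beta = 0, exposure_days = 4,
                        noise = "none"),
    simulate_clonogenic(alpha = 0.8, beta = 0, exposure_days = 6, pe0 = 0.3,
                        noise = "none")
  )
  sf <- surviving_fraction(tbl, exposure_days)
  expect_equal(nrow(sf), 10)
  expect_equal(sf$sf[sf$dose_Gy == 0], c(1, 1))
  # noise-free SF at 2 Gy equals the generating survival law per arm
  expect_equal(sf$sf[sf$exposure_days == 4 & sf$dose_Gy == 2], exp(-0.8),
               tolerance = 1e-12)
  expect_equal(sf$sf[sf$exposure_days == 6 & sf$dose_Gy == 2], exp(-1.6),
               tolerance = 1e-12)
  # a missing control is an error, not a silent NA
  expect_error(surviving_fraction(tbl[tbl$dose_Gy > 0, ], exposure_days),
               "control")
})

test_that("noiseless LQ data are recovered exactly", {
  f <- fit_lq(lq_points(0.5, 0.04))
  expect_equal(f$alpha, 0.5, tolerance = 1e-6)
  expect_equal(f$beta, 0.04, tolerance = 1e-6)
  expect_false(f$bound_active)
  # three distinct doses suffice for exact recovery
  f3 <- fit_lq(lq_points(1.2, 0.1, doses = c(1, 2, 3), anchor = FALSE))
  expect_equal(f3$alpha, 1.2, tolerance = 1e-9)
  expect_equal(f3$beta, 0.1, tolerance = 1e-9)
  expect_error(fit_lq(tibble::tibble(dose_Gy = 0, sf = 1)), "positive dose")
})

test_that("the beta >= 0 bound activates and matches a grid-search oracle", {
  pts <- lq_points(1.0, -0.02)
  f <- suppressMessages(fit_lq(pts))
  expect_true(f$bound_active)
  expect_identical(f$beta, 0)
  oracle <- grid_lq(pts$dose_Gy, -log(pts$sf))
  expect_equal(f$alpha, oracle$alpha, tolerance = 2e-3)
  expect_identical(f$beta_se, 0)
})

test_that("the fit is invariant to point order and to split weights", {
  withr::with_seed(3, {
    pts <- lq_points(0.6, 0.05)
    pts$sf <- pts$sf * exp(stats::rnorm(nrow(pts), sd = 0.05))
    pts$sf_se <- 0.05 * pts$sf
    f1 <- fit_lq(pts)
    f2 <- fit_lq(pts[sample(nrow(pts)), ])
    expect_equal(f1$alpha, f2$alpha, tolerance = 1e-12)
    expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
    # duplicating a point with variance doubled (weight halved each) leaves
    # the estimate unchanged
    dup <- dplyr::bind_rows(pts, pts[3, ])
    dup$sf_se[c(3, nrow(dup))] <- pts$sf_se[3] * sqrt(2)
    f3 <- fit_lq(dup)
    expect_equal(f3$alpha, f1$alpha, tolerance = 1e-12)
    expect_equal(f3$beta, f1$beta, tolerance = 1e-12)
  })
})

test_that("dish-level LQ fit recovers the generating model", {
  tbl <- simulate_clonogenic(alpha = 0.5, beta = 0.04, noise = "none")
  f <- fit_lq_colonies(tbl)
  expect_equal(f$alpha, 0.5, tolerance = 1e-6)
  expect_equal(f$beta, 0.04, tolerance = 1e-6)
  expect_equal(f$pe0, 0.5, tolerance = 1e-6)
  # noisy data: estimate lands within a few SE of truth
  fn <- fit_lq_colonies(simulate_clonogenic(alpha = 0.5, beta = 0.04,
                                            seed = 123))
  expect_lt(abs(fn$alpha - 0.5), 4 * fn$alpha_se)
  expect_gt(fn$df_residual, 0)
  expect_error(
    fit_lq_colonies(tibble::tibble(dose_Gy = c(1, 2), cells_seeded = 100,
                                   colonies = c(50, 40))),
    "control"
  )
})

test_that("broom accessors and predictions expose the fit", {
  f <- fit_lq(lq_points(0.5, 0.04))
  td <- tidy(f)
  expect_equal(td$term, c("alpha", "beta"))
  expect_equal(td$estimate, c(0.5, 0.04), tolerance = 1e-6)
  gl <- glance(f)
  expect_equal(gl$n_points, 5L)
  expect_false(gl$bound_active)
  expect_equal(predict(f, 2), exp(-0.5 * 2 - 0.04 * 4), tolerance = 1e-6)
  curve <- survival_curve(f, c(0, 1, 2))
  expect_equal(curve$sf[1], 1, tolerance = 1e-9)
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})

test_that("isoeffect doses agree with bisection on the survival curve", {
  expect_equal(dose_at_sf(lq_params(1, 0), exp(-1)), 1, tolerance = 1e-12)
  expect_equal(dose_at_sf(lq_params(0.12, 0.06), 0.1),
               bisect_dose_at_sf(0.12, 0.06, 0.1), tolerance = 1e-9)
  expect_equal(dose_at_sf(lq_params(0.12, 0.06), 0.1), 5.275,
               tolerance = 1e-3)
  expect_equal(dose_at_sf(lq_params(0.5, 0.04), 0.1),
               bisect_dose_at_sf(0.5, 0.04, 0.1), tolerance = 1e-9)
  expect_equal(dose_at_sf(lq_params(0.5, 0.04), 0.1), 3.580,
               tolerance = 1e-3)
  expect_error(dose_at_sf(lq_params(0, 0), 0.1), "alpha > 0 or beta > 0")
  expect_error(dose_at_sf(lq_params(1, 0), 1.2), "between 0 and 1")
})

test_that("isoeffect doses roundtrip through the survival model", {
  withr::with_seed(5, {
    for (i in 1:50) {
      a <- stats::runif(1, 0.05, 2)
      b <- stats::runif(1, 0, 0.3)
      s <- stats::runif(1, 0.005, 0.95)
      fit <- lq_params(a, b)
      D <- dose_at_sf(fit, s)
      expect_equal(predict(fit, D), s, tolerance = 1e-9)
    }
  })
})

test_that("RBE is the reference-to-test isoeffect dose ratio", {
  ref <- lq_params(0.12, 0.06)
  test_fit <- lq_params(0.5, 0.04)
  expect_equal(rbe(ref, ref), 1)
  expect_equal(rbe(test_fit, ref, sf = 0.1), 1.4735, tolerance = 1e-3)
  # for purely linear test curves, scaling (alpha, beta) by 2 halves the
  # test dose and doubles the RBE
  lin <- lq_params(0.4, 0)
  expect_equal(rbe(lq_params(0.8, 0), ref), 2 * rbe(lin, ref),
               tolerance = 1e-12)
})

test_that("a curve strictly below the reference gives RBE above 1", {
  withr::with_seed(9, {
    for (i in 1:20) {
      a_ref <- stats::runif(1, 0.05, 0.5)
      b_ref <- stats::runif(1, 0, 0.1)
      # test curve kills strictly more at every dose
      a_test <- a_ref + stats::runif(1, 0.05, 1)
      b_test <- b_ref + stats::runif(1, 0, 0.1)
      expect_gt(rbe(lq_params(a_test, b_test), lq_params(a_ref, b_ref)), 1)
    }
  })
})
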