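#' Per-dish plating efficiency
#'
#' Plating efficiency (PE) is the fraction of seeded cells that form a
#' colony of at least 50 cells. This adds a `pe` column to a colony-count
#' table; use [summarise_pe()] for condition-level means and standard
#' errors.
#'
#' @param data A data frame with integer columns `cells_seeded` (> 0) and
#'   `colonies` (>= 0, at most `cells_seeded`).
#' @return The input as a tibble with a `pe` column appended.
#' @examples
#' plating_efficiency(tibble::tibble(cells_seeded = 200, colonies = 100))
#' @export
plating_efficiency <- function(data) {
  check_colony_table(data)
  dplyr::mutate(tibble::as_tibble(data),
                pe = .data$colonies / .data$cells_seeded)
}

check_colony_table <- function(data) {
  required <- c("cells_seeded", "colonies")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop("Colony table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(data$cells_seeded <= 0)
  if (length(bad) > 0) {
    stop("`cells_seeded` must be positive (rows ",
         paste(utils::head(bad, 5), collapse = ", "), ").", call. = FALSE)
  }
  bad <- which(data$colonies < 0 | data$colonies > data$cells_seeded)
  if (length(bad) > 0) {
    stop("`colonies` must lie in [0, cells_seeded] (rows ",
         paste(utils::head(bad, 5), collapse = ", "), ").", call. = FALSE)
  }
  invisible(data)
}

#' Condition-level plating efficiency
#'
#' Pools replicate dishes within each condition: the condition PE is the
#' mean of per-dish PEs and its standard error is the sample SD over
#' replicates divided by sqrt(n). With a single replicate the SE is
#' undefined and reported as `NA`, never as zero.
#'
#' @inheritParams plating_efficiency
#' @param ... Grouping columns identifying a condition (tidy-select), e.g.
#'   `dose_Gy, exposure_days`.
#' @return A tibble with one row per condition: grouping columns, `pe_mean`,
#'   `pe_se`, `n_dishes`.
#' @export
summarise_pe <- function(data, ...) {
  data <- plating_efficiency(data)
  dplyr::summarise(
    dplyr::group_by(data, ...),
    pe_mean = mean(.data$pe),
    pe_se = if (dplyr::n() > 1) stats::sd(.data$pe) / sqrt(dplyr::n()) else NA_real_,
    n_dishes = dplyr::n(),
    .groups = "drop"
  )
}

#' Surviving fractions from a colony-count table
#'
#' The surviving fraction (SF) at each dose is the treated condition's PE
#' relative to the untreated control of the *same exposure arm*; its SE is
#' propagated in quadrature of the relative errors,
#' \eqn{SE_{SF} = SF \sqrt{(SE_t/PE_t)^2 + (SE_c/PE_c)^2}}.
#' The control itself appears as the dose-0 row with SF = 1 and, as its
#' uncertainty, the control PE's own relative SE (the numerator and
#' denominator of SF(0) are the same measurement, so their errors are not
#' propagated independently); that row anchors the linear-quadratic fit.
#'
#' @param data A colony-count table with columns `cells_seeded`, `colonies`,
#'   `dose_Gy` and optionally `is_control` (dose 0 rows are treated as
#'   controls when absent), plus any arm columns passed in `...`.
#' @param ... Columns identifying an exposure arm (e.g. `exposure_days`,
#'   `cell_line`); SF is computed within each arm against that arm's own
#'   control.
#' @return A tibble with columns from `...` plus `dose_Gy`, `pe_mean`,
#'   `pe_se`, `n_dishes`, `sf`, `sf_se`.
#' @export
surviving_fraction <- function(data, ...) {
  if (!"dose_Gy" %in% names(data)) {
    stop("Colony table needs a `dose_Gy` column.", call. = FALSE)
  }
  if (!"is_control" %in% names(data)) {
    data$is_control <- data$dose_Gy == 0
  }
  pe <- summarise_pe(data, ..., .data$dose_Gy, .data$is_control)
  arms <- dplyr::group_by(pe, ...)
  out <- dplyr::group_modify(arms, function(arm, key) {
    ctrl <- arm[arm$is_control, ]
    if (nrow(ctrl) != 1) {
      stop("Each exposure arm needs exactly one control condition; found ",
           nrow(ctrl), ".", call. = FALSE)
    }
    if (ctrl$pe_mean <= 0) {
      stop("Control plating efficiency must be positive.", call. = FALSE)
    }
    rel_c <- ctrl$pe_se / ctrl$pe_mean
    treated <- arm[!arm$is_control, ]
    sf_t <- treated$pe_mean / ctrl$pe_mean
    rel_t <- treated$pe_se / treated$pe_mean
    dplyr::bind_rows(
      tibble::tibble(
        dose_Gy = ctrl$dose_Gy, pe_mean = ctrl$pe_mean, pe_se = ctrl$pe_se,
        n_dishes = ctrl$n_dishes, sf = 1, sf_se = rel_c
      ),
      tibble::tibble(
        dose_Gy = treated$dose_Gy, pe_mean = treated$pe_mean,
        pe_se = treated$pe_se, n_dishes = treated$n_dishes,
        sf = sf_t, sf_se = sf_t * sqrt(rel_t^2 + rel_c^2)
      )
    )
  })
  dplyr::arrange(dplyr::ungroup(out), ..., .data$dose_Gy)
}

#' Ratio of two plating efficiencies with propagated error
#'
#' Low-level helper behind [surviving_fraction()], exposed for direct use:
#' SF = PE_treated / PE_control with the SE propagated in quadrature of the
#' relative errors.
#'
#' @param pe_treated,pe_control Plating efficiencies (control > 0).
#' @param se_treated,se_control Their standard errors (optional).
#' @return A tibble with `sf` and `sf_se`.
#' @examples
#' sf_ratio(0.1, 0.5, 0.01, 0.02)
#' @export
sf_ratio <- function(pe_treated, pe_control,
                     se_treated = NA_real_, se_control = NA_real_) {
  if (any(pe_control <= 0)) {
    stop("Control plating efficiency must be positive.", call. = FALSE)
  }
  sf <- pe_treated / pe_control
  sf_se <- sf * sqrt((se_treated / pe_treated)^2 + (se_control / pe_control)^2)
  tibble::tibble(sf = sf, sf_se = sf_se)
}

#' Fit the linear-quadratic survival model
#'
#' Fits \eqn{SF(D) = \exp(-\alpha D - \beta D^2)} by least squares on the
#' log scale: \eqn{-\ln SF = \alpha D + \beta D^2} with no intercept. The
#' quadratic coefficient is constrained to be non-negative; because the
#' model is linear in \eqn{(\alpha, \beta)}, the constrained optimum is
#' exact — if the unconstrained \eqn{\hat\beta} is negative the bound is
#' active and the model refits with \eqn{\beta = 0} (the flag
#' `bound_active` records this, the behaviour seen for purely linear
#' survival curves).
#'
#' Points are weighted by the inverse variance of \eqn{\ln SF}, with
#' \eqn{SE_{\ln SF} = SE_{SF}/SF} by the delta method, when SEs are
#' available and `weighted = TRUE`; otherwise the fit is unweighted.
#' Points with SF >= 1 are retained (their log-survival is <= 0) but
#' flagged with a message. Points with SF <= 0 cannot enter the log-scale
#' fit and are dropped with a message.
#'
#' @param data A data frame with columns `dose_Gy` and `sf`, optionally
#'   `sf_se` — typically the output of [surviving_fraction()], which
#'   includes the dose-0 anchor with the control's SE.
#' @param weighted Use inverse-variance weights when `sf_se` is available.
#' @return An object of class `lq_fit` with elements `alpha`, `beta`,
#'   `alpha_se`, `beta_se`, `bound_active`, `n_points`, `weighted`,
#'   `sigma`, `df_residual`, `cov` and the fitted `data`. Supports
#'   [generics::tidy()], [generics::glance()], `predict()`,
#'   [ggplot2::autoplot()], [dose_at_sf()] and [rbe()].
#' @examples
#' pts <- tibble::tibble(dose_Gy = c(0.5, 1, 2, 4),
#'                       sf = exp(-0.5 * dose_Gy - 0.04 * dose_Gy^2))
#' fit_lq(pts)
#' @export
fit_lq <- function(data, weighted = TRUE) {
  if (!all(c("dose_Gy", "sf") %in% names(data))) {
    stop("`data` needs columns `dose_Gy` and `sf`.", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  drop <- data$sf <= 0 | !is.finite(data$sf)
  if (any(drop)) {
    message(sum(drop), " point(s) with SF <= 0 dropped from the log-scale fit.")
    data <- data[!drop, ]
  }
  if (any(data$sf >= 1 & data$dose_Gy > 0)) {
    message("Point(s) with SF >= 1 at positive dose retained; ",
            "check for stimulated growth or noisy controls.")
  }
  if (sum(data$dose_Gy > 0) < 2) {
    stop("Need at least 2 points at positive dose to fit the LQ model.",
         call. = FALSE)
  }
  y <- -log(data$sf)
  w <- rep(1, nrow(data))
  use_w <- weighted && "sf_se" %in% names(data) &&
    all(is.finite(data$sf_se)) && all(data$sf_se > 0)
  if (use_w) {
    se_log <- data$sf_se / data$sf # delta method
    w <- 1 / se_log^2
  }
  df_fit <- data.frame(y = y, dose = data$dose_Gy, dose2 = data$dose_Gy^2,
                       w = w)
  fit2 <- stats::lm(y ~ dose + dose2 - 1, data = df_fit, weights = w)
  bound_active <- unname(stats::coef(fit2)["dose2"] < 0)
  if (bound_active) {
    fit_used <- stats::lm(y ~ dose - 1, data = df_fit, weights = w)
    coefs <- c(alpha = unname(stats::coef(fit_used)["dose"]), beta = 0)
  } else {
    fit_used <- fit2
    coefs <- c(alpha = unname(stats::coef(fit2)["dose"]),
               beta = unname(stats::coef(fit2)["dose2"]))
  }

  df_res <- fit_used$df.residual
  sigma2 <- if (df_res > 0) sum(w * stats::residuals(fit_used)^2) / df_res else NA_real_
  cov_used <- suppressWarnings(stats::vcov(fit_used)) # noiseless fits trip summary.lm
  cov_full <- matrix(0, 2, 2, dimnames = list(c("alpha", "beta"),
                                              c("alpha", "beta")))
  if (bound_active) {
    cov_full[1, 1] <- cov_used[1, 1]
    ses <- c(alpha = sqrt(cov_used[1, 1]), beta = 0)
  } else {
    cov_full[] <- cov_used
    ses <- c(alpha = sqrt(cov_used[1, 1]), beta = sqrt(cov_used[2, 2]))
  }

  structure(
    list(
      alpha = coefs[["alpha"]], beta = coefs[["beta"]],
      alpha_se = ses[["alpha"]], beta_se = ses[["beta"]],
      bound_active = unname(bound_active),
      n_points = nrow(data),
      weighted = use_w,
      sigma = if (is.na(sigma2)) NA_real_ else sqrt(sigma2),
      df_residual = df_res,
      cov = cov_full,
      data = data
    ),
    class = "lq_fit"
  )
}

#' Construct an LQ parameter set directly
#'
#' Wraps published or externally fitted alpha/beta values in the same
#' `lq_fit` container used by [fit_lq()], so that [dose_at_sf()] and
#' [rbe()] can consume tabulated parameters.
#'
#' @param alpha Linear coefficient, Gy^-1.
#' @param beta Quadratic coefficient, Gy^-2 (>= 0).
#' @param alpha_se,beta_se Optional standard errors.
#' @return An object of class `lq_fit`.
#' @examples
#' lq_params(0.12, 0.06) # a cobalt-60 reference curve
#' @export
lq_params <- function(alpha, beta, alpha_se = NA_real_, beta_se = NA_real_) {
  if (beta < 0) stop("`beta` must be non-negative.", call. = FALSE)
  structure(
    list(alpha = alpha, beta = beta, alpha_se = alpha_se, beta_se = beta_se,
         bound_active = beta == 0, n_points = NA_integer_, weighted = NA,
         sigma = NA_real_, df_residual = NA_integer_, cov = NULL,
         data = NULL),
    class = "lq_fit"
  )
}

#' @export
print.lq_fit <- function(x, ...) {
  cat("<lq_fit> SF(D) = exp(-alpha D - beta D^2)\n")
  cat(sprintf("  alpha = %.4g +/- %.3g Gy^-1\n", x$alpha, x$alpha_se))
  cat(sprintf("  beta  = %.4g +/- %.3g Gy^-2%s\n", x$beta, x$beta_se,
              if (isTRUE(x$bound_active)) "  (beta >= 0 bound active)" else ""))
  if (!is.na(x$n_points)) {
    cat(sprintf("  fitted on %d points (%s)\n", x$n_points,
                if (isTRUE(x$weighted)) "inverse-variance weighted" else "unweighted"))
  }
  invisible(x)
}

#' @export
predict.lq_fit <- function(object, dose_Gy, ...) {
  exp(-object$alpha * dose_Gy - object$beta * dose_Gy^2)
}

#' Tidy an LQ fit
#'
#' @param x An `lq_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy lq_fit
#' @export
tidy.lq_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = c(x$alpha_se, x$beta_se)
  )
}

#' One-row summary of an LQ fit
#'
#' @param x An `lq_fit` object.
#' @param ... Unused.
#' @return A tibble with `n_points`, `bound_active`, `weighted`, `sigma`,
#'   `df.residual`.
#' @method glance lq_fit
#' @export
glance.lq_fit <- function(x, ...) {
  tibble::tibble(
    n_points = x$n_points,
    bound_active = x$bound_active,
    weighted = x$weighted,
    sigma = x$sigma,
    df.residual = x$df_residual
  )
}

#' Confidence interval for the LQ linear coefficient
#'
#' t-interval on the residual degrees of freedom of the weighted fit.
#'
#' @param object An `lq_fit` from [fit_lq()].
#' @param parm Parameter name(s), `"alpha"` and/or `"beta"`.
#' @param level Confidence level.
#' @param ... Unused.
#' @return A matrix of lower/upper bounds, one row per parameter.
#' @export
confint.lq_fit <- function(object, parm = c("alpha", "beta"), level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  if (is.na(object$df_residual) || object$df_residual <= 0) {
    stop("No residual degrees of freedom: interval unavailable.", call. = FALSE)
  }
  tq <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  est <- c(alpha = object$alpha, beta = object$beta)[parm]
  se <- c(alpha = object$alpha_se, beta = object$beta_se)[parm]
  out <- cbind(est - tq * se, est + tq * se)
  dimnames(out) <- list(parm, sprintf("%.1f %%", c((1 - level) / 2,
                                                   1 - (1 - level) / 2) * 100))
  out
}

#' Survival curve plot for an LQ fit
#'
#' Data points with SE bars (when available) and the fitted survival curve
#' on a log-scaled y axis, the standard presentation of clonogenic data.
#'
#' @param object An `lq_fit`.
#' @param dose_max Upper end of the dose grid; defaults to 1.1 x the
#'   largest fitted dose (or 5 Gy for parameter-only objects).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lq_fit
#' @export
autoplot.lq_fit <- function(object, dose_max = NULL, ...) {
  if (is.null(dose_max)) {
    dose_max <- if (!is.null(object$data)) 1.1 * max(object$data$dose_Gy) else 5
  }
  grid <- tibble::tibble(dose_Gy = seq(0, dose_max, length.out = 200))
  grid$sf <- predict(object, grid$dose_Gy)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$dose_Gy, y = .data$sf)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Absorbed dose [Gy]", y = "Surviving fraction")
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(data = object$data)
    if ("sf_se" %in% names(object$data) && any(is.finite(object$data$sf_se))) {
      p <- p + ggplot2::geom_errorbar(
        data = object$data,
        ggplot2::aes(ymin = .data$sf - .data$sf_se,
                     ymax = .data$sf + .data$sf_se),
        width = 0.05
      )
    }
  }
  p
}

#' Isoeffect dose for a target surviving fraction
#'
#' Inverts the LQ model: the dose at which the fitted survival curve
#' crosses `sf`. With beta > 0 this is the single positive root of
#' \eqn{\beta D^2 + \alpha D + \ln(sf) = 0}; with beta = 0 it reduces to
#' \eqn{D = -\ln(sf)/\alpha}.
#'
#' @param fit An `lq_fit` (from [fit_lq()] or [lq_params()]).
#' @param sf Target surviving fraction, strictly between 0 and 1.
#' @return Dose in Gy.
#' @examples
#' dose_at_sf(lq_params(0.5, 0.04), 0.1) # about 3.58 Gy
#' @export
dose_at_sf <- function(fit, sf) {
  stopifnot(inherits(fit, "lq_fit"))
  if (any(sf <= 0) || any(sf >= 1)) {
    stop("`sf` must lie strictly between 0 and 1.", call. = FALSE)
  }
  a <- fit$alpha
  b <- fit$beta
  if (a <= 0 && b <= 0) {
    stop("Isoeffect dose undefined: need alpha > 0 or beta > 0.", call. = FALSE)
  }
  if (b == 0) {
    return(-log(sf) / a)
  }
  disc <- a^2 - 4 * b * log(sf) # log(sf) < 0, so disc > a^2 >= 0
  roots <- cbind((-a + sqrt(disc)) / (2 * b), (-a - sqrt(disc)) / (2 * b))
  pos <- roots[, 1]
  # with b > 0 and log(sf) < 0 the product of roots is negative:
  # exactly one positive root exists
  stopifnot(all(pos > 0), all(roots[, 2] < 0))
  pos
}

#' Relative biological effectiveness at an isoeffect endpoint
#'
#' RBE compares a radiation under test to a reference radiation at the same
#' biological endpoint: the ratio of the reference dose to the test dose
#' producing the same surviving fraction,
#' \eqn{RBE = D_{ref}(sf) / D_{test}(sf)}. Values above 1 mean the test
#' radiation needs less dose for the same effect.
#'
#' @param fit_test `lq_fit` for the radiation under test.
#' @param fit_ref `lq_fit` for the reference radiation.
#' @param sf Endpoint surviving fraction (default 10%).
#' @return Dimensionless RBE.
#' @examples
#' rbe(lq_params(0.5, 0.04), lq_params(0.12, 0.06)) # about 1.47
#' @export
rbe <- function(fit_test, fit_ref, sf = 0.1) {
  dose_at_sf(fit_ref, sf) / dose_at_sf(fit_test, sf)
}

#' Predicted survival curve as a table
#'
#' @param fit An `lq_fit`.
#' @param doses_Gy Dose grid (Gy).
#' @return A tibble with `dose_Gy` and predicted `sf`.
#' @export
survival_curve <- function(fit, doses_Gy = seq(0, 6, by = 0.1)) {
  tibble::tibble(dose_Gy = doses_Gy, sf = predict(fit, doses_Gy))
}

#' Fit the LQ model directly to per-dish colony counts
#'
#' The inference route of choice when the dish-level table is available.
#' Each dish is an independent binomial observation (colonies out of
#' seeded cells), so the model
#' \deqn{\ln PE_{dish} = \ln pe_0 - \alpha D - \beta D^2}
#' is fitted to per-dish log plating efficiencies by weighted least
#' squares with delta-method inverse-variance weights
#' \eqn{w = n \hat p / (1 - \hat p)} (the reciprocal variance of
#' \eqn{\ln \widehat{PE}}). The control enters through the intercept
#' rather than as a shared divisor, which keeps the dish errors
#' independent — unlike the surviving-fraction route, where the common
#' control and the replicate-estimated SEs make the reported
#' uncertainties approximate. Confidence intervals from this fit are
#' t-intervals on the residual degrees of freedom and are calibrated at
#' study-scale designs (see the package vignette).
#'
#' The beta >= 0 constraint is applied exactly as in [fit_lq()]. Dishes
#' with zero colonies carry no log-scale information and are dropped with
#' a message.
#'
#' @param data A colony-count table with columns `dose_Gy`,
#'   `cells_seeded`, `colonies` (e.g. from [simulate_clonogenic()] or
#'   [read_pipeline_config()] ingestion); one exposure arm at a time.
#' @param weighted Use binomial inverse-variance weights (default) or
#'   ordinary least squares.
#' @return An `lq_fit` object; `$pe0` holds the fitted control plating
#'   efficiency.
#' @examples
#' fit_lq_colonies(simulate_clonogenic(seed = 1))
#' @export
fit_lq_colonies <- function(data, weighted = TRUE) {
  check_colony_table(data)
  if (!"dose_Gy" %in% names(data)) {
    stop("Colony table needs a `dose_Gy` column.", call. = FALSE)
  }
  d <- plating_efficiency(data)
  zero <- d$colonies == 0
  if (any(zero)) {
    message(sum(zero), " dish(es) with zero colonies dropped from the fit.")
    d <- d[!zero, ]
  }
  if (sum(d$dose_Gy > 0) < 2 || !any(d$dose_Gy == 0)) {
    stop("Need control dishes and >= 2 dishes at positive dose.",
         call. = FALSE)
  }
  d$w <- if (weighted) d$cells_seeded * d$pe / (1 - d$pe) else rep(1, nrow(d))
  d$logpe <- log(d$pe)
  fit2 <- stats::lm(logpe ~ dose_Gy + I(dose_Gy^2), data = d, weights = w)
  bound_active <- unname(stats::coef(fit2)[3] > 0) # beta = -coef
  fit_used <- if (bound_active) {
    stats::lm(logpe ~ dose_Gy, data = d, weights = w)
  } else {
    fit2
  }
  cf <- stats::coef(fit_used)
  vc <- suppressWarnings(stats::vcov(fit_used))
  alpha <- -unname(cf[2])
  beta <- if (bound_active) 0 else -unname(cf[3])
  cov_full <- matrix(0, 2, 2,
                     dimnames = list(c("alpha", "beta"), c("alpha", "beta")))
  if (bound_active) {
    cov_full[1, 1] <- vc[2, 2]
  } else {
    cov_full[] <- vc[2:3, 2:3]
  }
  structure(
    list(
      alpha = alpha, beta = beta,
      alpha_se = sqrt(cov_full[1, 1]),
      beta_se = if (bound_active) 0 else sqrt(cov_full[2, 2]),
      bound_active = bound_active,
      n_points = nrow(d),
      weighted = weighted,
      sigma = suppressWarnings(summary(fit_used)$sigma),
      df_residual = fit_used$df.residual,
      cov = cov_full,
      pe0 = exp(unname(cf[1])),
      data = tibble::tibble(dose_Gy = d$dose_Gy, sf = d$pe / exp(cf[1])),
      dishes = d
    ),
    class = "lq_fit"
  )
}
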