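#' Physical decay data for a radionuclide
#'
#' Builds the small physics record the dosimetry functions consume: the
#' half-life (stored canonically in seconds) and the decay constant derived
#' from it. The default is silver-111, the beta-emitter these tools were
#' written around, with a half-life of 7.45 days.
#'
#' @param half_life_days Physical half-life in days. Must be positive.
#' @param name Radionuclide label carried through reports.
#'
#' @return An object of class `radionuclide_physics`: a list with elements
#'   `name`, `half_life_s`, `half_life_days` and `decay_constant` (s^-1).
#' @examples
#' ph <- ag111_physics()
#' ph$decay_constant # about 1.077e-6 s^-1
#' @export
ag111_physics <- function(half_life_days = 7.45, name = "Ag-111") {
  stopifnot(is.numeric(half_life_days), length(half_life_days) == 1)
  if (!is.finite(half_life_days) || half_life_days <= 0) {
    stop("`half_life_days` must be a positive, finite number.", call. = FALSE)
  }
  hl_s <- half_life_days * 86400
  structure(
    list(
      name = name,
      half_life_days = half_life_days,
      half_life_s = hl_s,
      decay_constant = decay_constant(hl_s)
    ),
    class = "radionuclide_physics"
  )
}

#' @export
print.radionuclide_physics <- function(x, ...) {
  cat(sprintf(
    "<radionuclide_physics> %s: t1/2 = %g d, lambda = %.6g s^-1\n",
    x$name, x$half_life_days, x$decay_constant
  ))
  invisible(x)
}

#' Decay constant from a half-life
#'
#' @param half_life_s Half-life in seconds (positive).
#' @return Decay constant ln(2) / half-life, in s^-1.
#' @examples
#' decay_constant(log(2)) # 1 s^-1
#' @export
decay_constant <- function(half_life_s) {
  if (!is.numeric(half_life_s) || any(!is.finite(half_life_s)) ||
      any(half_life_s <= 0)) {
    stop("Half-life must be positive and finite.", call. = FALSE)
  }
  log(2) / half_life_s
}

#' Decay integral over an exposure window
#'
#' The time integral of the physical-decay factor,
#' \eqn{\int_0^T e^{-\lambda t} dt = (1 - e^{-\lambda T})/\lambda},
#' which converts an initial activity (concentration) into a cumulated
#' activity (concentration) over the window. It is bounded above by both
#' `T` and `1/lambda`.
#'
#' @param exposure_days Exposure duration T in days (vectorised, all >= 0).
#' @param physics A [ag111_physics()] record.
#' @return Effective integration time in seconds.
#' @examples
#' decay_integral(4) # about 2.886e5 s for Ag-111
#' @export
decay_integral <- function(exposure_days, physics = ag111_physics()) {
  stopifnot(inherits(physics, "radionuclide_physics"))
  if (!is.numeric(exposure_days) || any(!is.finite(exposure_days)) ||
      any(exposure_days < 0)) {
    stop("`exposure_days` must be non-negative and finite.", call. = FALSE)
  }
  lambda <- physics$decay_constant
  t_s <- exposure_days * 86400
  # expm1 keeps precision for short windows (lambda * T << 1)
  -expm1(-lambda * t_s) / lambda
}

#' Reference S-values for the medium and cytoplasm source regions
#'
#' Mean absorbed dose per cumulated activity for the two source -> target
#' pairs used here: the radioactive culture medium into the cell (expressed
#' per cumulated activity *concentration*, Gy mL / (Bq s)), and a uniform
#' cytoplasmic source into the cell nucleus (per cumulated activity,
#' Gy / (Bq s)).
#'
#' Two medium S-values are shipped because the literature unit string for
#' the half-sphere geometry is ambiguous:
#' * `s_medium_calibrated()` back-solves S from the published 4-day exposure
#'   plan (478 kBq/mL delivering 4 Gy in 4 d), giving 2.8998e-11
#'   Gy mL/(Bq s). This is the default everywhere: it reproduces the full
#'   published activity ladder.
#' * `s_medium_nominal` is the naive reading of "half of 0.06 mGy/(Bq s)"
#'   as 0.03 mGy mL/(MBq s) = 3e-11 Gy mL/(Bq s); it reproduces the ladder
#'   only to about 3.5%.
#'
#' @param medium Medium -> cell S-value, Gy mL / (Bq s).
#' @param cytoplasm Cytoplasm -> nucleus S-value, Gy / (Bq s). The default
#'   is the published 0.075 mGy/(Bq s) for an ellipsoidal nucleus.
#' @param geometry_note Free-text provenance note.
#' @return An object of class `s_value_set`.
#' @examples
#' s_value_set()
#' @export
s_value_set <- function(medium = s_medium_calibrated(),
                        cytoplasm = 0.075e-3,
                        geometry_note = "cell on dish bottom; half-sphere medium source") {
  if (!is.numeric(medium) || medium <= 0 || !is.numeric(cytoplasm) || cytoplasm <= 0) {
    stop("S-values must be positive.", call. = FALSE)
  }
  structure(
    list(medium = medium, cytoplasm = cytoplasm, geometry_note = geometry_note),
    class = "s_value_set"
  )
}

#' @rdname s_value_set
#' @param physics A [ag111_physics()] record used for the calibration.
#' @export
s_medium_calibrated <- function(physics = ag111_physics()) {
  # anchor: 478 kBq/mL over 4 d delivers 4 Gy
  4 / (478e3 * decay_integral(4, physics))
}

#' @rdname s_value_set
#' @format NULL
#' @export
s_medium_nominal <- 3e-11

#' Absorbed dose from an activity concentration
#'
#' MIRD-schema dose to a cell from a uniformly radioactive culture medium:
#' \eqn{D(T) = S \cdot A_c \cdot (1 - e^{-\lambda T})/\lambda}. Linear in
#' both the activity concentration and the S-value.
#'
#' @param activity_kBq_mL Initial activity concentration, kBq/mL
#'   (vectorised, >= 0).
#' @param exposure_days Exposure window T in days (>= 0).
#' @param s_medium Medium -> cell S-value in Gy mL/(Bq s).
#' @param physics A [ag111_physics()] record.
#' @return Absorbed dose in Gy.
#' @examples
#' dose_from_activity(478, 4) # 4 Gy
#' @export
dose_from_activity <- function(activity_kBq_mL, exposure_days,
                               s_medium = s_medium_calibrated(physics),
                               physics = ag111_physics()) {
  if (!is.numeric(activity_kBq_mL) || any(activity_kBq_mL < 0)) {
    stop("`activity_kBq_mL` must be non-negative.", call. = FALSE)
  }
  if (!is.numeric(s_medium) || any(s_medium <= 0)) {
    stop("`s_medium` must be positive.", call. = FALSE)
  }
  s_medium * (activity_kBq_mL * 1e3) * decay_integral(exposure_days, physics)
}

#' Activity concentration required for a target dose
#'
#' Exact algebraic inversion of [dose_from_activity()]: the initial activity
#' concentration that delivers absorbed dose `dose_Gy` over `exposure_days`.
#'
#' @param dose_Gy Target absorbed dose in Gy (vectorised, >= 0).
#' @inheritParams dose_from_activity
#' @return Activity concentration in kBq/mL (unrounded; round only when
#'   reporting a plan).
#' @examples
#' activity_for_dose(4, 4) # 478 kBq/mL
#' @export
activity_for_dose <- function(dose_Gy, exposure_days,
                              s_medium = s_medium_calibrated(physics),
                              physics = ag111_physics()) {
  if (!is.numeric(dose_Gy) || any(dose_Gy < 0)) {
    stop("`dose_Gy` must be non-negative.", call. = FALSE)
  }
  if (any(exposure_days <= 0 & dose_Gy > 0)) {
    stop("A positive dose cannot be delivered in zero exposure time.", call. = FALSE)
  }
  integral <- decay_integral(exposure_days, physics)
  out <- ifelse(dose_Gy == 0, 0, dose_Gy / (s_medium * integral) / 1e3)
  as.numeric(out)
}

#' Time-matched activity concentration
#'
#' The activity concentration at exposure time `to_days` that delivers the
#' same absorbed dose as `activity_kBq_mL` at `from_days`. The S-value
#' cancels, so only the decay integrals matter:
#' \eqn{A_c' = A_c \, I(T_{from}) / I(T_{to})}.
#'
#' @param activity_kBq_mL Activity concentration at `from_days`, kBq/mL.
#' @param from_days,to_days Exposure windows in days (both > 0).
#' @inheritParams dose_from_activity
#' @return Equivalent activity concentration in kBq/mL (unrounded).
#' @examples
#' equivalent_activity(478, 4, 6) # about 347 kBq/mL
#' @export
equivalent_activity <- function(activity_kBq_mL, from_days, to_days,
                                physics = ag111_physics()) {
  if (any(from_days <= 0) || any(to_days <= 0)) {
    stop("Exposure times must be positive.", call. = FALSE)
  }
  if (!is.numeric(activity_kBq_mL) || any(activity_kBq_mL < 0)) {
    stop("`activity_kBq_mL` must be non-negative.", call. = FALSE)
  }
  activity_kBq_mL * decay_integral(from_days, physics) / decay_integral(to_days, physics)
}

#' Instantaneous dose rate during an exposure
#'
#' \eqn{\dot D(t) = S \cdot A_c \cdot e^{-\lambda t}}: the dose rate decays
#' with the physical half-life, starting from `S * Ac` at t = 0.
#'
#' @param t_days Time since the start of exposure, days (vectorised, >= 0).
#' @inheritParams dose_from_activity
#' @return Dose rate in Gy/s.
#' @export
dose_rate <- function(t_days, activity_kBq_mL,
                      s_medium = s_medium_calibrated(physics),
                      physics = ag111_physics()) {
  if (!is.numeric(t_days) || any(t_days < 0)) {
    stop("`t_days` must be non-negative.", call. = FALSE)
  }
  s_medium * (activity_kBq_mL * 1e3) * exp(-physics$decay_constant * t_days * 86400)
}

#' Relative nucleus-dose increase from cytoplasmic internalization
#'
#' Evaluates the scenario where the radiometal is internalized so that the
#' cytoplasm holds the same activity concentration as the medium. The extra
#' nucleus dose from the cytoplasmic source, relative to the medium-only
#' dose, is
#' \deqn{\frac{S_{N \leftarrow Cy} \cdot (A_c V_{cy}) \cdot I(T)}
#'            {S_{med} \cdot A_c \cdot I(T)}
#'       = \frac{S_{N \leftarrow Cy} \, V_{cy}}{S_{med}},}
#' independent of both the activity concentration and the exposure time
#' (they cancel). Unit conversions (mGy to Gy, mL to um^3) are handled
#' internally.
#'
#' @param cytoplasm_volume_um3 Cytoplasm volume in cubic micrometres. The
#'   default 1000 um^3 is an order-of-magnitude mammalian-cell assumption,
#'   flagged as such in reports; it is not a measured value.
#' @param s_values An [s_value_set()].
#' @param exposure_days Exposure window (kept in the signature for symmetry
#'   with the other dose functions; the ratio does not depend on it).
#' @inheritParams dose_from_activity
#' @return Dimensionless fraction (0.0026 means +0.26%).
#' @examples
#' internalization_excess() # about 0.0026 with the defaults
#' @export
internalization_excess <- function(cytoplasm_volume_um3 = 1000,
                                   s_values = s_value_set(),
                                   exposure_days = 4,
                                   physics = ag111_physics()) {
  stopifnot(inherits(s_values, "s_value_set"))
  if (!is.numeric(cytoplasm_volume_um3) || any(cytoplasm_volume_um3 < 0)) {
    stop("`cytoplasm_volume_um3` must be non-negative.", call. = FALSE)
  }
  if (s_values$medium <= 0) {
    stop("Medium S-value must be positive: zero medium dose.", call. = FALSE)
  }
  v_mL <- cytoplasm_volume_um3 * 1e-12 # 1 um^3 = 1e-12 mL
  s_values$cytoplasm * v_mL / s_values$medium
}

#' Build an exposure plan for a dose ladder
#'
#' Converts target absorbed doses into the activity concentrations to
#' administer for each exposure time, the planning step that precedes a
#' multi-arm irradiation experiment.
#'
#' @param doses_Gy Target absorbed doses in Gy.
#' @param exposure_days One or more exposure windows in days; the plan
#'   crosses every dose with every window.
#' @inheritParams dose_from_activity
#' @return A tibble with columns `dose_Gy`, `exposure_days`,
#'   `activity_kBq_per_mL` (unrounded) and `activity_planned_kBq_per_mL`
#'   (rounded to integer kBq/mL, the reporting convention).
#' @examples
#' plan_exposure(c(0.5, 1, 2, 4), c(4, 6))
#' @export
plan_exposure <- function(doses_Gy, exposure_days = c(4, 6),
                          s_medium = s_medium_calibrated(physics),
                          physics = ag111_physics()) {
  if (length(doses_Gy) == 0) {
    return(tibble::tibble(
      dose_Gy = numeric(), exposure_days = numeric(),
      activity_kBq_per_mL = numeric(), activity_planned_kBq_per_mL = numeric()
    ))
  }
  plan <- tidyr::expand_grid(exposure_days = exposure_days, dose_Gy = doses_Gy)
  dplyr::mutate(
    plan,
    activity_kBq_per_mL = activity_for_dose(
      .data$dose_Gy, .data$exposure_days,
      s_medium = s_medium, physics = physics
    ),
    activity_planned_kBq_per_mL = round(.data$activity_kBq_per_mL),
    .before = 1
  )[, c("dose_Gy", "exposure_days", "activity_kBq_per_mL", "activity_planned_kBq_per_mL")]
}

#' Read or write an exposure plan as CSV
#'
#' Plans are exchanged as plain CSV with columns `dose_Gy`, `exposure_days`,
#' `activity_kBq_per_mL`.
#'
#' @param plan A tibble as returned by [plan_exposure()].
#' @param path File path.
#' @return `read_exposure_plan()` returns a tibble; `write_exposure_plan()`
#'   returns `path` invisibly.
#' @export
write_exposure_plan <- function(plan, path) {
  utils::write.csv(
    plan[, c("dose_Gy", "exposure_days", "activity_kBq_per_mL")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_exposure_plan
#' @export
read_exposure_plan <- function(path) {
  df <- utils::read.csv(path)
  required <- c("dose_Gy", "exposure_days", "activity_kBq_per_mL")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("Exposure plan is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}
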