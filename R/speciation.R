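#' Equilibrium constants for the Ag-Cl system
#'
#' Defaults are the constants used for the administered solutions:
#' solubility product of AgCl(s) Ks = 1.77e-10 M^2, overall formation
#' constants beta1 = 2e3 M^-1 for AgCl(aq) and beta2 = 1.86e5 M^-2 for
#' AgCl2-. Concentrations are treated as activities (no ionic-strength
#' correction), consistent with how the constants are used.
#'
#' @param ksp Solubility product, M^2.
#' @param beta1 Overall formation constant of AgCl(aq), M^-1.
#' @param beta2 Overall formation constant of AgCl2-, M^-2.
#' @return A list of class `agcl_constants`.
#' @export
agcl_constants <- function(ksp = 1.77e-10, beta1 = 2e3, beta2 = 1.86e5) {
  if (any(c(ksp, beta1, beta2) <= 0)) {
    stop("Equilibrium constants must be positive.", call. = FALSE)
  }
  structure(list(ksp = ksp, beta1 = beta1, beta2 = beta2),
            class = "agcl_constants")
}

# Dissolved Ag speciation at a known free chloride concentration.
# The Ag mass balance is linear in free Ag+ at fixed [Cl-]:
#   total_ag_dissolved = [Ag+] (1 + b1[Cl] + b2[Cl]^2)
agcl_fractions_at_cl <- function(free_cl, k) {
  terms <- c(1, k$beta1 * free_cl, k$beta2 * free_cl^2)
  terms / sum(terms)
}

#' Solve the Ag-Cl speciation equilibrium
#'
#' Distributes total silver over Ag+, AgCl(aq) and AgCl2- (and AgCl(s) if
#' the solution is oversaturated) by simultaneous Ag and Cl mass balance.
#' The solver brackets free \[Cl-\] and finds the root of the chloride mass
#' balance with [stats::uniroot()]; at fixed \[Cl-\] the silver balance is
#' linear in free \[Ag+\] and closes in closed form. If the unsaturated
#' solution would exceed the solubility product, the saturated branch
#' solves for the amount of solid that pins the residual ion product
#' exactly at Ks.
#'
#' Defaults reproduce the administered-solution scenario: with
#' total Ag 1.23e-7 M and total Cl 0.246 M the silver is almost entirely
#' the soluble dichloroargentate complex (about 96%), the rest AgCl(aq)
#' (about 4%), with a negligible free-ion fraction and no solid.
#'
#' @param total_ag,total_cl Analytical (total) concentrations in mol/L,
#'   both >= 0. Vectorised: longer inputs are recycled rowwise.
#' @param constants An [agcl_constants()] set.
#' @param tol Relative convergence tolerance on the mass balances.
#' @return A tibble with one row per input composition and columns
#'   `total_ag`, `total_cl`, `free_ag`, `free_cl`, `fraction_free_ag`,
#'   `fraction_agcl`, `fraction_agcl2`, `fraction_solid` (all fractions of
#'   total Ag), `ion_product`, `saturated`. Dissolved fractions sum to 1
#'   (minus the solid fraction when saturated).
#' @examples
#' speciate_agcl(1.23e-7, 2.46e-1)
#' @export
speciate_agcl <- function(total_ag, total_cl, constants = agcl_constants(),
                          tol = 1e-12) {
  stopifnot(inherits(constants, "agcl_constants"))
  if (any(total_ag < 0) || any(total_cl < 0)) {
    stop("Total concentrations must be non-negative.", call. = FALSE)
  }
  n <- max(length(total_ag), length(total_cl))
  total_ag <- rep_len(total_ag, n)
  total_cl <- rep_len(total_cl, n)
  purrr::map2_dfr(total_ag, total_cl, speciate_agcl_one,
                  k = constants, tol = tol)
}

speciate_agcl_one <- function(tag, tcl, k, tol) {
  if (tag == 0 || tcl == 0) {
    # no complexation possible: everything stays free
    free_ag <- tag
    free_cl <- tcl
    fr <- if (tag > 0) c(1, 0, 0) else c(NA_real_, NA_real_, NA_real_)
    return(speciation_row(tag, tcl, free_ag, free_cl, fr, 0, k))
  }

  # unsaturated branch: root of the Cl mass balance in free [Cl-]
  cl_residual <- function(cl) {
    fr <- agcl_fractions_at_cl(cl, k)
    bound_cl <- tag * (fr[2] + 2 * fr[3])
    cl + bound_cl - tcl
  }
  # free Cl lies in (0, tcl]; residual at tcl is >= 0, near 0 it is < 0
  # (all Cl would have to be bound, impossible when tag*2 < tcl - cl)
  lo <- tcl * 1e-15
  if (cl_residual(lo) > 0) {
    # practically all chloride is consumable by Ag; bracket down further
    lo <- .Machine$double.xmin
  }
  root <- stats::uniroot(cl_residual, c(lo, tcl), tol = tcl * tol)
  free_cl <- root$root
  fr <- agcl_fractions_at_cl(free_cl, k)
  free_ag <- tag * fr[1]

  if (free_ag * free_cl > k$ksp * (1 + 1e-12)) {
    return(speciate_saturated(tag, tcl, k, tol))
  }
  speciation_row(tag, tcl, free_ag, free_cl, fr, 0, k)
}

# Saturated branch: AgCl(s) present, so [Ag+] = Ks/[Cl-]. Eliminating the
# solid between the two mass balances leaves one equation in free [Cl-]:
#   tcl - tag = [Cl-] + [AgCl2-] - [Ag+]
speciate_saturated <- function(tag, tcl, k, tol) {
  resid <- function(cl) {
    ag <- k$ksp / cl
    agcl2 <- k$beta2 * ag * cl^2
    (cl + agcl2 - ag) - (tcl - tag)
  }
  root <- stats::uniroot(resid, c(.Machine$double.xmin, tcl + tag),
                         tol = (tcl + tag) * tol)
  free_cl <- root$root
  free_ag <- k$ksp / free_cl
  agcl <- k$beta1 * free_ag * free_cl
  agcl2 <- k$beta2 * free_ag * free_cl^2
  dissolved <- free_ag + agcl + agcl2
  solid <- tag - dissolved
  if (solid < -tag * 1e-9) {
    stop("Saturation solver failed: negative solid amount.", call. = FALSE)
  }
  solid <- max(solid, 0)
  fr <- c(free_ag, agcl, agcl2) / tag
  speciation_row(tag, tcl, free_ag, free_cl, fr, solid / tag, k,
                 saturated = TRUE)
}

speciation_row <- function(tag, tcl, free_ag, free_cl, fr, frac_solid, k,
                           saturated = FALSE) {
  tibble::tibble(
    total_ag = tag,
    total_cl = tcl,
    free_ag = free_ag,
    free_cl = free_cl,
    fraction_free_ag = fr[1],
    fraction_agcl = fr[2],
    fraction_agcl2 = fr[3],
    fraction_solid = frac_solid,
    ion_product = free_ag * free_cl,
    saturated = saturated
  )
}

#' Saturation check against the AgCl solubility product
#'
#' @param free_ag,free_cl Free-ion concentrations in mol/L (vectorised).
#' @param constants An [agcl_constants()] set.
#' @return A tibble with `ion_product` (\[Ag+\]\[Cl-\], M^2) and `saturated`
#'   (`TRUE` when the ion product exceeds Ks).
#' @examples
#' saturation_check(1e-3, 1e-3) # oversaturated
#' @export
saturation_check <- function(free_ag, free_cl, constants = agcl_constants()) {
  if (any(free_ag < 0) || any(free_cl < 0)) {
    stop("Concentrations must be non-negative.", call. = FALSE)
  }
  ip <- free_ag * free_cl
  tibble::tibble(ion_product = ip, saturated = ip > constants$ksp)
}
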