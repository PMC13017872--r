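# Independent oracles used across the suite. These deliberately take the
# brute-force route (quadrature, bisection, grid search) rather than the
# closed forms the package implements.

# time integral of exp(-lambda t) on [0, T_seconds] by adaptive quadrature
quad_decay_integral <- function(T_days, half_life_days = 7.45) {
  lambda <- log(2) / (half_life_days * 86400)
  stats::integrate(function(t) exp(-lambda * t), 0, T_days * 86400,
                   rel.tol = 1e-12)$value
}

# Ag-Cl equilibrium by bisection on free [Ag+] over [0, total_ag]:
# for trial free Ag the chloride balance is a quadratic in free Cl
# (2 b2 ag cl^2 + (1 + b1 ag) cl - tcl = 0); the silver-balance residual
# is then bisected to zero. Unsaturated systems only.
bisect_speciation <- function(tag, tcl, ksp = 1.77e-10, b1 = 2e3,
                              b2 = 1.86e5, iters = 200) {
  cl_at <- function(ag) {
    a <- 2 * b2 * ag
    b <- 1 + b1 * ag
    if (a == 0) return(tcl / b)
    (-b + sqrt(b^2 + 4 * a * tcl)) / (2 * a)
  }
  resid <- function(ag) {
    cl <- cl_at(ag)
    ag * (1 + b1 * cl + b2 * cl^2) - tag
  }
  lo <- 0; hi <- tag
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) hi <- mid else lo <- mid
  }
  ag <- (lo + hi) / 2
  cl <- cl_at(ag)
  fr <- c(1, b1 * cl, b2 * cl^2)
  list(free_ag = ag, free_cl = cl, fractions = fr / sum(fr))
}

# isoeffect dose by bisection on the LQ survival curve
bisect_dose_at_sf <- function(alpha, beta, sf, hi = 1000, iters = 200) {
  surv <- function(D) exp(-alpha * D - beta * D^2)
  lo <- 0
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (surv(mid) > sf) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# constrained LQ least squares by grid search over (alpha, beta >= 0)
grid_lq <- function(dose, y, w = rep(1, length(dose)),
                    alpha_grid = seq(0, 2, by = 0.002),
                    beta_grid = seq(0, 0.3, by = 0.002)) {
  best <- c(NA, NA); best_rss <- Inf
  for (a in alpha_grid) for (b in beta_grid) {
    rss <- sum(w * (y - a * dose - b * dose^2)^2)
    if (rss < best_rss) { best_rss <- rss; best <- c(a, b) }
  }
  list(alpha = best[1], beta = best[2], rss = best_rss)
}
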