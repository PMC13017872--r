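#' Simulate a clonogenic colony-count table
#'
#' Generates per-dish colony counts under the linear-quadratic survival
#' law. Each dish seeds `cells_seeded` cells; every cell independently
#' forms a colony with probability \eqn{pe_0 \cdot SF(D)}, so counts are
#' binomial thinnings of the seeded cells and can never exceed them
#' (the physical bound that rules out a Poisson model). Control dishes sit
#' at D = 0. With `noise = "none"` the expected counts are returned
#' (rounded to 1e-6 cells, not sampled), which makes the generating
#' parameters exactly recoverable by [fit_lq()].
#'
#' Defaults are the study-scale design: dose ladder \{0.5, 1, 2, 4\} Gy,
#' triplicate dishes, 1000 cells per dish, control plating efficiency 0.5.
#'
#' @param alpha,beta True LQ parameters (Gy^-1, Gy^-2).
#' @param doses_Gy Treated dose levels (Gy, positive).
#' @param cells_seeded Cells seeded per dish.
#' @param pe0 Control plating efficiency in (0, 1].
#' @param replicates Dishes per condition.
#' @param exposure_days Exposure label carried through the records.
#' @param noise `"binomial"` (sampled counts) or `"none"` (expected
#'   counts).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return A tibble of colony records: `sample_id`, `dose_Gy`,
#'   `exposure_days`, `replicate`, `cells_seeded`, `colonies`,
#'   `is_control`, with the generating truth in `attr(, "truth")`.
#' @examples
#' simulate_clonogenic(seed = 1)
#' @export
simulate_clonogenic <- function(alpha = 0.5, beta = 0.04,
                                doses_Gy = c(0.5, 1, 2, 4),
                                cells_seeded = 1000, pe0 = 0.5,
                                replicates = 3, exposure_days = 6,
                                noise = c("binomial", "none"),
                                seed = 1) {
  noise <- match.arg(noise)
  if (pe0 <= 0 || pe0 > 1) stop("`pe0` must be in (0, 1].", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1.", call. = FALSE)
  all_doses <- c(0, doses_Gy)
  sf <- exp(-alpha * all_doses - beta * all_doses^2)
  p <- pe0 * sf
  if (any(p > 1)) {
    stop("pe0 * SF exceeds 1 at some dose: invalid configuration.",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(dose_Gy = all_doses,
                             replicate = seq_len(replicates))
  grid$p <- rep(p, each = replicates)
  colonies <- if (noise == "binomial") {
    withr::with_seed(seed,
      stats::rbinom(nrow(grid), cells_seeded, grid$p))
  } else {
    cells_seeded * grid$p
  }
  out <- tibble::tibble(
    sample_id = sprintf("D%g_r%d_%gd", grid$dose_Gy, grid$replicate,
                        exposure_days),
    dose_Gy = grid$dose_Gy,
    exposure_days = exposure_days,
    replicate = grid$replicate,
    cells_seeded = cells_seeded,
    colonies = colonies,
    is_control = grid$dose_Gy == 0
  )
  attr(out, "truth") <- list(alpha = alpha, beta = beta, pe0 = pe0,
                             seed = seed, noise = noise)
  out
}

#' Simulate a DAPI / focus-channel image pair with ground truth
#'
#' Renders a two-channel fluorescence micrograph the analysis functions can
#' be validated against: elliptical nuclei with smooth interiors placed
#' without overlap, 2-D Gaussian foci planted inside nuclei in the focus
#' channel, small circular micronuclei placed a few pixels outside a
#' random fraction of nuclei in the DAPI channel, and additive Gaussian
#' background noise in both channels. Every planted object is recorded in
#' the returned ground-truth tables.
#'
#' Intensities are arbitrary fluorescence units: background 0 with noise
#' SD `noise_sd`, nucleus interior `nucleus_intensity`, focus peak
#' amplitude `focus_amplitude` x `noise_sd` (so amplitudes are stated in
#' multiples of the background SD, the scale the detection threshold
#' lives on).
#'
#' @param n_nuclei Number of nuclei to place.
#' @param image_size Image side in px (square image).
#' @param axis_range Range of the nucleus semi-major axis in px (major
#'   axis 20-30 px at the default scale).
#' @param aspect_range Range of the semi-minor/semi-major axis ratio.
#' @param foci_per_nucleus Either a fixed integer count per nucleus or
#'   `list(poisson = mean)` for Poisson-distributed counts.
#' @param focus_amplitude Focus peak height in multiples of `noise_sd`.
#' @param focus_sigma Focus Gaussian sigma in px (default 0.8, a
#'   near-diffraction-limited spot ~3 px across).
#' @param focus_min_sep Minimum separation between planted foci centres in
#'   px. Foci closer than about 5.5 px are not resolvable by the
#'   connected-component counting rule at the default band-pass, so the
#'   generator only plants resolvable configurations; it fails explicitly
#'   when `foci_per_nucleus` cannot be packed into a nucleus at this
#'   separation.
#' @param mn_frequency Fraction of nuclei given one adjacent micronucleus.
#' @param mn_radius Micronucleus radius in px.
#' @param nucleus_intensity Nucleus interior level (DAPI channel).
#' @param noise_sd Additive Gaussian noise SD (both channels).
#' @param max_tries Placement attempts per nucleus before giving up.
#' @param seed Integer seed.
#' @return A list of class `image_pair`: `dapi` and `focus` matrices,
#'   and `truth` — a list of tibbles `nuclei` (centre, axes, orientation),
#'   `foci` (positions, per-nucleus counts) and `micronuclei`. Fails
#'   explicitly (reporting the achieved count) if the nuclei cannot be
#'   packed.
#' @export
generate_image_pair <- function(n_nuclei = 50, image_size = 512,
                                axis_range = c(10, 15),
                                aspect_range = c(0.7, 0.9),
                                foci_per_nucleus = 0,
                                focus_amplitude = 10, focus_sigma = 0.8,
                                focus_min_sep = 5.5,
                                mn_frequency = 0, mn_radius = 3,
                                nucleus_intensity = 40, noise_sd = 1,
                                max_tries = 2000, seed = 1) {
  stopifnot(n_nuclei >= 0, image_size > 4 * max(axis_range),
            focus_amplitude > 0, noise_sd > 0,
            mn_frequency >= 0, mn_frequency <= 1)
  res <- withr::with_seed(seed, render_image_pair(
    n_nuclei, image_size, axis_range, aspect_range, foci_per_nucleus,
    focus_amplitude, focus_sigma, focus_min_sep, mn_frequency, mn_radius,
    nucleus_intensity, noise_sd, max_tries
  ))
  res$seed <- seed
  structure(res, class = "image_pair")
}

render_image_pair <- function(n_nuclei, image_size, axis_range, aspect_range,
                              foci_per_nucleus, focus_amplitude, focus_sigma,
                              focus_min_sep, mn_frequency, mn_radius,
                              nucleus_intensity, noise_sd, max_tries) {
  sz <- image_size
  dapi <- matrix(0, sz, sz)
  focus <- matrix(0, sz, sz)
  rows <- matrix(rep(seq_len(sz), sz), sz, sz)
  cols <- matrix(rep(seq_len(sz), each = sz), sz, sz)

  # margin keeps nuclei, their foci and adjacent micronuclei off the border
  margin <- max(axis_range) + 2 * mn_radius + 8
  nuclei <- tibble::tibble(label = integer(), centre_row = numeric(),
                           centre_col = numeric(), semi_major = numeric(),
                           semi_minor = numeric(), angle = numeric())
  placed <- 0
  for (i in seq_len(n_nuclei)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      a <- stats::runif(1, axis_range[1], axis_range[2])
      b <- a * stats::runif(1, aspect_range[1], aspect_range[2])
      cr <- stats::runif(1, margin, sz - margin)
      cc <- stats::runif(1, margin, sz - margin)
      # non-overlap: centre separation > sum of semi-major axes + MN gap
      if (placed == 0 ||
          all(sqrt((nuclei$centre_row - cr)^2 + (nuclei$centre_col - cc)^2) >
              nuclei$semi_major + a + 2 * mn_radius + 6)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(
        "Could not place nucleus %d of %d after %d tries (image too crowded).",
        i, n_nuclei, max_tries
      ), call. = FALSE)
    }
    angle <- stats::runif(1, 0, pi)
    nuclei <- dplyr::bind_rows(nuclei, tibble::tibble(
      label = i, centre_row = cr, centre_col = cc,
      semi_major = a, semi_minor = b, angle = angle
    ))
    placed <- placed + 1
    # smooth interior: peak at centre, falling to ~60% at the rim
    u <- ((rows - cr) * cos(angle) + (cols - cc) * sin(angle)) / a
    v <- (-(rows - cr) * sin(angle) + (cols - cc) * cos(angle)) / b
    r2 <- u^2 + v^2
    inside <- r2 <= 1
    dapi[inside] <- dapi[inside] + nucleus_intensity * (1 - 0.4 * r2[inside])
  }

  # foci: planted inside the nucleus (within 85% of the radius), with a
  # minimum pairwise separation so every planted focus stays resolvable
  foci <- tibble::tibble(nucleus_label = integer(), row = numeric(),
                         col = numeric())
  if (nrow(nuclei) > 0) {
    k_draw <- function() {
      if (is.list(foci_per_nucleus)) {
        stats::rpois(1, foci_per_nucleus$poisson)
      } else {
        as.integer(foci_per_nucleus)
      }
    }
    for (i in seq_len(nrow(nuclei))) {
      k <- k_draw()
      if (k == 0) next
      nuc <- nuclei[i, ]
      pts <- place_separated_points(
        k, nuc$semi_major * 0.85, nuc$semi_minor * 0.85, focus_min_sep
      )
      if (is.null(pts)) {
        stop(sprintf(
          paste0("Could not place %d foci with separation %.1f px in ",
                 "nucleus %d (axes %.1f x %.1f px): reduce the count or ",
                 "enlarge the nuclei."),
          k, focus_min_sep, nuc$label, nuc$semi_major, nuc$semi_minor
        ), call. = FALSE)
      }
      fr <- nuc$centre_row + pts[, 1] * cos(nuc$angle) -
        pts[, 2] * sin(nuc$angle)
      fc <- nuc$centre_col + pts[, 1] * sin(nuc$angle) +
        pts[, 2] * cos(nuc$angle)
      for (j in seq_len(k)) {
        focus <- focus + focus_amplitude * noise_sd *
          exp(-((rows - fr[j])^2 + (cols - fc[j])^2) / (2 * focus_sigma^2))
      }
      foci <- dplyr::bind_rows(foci, tibble::tibble(
        nucleus_label = nuc$label, row = fr, col = fc
      ))
    }
  }

  # micronuclei: small discs just outside a random subset of nuclei
  micronuclei <- tibble::tibble(nucleus_label = integer(), row = numeric(),
                                col = numeric(), radius = numeric())
  if (nrow(nuclei) > 0 && mn_frequency > 0) {
    with_mn <- which(stats::runif(nrow(nuclei)) < mn_frequency)
    for (i in with_mn) {
      nuc <- nuclei[i, ]
      theta <- stats::runif(1, 0, 2 * pi)
      # gap of 3-6 px between nucleus rim and micronucleus edge
      gap <- stats::runif(1, 3, 6)
      # rim distance along theta (ellipse radius in that direction)
      ct <- cos(theta - nuc$angle); st <- sin(theta - nuc$angle)
      rim <- 1 / sqrt((ct / nuc$semi_major)^2 + (st / nuc$semi_minor)^2)
      d <- rim + gap + mn_radius
      mr <- nuc$centre_row + d * cos(theta)
      mc <- nuc$centre_col + d * sin(theta)
      disc <- (rows - mr)^2 + (cols - mc)^2 <= mn_radius^2
      dapi[disc] <- dapi[disc] + nucleus_intensity
      micronuclei <- dplyr::bind_rows(micronuclei, tibble::tibble(
        nucleus_label = nuc$label, row = mr, col = mc, radius = mn_radius
      ))
    }
  }

  dapi <- dapi + matrix(stats::rnorm(sz * sz, sd = noise_sd), sz, sz)
  focus <- focus + matrix(stats::rnorm(sz * sz, sd = noise_sd), sz, sz)

  list(dapi = dapi, focus = focus,
       truth = list(nuclei = nuclei, foci = foci, micronuclei = micronuclei))
}

# Sample k points inside an axis-aligned ellipse (semi-axes a, b, centred
# at the origin) with pairwise distance >= min_sep. Greedy best-candidate
# sampling with restarts; NULL when the configuration cannot be packed.
place_separated_points <- function(k, a, b, min_sep, n_candidates = 64,
                                   n_restarts = 200) {
  if (k == 1) {
    repeat {
      p <- stats::runif(2, -1, 1)
      if (sum(p^2) <= 1) return(cbind(p[1] * a, p[2] * b))
    }
  }
  draw_inside <- function(n) {
    u <- stats::runif(2 * n, -1, 1)
    m <- matrix(u, ncol = 2)
    m <- m[m[, 1]^2 + m[, 2]^2 <= 1, , drop = FALSE]
    cbind(m[, 1] * a, m[, 2] * b)
  }
  for (r in seq_len(n_restarts)) {
    pts <- draw_inside(8)[1, , drop = FALSE]
    ok <- TRUE
    for (j in seq_len(k - 1)) {
      cand <- draw_inside(n_candidates * 2)
      if (nrow(cand) == 0) { ok <- FALSE; break }
      dmin <- apply(cand, 1, function(p) {
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))
      })
      best <- which.max(dmin)
      if (dmin[best] < min_sep) { ok <- FALSE; break }
      pts <- rbind(pts, cand[best, , drop = FALSE])
    }
    if (ok) return(pts)
  }
  NULL
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf(
    "<image_pair> %d x %d px, %d nuclei, %d foci, %d micronuclei (seed %d)\n",
    nrow(x$dapi), ncol(x$dapi), nrow(x$truth$nuclei), nrow(x$truth$foci),
    nrow(x$truth$micronuclei), x$seed
  ))
  invisible(x)
}

#' Simulate a full two-arm exposure dataset
#'
#' Combines the dosimetry planner and the clonogenic generator: builds the
#' exposure plan (activity concentrations per dose and exposure time) and
#' simulates a colony-count table for each exposure arm under per-arm LQ
#' parameters. This reproduces the structure of a two-exposure-time
#' radionuclide study, where the same dose ladder is delivered at two dose
#' rates.
#'
#' @param doses_Gy Dose ladder (Gy).
#' @param exposure_days Exposure arms (days).
#' @param arm_params Named list mapping each exposure time (as character)
#'   to `list(alpha =, beta =)` truth for that arm.
#' @param s_medium,physics Dosimetry constants, see [dose_from_activity()].
#' @param seed Integer seed; per-arm child seeds are derived from it.
#' @param ... Further arguments passed to [simulate_clonogenic()]
#'   (`cells_seeded`, `pe0`, `replicates`, `noise`).
#' @return A list with `plan` (tibble from [plan_exposure()]) and
#'   `colonies` (tibble of colony records over both arms).
#' @export
generate_exposure_dataset <- function(doses_Gy = c(0.5, 1, 2, 4),
                                      exposure_days = c(4, 6),
                                      arm_params = list(
                                        "4" = list(alpha = 0.4, beta = 0.03),
                                        "6" = list(alpha = 0.5, beta = 0.04)
                                      ),
                                      s_medium = s_medium_calibrated(physics),
                                      physics = ag111_physics(),
                                      seed = 1, ...) {
  plan <- plan_exposure(doses_Gy, exposure_days, s_medium = s_medium,
                        physics = physics)
  if (length(doses_Gy) == 0) {
    return(list(plan = plan, colonies = tibble::tibble()))
  }
  colonies <- purrr::imap_dfr(
    stats::setNames(exposure_days, as.character(exposure_days)),
    function(days, key) {
      pars <- arm_params[[as.character(days)]]
      if (is.null(pars)) {
        stop("No LQ truth supplied for the ", days, "-day arm.", call. = FALSE)
      }
      simulate_clonogenic(
        alpha = pars$alpha, beta = pars$beta, doses_Gy = doses_Gy,
        exposure_days = days,
        seed = seed + match(days, exposure_days) * 1000L, ...
      )
    }
  )
  list(plan = plan, colonies = colonies)
}
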