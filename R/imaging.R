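#' Detection parameters for foci and micronucleus quantification
#'
#' Collects the tunable knobs of the image pipeline in one validated list.
#' Defaults are stated at the working scale of the synthetic fixtures
#' (nucleus major axis 20-30 px, focus diameter 3-6 px) and mirror common
#' foci-counting practice: difference-of-Gaussians background subtraction
#' followed by a threshold at `threshold_multiplier` times the median
#' per-nucleus background SD.
#'
#' @param dog_sigma_small,dog_sigma_large Gaussian sigmas (px) of the DoG
#'   band-pass; small < large.
#' @param threshold_multiplier Foci threshold in units of the median
#'   nuclear background SD (default 3).
#' @param min_focus_area Minimum focus size in px.
#' @param bg_exclusion_radius Radius (px) by which candidate-focus regions
#'   are dilated before the background SD is measured on the remaining
#'   nucleus pixels; covers the sub-threshold tails of bright spots.
#' @param nucleus_min_area Minimum nucleus size in px; smaller objects are
#'   discarded by the segmenter.
#' @param mn_area_range Micronucleus area window as a fraction of the mean
#'   nucleus area (the assay's "small chromatin body" size gate).
#' @param mn_max_distance Maximum distance (px) from a micronucleus to the
#'   nearest nucleus boundary.
#' @param mn_min_circularity Minimum circularity 4 pi A / P^2 of a
#'   micronucleus candidate (discards debris and streaks).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(dog_sigma_small = 1,
                             dog_sigma_large = 4,
                             threshold_multiplier = 3,
                             min_focus_area = 3,
                             bg_exclusion_radius = 3,
                             nucleus_min_area = 50,
                             mn_area_range = c(0.01, 0.30),
                             mn_max_distance = 25,
                             mn_min_circularity = 0.6) {
  if (dog_sigma_small <= 0 || dog_sigma_large <= 0) {
    stop("DoG sigmas must be positive.", call. = FALSE)
  }
  if (dog_sigma_small >= dog_sigma_large) {
    stop("`dog_sigma_small` must be smaller than `dog_sigma_large`.",
         call. = FALSE)
  }
  if (threshold_multiplier <= 0) {
    stop("`threshold_multiplier` must be positive.", call. = FALSE)
  }
  structure(
    list(
      dog_sigma_small = dog_sigma_small, dog_sigma_large = dog_sigma_large,
      threshold_multiplier = threshold_multiplier,
      min_focus_area = min_focus_area,
      bg_exclusion_radius = bg_exclusion_radius,
      nucleus_min_area = nucleus_min_area,
      mn_area_range = mn_area_range, mn_max_distance = mn_max_distance,
      mn_min_circularity = mn_min_circularity
    ),
    class = "detection_params"
  )
}

as_image_matrix <- function(img) {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("Images must be numeric matrices (row, col).", call. = FALSE)
  }
  storage.mode(img) <- "double"
  img
}

#' Difference-of-Gaussians background subtraction
#'
#' Band-pass filters an image: \eqn{G(\sigma_s) * I - G(\sigma_l) * I}.
#' Constant backgrounds (and any added offset) map to zero, which is what
#' makes the downstream foci threshold robust to illumination level.
#'
#' @param img Numeric matrix, pixel (row, col) indexing (1-based).
#' @param sigma_small,sigma_large Gaussian sigmas in px, small < large.
#' @return A matrix of the same size.
#' @export
dog_subtract <- function(img, sigma_small = 1, sigma_large = 4) {
  img <- as_image_matrix(img)
  if (sigma_small <= 0 || sigma_large <= 0) {
    stop("Sigmas must be positive.", call. = FALSE)
  }
  if (sigma_small >= sigma_large) {
    stop("`sigma_small` must be smaller than `sigma_large`.", call. = FALSE)
  }
  small <- EBImage::gblur(img, sigma = sigma_small)
  large <- EBImage::gblur(img, sigma = sigma_large)
  as_image_matrix(small) - as_image_matrix(large)
}

#' Segment nuclei in a DAPI image
#'
#' Global automatic (Otsu) threshold on a lightly smoothed image, connected
#' components, then removal of objects below `nucleus_min_area` and of
#' objects touching the image border (whose area and morphology are
#' censored). Deterministic for a fixed input.
#'
#' @param dapi Numeric matrix (row, col), the nuclear-stain channel.
#' @param params A [detection_params()] list.
#' @param smooth_sigma Pre-threshold Gaussian smoothing sigma in px.
#' @return An object of class `nucleus_masks`: list with `labels` (integer
#'   matrix, 0 = background) and `nuclei`, a tibble with `label`, `area`
#'   (px), `centroid_row`, `centroid_col` (1-based pixel coordinates).
#'   A blank or constant image yields zero nuclei, not an error.
#' @export
segment_nuclei <- function(dapi, params = detection_params(),
                           smooth_sigma = 2) {
  dapi <- as_image_matrix(dapi)
  if (any(!is.finite(dapi))) {
    stop("DAPI image contains non-finite intensities.", call. = FALSE)
  }
  rng <- range(dapi)
  empty <- function() {
    structure(
      list(
        labels = matrix(0L, nrow(dapi), ncol(dapi)),
        nuclei = tibble::tibble(label = integer(), area = integer(),
                                centroid_row = numeric(),
                                centroid_col = numeric())
      ),
      class = "nucleus_masks"
    )
  }
  if (diff(rng) == 0) return(empty())

  sm <- as_image_matrix(EBImage::gblur(dapi, sigma = smooth_sigma))
  norm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  labels <- as_image_matrix(EBImage::bwlabel(mask))

  info <- label_stats(labels)
  if (nrow(info) == 0) return(empty())
  keep <- info$area >= params$nucleus_min_area & !info$touches_border
  info <- info[keep, , drop = FALSE]
  labels[!(labels %in% info$label)] <- 0
  # relabel 1..n in raster order of first appearance
  new_id <- stats::setNames(seq_len(nrow(info)), info$label)
  relabelled <- labels
  relabelled[labels > 0] <- new_id[as.character(labels[labels > 0])]
  info$label <- as.integer(new_id[as.character(info$label)])

  structure(
    list(
      labels = matrix(as.integer(relabelled), nrow(dapi), ncol(dapi)),
      nuclei = tibble::tibble(
        label = info$label, area = info$area,
        centroid_row = info$centroid_row, centroid_col = info$centroid_col
      )
    ),
    class = "nucleus_masks"
  )
}

# Per-label area, centroid and border contact for a label matrix.
label_stats <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0) {
    return(tibble::tibble(label = integer(), area = integer(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          touches_border = logical()))
  }
  lab <- labels[idx]
  rows <- ((idx - 1) %% nrow(labels)) + 1
  cols <- ((idx - 1) %/% nrow(labels)) + 1
  on_border <- rows == 1 | rows == nrow(labels) |
    cols == 1 | cols == ncol(labels)
  df <- tibble::tibble(label = lab, row = rows, col = cols,
                       border = on_border)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$label),
    area = dplyr::n(),
    centroid_row = mean(.data$row),
    centroid_col = mean(.data$col),
    touches_border = any(.data$border),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$label)
}

#' @export
print.nucleus_masks <- function(x, ...) {
  cat(sprintf("<nucleus_masks> %d nuclei in a %d x %d image\n",
              nrow(x$nuclei), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Count DNA-damage foci per nucleus
#'
#' Implements the threshold rule of standard foci-counting macros: the
#' focus channel is background-subtracted with a difference of Gaussians,
#' and the detection threshold is set to `threshold_multiplier` (default 3)
#' times the *median over nuclei* of the per-nucleus background SD. The
#' per-nucleus background SD is computed on the DoG image in two passes:
#' a provisional threshold is set from a robust per-nucleus scale estimate
#' (the median absolute deviation, which bright candidate foci cannot
#' inflate); the candidate-focus regions above it, dilated by
#' `bg_exclusion_radius` to cover their sub-threshold tails, are excluded;
#' and the background SD proper is then computed once on the remaining
#' nucleus pixels. Candidate foci are connected components above
#' the final threshold inside each nucleus; components smaller than
#' `min_focus_area` are discarded.
#'
#' @param focus_img Numeric matrix (row, col), one immunofluorescence
#'   channel (e.g. 53BP1 or gamma-H2AX), registered to the DAPI channel.
#' @param masks A `nucleus_masks` object from [segment_nuclei()].
#' @param params A [detection_params()] list.
#' @param channel Label copied into the output (e.g. `"53BP1"`).
#' @return A tibble with one row per nucleus: `nucleus_label`, `channel`,
#'   `n_foci` and the standard recurrence `group` (`"0"`, `"1-4"`, `"5-9"`,
#'   `">=10"`). No nuclei yields an empty tibble.
#' @export
detect_foci <- function(focus_img, masks, params = detection_params(),
                        channel = "foci") {
  stopifnot(inherits(masks, "nucleus_masks"))
  focus_img <- as_image_matrix(focus_img)
  if (!all(dim(focus_img) == dim(masks$labels))) {
    stop("Focus channel and nucleus masks have different dimensions.",
         call. = FALSE)
  }
  empty <- tibble::tibble(nucleus_label = integer(), channel = character(),
                          n_foci = integer(), group = character())
  if (nrow(masks$nuclei) == 0) return(empty)

  dog <- dog_subtract(focus_img, params$dog_sigma_small, params$dog_sigma_large)
  labs <- masks$nuclei$label

  # pass 1: robust scale (MAD) over all nucleus pixels -> provisional
  # threshold that bright foci cannot drag upwards
  mad_all <- vapply(labs, function(l) stats::mad(dog[masks$labels == l]),
                    numeric(1))
  provisional <- params$threshold_multiplier * stats::median(mad_all, na.rm = TRUE)
  # pass 2: background SD on nucleus pixels outside the dilated
  # candidate-focus regions (dilation covers the spots' sub-threshold tails)
  brush <- EBImage::makeBrush(2 * params$bg_exclusion_radius + 1, "disc")
  excluded <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(dog > provisional), brush)
  ) > 0
  sd_bg <- vapply(labs, function(l) {
    px <- dog[masks$labels == l & !excluded]
    if (length(px) < 30) return(NA_real_)
    stats::sd(px)
  }, numeric(1))
  if (all(is.na(sd_bg))) {
    # pathological: foci cover nearly every nucleus; fall back to the
    # robust whole-nucleus scale
    sd_bg <- mad_all
  }
  threshold <- params$threshold_multiplier * stats::median(sd_bg, na.rm = TRUE)

  n_foci <- vapply(labs, function(l) {
    inside <- masks$labels == l
    cand <- dog > threshold & inside
    if (!any(cand)) return(0L)
    comp <- as_image_matrix(EBImage::bwlabel(cand))
    sizes <- tabulate(comp[comp > 0])
    sum(sizes >= params$min_focus_area)
  }, integer(1))

  tibble::tibble(
    nucleus_label = labs,
    channel = channel,
    n_foci = n_foci,
    group = bin_foci(n_foci)
  )
}

#' Foci recurrence groups
#'
#' Assigns the conventional four recurrence classes used to summarise
#' foci-per-nucleus distributions: 0, 1-4, 5-9 and >=10.
#'
#' @param n_foci Non-negative integer counts (vectorised).
#' @return A character vector with levels `"0"`, `"1-4"`, `"5-9"`, `">=10"`.
#' @examples
#' bin_foci(c(0, 4, 5, 10))
#' @export
bin_foci <- function(n_foci) {
  if (any(n_foci < 0) || any(n_foci != floor(n_foci))) {
    stop("`n_foci` must be non-negative integers.", call. = FALSE)
  }
  dplyr::case_when(
    n_foci == 0 ~ "0",
    n_foci <= 4 ~ "1-4",
    n_foci <= 9 ~ "5-9",
    TRUE ~ ">=10"
  )
}

#' Foci group distribution
#'
#' @param foci A tibble from [detect_foci()] (possibly several images
#'   bound together).
#' @param ... Extra grouping columns (e.g. `channel`, `dose_Gy`).
#' @return A tibble of group counts and fractions per grouping.
#' @export
foci_group_distribution <- function(foci, ...) {
  counts <- dplyr::count(foci, ..., group = factor(.data$group,
                                                   levels = c("0", "1-4", "5-9", ">=10")),
                         .drop = FALSE, name = "n_cells")
  dplyr::mutate(dplyr::group_by(counts, ...),
                fraction = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup()
}

#' Detect micronuclei in a DAPI image
#'
#' Micronuclei are small DAPI-positive chromatin bodies lying outside, but
#' near, a main nucleus. Candidates are the segmented DAPI objects that
#' were too small to be nuclei; they qualify as micronuclei when their
#' area falls inside `mn_area_range` times the mean nucleus area, their
#' circularity is at least `mn_min_circularity`, they do not touch any
#' nucleus, and their centroid lies within `mn_max_distance` px of the
#' nearest nucleus boundary. Each micronucleus is assigned to the nucleus
#' with the nearest centroid.
#'
#' @param dapi Numeric matrix (row, col), the nuclear-stain channel.
#' @param masks A `nucleus_masks` object from [segment_nuclei()] on the
#'   same image.
#' @param params A [detection_params()] list.
#' @return An object of class `mn_result`: list with `records` (tibble:
#'   `nucleus_label`, `mn_count` for every nucleus) and `candidates`
#'   (tibble of accepted micronuclei with area, centroid and distance).
#'   Summarise with [mn_frequency()].
#' @export
detect_micronuclei <- function(dapi, masks, params = detection_params()) {
  stopifnot(inherits(masks, "nucleus_masks"))
  dapi <- as_image_matrix(dapi)
  if (nrow(masks$nuclei) == 0) {
    stop("No nuclei segmented: micronucleus frequency is undefined.",
         call. = FALSE)
  }

  sm <- as_image_matrix(EBImage::gblur(dapi, sigma = 1))
  norm <- (sm - min(sm)) / max(max(sm) - min(sm), .Machine$double.eps)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  all_labels <- as_image_matrix(EBImage::bwlabel(mask))
  info <- label_stats(all_labels)

  mean_area <- mean(masks$nuclei$area)
  area_lo <- params$mn_area_range[1] * mean_area
  area_hi <- params$mn_area_range[2] * mean_area

  # distance of every pixel to the nearest nucleus pixel
  dist_to_nucleus <- as_image_matrix(EBImage::distmap(masks$labels == 0))

  # object-level gates
  nucleus_overlap <- vapply(info$label, function(l) {
    any(masks$labels[all_labels == l] > 0)
  }, logical(1))
  perim <- object_perimeters(all_labels, info$label)
  circ <- 4 * pi * info$area / pmax(perim, 1)^2
  cent_idx <- cbind(round(info$centroid_row), round(info$centroid_col))
  cent_dist <- dist_to_nucleus[cent_idx]

  accept <- !nucleus_overlap &
    info$area >= area_lo & info$area <= area_hi &
    circ >= params$mn_min_circularity &
    cent_dist > 0 & cent_dist <= params$mn_max_distance
  cand <- info[accept, , drop = FALSE]

  nearest <- integer(nrow(cand))
  if (nrow(cand) > 0) {
    nc <- as.matrix(masks$nuclei[, c("centroid_row", "centroid_col")])
    for (i in seq_len(nrow(cand))) {
      d2 <- (nc[, 1] - cand$centroid_row[i])^2 +
        (nc[, 2] - cand$centroid_col[i])^2
      nearest[i] <- masks$nuclei$label[which.min(d2)]
    }
  }

  counts <- table(factor(nearest, levels = masks$nuclei$label))
  structure(
    list(
      records = tibble::tibble(
        nucleus_label = masks$nuclei$label,
        mn_count = as.integer(counts)
      ),
      candidates = tibble::tibble(
        nucleus_label = nearest,
        area = cand$area,
        centroid_row = cand$centroid_row,
        centroid_col = cand$centroid_col,
        boundary_distance = cent_dist[accept]
      )
    ),
    class = "mn_result"
  )
}

# 4-neighbour boundary pixel count per label: a cheap perimeter estimate
# adequate for a circularity gate.
object_perimeters <- function(labels, which_labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  padded <- matrix(0L, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- labels
  core <- padded[2:(nr + 1), 2:(nc + 1)]
  boundary <- core > 0 & (
    padded[1:nr, 2:(nc + 1)] != core |
      padded[3:(nr + 2), 2:(nc + 1)] != core |
      padded[2:(nr + 1), 1:nc] != core |
      padded[2:(nr + 1), 3:(nc + 2)] != core
  )
  vapply(which_labels, function(l) sum(core == l & boundary), numeric(1))
}

#' @export
print.mn_result <- function(x, ...) {
  s <- mn_frequency(x)
  cat(sprintf(
    "<mn_result> %d nuclei, %d micronuclei; frequency %.3f +/- %.3f\n",
    nrow(x$records), sum(x$records$mn_count), s$frequency, s$se
  ))
  invisible(x)
}

#' Micronucleus frequency with binomial standard error
#'
#' The assay's summary statistic: the fraction of cells carrying at least
#' one micronucleus, with the standard error computed from the number of
#' scored cells, \eqn{SE = \sqrt{p(1-p)/n}}.
#'
#' @param x An `mn_result` from [detect_micronuclei()], or a tibble with a
#'   `mn_count` column (one row per cell; rows from several images or
#'   coverslips may be bound together before summarising).
#' @return A tibble with `n_cells`, `n_with_mn`, `frequency`, `se`.
#' @export
mn_frequency <- function(x) {
  records <- if (inherits(x, "mn_result")) x$records else tibble::as_tibble(x)
  if (!"mn_count" %in% names(records)) {
    stop("Need a `mn_count` column.", call. = FALSE)
  }
  n <- nrow(records)
  if (n == 0) {
    stop("Zero cells: micronucleus frequency is undefined.", call. = FALSE)
  }
  p <- mean(records$mn_count >= 1)
  tibble::tibble(
    n_cells = n,
    n_with_mn = sum(records$mn_count >= 1),
    frequency = p,
    se = sqrt(p * (1 - p) / n)
  )
}
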