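# deterministic two-ellipse raster used by several segmentation tests
draw_ellipses <- function(centres, a = 10, b = 8, size = 128, level = 40) {
  img <- matrix(0, size, size)
  rows <- matrix(rep(seq_len(size), size), size, size)
  cols <- matrix(rep(seq_len(size), each = size), size, size)
  for (i in seq_len(nrow(centres))) {
    inside <- ((rows - centres[i, 1]) / a)^2 +
      ((cols - centres[i, 2]) / b)^2 <= 1
    img[inside] <- level
  }
  img
}

test_that("difference of Gaussians kills constants and is linear", {
  flat <- dog_subtract(matrix(7.5, 64, 64))
  expect_lt(max(abs(flat)), 1e-10)
  # single bright pixel: positive centre response
  spot <- matrix(0, 65, 65)
  spot[33, 33] <- 1
  resp <- dog_subtract(spot)
  expect_gt(resp[33, 33], 0)
  expect_equal(which.max(resp), which.max(spot))
  # responses of two distant spots superpose
  two <- matrix(0, 129, 129)
  two[30, 30] <- 1
  two[100, 100] <- 1
  r2 <- dog_subtract(two)
  one_a <- matrix(0, 129, 129); one_a[30, 30] <- 1
  one_b <- matrix(0, 129, 129); one_b[100, 100] <- 1
  expect_equal(r2, dog_subtract(one_a) + dog_subtract(one_b),
               tolerance = 1e-6)
  expect_error(dog_subtract(spot, 4, 1), "smaller")
  expect_error(dog_subtract(spot, -1, 4), "positive")
})

test_that("segmentation finds planted nuclei and nothing in blank images", {
  blank <- segment_nuclei(matrix(0, 128, 128))
  expect_equal(nrow(blank$nuclei), 0)
  expect_true(all(blank$labels == 0))

  pair <- generate_image_pair(n_nuclei = 10, image_size = 384, seed = 21)
  masks <- segment_nuclei(pair$dapi)
  expect_equal(nrow(masks$nuclei), 10)
  # every truth centre has a segmented centroid within 2 px
  for (i in seq_len(10)) {
    d <- sqrt((masks$nuclei$centroid_row - pair$truth$nuclei$centre_row[i])^2 +
                (masks$nuclei$centroid_col - pair$truth$nuclei$centre_col[i])^2)
    expect_lt(min(d), 2)
  }
})

test_that("segmentation is translation-equivariant", {
  img <- draw_ellipses(rbind(c(40, 40), c(90, 80)), size = 160)
  img <- img + withr::with_seed(1, matrix(stats::rnorm(160^2), 160, 160))
  shifted <- matrix(min(img), 160, 160)
  shifted[(1 + 5):160, (1 + 7):160] <- img[1:(160 - 5), 1:(160 - 7)]
  m1 <- segment_nuclei(img)
  m2 <- segment_nuclei(shifted)
  expect_equal(nrow(m2$nuclei), nrow(m1$nuclei))
  ord1 <- order(m1$nuclei$centroid_row)
  ord2 <- order(m2$nuclei$centroid_row)
  expect_equal(m2$nuclei$centroid_row[ord2],
               m1$nuclei$centroid_row[ord1] + 5, tolerance = 0.2)
  expect_equal(m2$nuclei$centroid_col[ord2],
               m1$nuclei$centroid_col[ord1] + 7, tolerance = 0.2)
})

test_that("foci recurrence bins follow the standard grouping", {
  expect_identical(bin_foci(0), "0")
  expect_identical(bin_foci(c(1, 4)), c("1-4", "1-4"))
  expect_identical(bin_foci(c(5, 9)), c("5-9", "5-9"))
  expect_identical(bin_foci(c(10, 25)), c(">=10", ">=10"))
  expect_error(bin_foci(-1), "non-negative")
  dist <- foci_group_distribution(
    tibble::tibble(channel = "53BP1", n_foci = c(0, 2, 3, 7, 12),
                   group = bin_foci(c(0, 2, 3, 7, 12)))
  )
  expect_equal(sum(dist$fraction), 1)
  expect_equal(dist$n_cells[dist$group == "1-4"], 2L)
})

test_that("foci detection recovers planted spots and rejects faint ones", {
  pair <- generate_image_pair(n_nuclei = 15, axis_range = c(12, 15),
                              foci_per_nucleus = 7, focus_amplitude = 10,
                              seed = 31)
  masks <- segment_nuclei(pair$dapi)
  foci <- detect_foci(pair$focus, masks, channel = "gH2AX")
  expect_equal(nrow(foci), 15)
  expect_identical(unique(foci$channel), "gH2AX")
  expect_gte(mean(foci$n_foci == 7), 0.95)
  expect_true(all(foci$group[foci$n_foci == 7] == "5-9"))

  # no planted spots: a uniform-background focus channel yields no foci
  quiet <- generate_image_pair(n_nuclei = 15, foci_per_nucleus = 0,
                               seed = 32)
  m0 <- segment_nuclei(quiet$dapi)
  f0 <- detect_foci(quiet$focus, m0)
  expect_lte(mean(f0$n_foci), 0.1)

  # spots at 1x the background SD sit far below the 3-sigma threshold
  faint <- generate_image_pair(n_nuclei = 15, axis_range = c(12, 15),
                               foci_per_nucleus = 7, focus_amplitude = 1,
                               seed = 33)
  mf <- segment_nuclei(faint$dapi)
  ff <- detect_foci(faint$focus, mf)
  expect_lte(mean(ff$n_foci), 0.3)
  expect_gte(mean(ff$n_foci == 0), 0.8)

  # no nuclei: empty record set, not an error
  empty <- detect_foci(matrix(0, 64, 64), segment_nuclei(matrix(0, 64, 64)))
  expect_equal(nrow(empty), 0)
})

test_that("foci counts ignore a constant intensity offset", {
  pair <- generate_image_pair(n_nuclei = 10, axis_range = c(12, 15),
                              foci_per_nucleus = 5, focus_amplitude = 10,
                              seed = 41)
  masks <- segment_nuclei(pair$dapi)
  f1 <- detect_foci(pair$focus, masks)
  f2 <- detect_foci(pair$focus + 100, masks)
  expect_equal(f2$n_foci, f1$n_foci)
})

test_that("micronuclei are found near nuclei and counted per cell", {
  pair <- generate_image_pair(n_nuclei = 40, mn_frequency = 0.25, seed = 51)
  masks <- segment_nuclei(pair$dapi)
  mn <- detect_micronuclei(pair$dapi, masks)
  truth_n <- nrow(pair$truth$micronuclei)
  expect_equal(sum(mn$records$mn_count), truth_n, tolerance = 0.25)
  # accepted candidates are assigned to the nucleus they were planted by;
  # truth labels (placement order) map to segmentation labels (raster
  # order) through the nucleus centroids
  truth_nuc <- pair$truth$nuclei
  seg_label_of <- vapply(seq_len(nrow(truth_nuc)), function(i) {
    d <- (masks$nuclei$centroid_row - truth_nuc$centre_row[i])^2 +
      (masks$nuclei$centroid_col - truth_nuc$centre_col[i])^2
    masks$nuclei$label[which.min(d)]
  }, integer(1))
  planted_seg <- seg_label_of[match(pair$truth$micronuclei$nucleus_label,
                                    truth_nuc$label)]
  truth_by_label <- table(factor(planted_seg, levels = masks$nuclei$label))
  expect_gte(mean(mn$records$mn_count == as.integer(truth_by_label)), 0.9)

  # none planted: frequency 0 with zero binomial SE
  clean <- generate_image_pair(n_nuclei = 20, mn_frequency = 0, seed = 52)
  m0 <- segment_nuclei(clean$dapi)
  s0 <- mn_frequency(detect_micronuclei(clean$dapi, m0))
  expect_identical(s0$frequency, 0)
  expect_identical(s0$se, 0)

  expect_error(
    detect_micronuclei(matrix(0, 64, 64),
                       segment_nuclei(matrix(0, 64, 64))),
    "undefined"
  )
})

test_that("objects outside the micronucleus size window are never counted", {
  # one nucleus plus a same-intensity blob larger than 30% of its area and
  # a tiny 2-px speck below the lower bound
  img <- draw_ellipses(rbind(c(50, 50)), a = 12, b = 10, size = 160)
  img <- img + draw_ellipses(rbind(c(50, 100)), a = 8, b = 8, size = 160)
  img[120, 50] <- 40; img[121, 50] <- 40
  img <- img + withr::with_seed(2, matrix(stats::rnorm(160^2), 160, 160))
  masks <- segment_nuclei(img)
  expect_equal(nrow(masks$nuclei), 2) # the blob segments as a "nucleus"
  mn <- detect_micronuclei(img, masks)
  expect_identical(sum(mn$records$mn_count), 0L)
})

test_that("micronucleus frequency carries the binomial standard error", {
  recs <- tibble::tibble(mn_count = c(1, 0, 0, 2, 0, 0, 0, 0, 0, 0))
  s <- mn_frequency(recs)
  expect_equal(s$frequency, 0.2)
  expect_equal(s$se, sqrt(0.2 * 0.8 / 10))
  all_mn <- mn_frequency(tibble::tibble(mn_count = c(1, 1, 2)))
  expect_identical(all_mn$se, 0) # SE vanishes only at p = 0 or 1
  expect_error(mn_frequency(tibble::tibble(mn_count = integer())), "Zero")
})
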