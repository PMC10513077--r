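test_that("label_and_filter excludes edge, merged and sub-minimal blobs", {
  b <- matrix(0L, 60, 60)
  b[1:10, 20:30] <- 1L          # touches top edge
  b[30:40, 5:15] <- 1L          # interior square, ~1.6 um^2 at ppm 8.8
  lf <- label_and_filter(b, exclusion_config(min_area_um2 = 1,
                                             max_area_um2 = 10), ppm = 8.8)
  expect_equal(max(lf$labels), 1L)
  expect_equal(lf$exclusions$reason, "edge")
  # area cap flags a merged-sized component
  big <- matrix(0L, 200, 200); big[50:150, 50:150] <- 1L
  lf2 <- label_and_filter(big, exclusion_config(min_area_um2 = 1,
                                                max_area_um2 = 100), ppm = 8.8)
  expect_equal(lf2$exclusions$reason, "merged")
  # a synthetic merged pair is excluded by shape/area, a singleton kept
  sm <- generate_glomerulus_scene(scene_params(n_glomeruli = 1L,
                                               merged_pair_fraction = 1,
                                               seed = 21L))
  lf3 <- label_and_filter(sm$tuft_mask > 0, exclusion_config(), 8.8)
  expect_equal(max(lf3$labels), 0L)
  expect_true("merged" %in% lf3$exclusions$reason)
  ok <- small_scene(seed = 22L)
  lf4 <- label_and_filter(ok$tuft_mask > 0, exclusion_config(), 8.8)
  expect_equal(max(lf4$labels), 1L)
  # monotone: shrinking max_area never re-admits a removed component
  for (cap in c(300, 200, 100, 50)) {
    lf5 <- label_and_filter(ok$tuft_mask > 0,
                            exclusion_config(min_area_um2 = 1,
                                             max_area_um2 = cap), 8.8)
    expect_lte(max(lf5$labels), max(lf4$labels))
  }
})

test_that("morphometrics convert pixel counts at the stated resolution", {
  tuft <- matrix(0L, 120, 120); tuft[11:98, 11:98] <- 1L  # 88x88 px
  nuc <- matrix(0L, 120, 120)
  nuc[20:27, 20:29] <- 1L   # 80 px
  nuc[60:67, 60:68] <- 2L   # 72 px
  mor <- compute_morphometrics(tuft, nuc, ppm = 8.8)
  expect_equal(mor$tuft_area_um2, 100)                      # (88/8.8)^2
  expect_equal(mor$podocyte_count, 2L)
  expect_equal(mor$mean_nuclear_area_um2, 76 / 8.8^2)
  expect_equal(mor$area_density_per_1e4um2, 2 / 100 * 1e4)
  expect_equal(mor$nuclear_tuft_ratio, (80 + 72) / 88^2)
  # zero-nucleus glomerulus: count 0, flagged mean area
  mor0 <- compute_morphometrics(tuft, matrix(0L, 120, 120), 8.8)
  expect_equal(mor0$podocyte_count, 0L)
  expect_true(is.na(mor0$mean_nuclear_area_um2))
  expect_error(compute_morphometrics(tuft, nuc, ppm = 0), "ppm")
})

test_that("ground-truth scenes are recovered within pixelation tolerance", {
  s <- small_scene(seed = 5L)
  mor <- compute_morphometrics(s$tuft_mask, s$nuclei_mask, 8.8)
  expect_equal(mor$podocyte_count, s$per_glomerulus$n_nuclei)
  expect_equal(mor$tuft_area_um2, s$per_glomerulus$tuft_area_um2,
               tolerance = 0.02)
  expect_equal(mor$mean_nuclear_area_um2,
               s$per_glomerulus$mean_nuclear_area_um2, tolerance = 0.02)
  # nuclei lie inside the tuft, so their summed area cannot exceed it
  expect_lte(sum(mor$podocyte_count * mor$mean_nuclear_area_um2),
             sum(mor$tuft_area_um2))
})

test_that("otsu threshold equals the exhaustive within-class oracle", {
  # two-level histogram: threshold strictly between, positive fraction 0.4
  v <- c(rep(10, 60), rep(200, 40))
  th <- otsu_threshold(v)
  expect_gt(th, 10); expect_lt(th, 200)
  expect_equal(mean(v > th), 0.40)
  expect_equal(th, otsu_brute_force(v))
  # constant sample is degenerate
  expect_warning(thc <- otsu_threshold(rep(5, 10)), "constant")
  expect_true(is.na(thc))
  # random 8-bit histograms agree with the oracle exactly
  withr::with_seed(11, {
    for (i in 1:40) {
      x <- sample(0:255, 150, replace = TRUE,
                  prob = runif(256)^sample(1:3, 1))
      expect_identical(otsu_threshold(x), otsu_brute_force(x))
    }
  })
})

test_that("nephrin area and stain fractions behave on constructed images", {
  tuft <- matrix(0L, 50, 50); tuft[11:40, 11:40] <- 1L
  img <- matrix(0.1, 50, 50)
  img[tuft == 1] <- 0.2
  set.seed(2)
  pos <- sample(which(tuft == 1), round(0.3 * sum(tuft)))
  img[pos] <- 0.9   # 30% bright pixels inside the tuft
  na <- nephrin_area(img, tuft, ppm = 8.8)
  expect_false(na$degenerate)
  expect_equal(na$cytoplasm_tuft_ratio, 0.3, tolerance = 0.01)
  expect_equal(na$cytoplasm_area_um2, 0.3 * sum(tuft) / 8.8^2,
               tolerance = 0.01)
  # constant intensity inside the tuft: degenerate, zero area
  flat <- matrix(0.5, 50, 50)
  na0 <- suppressWarnings(nephrin_area(flat, tuft, 8.8))
  expect_true(na0$degenerate)
  expect_equal(na0$cytoplasm_area_um2, 0)
  # stain_fraction limits
  expect_equal(stain_fraction(matrix(1, 5, 5), matrix(1, 5, 5), threshold = 0.5), 1)
  expect_equal(stain_fraction(matrix(0, 5, 5), matrix(1, 5, 5), threshold = 0.5), 0)
  expect_error(stain_fraction(img, matrix(0, 50, 50)), "empty mask")
})
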