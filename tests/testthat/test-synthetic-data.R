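test_that("scene generation is seed-deterministic and truth-conserving", {
  p <- scene_params(seed = 7L)
  s1 <- generate_glomerulus_scene(p)
  s2 <- generate_glomerulus_scene(p)
  expect_identical(s1$image_wt1, s2$image_wt1)
  expect_identical(s1$nuclei_mask, s2$nuclei_mask)

  # labels are consecutive positive integers; truth table matches masks
  expect_identical(sort(unique(as.vector(s1$tuft_mask[s1$tuft_mask > 0]))),
                   seq_len(max(s1$tuft_mask)))
  expect_equal(nrow(s1$per_glomerulus), max(s1$tuft_mask))
  # conservation: nucleus labels inside tuft g equal the recorded count
  for (g in s1$per_glomerulus$glomerulus) {
    labs <- unique(s1$nuclei_mask[s1$tuft_mask == g])
    expect_equal(length(setdiff(labs, 0L)), s1$per_glomerulus$n_nuclei[g])
  }
  # different seed changes the image
  s3 <- generate_glomerulus_scene(scene_params(seed = 8L))
  expect_false(identical(s1$image_wt1, s3$image_wt1))
})

test_that("empty scenes and degenerate requests behave", {
  se <- generate_glomerulus_scene(scene_params(n_glomeruli = 0L))
  expect_equal(nrow(se$per_glomerulus), 0L)
  expect_equal(max(se$tuft_mask), 0L)
  expect_equal(max(se$nuclei_mask), 0L)
  # infeasible packing fails loudly
  expect_error(
    generate_glomerulus_scene(scene_params(frame_size_px = c(64L, 64L),
                                           n_glomeruli = 3L)),
    "infeasible packing")
})

test_that("a circular tuft's recorded area matches the analytic disk", {
  s <- generate_glomerulus_scene(scene_params(
    n_glomeruli = 1L, tuft_radius_um = c(10, 10),
    nuclei_per_glomerulus = c(5L, 5L), seed = 3L))
  expect_lt(abs(s$per_glomerulus$tuft_area_um2 / (pi * 100) - 1), 0.01)
})

test_that("edge and merged flags mark the constructed structures", {
  s <- generate_glomerulus_scene(scene_params(
    frame_size_px = c(700L, 700L), n_glomeruli = 2L,
    edge_touch_fraction = 0.5, merged_pair_fraction = 0.5, seed = 11L))
  pg <- s$per_glomerulus
  expect_equal(sum(pg$edge), 1L)
  expect_equal(sum(pg$merged), 1L)
  # the edge-flagged tuft really touches the frame
  g <- pg$glomerulus[pg$edge]
  idx <- which(s$tuft_mask == g)
  H <- nrow(s$tuft_mask)
  rows <- ((idx - 1L) %% H) + 1L; cols <- ((idx - 1L) %/% H) + 1L
  expect_true(any(rows == 1L | rows == H | cols == 1L |
                    cols == ncol(s$tuft_mask)))
})

test_that("scene TIFF round trip preserves images and label masks", {
  s <- small_scene(seed = 2L)
  dir <- withr::local_tempdir()
  paths <- write_scene(s, dir)
  expect_true(all(file.exists(paths)))
  back <- read_label_tiff(paths[["nuclei"]])
  expect_identical(back, s$nuclei_mask)
  img <- tiff::readTIFF(paths[["wt1"]])
  expect_lt(max(abs(img - s$image_wt1)), 1 / 65535)
})

test_that("sted scenes record analytic arc length, clipped at the field", {
  sg <- generate_sted_scene(list(curve_segment(c(5, 10), c(15, 10))), seed = 1)
  expect_equal(sg$true_total_length_um, 10)
  ci <- generate_sted_scene(list(curve_circle(c(10, 10), 4)), seed = 1)
  expect_equal(ci$true_total_length_um, 2 * pi * 4, tolerance = 1e-9)
  # sinusoid truth agrees with a dense polyline quadrature oracle
  cur <- curve_sinusoid(origin = c(2, 10), length = 15, amplitude = 2,
                        period = 5)
  sn <- generate_sted_scene(list(cur), seed = 1)
  x <- seq(0, 15, length.out = 2e5)
  y <- 2 * sin(2 * pi * x / 5)
  oracle <- sum(sqrt(diff(x)^2 + diff(y)^2))
  expect_equal(sn$true_total_length_um, oracle, tolerance = 1e-3)
  # a circle centred on the field edge is clipped to about half
  cl <- generate_sted_scene(list(curve_circle(c(0, 10), 5)), seed = 2)
  expect_lt(cl$true_total_length_um, pi * 5 * 1.1)
  expect_gt(cl$true_total_length_um, pi * 5 * 0.9)
  # projection dominates every slice
  pr <- project_zstack(sg$zstack)
  expect_true(all(pr >= sg$zstack[, , 3]))
})

test_that("sphere profile sampler matches the analytic section-area law", {
  pr <- sample_sphere_profiles(1, 2e5, seed = 4)
  expect_true(all(pr <= pi + 1e-12))
  expect_true(all(pr >= 0))
  # mean section area of the unit sphere is (2/3) pi
  expect_equal(mean(pr), 2 / 3 * pi, tolerance = 0.01)
  # standard error shrinks like 1/sqrt(n)
  m1 <- replicate(20, mean(sample_sphere_profiles(1, 100, sample.int(1e6, 1))))
  m2 <- replicate(20, mean(sample_sphere_profiles(1, 10000, sample.int(1e6, 1))))
  expect_lt(sd(m2), sd(m1))
})

test_that("plate and count-matrix generators record exact ground truth", {
  pl <- generate_plate(noise_sd = 0, seed = 1)
  expect_equal(pl$standard_absorbances,
               pl$blank + pl$slope * pl$standard_concentrations)
  cm <- generate_count_matrix(n_cells = 200L, seed = 9L)
  tot <- Matrix::rowSums(cm$counts)
  mito <- Matrix::rowSums(cm$counts[, startsWith(cm$gene_names, "mt-")])
  genes <- Matrix::rowSums(cm$counts > 0)
  expect_identical(cm$true_pass_count,
                   sum(mito / tot < 0.40 & genes > 200))
  cm2 <- generate_count_matrix(n_cells = 200L, seed = 9L)
  expect_identical(as.matrix(cm$counts), as.matrix(cm2$counts))
})
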