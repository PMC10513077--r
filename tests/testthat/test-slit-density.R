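test_that("z-stack projection is the pixelwise maximum", {
  st <- array(0, c(10, 10, 3))
  st[2, 2, 1] <- 0.8; st[8, 8, 2] <- 0.6
  pr <- project_zstack(st)
  expect_equal(pr[2, 2], 0.8)
  expect_equal(pr[8, 8], 0.6)
  for (z in 1:3) expect_true(all(pr >= st[, , z]))
  expect_identical(project_zstack(st[, , 1]), st[, , 1])
  expect_error(project_zstack(array(0, c(4, 4, 0))))
})

test_that("skeleton length is exact on axis-aligned and diagonal runs", {
  b <- matrix(0L, 100, 100); b[50, 6:94] <- 1L          # 89 px run
  expect_equal(skeleton_length(b, 8.8), 10.0)
  d <- matrix(0L, 100, 100)
  d[cbind(6:94, 6:94)] <- 1L
  expect_equal(skeleton_length(d, 8.8), 88 * sqrt(2) / 8.8)
  expect_equal(skeleton_length(matrix(0L, 10, 10), 8.8), 0)
  # scale equivariance: doubling ppm halves the metric length
  expect_equal(skeleton_length(b, 17.6), 5.0)
})

test_that("thick curves are measured within tolerance after thinning", {
  # circle of radius 5 um drawn 4-5 px wide at 8.8 px/um
  H <- 120; ppm <- 8.8
  rad <- sqrt((row(matrix(0, H, H)) - 60)^2 + (col(matrix(0, H, H)) - 60)^2)
  for (w in c(2, 3)) {           # stroke widths ~4-7 px
    ann <- (rad >= 5 * ppm - w & rad <= 5 * ppm + w) * 1L
    expect_equal(skeleton_length(ann, ppm), 2 * pi * 5, tolerance = 0.05)
  }
  ann3 <- (rad >= 5 * ppm - 1.5 & rad <= 5 * ppm + 1.5) * 1L  # ~3 px stroke
  expect_equal(skeleton_length(ann3, ppm), 2 * pi * 5, tolerance = 0.10)
  # translation invariance of the measured length
  sh <- matrix(0L, H, H); sh[6:(H - 10), 6:(H - 10)] <-
    ((rad >= 5 * ppm - 2 & rad <= 5 * ppm + 2) * 1L)[11:(H - 5), 11:(H - 5)]
  ann <- (rad >= 5 * ppm - 2 & rad <= 5 * ppm + 2) * 1L
  expect_equal(skeleton_length(sh, ppm), skeleton_length(ann, ppm),
               tolerance = 0.02)
})

test_that("synthetic slit scenes are recovered end to end", {
  sc <- generate_sted_scene(list(curve_segment(c(2, 10), c(12, 10)),
                                 curve_circle(c(10, 10), 4),
                                 curve_sinusoid(c(3, 4), 12, 1.5, 4)),
                            seed = 3)
  r <- slit_density(sc)
  expect_equal(r$total_length_um, sc$true_total_length_um, tolerance = 0.10)
  expect_equal(r$density_um_per_um2,
               r$total_length_um / r$field_area_um2)
  expect_equal(r$field_area_um2, sc$field_area_um2)
})

test_that("aggregation computes hierarchical field-glomerulus-mouse means", {
  rec <- do.call(rbind, lapply(1:10, function(i)
    data.frame(field_id = i, glomerulus_id = (i - 1) %/% 5 + 1, mouse_id = 1,
               total_length_um = 10, field_area_um2 = 100,
               density_um_per_um2 = c(0.1, 0.2)[(i - 1) %/% 5 + 1])))
  agg <- suppressWarnings(aggregate_slit_density(rec, aggregation_plan()))
  expect_equal(agg$per_glomerulus$density_um_per_um2, c(0.1, 0.2))
  expect_equal(agg$per_mouse$density_um_per_um2, 0.15)
  # five equal fields collapse to the field value
  expect_equal(agg$per_glomerulus$n_fields, c(5L, 5L))
  expect_warning(
    expect_warning(aggregate_slit_density(rec[1:3, ], aggregation_plan()),
                   "fields"),
    "glomeruli")
})
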