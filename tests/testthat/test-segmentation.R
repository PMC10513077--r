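test_that("weight map follows the border formula and class-balance floor", {
  # two single-pixel objects 10 px apart: midway pixel has d1 = d2 = 5
  m <- matrix(0L, 20, 20); m[10, 5] <- 1L; m[10, 15] <- 2L
  w <- make_weight_map(m, w0 = 10, sigma = 5, class_balance = c(1, 1))
  expect_equal(w[10, 10] - 1, 10 * exp(-(5 + 5)^2 / (2 * 25)), tolerance = 1e-9)
  # full map equals the formula with brute-force per-object distances
  m2 <- matrix(0L, 12, 14); m2[3:5, 3:5] <- 1L; m2[8:10, 9:12] <- 2L
  w2 <- make_weight_map(m2, w0 = 10, sigma = 5, class_balance = c(1, 1))
  pix <- which(m2 > 0)
  pr <- ((pix - 1) %% 12) + 1; pc <- ((pix - 1) %/% 12) + 1
  for (i in c(1, 4, 7, 12)) for (j in c(1, 6, 10, 14)) {
    dd <- sqrt((pr - i)^2 + (pc - j)^2)
    d1 <- min(dd[m2[pix] == 1]); d2 <- min(dd[m2[pix] == 2])
    dmin <- min(d1, d2); dmax <- max(d1, d2)
    expect_equal(w2[i, j], 1 + 10 * exp(-(dmin + dmax)^2 / 50),
                 tolerance = 1e-6)
  }
  # d1 = 1, d2 = 2 evaluates the printed exponential
  expect_equal(10 * exp(-9 / 50), 8.3527021, tolerance = 1e-6)
  # single object: border term identically zero
  m1 <- matrix(0L, 10, 10); m1[5, 5] <- 1L
  expect_true(all(make_weight_map(m1, class_balance = c(1, 1)) == 1))
  # weight never drops below the class floor; border decays with d1+d2
  w3 <- make_weight_map(m, w0 = 10, sigma = 5)
  cb_bg <- min(w3[m == 0])
  expect_true(all(w3 >= cb_bg - 1e-12))
  expect_gt(w3[10, 10], w3[10, 1])
})

test_that("augmentation applies one transform to both planes", {
  s <- small_scene(seed = 3L)
  img <- s$image_wt1[1:96, 1:96]; msk <- s$nuclei_mask[1:96, 1:96]
  # disabled: identity
  a0 <- augment_pair(img, msk, flips = FALSE, rotations = FALSE,
                     elastic = FALSE, seed = 5)
  expect_identical(a0$image, img)
  expect_identical(a0$mask, msk)
  # seeded determinism
  a1 <- augment_pair(img, msk, seed = 5)
  a2 <- augment_pair(img, msk, seed = 5)
  expect_identical(a1, a2)
  # label set preserved under warping
  expect_true(all(unique(as.vector(a1$mask)) %in% unique(as.vector(msk))))
  # flips are involutions; rotation by 4 quarter turns is identity
  expect_identical(flip_horizontal(flip_horizontal(img)), img)
  expect_identical(flip_vertical(flip_vertical(img)), img)
  expect_identical(rot90k(img, 4), img)
})

test_that("dice agrees with brute-force set overlap on random masks", {
  expect_equal(dice_coefficient(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(dice_coefficient(a, b), 0)
  withr::with_seed(42, {
    for (i in 1:25) {
      x <- matrix(rbinom(64, 1, runif(1)), 8)
      y <- matrix(rbinom(64, 1, runif(1)), 8)
      expect_equal(dice_coefficient(x, y), dice_brute_force(x, y))
    }
  })
})

test_that("network backward pass matches numerical gradients", {
  withr::with_seed(1, {
    net <- segnet_init(1L, base = 2L, seed = 42)
    x <- array(rnorm(16 * 16), c(16, 16, 1))
    y <- matrix(rbinom(256, 1, 0.4), 16, 16)
    w <- matrix(runif(256, 0.5, 2), 16, 16)
    act <- podometrics:::segnet_forward(net, x, keep = TRUE)
    ls <- podometrics:::wbce_loss(act$logits, y, w)
    g <- podometrics:::segnet_backward(net, act, ls$dlogits)
    eps <- 1e-6
    for (nm in names(net$layers)) {
      i <- sample(length(net$layers[[nm]]$w), 1)
      n2 <- net
      n2$layers[[nm]]$w[i] <- n2$layers[[nm]]$w[i] + eps
      z2 <- podometrics:::segnet_forward(n2, x)
      num <- (podometrics:::wbce_loss(z2, y, w)$loss - ls$loss) / eps
      expect_equal(g[[nm]]$dw[i], num, tolerance = 1e-3)
    }
  })
})

test_that("prediction is a probability map and thresholding is idempotent", {
  net <- segnet_init(1L, base = 2L, seed = 1)
  img <- matrix(runif(64 * 60), 64, 60)  # non-square, not divisible by 4
  p <- predict_prob(net, img)
  expect_equal(dim(p), dim(img))
  expect_true(all(p >= 0 & p <= 1))
  m <- predict_mask(net, img)
  expect_true(all(m %in% c(0L, 1L)))
  # thresholding a 0/1 grid at 0.5 reproduces it
  g01 <- matrix(rep(c(0, 1), 18), 6)
  expect_identical(matrix(as.integer(g01 > 0.5), 6), matrix(as.integer(g01), 6))
})

test_that("training on constant-zero masks drives foreground to zero and the
           validation split is honoured", {
  scenes <- lapply(1:4, function(i)
    generate_glomerulus_scene(scene_params(frame_size_px = c(96L, 96L),
                                           n_glomeruli = 0L, seed = i)))
  cfg <- train_config(epochs = 2L, steps_per_epoch = 6L, batch_size = 2L,
                      patch_px = 48L, elastic = FALSE, seed = 3L)
  fit <- train_segmenter(scenes, "nuclei", cfg)
  expect_length(intersect(fit$val_idx, fit$train_idx), 0)
  expect_gte(length(fit$val_idx), 1)
  pred <- predict_prob(fit, scenes[[fit$val_idx[1]]]$image_wt1)
  expect_lt(mean(pred > 0.5), 0.01)
  # checkpoint round trip preserves the learned weights
  path <- withr::local_tempfile(fileext = ".rds")
  save_segnet(fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_segnet(path)
  expect_equal(m2$layers, fit$model$layers)
})
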