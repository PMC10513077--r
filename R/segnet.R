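#' Training configuration for the segmentation network
#'
#' @param epochs training epochs.
#' @param steps_per_epoch gradient steps per epoch.
#' @param batch_size patches per gradient step.
#' @param patch_px square patch side (must be divisible by 4).
#' @param learning_rate Adam step size.
#' @param val_fraction fraction of scenes held out for validation (0, 1).
#' @param flips,rotations,elastic augmentation toggles.
#' @param prob_threshold probability cut for binarising predictions.
#' @param w0,sigma border weight-map constants (see [make_weight_map()]).
#' @param base_channels channels of the first encoder level.
#' @param seed integer seed controlling the split, init and sampling.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 8L, steps_per_epoch = 30L, batch_size = 4L,
                         patch_px = 96L, learning_rate = 2e-3,
                         val_fraction = 0.2, flips = TRUE, rotations = TRUE,
                         elastic = FALSE, prob_threshold = 0.5,
                         w0 = 10, sigma = 5, base_channels = 8L, seed = 1L) {
  assert_scalar(val_fraction, "val_fraction", 1e-9, 1 - 1e-9)
  assert_scalar(prob_threshold, "prob_threshold", 1e-9, 1 - 1e-9)
  assert_that(patch_px %% 4 == 0, "`patch_px` must be divisible by 4")
  structure(as.list(environment()), class = "train_config")
}

relu <- function(x) { x[x < 0] <- 0; x }

conv_init <- function(cin, cout, seed_offset = 0) {
  # He initialisation for 3x3 kernels
  list(w = matrix(rnorm(cout * cin * 9, 0, sqrt(2 / (cin * 9))), cout, cin * 9),
       b = rep(0, cout))
}

#' Initialise an encoder-decoder segmentation network
#'
#' A three-level fully convolutional encoder-decoder with skip
#' connections: two 3x3 conv+ReLU blocks per level, 2x2 max pooling,
#' nearest-neighbour upsampling, channel concatenation with the matching
#' encoder level, and a 3x3 logit head. Channel widths are
#' `base, 2*base, 4*base`.
#'
#' @param in_channels input image channels.
#' @param base first-level channel width.
#' @param task free-form tag (`"tuft"` or `"nuclei"`).
#' @param seed integer seed for the weight initialisation.
#' @return list of class `segnet` holding the layer parameters.
#' @export
segnet_init <- function(in_channels = 1L, base = 8L, task = "tuft", seed = 1L) {
  with_rng(seed, {
    b <- base
    layers <- list(
      e1a = conv_init(in_channels, b), e1b = conv_init(b, b),
      e2a = conv_init(b, 2 * b), e2b = conv_init(2 * b, 2 * b),
      ba = conv_init(2 * b, 4 * b), bb = conv_init(4 * b, 4 * b),
      d1a = conv_init(6 * b, 2 * b), d1b = conv_init(2 * b, 2 * b),
      d2a = conv_init(3 * b, b), d2b = conv_init(b, b),
      out = conv_init(b, 1L))
    structure(list(layers = layers, base = b, in_channels = in_channels,
                   task = task, seed = seed),
              class = "segnet")
  })
}

cat_cube <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

segnet_forward <- function(net, x, keep = FALSE) {
  L <- net$layers
  cv <- function(x, l) nn_conv3_fw(x, l$w, l$b)
  a <- list()
  a$x <- x
  a$e1a <- relu(cv(x, L$e1a)); a$e1b <- relu(cv(a$e1a, L$e1b))
  p1 <- nn_pool_fw(a$e1b); a$p1 <- p1$y; a$p1i <- p1$idx
  a$e2a <- relu(cv(a$p1, L$e2a)); a$e2b <- relu(cv(a$e2a, L$e2b))
  p2 <- nn_pool_fw(a$e2b); a$p2 <- p2$y; a$p2i <- p2$idx
  a$ba <- relu(cv(a$p2, L$ba)); a$bb <- relu(cv(a$ba, L$bb))
  a$u1 <- nn_up_fw(a$bb); a$c1 <- cat_cube(a$u1, a$e2b)
  a$d1a <- relu(cv(a$c1, L$d1a)); a$d1b <- relu(cv(a$d1a, L$d1b))
  a$u2 <- nn_up_fw(a$d1b); a$c2 <- cat_cube(a$u2, a$e1b)
  a$d2a <- relu(cv(a$c2, L$d2a)); a$d2b <- relu(cv(a$d2a, L$d2b))
  a$logits <- cv(a$d2b, L$out)
  if (keep) a else a$logits
}

# backward pass given d(loss)/d(logits); returns per-layer gradients
segnet_backward <- function(net, act, dlogits) {
  L <- net$layers
  g <- list()
  bw <- function(name, x, dy, act_out = NULL) {
    if (!is.null(act_out)) dy <- dy * (act_out > 0)  # ReLU gate
    r <- nn_conv3_bw(x, L[[name]]$w, dy)
    g[[name]] <<- list(dw = r$dw, db = r$db)
    r$dx
  }
  d <- bw("out", act$d2b, dlogits)
  d <- bw("d2b", act$d2a, d, act$d2b)
  d <- bw("d2a", act$c2, d, act$d2a)
  nb <- net$base
  du2 <- d[, , seq_len(2 * nb), drop = FALSE]
  de1b_skip <- d[, , 2 * nb + seq_len(nb), drop = FALSE]
  d <- nn_up_bw(du2)
  d <- bw("d1b", act$d1a, d, act$d1b)
  d <- bw("d1a", act$c1, d, act$d1a)
  du1 <- d[, , seq_len(4 * nb), drop = FALSE]
  de2b_skip <- d[, , 4 * nb + seq_len(2 * nb), drop = FALSE]
  d <- nn_up_bw(du1)
  d <- bw("bb", act$ba, d, act$bb)
  d <- bw("ba", act$p2, d, act$ba)
  d <- nn_pool_bw(act$p2i, d, dim(act$e2b)[1], dim(act$e2b)[2]) + de2b_skip
  d <- bw("e2b", act$e2a, d, act$e2b)
  d <- bw("e2a", act$p1, d, act$e2a)
  d <- nn_pool_bw(act$p1i, d, dim(act$e1b)[1], dim(act$e1b)[2]) + de1b_skip
  d <- bw("e1b", act$e1a, d, act$e1b)
  bw("e1a", act$x, d, act$e1a)
  g
}

# weighted binary cross-entropy with logits; returns loss and d/dlogits
wbce_loss <- function(logits, target, weights) {
  z <- logits[, , 1]; y <- target; w <- weights
  sw <- sum(w)
  loss <- sum(w * (pmax(z, 0) - z * y + log1p(exp(-abs(z))))) / sw
  p <- 1 / (1 + exp(-z))
  dl <- array(w * (p - y) / sw, c(dim(z), 1L))
  list(loss = loss, dlogits = dl)
}

adam_state <- function(net) {
  lapply(net$layers, function(l)
    list(mw = l$w * 0, vw = l$w * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_update <- function(net, st, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- st[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$dw
    s$vw <- beta2 * s$vw + (1 - beta2) * g$dw^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    net$layers[[nm]]$w <- net$layers[[nm]]$w - lr * (s$mw / c1) / (sqrt(s$vw / c2) + eps)
    net$layers[[nm]]$b <- net$layers[[nm]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    st[[nm]] <- s
  }
  list(net = net, st = st)
}

scene_task_planes <- function(scene, task) {
  if (task == "tuft") {
    list(image = scene$image_wt1, labels = scene$tuft_mask)
  } else {
    list(image = scene$image_wt1, labels = scene$nuclei_mask)
  }
}

#' Train the segmentation network on synthetic scenes
#'
#' Splits scenes into train/validation by scene (the validation scenes
#' never contribute training patches), precomputes border weight maps,
#' then optimises a per-pixel weighted cross-entropy with Adam on
#' randomly augmented patches. Training aborts if the loss turns
#' non-finite.
#'
#' @param scenes list of `scene_truth` objects (>= 2).
#' @param task `"tuft"` (glomerular tuft) or `"nuclei"` (podocyte nuclei).
#' @param config a [train_config()].
#' @return list of class `segnet_fit`: `model`, `log` (per-epoch
#'   data.frame with mean loss and validation Dice), `val_idx`,
#'   `train_idx`, `config`.
#' @export
train_segmenter <- function(scenes, task = c("tuft", "nuclei"),
                            config = train_config()) {
  task <- match.arg(task)
  stopifnot(length(scenes) >= 2, inherits(config, "train_config"))
  with_rng(config$seed, {
    n <- length(scenes)
    n_val <- max(1L, round(config$val_fraction * n))
    val_idx <- sort(sample.int(n, n_val))
    train_idx <- setdiff(seq_len(n), val_idx)
    assert_that(length(train_idx) >= 1, "validation split leaves no training scenes")

    prep <- lapply(scenes, function(s) {
      pl <- scene_task_planes(s, task)
      list(image = pl$image, target = matrix(as.numeric(pl$labels > 0),
                                             nrow(pl$labels)),
           weights = make_weight_map(pl$labels, w0 = config$w0,
                                     sigma = config$sigma))
    })

    net <- segnet_init(1L, config$base_channels, task,
                       seed = sample.int(.Machine$integer.max, 1))
    st <- adam_state(net)
    P <- config$patch_px
    log_rows <- list()
    t_step <- 0L
    for (ep in seq_len(config$epochs)) {
      losses <- numeric(0)
      for (step in seq_len(config$steps_per_epoch)) {
        grads_acc <- NULL; loss_acc <- 0
        for (bi in seq_len(config$batch_size)) {
          sc <- prep[[sample(train_idx, 1)]]
          H <- nrow(sc$image); W <- ncol(sc$image)
          r0 <- sample.int(H - P + 1L, 1); c0 <- sample.int(W - P + 1L, 1)
          img <- sc$image[r0:(r0 + P - 1L), c0:(c0 + P - 1L)]
          tgt <- sc$target[r0:(r0 + P - 1L), c0:(c0 + P - 1L)]
          wts <- sc$weights[r0:(r0 + P - 1L), c0:(c0 + P - 1L)]
          if (config$flips || config$rotations || config$elastic) {
            sd2 <- sample.int(.Machine$integer.max, 1)
            au <- augment_pair(img, tgt, config$flips, config$rotations,
                               config$elastic, seed = sd2)
            wau <- augment_pair(wts, tgt, config$flips, config$rotations,
                                config$elastic, seed = sd2)
            img <- au$image; tgt <- au$mask; wts <- wau$image
          }
          act <- segnet_forward(net, array(img, c(P, P, 1L)), keep = TRUE)
          ls <- wbce_loss(act$logits, tgt, wts)
          if (!is.finite(ls$loss))
            stop("non-finite training loss at epoch ", ep, ", step ", step,
                 call. = FALSE)
          g <- segnet_backward(net, act, ls$dlogits)
          loss_acc <- loss_acc + ls$loss
          if (is.null(grads_acc)) grads_acc <- g else {
            for (nm in names(g)) {
              grads_acc[[nm]]$dw <- grads_acc[[nm]]$dw + g[[nm]]$dw
              grads_acc[[nm]]$db <- grads_acc[[nm]]$db + g[[nm]]$db
            }
          }
        }
        for (nm in names(grads_acc)) {
          grads_acc[[nm]]$dw <- grads_acc[[nm]]$dw / config$batch_size
          grads_acc[[nm]]$db <- grads_acc[[nm]]$db / config$batch_size
        }
        t_step <- t_step + 1L
        up <- adam_update(net, st, grads_acc, config$learning_rate, t_step)
        net <- up$net; st <- up$st
        losses <- c(losses, loss_acc / config$batch_size)
      }
      vd <- mean(vapply(val_idx, function(i) {
        pl <- scene_task_planes(scenes[[i]], task)
        pred <- predict_mask(net, pl$image, config$prob_threshold)
        dice_coefficient(pred, pl$labels > 0)
      }, 0))
      log_rows[[ep]] <- data.frame(epoch = ep, mean_loss = mean(losses),
                                   val_dice = vd)
    }
    structure(list(model = net, log = do.call(rbind, log_rows),
                   val_idx = val_idx, train_idx = train_idx, config = config),
              class = "segnet_fit")
  })
}

#' Predict per-pixel foreground probabilities
#'
#' Runs the network over the image (padded to a multiple of 4 by edge
#' replication, then cropped back). Output values are probabilities in
#' `[0, 1]`.
#'
#' @param model a `segnet` (or `segnet_fit`).
#' @param image intensity matrix.
#' @return probability matrix of the same shape as `image`.
#' @export
predict_prob <- function(model, image) {
  if (inherits(model, "segnet_fit")) model <- model$model
  stopifnot(inherits(model, "segnet"), is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  H4 <- ceiling(H / 4) * 4; W4 <- ceiling(W / 4) * 4
  pad <- matrix(0, H4, W4)
  pad[seq_len(H), seq_len(W)] <- image
  if (H4 > H) pad[(H + 1):H4, seq_len(W)] <- matrix(image[H, ], H4 - H, W, byrow = TRUE)
  if (W4 > W) pad[, (W + 1):W4] <- pad[, W]
  z <- segnet_forward(model, array(pad, c(H4, W4, 1L)))[, , 1]
  p <- 1 / (1 + exp(-z))
  p[seq_len(H), seq_len(W), drop = FALSE]
}

#' Binarise a predicted probability map
#'
#' @param model a `segnet` or `segnet_fit`.
#' @param image intensity matrix.
#' @param prob_threshold probability cut in (0, 1).
#' @return integer binary matrix.
#' @export
predict_mask <- function(model, image, prob_threshold = 0.5) {
  assert_scalar(prob_threshold, "prob_threshold", 1e-9, 1 - 1e-9)
  p <- predict_prob(model, image)
  m <- matrix(as.integer(p > prob_threshold), nrow(p))
  m
}

#' Save / load a trained network
#'
#' The checkpoint is a serialized weight file with a JSON sidecar
#' (`<path>.json`) recording the architecture, task and seed.
#'
#' @param model a `segnet` or `segnet_fit`.
#' @param path checkpoint path.
#' @return `save_segnet` invisibly returns the path; `load_segnet`
#'   returns the `segnet`.
#' @export
save_segnet <- function(model, path) {
  if (inherits(model, "segnet_fit")) model <- model$model
  saveRDS(model, path)
  sidecar <- list(class = "segnet", base = model$base,
                  in_channels = model$in_channels, task = model$task,
                  seed = model$seed, depth = 3L)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_segnet
#' @export
load_segnet <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "segnet"))
  m
}
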