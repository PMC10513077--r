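#' Geometric augmentation primitives
#'
#' Deterministic transforms applied identically to an image and its mask.
#' `flip_horizontal`/`flip_vertical` mirror the frame, `rot90k` rotates by
#' `k` quarter turns, and `elastic_warp` applies a smooth random
#' displacement field (bilinear interpolation for intensities, nearest
#' neighbour for labels so the label set is preserved).
#'
#' @param x matrix (image or mask).
#' @param k number of counter-clockwise quarter turns.
#' @name augment_primitives
NULL

#' @rdname augment_primitives
#' @export
flip_horizontal <- function(x) x[, rev(seq_len(ncol(x))), drop = FALSE]

#' @rdname augment_primitives
#' @export
flip_vertical <- function(x) x[rev(seq_len(nrow(x))), , drop = FALSE]

#' @rdname augment_primitives
#' @export
rot90k <- function(x, k = 1) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) x <- t(x)[rev(seq_len(ncol(x))), , drop = FALSE]
  x
}

# smooth random displacement field: coarse Gaussian noise upsampled by
# bilinear interpolation, scaled to `alpha` pixels
elastic_field <- function(H, W, alpha, sigma_cells = 4) {
  gh <- max(2, ceiling(H / 32)); gw <- max(2, ceiling(W / 32))
  up <- function(g) {
    ry <- seq(1, gh, length.out = H); rx <- seq(1, gw, length.out = W)
    y0 <- pmin(floor(ry), gh - 1); x0 <- pmin(floor(rx), gw - 1)
    fy <- ry - y0; fx <- rx - x0
    g00 <- g[cbind(rep(y0, W), rep(x0, each = H))]
    g10 <- g[cbind(rep(y0 + 1, W), rep(x0, each = H))]
    g01 <- g[cbind(rep(y0, W), rep(x0 + 1, each = H))]
    g11 <- g[cbind(rep(y0 + 1, W), rep(x0 + 1, each = H))]
    m <- matrix(g00 * (1 - fy) * rep(1 - fx, each = H) +
                  g10 * fy * rep(1 - fx, each = H) +
                  g01 * (1 - fy) * rep(fx, each = H) +
                  g11 * fy * rep(fx, each = H), H, W)
    m
  }
  list(dy = up(matrix(rnorm(gh * gw), gh, gw)) * alpha,
       dx = up(matrix(rnorm(gh * gw), gh, gw)) * alpha)
}

warp_with_field <- function(x, field, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(x); W <- ncol(x)
  ry <- pmin(pmax(row(x) + field$dy, 1), H)
  rx <- pmin(pmax(col(x) + field$dx, 1), W)
  if (interp == "nearest") {
    return(matrix(x[cbind(as.vector(round(ry)), as.vector(round(rx)))], H, W))
  }
  y0 <- pmin(floor(ry), H - 1); x0 <- pmin(floor(rx), W - 1)
  fy <- ry - y0; fx <- rx - x0
  v <- x[cbind(as.vector(y0), as.vector(x0))] * as.vector((1 - fy) * (1 - fx)) +
    x[cbind(as.vector(y0 + 1), as.vector(x0))] * as.vector(fy * (1 - fx)) +
    x[cbind(as.vector(y0), as.vector(x0 + 1))] * as.vector((1 - fy) * fx) +
    x[cbind(as.vector(y0 + 1), as.vector(x0 + 1))] * as.vector(fy * fx)
  matrix(v, H, W)
}

#' @rdname augment_primitives
#' @param mask aligned label/binary matrix.
#' @param alpha elastic displacement amplitude in pixels.
#' @export
elastic_warp <- function(x, mask, alpha = 3) {
  f <- elastic_field(nrow(x), ncol(x), alpha)
  list(image = warp_with_field(x, f, "bilinear"),
       mask = warp_with_field(mask, f, "nearest"))
}

#' Randomly augment an image/mask pair
#'
#' Applies a seeded random combination of the enabled transforms -- the
#' same geometric transform to image and mask -- and is the identity when
#' all augmentations are disabled.
#'
#' @param image intensity matrix.
#' @param mask aligned label (or binary) matrix.
#' @param flips,rotations,elastic enable the respective transform family.
#' @param elastic_alpha displacement amplitude (px) for the elastic warp.
#' @param seed integer seed; same seed gives the identical augmentation.
#' @return list with `image` and `mask`.
#' @export
augment_pair <- function(image, mask, flips = TRUE, rotations = TRUE,
                         elastic = TRUE, elastic_alpha = 2, seed = 1L) {
  stopifnot(all(dim(image) == dim(mask)))
  with_rng(seed, {
    if (flips) {
      if (runif(1) < 0.5) { image <- flip_horizontal(image); mask <- flip_horizontal(mask) }
      if (runif(1) < 0.5) { image <- flip_vertical(image); mask <- flip_vertical(mask) }
    }
    if (rotations && nrow(image) == ncol(image)) {
      k <- sample(0:3, 1)
      image <- rot90k(image, k); mask <- rot90k(mask, k)
    }
    if (elastic) {
      out <- elastic_warp(image, mask, alpha = elastic_alpha)
      image <- out$image; mask <- out$mask
    }
    list(image = image, mask = mask)
  })
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b binary matrices of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  a <- as_binary_matrix(mask_a, "mask_a"); b <- as_binary_matrix(mask_b, "mask_b")
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
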