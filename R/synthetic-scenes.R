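#' Parameters for a synthetic glomerulus scene
#'
#' Bundles the geometry, intensity and reproducibility settings used by
#' [generate_glomerulus_scene()]. The defaults describe a desk-scale frame:
#' 512x512 pixels at the acquisition resolution of 8.8 pixels per micron,
#' holding a few elliptical glomerular tufts whose interiors contain
#' non-overlapping podocyte-nucleus blobs. Full-scale runs use 2048x2048
#' frames at the same pixel size.
#'
#' @param frame_size_px integer pair, frame height and width in pixels.
#' @param pixels_per_micron pixel density (px/um); 8.8 matches the
#'   acquisition setting the pipeline is calibrated for.
#' @param n_glomeruli number of glomerulus units (labels) to draw.
#' @param tuft_radius_um range of tuft semi-axis lengths in um.
#' @param nuclei_per_glomerulus integer range of nuclei per glomerulus.
#' @param nucleus_radius_um range of nucleus semi-axis lengths in um.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (images live on a 0..1 scale).
#' @param edge_touch_fraction fraction of glomeruli deliberately placed so
#'   they are cut by the frame edge.
#' @param merged_pair_fraction fraction of glomerulus labels drawn as two
#'   overlapping tufts sharing one label (the "merged structures" failure
#'   mode that downstream post-processing must exclude).
#' @param seed integer seed; identical parameters and seed reproduce the
#'   scene pixel for pixel.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(frame_size_px = c(512L, 512L),
                         pixels_per_micron = 8.8,
                         n_glomeruli = 3L,
                         tuft_radius_um = c(7, 10),
                         nuclei_per_glomerulus = c(4L, 8L),
                         nucleus_radius_um = c(1.0, 1.5),
                         noise_sd = 0.05,
                         edge_touch_fraction = 0,
                         merged_pair_fraction = 0,
                         seed = 1L) {
  assert_that(length(frame_size_px) == 2 && all(frame_size_px >= 8),
              "`frame_size_px` must be an integer pair >= 8")
  assert_scalar(pixels_per_micron, "pixels_per_micron", lo = 1e-6)
  assert_scalar(n_glomeruli, "n_glomeruli", lo = 0)
  assert_range(tuft_radius_um, "tuft_radius_um", lo = 0)
  assert_range(nuclei_per_glomerulus, "nuclei_per_glomerulus", lo = 0)
  assert_range(nucleus_radius_um, "nucleus_radius_um", lo = 0)
  assert_scalar(noise_sd, "noise_sd", lo = 0)
  assert_scalar(edge_touch_fraction, "edge_touch_fraction", 0, 1)
  assert_scalar(merged_pair_fraction, "merged_pair_fraction", 0, 1)
  structure(list(frame_size_px = as.integer(frame_size_px),
                 pixels_per_micron = pixels_per_micron,
                 n_glomeruli = as.integer(n_glomeruli),
                 tuft_radius_um = tuft_radius_um,
                 nuclei_per_glomerulus = as.integer(nuclei_per_glomerulus),
                 nucleus_radius_um = nucleus_radius_um,
                 noise_sd = noise_sd,
                 edge_touch_fraction = edge_touch_fraction,
                 merged_pair_fraction = merged_pair_fraction,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# pixel-center coordinates of an ellipse interior, clipped to the frame
rasterize_ellipse <- function(cx, cy, a, b, theta, H, W) {
  r0 <- max(1L, floor(cy - max(a, b))); r1 <- min(H, ceiling(cy + max(a, b)))
  c0 <- max(1L, floor(cx - max(a, b))); c1 <- min(W, ceiling(cx + max(a, b)))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dy <- rep(rr - cy, times = length(cc))
  dx <- rep(cc - cx, each = length(rr))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  rows <- rep(rr, times = length(cc))[inside]
  cols <- rep(cc, each = length(rr))[inside]
  (cols - 1L) * H + rows   # linear indices
}

point_in_ellipse <- function(px, py, cx, cy, a, b, theta, shrink = 1) {
  u <- (px - cx) * cos(theta) + (py - cy) * sin(theta)
  v <- -(px - cx) * sin(theta) + (py - cy) * cos(theta)
  (u / (a * shrink))^2 + (v / (b * shrink))^2 <= 1
}

runif_in <- function(range) runif(1, range[1], range[2])

#' Generate a synthetic glomerulus scene with known ground truth
#'
#' Draws elliptical glomerular tufts containing nucleus blobs, renders a
#' WT-1-like image (bright nuclei over a dim cytoplasmic tuft) and a
#' nephrin-like image (textured bright cytoplasm, dimmer nuclei), and
#' records labeled ground-truth masks plus per-glomerulus truth. Objects
#' are smoothed indicator functions with additive Gaussian noise.
#' Designated fractions of glomeruli touch the frame edge or are drawn as
#' merged pairs (two overlapping tufts under one label), emulating the
#' structures that morphometry post-processing must exclude.
#'
#' @param params a [scene_params()] object.
#' @return A list of class `scene_truth` with elements `image_wt1`,
#'   `image_nephrin` (matrices in 0..1), `tuft_mask`, `nuclei_mask`
#'   (integer label matrices, 0 = background), `per_glomerulus`
#'   (data.frame: `glomerulus`, `n_nuclei`, `tuft_area_um2`,
#'   `mean_nuclear_area_um2`, `edge`, `merged`), and `params`.
#' @export
generate_glomerulus_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_rng(params$seed, generate_scene_impl(params))
}

generate_scene_impl <- function(p) {
  H <- p$frame_size_px[1]; W <- p$frame_size_px[2]
  ppm <- p$pixels_per_micron
  n <- p$n_glomeruli
  tuft <- matrix(0L, H, W)
  nuc <- matrix(0L, H, W)

  n_merged <- round(p$merged_pair_fraction * n)
  n_edge <- round(p$edge_touch_fraction * n)
  # flags per unit: merged units first, then edge units among the rest
  merged_flag <- rep(c(TRUE, FALSE), c(n_merged, n - n_merged))
  edge_flag <- rep(FALSE, n)
  if (n_edge > 0) edge_flag[rev(seq_len(n))[seq_len(n_edge)]] <- TRUE

  rad_px <- p$tuft_radius_um * ppm
  units <- vector("list", n)
  margin <- 3
  for (g in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(300)) {
      a <- runif_in(rad_px); b <- runif_in(rad_px); th <- runif(1, 0, pi)
      rmax <- max(a, b)
      if (edge_flag[g]) {
        # center close enough to a boundary that the ellipse is cut
        side <- sample.int(4, 1)
        off <- runif(1, 0, 0.6 * rmax)
        cx <- runif(1, rmax, W - rmax); cy <- runif(1, rmax, H - rmax)
        if (side == 1) cy <- 1 + off else if (side == 2) cy <- H - off
        if (side == 3) cx <- 1 + off else if (side == 4) cx <- W - off
      } else {
        if (W - rmax - margin <= rmax + margin || H - rmax - margin <= rmax + margin) next
        cx <- runif(1, rmax + margin, W - rmax - margin)
        cy <- runif(1, rmax + margin, H - rmax - margin)
      }
      ell <- list(list(cx = cx, cy = cy, a = a, b = b, th = th))
      if (merged_flag[g]) {
        a2 <- runif_in(rad_px); b2 <- runif_in(rad_px); th2 <- runif(1, 0, pi)
        ang <- runif(1, 0, 2 * pi)
        # centres closer than the sum of the smaller semi-axes: the two
        # tufts always overlap and form one dumbbell-shaped component
        d <- 0.9 * (min(a, b) + min(a2, b2))
        ell[[2]] <- list(cx = cx + d * cos(ang), cy = cy + d * sin(ang),
                         a = a2, b = b2, th = th2)
      }
      reach <- max(vapply(ell, function(e)
        sqrt((e$cx - cx)^2 + (e$cy - cy)^2) + max(e$a, e$b), 0))
      if (!edge_flag[g] &&
          (cx - reach < 1 || cx + reach > W || cy - reach < 1 || cy + reach > H))
        next
      ok <- TRUE
      for (u in units[seq_len(g - 1)]) {
        if (is.null(u)) next
        if (sqrt((u$cx - cx)^2 + (u$cy - cy)^2) < reach + u$reach + 4) { ok <- FALSE; break }
      }
      if (!ok) next
      units[[g]] <- list(cx = cx, cy = cy, reach = reach, ellipses = ell)
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible packing: could not place glomerulus ", g,
                      " after bounded retries", call. = FALSE)
  }

  for (g in seq_len(n)) {
    for (e in units[[g]]$ellipses) {
      idx <- rasterize_ellipse(e$cx, e$cy, e$a, e$b, e$th, H, W)
      tuft[idx] <- g
    }
  }

  # nuclei: centers inside a tuft ellipse, mutually separated so blobs stay
  # resolvable; a merged unit receives nuclei across both of its ellipses
  nuc_rad_px <- p$nucleus_radius_um * ppm
  nuclei <- list()
  n_nuclei_unit <- integer(n)
  for (g in seq_len(n)) {
    k <- if (diff(p$nuclei_per_glomerulus) == 0) p$nuclei_per_glomerulus[1] else
      sample(p$nuclei_per_glomerulus[1]:p$nuclei_per_glomerulus[2], 1)
    placed_k <- 0L
    for (j in seq_len(k)) {
      done <- FALSE
      for (try in seq_len(300)) {
        e <- units[[g]]$ellipses[[sample.int(length(units[[g]]$ellipses), 1)]]
        rn <- runif_in(nuc_rad_px)
        # uniform point in the shrunken ellipse so the nucleus fits inside
        shrink <- max(0.05, 1 - rn / min(e$a, e$b))
        rho <- sqrt(runif(1)); phi <- runif(1, 0, 2 * pi)
        u <- rho * cos(phi) * e$a * shrink; v <- rho * sin(phi) * e$b * shrink
        px <- e$cx + u * cos(e$th) - v * sin(e$th)
        py <- e$cy + u * sin(e$th) + v * cos(e$th)
        if (px < 1 || px > W || py < 1 || py > H) next
        sep_ok <- TRUE
        for (q in nuclei) {
          if (sqrt((q$cx - px)^2 + (q$cy - py)^2) < (q$r + rn) * 1.2 + 1) { sep_ok <- FALSE; break }
        }
        if (!sep_ok) next
        asp <- runif(1, 0.8, 1)
        nuclei[[length(nuclei) + 1]] <- list(cx = px, cy = py, r = rn,
                                             a = rn, b = rn * asp,
                                             th = runif(1, 0, pi), unit = g)
        done <- TRUE
        break
      }
      if (done) placed_k <- placed_k + 1L else break
    }
    if (placed_k < k)
      stop("infeasible packing: could not place ", k, " nuclei in glomerulus ",
           g, call. = FALSE)
    n_nuclei_unit[g] <- placed_k
  }
  for (i in seq_along(nuclei)) {
    q <- nuclei[[i]]
    idx <- rasterize_ellipse(q$cx, q$cy, q$a, q$b, q$th, H, W)
    nuc[idx] <- i
  }

  # intensity model: smoothed indicators + Gaussian noise
  tuft_ind <- matrix(as.numeric(tuft > 0), H, W)
  nuc_ind <- matrix(as.numeric(nuc > 0), H, W)
  smooth <- function(x, s) EBImage::imageData(EBImage::gblur(x, sigma = s))
  wt1 <- 0.08 + 0.18 * smooth(tuft_ind, 1.5) + 0.55 * smooth(nuc_ind, 1.2)
  tex <- smooth(matrix(rnorm(H * W), H, W), 4)
  tex <- 1 + 0.35 * tex / max(1e-9, sd(tex))
  neph <- 0.08 + 0.55 * smooth(tuft_ind, 1.5) * tex - 0.30 * smooth(nuc_ind, 1.2)
  if (p$noise_sd > 0) {
    wt1 <- wt1 + rnorm(H * W, 0, p$noise_sd)
    neph <- neph + rnorm(H * W, 0, p$noise_sd)
  }
  clip01 <- function(x) pmin(pmax(x, 0), 1)

  areas <- label_areas_px(tuft)
  if (n > 0) {
    nuc_areas <- label_areas_px(nuc)
    unit_of_nuc <- vapply(nuclei, `[[`, 0, "unit")
    mean_na <- vapply(seq_len(n), function(g) {
      id <- which(unit_of_nuc == g)
      if (!length(id)) NA_real_ else mean(nuc_areas[id]) / ppm^2
    }, 0)
    per <- data.frame(glomerulus = seq_len(n),
                      n_nuclei = n_nuclei_unit,
                      tuft_area_um2 = areas[seq_len(n)] / ppm^2,
                      mean_nuclear_area_um2 = mean_na,
                      edge = edge_flag, merged = merged_flag)
  } else {
    per <- data.frame(glomerulus = integer(0), n_nuclei = integer(0),
                      tuft_area_um2 = numeric(0),
                      mean_nuclear_area_um2 = numeric(0),
                      edge = logical(0), merged = logical(0))
  }

  structure(list(image_wt1 = clip01(wt1), image_nephrin = clip01(neph),
                 tuft_mask = tuft, nuclei_mask = nuc,
                 per_glomerulus = per, params = p),
            class = "scene_truth")
}

#' Write a scene to disk as 16-bit TIFF images plus a truth CSV
#'
#' @param scene a `scene_truth` object.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "scene_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(wt1 = file.path(dir, "image_wt1.tif"),
             nephrin = file.path(dir, "image_nephrin.tif"),
             tuft = file.path(dir, "tuft_mask.tif"),
             nuclei = file.path(dir, "nuclei_mask.tif"),
             truth = file.path(dir, "per_glomerulus.csv"))
  tiff::writeTIFF(scene$image_wt1, paths["wt1"], bits.per.sample = 16)
  tiff::writeTIFF(scene$image_nephrin, paths["nephrin"], bits.per.sample = 16)
  tiff::writeTIFF(scene$tuft_mask / 65535, paths["tuft"], bits.per.sample = 16)
  tiff::writeTIFF(scene$nuclei_mask / 65535, paths["nuclei"], bits.per.sample = 16)
  write.csv(scene$per_glomerulus, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Read a label mask written by [write_scene()]
#' @param path TIFF path.
#' @return integer label matrix.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  m <- round(m * 65535)
  storage.mode(m) <- "integer"
  m
}
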