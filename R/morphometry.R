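#' Exclusion settings for glomerulus post-processing
#'
#' Controls which connected components of a tuft segmentation are kept:
#' components cut at the frame edge, implausibly large or low-solidity
#' components (merged structures), and sub-minimal specks are removed.
#'
#' @param edge_margin_px components with a pixel within this distance of
#'   the frame border count as edge-cut (0 = any direct touch).
#' @param min_area_um2,max_area_um2 retained area bounds (um^2).
#' @param min_solidity minimum area / convex-hull-area ratio; merged
#'   tuft pairs are markedly non-convex.
#' @return list of class `exclusion_config`.
#' @export
exclusion_config <- function(edge_margin_px = 0L, min_area_um2 = 50,
                             max_area_um2 = 320, min_solidity = 0.95) {
  assert_that(min_area_um2 < max_area_um2, "min_area must be < max_area")
  assert_scalar(min_solidity, "min_solidity", 1e-9, 1)
  structure(list(edge_margin_px = as.integer(edge_margin_px),
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_solidity = min_solidity),
            class = "exclusion_config")
}

# area of the convex hull of a pixel set (px^2), pixels as unit squares
hull_area_px <- function(rows, cols) {
  # corners of each pixel so single-pixel-wide shapes have positive hulls
  pts <- cbind(c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5),
               c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) return(length(rows))
  x <- hp[, 2]; y <- hp[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Label a binary tuft mask and exclude non-representative components
#'
#' Connected components (8-connectivity) are labeled, then components are
#' removed when they touch the frame edge, exceed the area bounds, or are
#' insufficiently solid (merged structures). Surviving components are
#' relabeled consecutively.
#'
#' @param binary_mask binary matrix.
#' @param config an [exclusion_config()].
#' @param ppm pixels per micron (> 0).
#' @return list of class `labeled_mask`: `labels` (integer matrix),
#'   `pixels_per_micron`, and `exclusions`, a data.frame with one row per
#'   removed component (`component`, `area_um2`, `solidity`, `reason` in
#'   `edge|merged|too_small`).
#' @export
label_and_filter <- function(binary_mask, config = exclusion_config(), ppm) {
  assert_scalar(ppm, "ppm", lo = 1e-9)
  b <- as_binary_matrix(binary_mask)
  lab <- label_components(b)
  n <- max(lab)
  keep <- logical(n); reason <- character(n)
  area <- numeric(n); solidity <- numeric(n)
  H <- nrow(lab); W <- ncol(lab)
  m <- config$edge_margin_px
  for (l in seq_len(n)) {
    idx <- which(lab == l)
    rows <- ((idx - 1L) %% H) + 1L
    cols <- ((idx - 1L) %/% H) + 1L
    area[l] <- length(idx) / ppm^2
    solidity[l] <- min(1, length(idx) / hull_area_px(rows, cols))
    touches <- any(rows <= 1L + m | rows >= H - m | cols <= 1L + m | cols >= W - m)
    if (touches) {
      reason[l] <- "edge"
    } else if (area[l] > config$max_area_um2 || solidity[l] < config$min_solidity) {
      reason[l] <- "merged"
    } else if (area[l] < config$min_area_um2) {
      reason[l] <- "too_small"
    } else keep[l] <- TRUE
  }
  new_lab <- matrix(0L, H, W)
  for (i in seq_along(which(keep))) {
    new_lab[lab == which(keep)[i]] <- i
  }
  excl <- data.frame(component = which(!keep),
                     area_um2 = area[!keep], solidity = solidity[!keep],
                     reason = reason[!keep])
  structure(list(labels = new_lab, pixels_per_micron = ppm,
                 exclusions = excl),
            class = "labeled_mask")
}

#' Per-glomerulus 2D morphometrics
#'
#' For each retained tuft label: tuft area (pixel count / ppm^2), podocyte
#' count (nucleus components whose centroid lies inside the tuft), mean
#' nuclear profile area over those nuclei, areal density of podocytes per
#' 10^4 um^2 of tuft, and the nuclear/tuft area ratio. Glomeruli with no
#' nuclei report a count of 0 and `NA` mean nuclear area.
#'
#' @param tuft a `labeled_mask` (or integer label matrix) of tufts.
#' @param nuclei a `labeled_mask` (or integer label matrix) of nuclei.
#' @param ppm pixels per micron (> 0).
#' @return data.frame with one row per glomerulus: `glomerulus_id`,
#'   `tuft_area_um2`, `podocyte_count`, `mean_nuclear_area_um2`,
#'   `area_density_per_1e4um2`, `nuclear_tuft_ratio`.
#' @export
compute_morphometrics <- function(tuft, nuclei, ppm) {
  assert_scalar(ppm, "ppm", lo = 1e-9)
  tl <- if (inherits(tuft, "labeled_mask")) tuft$labels else tuft
  nl <- if (inherits(nuclei, "labeled_mask")) nuclei$labels else nuclei
  stopifnot(all(dim(tl) == dim(nl)))
  ng <- max(tl)
  if (ng == 0L)
    return(data.frame(glomerulus_id = integer(0), tuft_area_um2 = numeric(0),
                      podocyte_count = integer(0),
                      mean_nuclear_area_um2 = numeric(0),
                      area_density_per_1e4um2 = numeric(0),
                      nuclear_tuft_ratio = numeric(0)))
  t_area_px <- label_areas_px(tl)
  n_area_px <- label_areas_px(nl)
  cent <- label_centroids(nl)
  # assign each nucleus to the tuft containing its centroid (0 = none)
  nuc_tuft <- if (nrow(cent)) {
    tl[cbind(pmin(pmax(round(cent[, "row"]), 1), nrow(tl)),
             pmin(pmax(round(cent[, "col"]), 1), ncol(tl)))]
  } else integer(0)
  rows <- lapply(seq_len(ng), function(g) {
    nid <- which(nuc_tuft == g)
    ta <- t_area_px[g] / ppm^2
    cnt <- length(nid)
    mna <- if (cnt) mean(n_area_px[nid]) / ppm^2 else NA_real_
    tot_n <- sum(n_area_px[nid]) / ppm^2
    data.frame(glomerulus_id = g, tuft_area_um2 = ta, podocyte_count = cnt,
               mean_nuclear_area_um2 = mna,
               area_density_per_1e4um2 = if (ta > 0) cnt / ta * 1e4 else NA_real_,
               nuclear_tuft_ratio = if (ta > 0) min(1, tot_n / ta) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Per-glomerulus nephrin-positive cytoplasm area via Otsu
#'
#' Within each tuft the Otsu threshold of the nephrin-like intensity is
#' computed and the above-threshold area reported. Cytoplasm area
#' includes nuclear pixels (no subtraction). A constant intensity inside
#' a tuft is degenerate: area 0 with `degenerate = TRUE`.
#'
#' @param image nephrin-channel intensity matrix.
#' @param tuft a `labeled_mask` (or integer label matrix).
#' @param ppm pixels per micron.
#' @return data.frame: `glomerulus_id`, `threshold`,
#'   `cytoplasm_area_um2`, `cytoplasm_tuft_ratio`, `degenerate`.
#' @export
nephrin_area <- function(image, tuft, ppm) {
  assert_scalar(ppm, "ppm", lo = 1e-9)
  tl <- if (inherits(tuft, "labeled_mask")) tuft$labels else tuft
  stopifnot(all(dim(image) == dim(tl)))
  ng <- max(tl)
  rows <- lapply(seq_len(ng), function(g) {
    v <- image[tl == g]
    th <- otsu_threshold(v)
    if (is.na(th)) {
      data.frame(glomerulus_id = g, threshold = NA_real_,
                 cytoplasm_area_um2 = 0, cytoplasm_tuft_ratio = 0,
                 degenerate = TRUE)
    } else {
      pos <- sum(v > th)
      data.frame(glomerulus_id = g, threshold = th,
                 cytoplasm_area_um2 = pos / ppm^2,
                 cytoplasm_tuft_ratio = pos / length(v),
                 degenerate = FALSE)
    }
  })
  if (!length(rows))
    return(data.frame(glomerulus_id = integer(0), threshold = numeric(0),
                      cytoplasm_area_um2 = numeric(0),
                      cytoplasm_tuft_ratio = numeric(0),
                      degenerate = logical(0)))
  do.call(rbind, rows)
}

#' Stain-positive fraction within a mask
#'
#' Fraction of mask pixels whose intensity exceeds `threshold`
#' (Otsu-derived when not supplied).
#'
#' @param image intensity matrix.
#' @param glom_mask binary matrix selecting the region.
#' @param threshold intensity cut; `NULL` to derive via
#'   [otsu_threshold()] on the in-mask intensities.
#' @return scalar fraction in `[0, 1]`.
#' @export
stain_fraction <- function(image, glom_mask, threshold = NULL) {
  m <- as_binary_matrix(glom_mask, "glom_mask")
  stopifnot(all(dim(image) == dim(m)))
  v <- image[m > 0]
  assert_that(length(v) > 0, "empty mask")
  if (is.null(threshold)) threshold <- otsu_threshold(v)
  if (is.na(threshold)) return(0)
  mean(v > threshold)
}
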