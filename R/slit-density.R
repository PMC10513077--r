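#' Maximum-intensity projection of a z-stack
#'
#' Merges all slices of a STED-like z-stack into one 2D image by the
#' per-pixel maximum across slices.
#'
#' @param stack 3D array (H x W x Z, Z >= 1) or 2D matrix (returned
#'   unchanged).
#' @return matrix H x W.
#' @export
project_zstack <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(is.array(stack), length(dim(stack)) == 3, dim(stack)[3] >= 1)
  apply(stack, c(1, 2), max)
}

shift_mat <- function(x, dr, dc) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0L, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- x[rs - dr, cs - dc]
  out
}

# sequential staircase/bump pruning: drop a skeleton pixel when its 2-3
# neighbours remain mutually 8-connected without it (Zhang-Suen leaves
# such redundant corner pixels, which would inflate length estimates)
prune_staircase <- function(sk) {
  H <- nrow(sk); W <- ncol(sk)
  off_i <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_j <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (p in which(sk == 1L)) {
    i <- ((p - 1L) %% H) + 1L; j <- ((p - 1L) %/% H) + 1L
    if (i <= 1L || i >= H || j <= 1L || j >= W) next
    ni <- i + off_i; nj <- j + off_j
    on <- sk[cbind(ni, nj)] == 1L
    k <- sum(on)
    if (k < 2L || k > 3L) next
    pi_ <- ni[on]; pj <- nj[on]
    # connectivity of the neighbour set under 8-adjacency
    seen <- 1L
    repeat {
      added <- FALSE
      for (r in seq_len(k)) {
        if (r %in% seen) next
        if (any(pmax(abs(pi_[seen] - pi_[r]), abs(pj[seen] - pj[r])) <= 1L)) {
          seen <- c(seen, r); added <- TRUE
        }
      }
      if (!added) break
    }
    if (length(seen) == k) sk[i, j] <- 0L
  }
  sk
}

#' Morphological thinning (Zhang-Suen) to a 1-pixel skeleton
#'
#' Iterative Zhang-Suen thinning followed by a staircase-pruning pass
#' that removes redundant corner pixels while preserving connectivity.
#'
#' @param binary binary matrix.
#' @return integer binary matrix of the skeleton.
#' @export
skeletonize <- function(binary) {
  sk <- as_binary_matrix(binary)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north: P2..P9
      P2 <- shift_mat(sk, 1, 0);  P3 <- shift_mat(sk, 1, -1)
      P4 <- shift_mat(sk, 0, -1); P5 <- shift_mat(sk, -1, -1)
      P6 <- shift_mat(sk, -1, 0); P7 <- shift_mat(sk, -1, 1)
      P8 <- shift_mat(sk, 0, 1);  P9 <- shift_mat(sk, 1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (step == 1) {
        cond <- sk == 1 & B >= 2 & B <= 6 & A == 1 &
          P2 * P4 * P6 == 0 & P4 * P6 * P8 == 0
      } else {
        cond <- sk == 1 & B >= 2 & B <= 6 & A == 1 &
          P2 * P4 * P8 == 0 & P2 * P6 * P8 == 0
      }
      if (any(cond)) { sk[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  prune_staircase(sk)
}

#' Total curve length of a binary pattern
#'
#' Thins the pattern to a 1-pixel skeleton and sums adjacent
#' skeleton-pixel pairs: 1 pixel spacing for 4-neighbours, sqrt(2) for
#' diagonal neighbours, each unordered pair counted once, divided by the
#' pixel density to give micrometres. A diagonal pair is not counted
#' when a shared 4-neighbour already connects the two pixels (the
#' diagonal would double-count that corner).
#'
#' @param binary binary matrix (already-thin input is preserved).
#' @param ppm pixels per micron (> 0).
#' @param thin set `FALSE` to skip the thinning step.
#' @return total length in um (0 for an empty mask).
#' @export
skeleton_length <- function(binary, ppm, thin = TRUE) {
  assert_scalar(ppm, "ppm", lo = 1e-9)
  sk <- if (thin) skeletonize(binary) else as_binary_matrix(binary)
  H <- nrow(sk); W <- ncol(sk)
  if (sum(sk) == 0) return(0)
  horiz <- sum(sk[, -W] & sk[, -1])
  vert <- sum(sk[-H, ] & sk[-1, ])
  diag1 <- sum(sk[-H, -W] & sk[-1, -1] & !(sk[-1, -W] | sk[-H, -1]))
  diag2 <- sum(sk[-1, -W] & sk[-H, -1] & !(sk[-H, -W] | sk[-1, -1]))
  (horiz + vert + sqrt(2) * (diag1 + diag2)) / ppm
}

#' Filtration-slit density of one field
#'
#' Projects the z-stack, binarises the projection with the Otsu
#' threshold, thins it, and reports ridge length per unit field area.
#'
#' @param field a `slit_scene_truth`, or a list with `zstack` (or a
#'   matrix/array), `ppm`, and optionally `field_area_um2`.
#' @param field_id,glomerulus_id,mouse_id identifiers carried into the
#'   record.
#' @param ppm pixels per micron; taken from `field$ppm` when present.
#' @return one-row data.frame: `field_id`, `glomerulus_id`, `mouse_id`,
#'   `total_length_um`, `field_area_um2`, `density_um_per_um2`.
#' @export
slit_density <- function(field, field_id = 1L, glomerulus_id = 1L,
                         mouse_id = 1L, ppm = NULL) {
  stack <- if (is.list(field)) field$zstack else field
  ppm <- ppm %||% (if (is.list(field)) field$ppm else NULL)
  assert_that(!is.null(ppm), "pixel density `ppm` is required")
  proj <- project_zstack(stack)
  area <- if (is.list(field) && !is.null(field$field_area_um2))
    field$field_area_um2 else nrow(proj) * ncol(proj) / ppm^2
  assert_that(area > 0, "zero field area")
  th <- otsu_threshold(as.vector(proj))
  bin <- if (is.na(th)) matrix(0L, nrow(proj), ncol(proj)) else proj > th
  len <- skeleton_length(bin, ppm)
  data.frame(field_id = field_id, glomerulus_id = glomerulus_id,
             mouse_id = mouse_id, total_length_um = len,
             field_area_um2 = area, density_um_per_um2 = len / area)
}

#' Sampling plan for slit-density aggregation
#'
#' @param areas_per_glomerulus fields sampled per glomerulus.
#' @param glomeruli_per_mouse_min minimum glomeruli per mouse.
#' @return list of class `aggregation_plan`.
#' @export
aggregation_plan <- function(areas_per_glomerulus = 5L,
                             glomeruli_per_mouse_min = 5L) {
  assert_scalar(areas_per_glomerulus, "areas_per_glomerulus", lo = 1)
  assert_scalar(glomeruli_per_mouse_min, "glomeruli_per_mouse_min", lo = 1)
  structure(list(areas_per_glomerulus = as.integer(areas_per_glomerulus),
                 glomeruli_per_mouse_min = as.integer(glomeruli_per_mouse_min)),
            class = "aggregation_plan")
}

#' Aggregate slit-density records field -> glomerulus -> mouse
#'
#' Hierarchical means: per-glomerulus mean over its fields, then
#' per-mouse mean over its glomeruli. Warns when a glomerulus has fewer
#' fields or a mouse fewer glomeruli than the plan requires.
#'
#' @param records data.frame of [slit_density()] rows.
#' @param plan an [aggregation_plan()].
#' @return list with `per_glomerulus` and `per_mouse` data.frames.
#' @export
aggregate_slit_density <- function(records, plan = aggregation_plan()) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  per_glom <- do.call(rbind, lapply(
    split(records, list(records$mouse_id, records$glomerulus_id), drop = TRUE),
    function(d) data.frame(mouse_id = d$mouse_id[1],
                           glomerulus_id = d$glomerulus_id[1],
                           n_fields = nrow(d),
                           density_um_per_um2 = mean(d$density_um_per_um2))))
  rownames(per_glom) <- NULL
  if (any(per_glom$n_fields < plan$areas_per_glomerulus))
    warning("some glomeruli have fewer fields than the plan requires")
  per_mouse <- do.call(rbind, lapply(
    split(per_glom, per_glom$mouse_id),
    function(d) data.frame(mouse_id = d$mouse_id[1],
                           n_glomeruli = nrow(d),
                           density_um_per_um2 = mean(d$density_um_per_um2))))
  rownames(per_mouse) <- NULL
  if (any(per_mouse$n_glomeruli < plan$glomeruli_per_mouse_min))
    warning("some mice have fewer glomeruli than the plan requires")
  list(per_glomerulus = per_glom, per_mouse = per_mouse)
}
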