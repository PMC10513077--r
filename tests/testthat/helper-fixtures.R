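# Small fixtures shared across test files; everything is generated in code.

# a compact single-glomerulus scene for unit tests
small_scene <- function(seed = 1L, ...) {
  generate_glomerulus_scene(scene_params(frame_size_px = c(256L, 256L),
                                         n_glomeruli = 1L, seed = seed, ...))
}

# brute-force Otsu oracle: minimise the weighted within-class variance over
# all candidate cuts of the raw histogram (independent of the package's
# cumulative-moment implementation, which maximises between-class variance)
otsu_brute_force <- function(x) {
  ux <- sort(unique(x))
  cand <- (ux[-length(ux)] + ux[-1]) / 2
  n <- length(x)
  best <- Inf; best_th <- NA_real_
  for (th in cand) {
    lo <- x[x <= th]; hi <- x[x > th]
    wcv <- length(lo) / n * mean((lo - mean(lo))^2) +
      length(hi) / n * mean((hi - mean(hi))^2)
    if (wcv < best - 1e-12) { best <- wcv; best_th <- th }
  }
  best_th
}

# brute-force Dice via explicit set overlap on index sets
dice_brute_force <- function(a, b) {
  ia <- which(a != 0); ib <- which(b != 0)
  if (!length(ia) && !length(ib)) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}
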