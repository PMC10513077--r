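#' @useDynLib podometrics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rpois sd var aov kruskal.test
#'   shapiro.test wilcox.test p.adjust qt pt ptukey lm coef integrate
#'   complete.cases median quantile
#' @importFrom utils head write.csv read.csv
NULL

# Run `code` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards. Every stochastic operation in the package funnels
# through this so that identical seeds give bit-identical outputs.
with_rng <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# scalar in [lo, hi]
assert_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  assert_that(is.numeric(x) && length(x) == 1 && is.finite(x) && x >= lo && x <= hi,
              sprintf("`%s` must be a finite scalar in [%g, %g]", name, lo, hi))
}

# numeric range c(lo, hi) with lo <= hi
assert_range <- function(x, name, lo = -Inf) {
  assert_that(is.numeric(x) && length(x) == 2 && all(is.finite(x)) &&
                x[1] <= x[2] && x[1] >= lo,
              sprintf("`%s` must be a nondecreasing length-2 range", name))
}

as_binary_matrix <- function(x, name = "mask") {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  assert_that(is.matrix(x) || (is.array(x) && length(dim(x)) == 2),
              sprintf("`%s` must be a 2D matrix", name))
  x <- matrix(as.numeric(x) != 0, nrow = nrow(x))
  storage.mode(x) <- "integer"
  x
}

label_components <- function(binary) {
  lab <- EBImage::bwlabel(matrix(as.numeric(binary != 0), nrow = nrow(binary)))
  m <- EBImage::imageData(lab)
  storage.mode(m) <- "integer"
  m
}

# per-label pixel counts, ordered by label 1..max
label_areas_px <- function(labels) {
  if (max(labels) == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = max(labels))
}

# centroids (row, col) of each label, 1-based pixel centers
label_centroids <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  r <- ((idx - 1L) %% nrow(labels)) + 1L
  c <- ((idx - 1L) %/% nrow(labels)) + 1L
  cbind(row = tapply(r, lab, mean)[as.character(seq_len(n))],
        col = tapply(c, lab, mean)[as.character(seq_len(n))])
}
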