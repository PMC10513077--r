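#' Otsu threshold of an intensity sample
#'
#' Picks the cut that maximises the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over the intensity histogram. Candidate cuts
#' are the midpoints between consecutive occupied intensity levels; when
#' more than `max_levels` distinct values are present the sample is first
#' binned into `max_levels` equal-width bins (bin centres serve as
#' levels), which reproduces classic 8-bit behaviour for integer images.
#' Ties are broken toward the lowest cut. Pixels with intensity strictly
#' above the returned threshold are "positive".
#'
#' @param x numeric vector of intensities (e.g. pixels inside one tuft).
#' @param max_levels histogram resolution for continuous data.
#' @return the threshold, or `NA` (with a warning) when the sample is
#'   constant.
#' @export
otsu_threshold <- function(x, max_levels = 256L) {
  x <- x[is.finite(x)]
  assert_that(length(x) >= 1, "otsu_threshold: empty sample")
  if (length(unique(x)) < 2L) {
    warning("otsu_threshold: constant intensity, threshold undefined")
    return(NA_real_)
  }
  ux <- sort(unique(x))
  if (length(ux) > max_levels) {
    lo <- min(x); hi <- max(x)
    bin <- pmin(max_levels, 1L + floor((x - lo) / (hi - lo) * max_levels))
    centers <- lo + (seq_len(max_levels) - 0.5) * (hi - lo) / max_levels
    cnt <- tabulate(bin, nbins = max_levels)
    keep <- cnt > 0
    levels <- centers[keep]; counts <- cnt[keep]
  } else {
    levels <- ux
    counts <- as.vector(table(factor(x, levels = ux)))
  }
  L <- length(levels)
  p <- counts / sum(counts)
  w0 <- cumsum(p)[-L]
  mu <- cumsum(p * levels)
  mu_t <- mu[L]
  mu0 <- mu[-L] / w0
  w1 <- 1 - w0
  mu1 <- (mu_t - mu[-L]) / w1
  sigma_b2 <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(sigma_b2)  # which.max takes the first maximum: lowest cut
  (levels[k] + levels[k + 1]) / 2
}
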