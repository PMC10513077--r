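#' Generate a synthetic plate-reader standard curve with known truth
#'
#' Emulates a colorimetric assay plate: absorbance is affine in
#' concentration (slope, blank intercept) plus bounded Gaussian noise.
#' Standards and samples are both rendered so the standard-curve
#' regression and back-calculation can be exercised against known
#' concentrations.
#'
#' @param standard_concentrations standard concentrations (e.g. mg/dL).
#' @param sample_true_concentrations true sample concentrations.
#' @param slope absorbance units per concentration unit.
#' @param blank blank absorbance added to every well.
#' @param noise_sd absorbance noise sd (0 gives exact affine readings).
#' @param seed integer seed.
#' @return A list of class `plate_truth`: `standard_concentrations`,
#'   `standard_absorbances`, `sample_true_concentrations`,
#'   `sample_absorbances`, `blank`, `slope`.
#' @export
generate_plate <- function(standard_concentrations = c(0, 5, 10, 20, 40, 80),
                           sample_true_concentrations = c(8, 22, 55),
                           slope = 0.012, blank = 0.05, noise_sd = 0.002,
                           seed = 1L) {
  stopifnot(length(standard_concentrations) >= 2)
  with_rng(seed, {
    ns <- length(standard_concentrations)
    nm <- length(sample_true_concentrations)
    std <- blank + slope * standard_concentrations + rnorm(ns, 0, noise_sd)
    smp <- blank + slope * sample_true_concentrations + rnorm(nm, 0, noise_sd)
    structure(list(standard_concentrations = standard_concentrations,
                   standard_absorbances = std,
                   sample_true_concentrations = sample_true_concentrations,
                   sample_absorbances = smp,
                   blank = blank, slope = slope),
              class = "plate_truth")
  })
}

#' Generate a synthetic cell-by-gene count matrix with QC ground truth
#'
#' Builds a nonnegative integer count matrix whose gene names include a
#' mitochondrial set (prefixed `mt-`, the mouse convention). Each cell
#' draws a total read depth, a mitochondrial read fraction, and a number
#' of expressed nuclear genes; reads are then allocated multinomially.
#' The generator records `true_pass_count`, the number of cells passing
#' the published QC rule (mitochondrial fraction < 0.40 and more than
#' 200 expressed genes), by direct application of the rule to the final
#' matrix.
#'
#' @param n_cells number of cells.
#' @param n_genes total genes including mitochondrial ones.
#' @param n_mito_genes number of `mt-` prefixed genes.
#' @param depth_range per-cell total read depth range (uniform integer).
#' @param mito_fraction either a length-2 range for a uniform draw per
#'   cell, or a vector of length `n_cells` of fixed fractions.
#' @param genes_per_cell range of expressed nuclear genes per cell.
#' @param seed integer seed.
#' @return A list of class `count_matrix_truth`: `counts` (a sparse
#'   `dgCMatrix`, cells x genes), `gene_names`, `true_pass_count`.
#' @export
generate_count_matrix <- function(n_cells = 1000L, n_genes = 500L,
                                  n_mito_genes = 13L,
                                  depth_range = c(1000L, 5000L),
                                  mito_fraction = c(0, 1),
                                  genes_per_cell = c(250L, 450L),
                                  seed = 1L) {
  stopifnot(n_genes > n_mito_genes, n_mito_genes >= 1)
  with_rng(seed, {
    gene_names <- c(paste0("mt-", sprintf("Gene%02d", seq_len(n_mito_genes))),
                    paste0("Gene", seq_len(n_genes - n_mito_genes)))
    mito_idx <- seq_len(n_mito_genes)
    nuc_idx <- setdiff(seq_len(n_genes), mito_idx)
    mf <- if (length(mito_fraction) == n_cells) mito_fraction else
      runif(n_cells, mito_fraction[1], mito_fraction[2])
    ii <- integer(0); jj <- integer(0); xx <- integer(0)
    for (cell in seq_len(n_cells)) {
      depth <- sample(depth_range[1]:depth_range[2], 1)
      m_reads <- round(depth * mf[cell])
      n_reads <- depth - m_reads
      k <- min(length(nuc_idx),
               sample(genes_per_cell[1]:genes_per_cell[2], 1))
      gsel <- sample(nuc_idx, k)
      if (n_reads > 0 && k > 0) {
        # every selected gene gets >= 1 read when depth allows
        alloc <- as.vector(stats::rmultinom(1, max(0L, n_reads - k), rep(1, k))) +
          (if (n_reads >= k) 1L else 0L)
        nz <- alloc > 0
        ii <- c(ii, rep(cell, sum(nz))); jj <- c(jj, gsel[nz]); xx <- c(xx, alloc[nz])
      }
      if (m_reads > 0) {
        malloc <- as.vector(stats::rmultinom(1, m_reads, rep(1, n_mito_genes)))
        nz <- malloc > 0
        ii <- c(ii, rep(cell, sum(nz))); jj <- c(jj, mito_idx[nz]); xx <- c(xx, malloc[nz])
      }
    }
    counts <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                   dims = c(n_cells, n_genes),
                                   dimnames = list(NULL, gene_names))
    # truth by direct application of the rule (independent of qc_filter)
    tot <- Matrix::rowSums(counts)
    mito <- Matrix::rowSums(counts[, mito_idx, drop = FALSE])
    frac <- ifelse(tot > 0, mito / tot, 0)
    expressed <- Matrix::rowSums(counts > 0)
    structure(list(counts = counts, gene_names = gene_names,
                   true_pass_count = sum(frac < 0.40 & expressed > 200)),
              class = "count_matrix_truth")
  })
}
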