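#' Blood-urea-nitrogen kinetic signal
#'
#' Two-read kinetic colorimetry: `((a60 - a120) - blank) * factor`, with
#' the conversion factor 0.467 (urea to urea nitrogen). The blanked,
#' scaled signal is subsequently mapped to mg/dL through the standard
#' curve.
#'
#' @param a60,a120 absorbances at 60 s and 120 s; vectorised.
#' @param blank blank signal.
#' @param factor conversion factor.
#' @return numeric signal.
#' @export
bun_signal <- function(a60, a120, blank, factor = 0.467) {
  stopifnot(all(is.finite(a60)), all(is.finite(a120)), all(is.finite(blank)))
  ((a60 - a120) - blank) * factor
}

#' Creatinine kinetic signal
#'
#' `(a120 - a60) - blank` (samples prediluted 1:9); mapped to mg/dL via
#' the standard curve.
#'
#' @inheritParams bun_signal
#' @return numeric signal.
#' @export
crea_signal <- function(a60, a120, blank) {
  stopifnot(all(is.finite(a60)), all(is.finite(a120)), all(is.finite(blank)))
  (a120 - a60) - blank
}

#' Fit a linear standard curve and back-calculate concentrations
#'
#' Least-squares line `signal ~ concentration` through the standards;
#' `predict_concentration` inverts it.
#'
#' @param concentrations standard concentrations (>= 2 distinct values).
#' @param signals measured standard signals.
#' @return list of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared` and function `predict_concentration(signal)`.
#' @export
standard_curve_fit <- function(concentrations, signals) {
  stopifnot(length(concentrations) == length(signals), length(signals) >= 2)
  assert_that(length(unique(concentrations)) >= 2,
              "degenerate standards: all concentrations equal")
  fit <- lm(signals ~ concentrations)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  assert_that(is.finite(slope) && abs(slope) > 1e-15,
              "degenerate standards: zero slope")
  r2 <- if (var(signals) > 0) suppressWarnings(summary(fit)$r.squared) else NA_real_
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 predict_concentration = function(signal)
                   (signal - intercept) / slope),
            class = "standard_curve")
}

#' Urinary albumin-to-creatinine ratio
#'
#' Albumin (ug/dL) divided by creatinine (mg/dL), i.e. ug albumin per mg
#' creatinine.
#'
#' @param albumin_ug_dl urinary albumin, ug/dL.
#' @param creatinine_mg_dl urinary creatinine, mg/dL (> 0).
#' @return ACR (ug/mg); vectorised.
#' @export
acr <- function(albumin_ug_dl, creatinine_mg_dl) {
  assert_that(all(creatinine_mg_dl > 0), "creatinine must be positive")
  albumin_ug_dl / creatinine_mg_dl
}

#' Albumin ELISA dilution factor from blood glucose
#'
#' Piecewise-constant rule: glucose < 200 mg/dL -> 1:150,
#' 200-350 mg/dL -> 1:250 (closed interval), > 350 mg/dL -> 1:500.
#'
#' @param blood_glucose_mg_dl blood glucose in mg/dL (>= 0); vectorised.
#' @return dilution factor in `{150, 250, 500}`.
#' @export
select_dilution <- function(blood_glucose_mg_dl) {
  assert_that(all(blood_glucose_mg_dl >= 0), "glucose must be nonnegative")
  ifelse(blood_glucose_mg_dl < 200, 150,
         ifelse(blood_glucose_mg_dl <= 350, 250, 500))
}

#' Single-cell QC filter
#'
#' Keeps cells with a mitochondrial read fraction below
#' `max_mito_fraction` and strictly more than `min_genes` expressed
#' (nonzero) genes. Mitochondrial genes are identified by a
#' case-insensitive `mt-` name prefix (mouse convention).
#'
#' @param counts cells x genes matrix (`matrix` or `Matrix` sparse).
#' @param gene_names gene names, length `ncol(counts)`.
#' @param max_mito_fraction exclusive upper bound on mito fraction.
#' @param min_genes exclusive lower bound on expressed genes.
#' @param mito_prefix name prefix marking mitochondrial genes.
#' @return list: `keep` (logical per cell), `n_pass`, `mito_fraction`,
#'   `n_genes` per cell.
#' @export
qc_filter <- function(counts, gene_names = colnames(counts),
                      max_mito_fraction = 0.40, min_genes = 200L,
                      mito_prefix = "mt-") {
  assert_that(!is.null(dim(counts)) && nrow(counts) >= 1 && ncol(counts) >= 1,
              "empty count matrix")
  assert_that(!is.null(gene_names) && length(gene_names) == ncol(counts),
              "gene_names must match the matrix columns")
  assert_scalar(max_mito_fraction, "max_mito_fraction", 1e-9, 1 - 1e-9)
  is_mito <- startsWith(tolower(gene_names), tolower(mito_prefix))
  rs <- if (inherits(counts, "Matrix")) Matrix::rowSums else rowSums
  total <- rs(counts)
  mito <- rs(counts[, is_mito, drop = FALSE])
  frac <- ifelse(total > 0, mito / total, 0)
  n_genes <- rs(counts > 0)
  keep <- frac < max_mito_fraction & n_genes > min_genes
  list(keep = keep, n_pass = sum(keep), mito_fraction = frac,
       n_genes = as.integer(n_genes))
}
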