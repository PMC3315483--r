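# Morphological trait x metabolite association matrices.

#' Trait-metabolite Pearson correlation matrices
#'
#' Z-scores both inputs (which leaves Pearson r unchanged but makes the
#' heterogeneous trait units explicit) and computes the full trait x
#' metabolite correlation and two-sided p-value matrices over the shared
#' genotypes.  Missing trait values are handled by pairwise-complete
#' observations, with the per-cell n reported so each p-value uses the
#' correct t degrees of freedom.
#'
#' @param traits Genotype x trait numeric matrix (row names = genotypes;
#'   `NA` permitted).
#' @param metabolites Genotype x metabolite mean matrix.
#' @param min_n Minimum complete pairs per cell (default 3); cells below it
#'   are `NA`.
#' @return `list(r, p, n)`: trait x metabolite matrices of correlations,
#'   p-values and complete-pair counts.
#' @export
trait_metabolite_correlations <- function(traits, metabolites, min_n = 3) {
  shared <- intersect(rownames(traits), rownames(metabolites))
  if (length(shared) < min_n) .fail("fewer than ", min_n, " shared genotypes")
  A <- as.matrix(traits[shared, , drop = FALSE])
  B <- as.matrix(metabolites[shared, , drop = FALSE])
  nmat <- crossprod(!is.na(A), !is.na(B))
  R <- suppressWarnings(cor(A, B, use = "pairwise.complete.obs"))
  R[nmat < min_n] <- NA
  r_cl <- pmin(pmax(R, -1), 1)
  tt <- abs(r_cl) * sqrt((nmat - 2) / pmax(1 - r_cl^2, .Machine$double.eps))
  P <- 2 * pt(-tt, pmax(nmat - 2, 1))
  P[abs(r_cl) == 1 & !is.na(r_cl)] <- 0
  P[is.na(R)] <- NA
  undefined <- rowSums(nmat >= min_n) == 0
  if (any(undefined))
    warning("trait(s) with no cell of >= ", min_n, " complete pairs: ",
            paste(colnames(A)[undefined], collapse = ", "), call. = FALSE)
  list(r = R, p = P, n = nmat)
}

#' Sign summary of a correlation matrix
#'
#' Fraction of strictly negative correlations among the defined cells,
#' together with negative/positive/zero counts -- the summary behind the
#' observation that most trait-metabolite associations in an IL population
#' are negative.
#'
#' @param r Correlation matrix (`NA` cells ignored).
#' @return `list(fraction_negative, n_negative, n_positive, n_zero,
#'   n_defined)`.
#' @export
sign_summary <- function(r) {
  v <- r[!is.na(r)]
  list(fraction_negative = if (length(v) > 0) mean(v < 0) else NA_real_,
       n_negative = sum(v < 0), n_positive = sum(v > 0),
       n_zero = sum(v == 0), n_defined = length(v))
}
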