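# Normalization chain applied to raw GC-MS relative responses before any
# statistics: per-sample median scaling, reference-sample (control) scaling
# per stratum, then log10.

#' Per-sample median normalization
#'
#' Divides every response by the median response of its own sample
#' (chromatogram), removing per-injection intensity differences.  For samples
#' with an odd number of metabolites the post-normalization sample median is
#' exactly 1.
#'
#' @param profiles A long-form profile table (see [validate_profiles()]).
#' @return The profile table with responses median-scaled.
#' @export
median_normalize <- function(profiles) {
  validate_profiles(profiles, require_control = FALSE)
  med <- tapply(profiles$response, profiles$sample_id, median)
  if (any(!is.finite(med) | med <= 0))
    .fail("sample(s) with non-positive or undefined median response: ",
          paste(names(med)[!is.finite(med) | med <= 0], collapse = ", "))
  profiles$response <- profiles$response / as.vector(med[profiles$sample_id])
  profiles
}

#' Reference (control-sample) normalization
#'
#' Divides each metabolite's responses by the mean response of the control
#' genotype for that metabolite within the same (season, tissue) stratum, the
#' proxy for an injection set.  The control mean maps to 1.  Metabolites
#' missing from the control in a stratum cannot be normalized there and are
#' dropped from that stratum with a warning.
#'
#' @param profiles A long-form profile table.
#' @param control_id Control genotype name (default `"M82"`).
#' @return The profile table with responses on the control-relative scale.
#' @export
reference_normalize <- function(profiles, control_id = "M82") {
  validate_profiles(profiles, control_id = control_id)
  stratum <- paste(profiles$season, profiles$tissue, sep = "\r")
  key <- paste(stratum, profiles$metabolite, sep = "\r")
  is_ctl <- profiles$genotype == control_id
  ctl_mean <- tapply(profiles$response[is_ctl], key[is_ctl], mean)
  ref <- as.vector(ctl_mean[key])
  orphan <- is.na(ref)
  if (any(orphan)) {
    bad <- unique(profiles$metabolite[orphan])
    warning(sprintf(
      "%d record(s) for metabolite(s) %s lack a control reference in their stratum; dropped",
      sum(orphan), paste(bad, collapse = ", ")), call. = FALSE)
    profiles <- profiles[!orphan, , drop = FALSE]
    ref <- ref[!orphan]
  }
  profiles$response <- profiles$response / ref
  profiles
}

#' Log10 transformation
#'
#' Elementwise log10 of positive normalized responses.  Accepts either a
#' numeric matrix/vector or a long-form profile table (in which case the
#' `response` column is transformed in place and the result is no longer a
#' valid raw profile table -- values may be negative).
#'
#' @param x Numeric matrix/vector or a profile `data.frame`.
#' @return Object of the same shape with log10 values.
#' @export
log10_transform <- function(x) {
  if (is.data.frame(x)) {
    bad <- which(!is.finite(x$response) | x$response <= 0)
    if (length(bad) > 0L)
      .fail("non-positive response at row(s): ",
            paste(head(bad, 10L), collapse = ", "))
    x$response <- log10(x$response)
    return(x)
  }
  if (any(!is.finite(x) | x <= 0))
    .fail("non-positive value(s) passed to log10_transform")
  log10(x)
}

#' Full normalization chain
#'
#' `median_normalize()` then [reference_normalize()]; the returned table is on
#' the control-relative positive scale expected by the mQTL, CV and
#' heritability stages (which log-transform internally where needed).
#'
#' @inheritParams reference_normalize
#' @param steps Character vector naming the steps to apply, in order.
#' @return Normalized profile table.
#' @export
normalize_profiles <- function(profiles, control_id = "M82",
                               steps = c("median", "reference")) {
  for (s in steps) {
    profiles <- switch(s,
      median = median_normalize(profiles),
      reference = reference_normalize(profiles, control_id),
      .fail("unknown normalization step: ", s))
  }
  profiles
}

#' Fold-change display scale
#'
#' Converts a ratio relative to the control to the displayed relative change,
#' `ratio - 1`: the control maps to 0, a ratio of 2.2 displays as +1.2, a
#' halving as -0.5.
#'
#' @param ratio Positive ratio(s) of IL level to control level.
#' @return `ratio - 1`.
#' @export
fold_change_display <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0))
    .fail("fold_change_display needs positive ratios")
  ratio - 1
}

#' Column z-score standardization
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1
#' (n-1 denominator).  Pearson correlations are invariant to this affine
#' transformation; it is applied before trait-metabolite correlation so
#' heterogeneous units are comparable.
#'
#' @param x Numeric matrix (columns = variables).
#' @return Matrix of z-scores with the input's dimnames.
#' @export
zscore <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0)) {
    bad <- colnames(x)[which(is.na(sds) | sds == 0)]
    if (is.null(bad)) bad <- which(is.na(sds) | sds == 0)
    .fail("constant or empty column(s): ", paste(bad, collapse = ", "))
  }
  scale(x)[, , drop = FALSE]
}
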