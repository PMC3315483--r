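# Phenotypic plasticity (CV), broad-sense heritability from expected mean
# squares of the model y = M + S + R(S) + G + GS + e, and the 2/3-factor
# fixed-effects variance-source screens.

#' Coefficient of variation per genotype and metabolite
#'
#' The per-genotype plasticity index: sample standard deviation over mean of
#' the replicate responses, on the normalized (pre-log) scale, computed for
#' every metabolite of every genotype within the selected stratum.
#'
#' @param profiles Normalized profile table.
#' @param season,tissue Optional stratum filters; by default replicates from
#'   all seasons of a tissue contribute, so the CV captures the response to
#'   the environment across the design.
#' @return `data.frame(genotype, metabolite, n, cv)`.  Cells with fewer than
#'   2 replicates or non-positive mean are dropped with a warning.
#' @export
coefficient_of_variation <- function(profiles, season = NULL, tissue = NULL) {
  if (!is.null(season)) profiles <- profiles[profiles$season %in% season, ]
  if (!is.null(tissue)) profiles <- profiles[profiles$tissue %in% tissue, ]
  key <- interaction(profiles$genotype, profiles$metabolite, sep = "\r",
                     drop = TRUE)
  n <- as.vector(tapply(profiles$response, key, length))
  mu <- as.vector(tapply(profiles$response, key, mean))
  sdev <- as.vector(tapply(profiles$response, key, sd))
  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  out <- data.frame(genotype = parts[, 1], metabolite = parts[, 2],
                    n = n, cv = sdev / mu, stringsAsFactors = FALSE)
  bad <- out$n < 2 | mu <= 0
  if (any(bad)) {
    warning(sum(bad), " genotype x metabolite cell(s) with <2 replicates or ",
            "non-positive mean excluded from CV", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Binned relative-frequency distribution
#'
#' Histogram of nonnegative values over `n_bins` half-open bins
#' `[k w, (k+1) w)` of width `w`; the last regular bin is right-closed and an
#' overflow bin `(n_bins w, Inf)` collects the remainder, so relative
#' frequencies always sum to 1.
#'
#' @param values Nonnegative numeric values.
#' @param bin_width Bin width (default 0.1).
#' @param n_bins Number of regular bins (default 40).
#' @return `data.frame(lower, upper, count, frequency)` with `n_bins + 1`
#'   rows (the last being the overflow bin).
#' @export
bin_frequencies <- function(values, bin_width = 0.1, n_bins = 40) {
  values <- values[is.finite(values)]
  stopifnot(all(values >= 0))
  lower <- (seq_len(n_bins) - 1) * bin_width
  upper <- lower + bin_width
  top <- n_bins * bin_width
  idx <- pmin(floor(values / bin_width), n_bins - 1) + 1
  idx[values >= top] <- n_bins + 1L       # overflow
  idx[values == top] <- n_bins            # last regular bin right-closed
  count <- tabulate(idx, nbins = n_bins + 1L)
  data.frame(lower = c(lower, top), upper = c(upper, Inf), count = count,
             frequency = if (length(values) > 0) count / length(values)
             else rep(0, n_bins + 1L))
}

# locate a term's row in a car::Anova table regardless of factor order
.anova_row <- function(a, parts) {
  rn <- rownames(a)
  hit <- vapply(rn, function(r) {
    rp <- strsplit(r, ":", fixed = TRUE)[[1]]
    length(rp) == length(parts) && setequal(rp, parts)
  }, TRUE)
  which(hit)[1]
}

#' Broad-sense heritability from ANOVA mean squares
#'
#' Fits, per metabolite, the fixed-effects linear model
#' `log10(y) = M + S + R(S) + G + GS + e` (season, replicate-within-season,
#' genotype, genotype-by-season) and converts mean squares to variance
#' components via their expectations under the corresponding random-effects
#' model: `sigma2_GS = (MS_GS - MS_E)/r`, `sigma2_G = (MS_G - MS_GS)/(r s)`,
#' with negative estimates truncated at zero, and
#' `H2 = sigma2_G / (sigma2_G + sigma2_GS/s + sigma2_E/(r s))`, clamped to
#' `[0, 1]`.  For unbalanced designs mean squares come from a type-II
#' partition and `r` is the harmonic mean of per-cell replicate counts.
#'
#' @param profiles Normalized profile table spanning at least two seasons
#'   (single-season data leave the model unidentifiable and are an error).
#' @param tissue Optional tissue filter.
#' @return `data.frame(metabolite, ms_g, ms_gs, ms_e, sigma2_g, sigma2_gs,
#'   sigma2_e, h2, truncated)`.
#' @export
broad_sense_heritability <- function(profiles, tissue = NULL) {
  if (!is.null(tissue)) profiles <- profiles[profiles$tissue %in% tissue, ]
  seasons <- unique(profiles$season)
  s <- length(seasons)
  if (s < 2) .fail("broad-sense heritability needs >= 2 seasons")
  mets <- unique(profiles$metabolite)
  rows <- lapply(mets, function(m) {
    d <- profiles[profiles$metabolite == m, ]
    d$y <- log10(d$response)
    d$genotype <- factor(d$genotype)
    d$season <- factor(d$season)
    d$repf <- factor(d$replicate)
    cell_n <- table(d$genotype, d$season)
    if (any(cell_n == 0)) return(NULL)
    r_harm <- 1 / mean(1 / cell_n)
    fit <- lm(y ~ season + season:repf + genotype + genotype:season,
              data = d)
    # type II partition; sequential partition as fallback for the degenerate
    # zero-residual (noise-free) case, where the two coincide anyway
    a <- tryCatch(suppressWarnings(car::Anova(fit, type = 2,
                                              singular.ok = TRUE)),
                  error = function(e) stats::anova(fit))
    ssq <- a[["Sum Sq"]]; dfs <- a[["Df"]]
    ms <- ssq / dfs
    i_g <- .anova_row(a, "genotype")
    i_gs <- .anova_row(a, c("genotype", "season"))
    i_e <- which(rownames(a) == "Residuals")
    ms_g <- ms[i_g]; ms_gs <- ms[i_gs]; ms_e <- ms[i_e]
    if (!is.finite(ms_e)) ms_e <- 0    # saturated/noise-free fit
    s2_gs <- (ms_gs - ms_e) / r_harm
    s2_g <- (ms_g - ms_gs) / (r_harm * s)
    truncated <- s2_gs < 0 || s2_g < 0
    s2_gs <- max(s2_gs, 0); s2_g <- max(s2_g, 0)
    denom <- s2_g + s2_gs / s + ms_e / (r_harm * s)
    h2 <- if (denom > 0) s2_g / denom else 0
    data.frame(metabolite = m, ms_g = ms_g, ms_gs = ms_gs, ms_e = ms_e,
               sigma2_g = s2_g, sigma2_gs = s2_gs, sigma2_e = ms_e,
               h2 = min(max(h2, 0), 1), truncated = truncated,
               stringsAsFactors = FALSE)
  })
  dropped <- mets[vapply(rows, is.null, TRUE)]
  if (length(dropped) > 0L)
    warning("metabolite(s) with empty genotype x season cells skipped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-factor fixed-effects ANOVA screen
#'
#' Per-metabolite fixed-effects linear models over any subset of the factors
#' genotype, tissue (organ) and season, with dummy coding: the `"full"` model
#' includes all interactions, `"two-way"` all main effects and pairwise
#' interactions, `"single"` main effects only.  Term p-values come from a
#' type-II partition; terms made untestable by aliasing are reported with
#' `NA`.
#'
#' @param profiles Normalized profile table.
#' @param factors Character subset of `c("genotype", "tissue", "season")`.
#' @param model `"full"`, `"two-way"` or `"single"`.
#' @return Long `data.frame(metabolite, term, df, statistic, p)`.
#' @export
factorial_anova <- function(profiles,
                            factors = c("genotype", "tissue", "season"),
                            model = c("full", "single", "two-way")) {
  model <- match.arg(model)
  factors <- match.arg(factors, several.ok = TRUE)
  for (f in factors)
    if (length(unique(profiles[[f]])) < 2)
      .fail("factor '", f, "' has fewer than 2 levels")
  rhs <- switch(model,
    full = paste(factors, collapse = " * "),
    single = paste(factors, collapse = " + "),
    `two-way` = if (length(factors) > 1)
      sprintf("(%s)^2", paste(factors, collapse = " + "))
    else factors)
  fml <- as.formula(paste("y ~", rhs))
  mets <- unique(profiles$metabolite)
  out <- lapply(mets, function(m) {
    d <- profiles[profiles$metabolite == m, ]
    d$y <- log10(d$response)
    for (f in factors) d[[f]] <- factor(d[[f]])
    fit <- lm(fml, data = d)
    a <- tryCatch(car::Anova(fit, type = 2, singular.ok = TRUE),
                  error = function(e) NULL)
    if (is.null(a)) {
      return(data.frame(metabolite = m, term = rhs, df = NA_integer_,
                        statistic = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    keep <- rownames(a) != "Residuals"
    data.frame(metabolite = m, term = rownames(a)[keep],
               df = a$Df[keep], statistic = a$`F value`[keep],
               p = a$`Pr(>F)`[keep], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
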