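# mQTL calling: one-way ANOVA screen -> Dunnett many-to-one test vs the
# control -> Bonferroni-corrected calls -> cross-season sharing -> two-way
# ANOVA confirmation -> localization onto introgressed segments.

#' One-way ANOVA screen across the population
#'
#' Classical fixed-effects one-way ANOVA of log10 response on genotype, per
#' metabolite, across all ILs and the control.  Metabolites at or below the
#' permissive screen threshold move on to Dunnett testing.
#'
#' @param profiles Normalized profile table (one season/tissue stratum, or
#'   filtered via `season`/`tissue`).
#' @param season,tissue Optional stratum filters.
#' @param alpha Screen threshold (default 0.05).
#' @return `data.frame(metabolite, p_anova, pass)`; metabolites with fewer
#'   than two genotype groups with replication are dropped with a warning.
#' @export
anova_screen <- function(profiles, season = NULL, tissue = NULL,
                         alpha = 0.05) {
  if (!is.null(season)) profiles <- profiles[profiles$season %in% season, ]
  if (!is.null(tissue)) profiles <- profiles[profiles$tissue %in% tissue, ]
  mets <- unique(profiles$metabolite)
  res <- lapply(mets, function(m) {
    d <- profiles[profiles$metabolite == m, ]
    g <- factor(d$genotype)
    keep <- g %in% names(which(table(g) >= 2))
    d <- d[keep, ]; g <- droplevels(g[keep])
    if (nlevels(g) < 2) return(NULL)
    p <- stats::oneway.test(log10(d$response) ~ g, var.equal = TRUE)$p.value
    data.frame(metabolite = m, p_anova = p, stringsAsFactors = FALSE)
  })
  dropped <- mets[vapply(res, is.null, TRUE)]
  if (length(dropped) > 0L)
    warning("metabolite(s) with <2 replicated groups excluded from screen: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, res)
  out$pass <- out$p_anova <= alpha
  rownames(out) <- NULL
  out
}

# Exact P(max_i |T_i| >= c) for k equicorrelated many-to-one t contrasts,
# correlation rho, df degrees of freedom, by double quadrature: outer over
# the pooled-SD scale factor S = sqrt(chi^2_df/df) (quantile midpoint rule),
# inner over the shared standard-normal factor (Simpson).  Vectorized over c.
.dunnett_p_equicorr <- function(cvals, k, df, rho = 0.5,
                                inner_n = 513, outer_n = 64) {
  cvals <- abs(cvals)
  if (df < 100) outer_n <- max(outer_n, 256)
  x <- seq(-8.5, 8.5, length.out = inner_n)
  h <- x[2] - x[1]
  wx <- h / 3 * c(1, rep(c(4, 2), (inner_n - 3) / 2), 4, 1)
  wphi <- wx * dnorm(x)
  sv <- if (is.finite(df))
    sqrt(qchisq((seq_len(outer_n) - 0.5) / outer_n, df) / df) else 1
  sq <- sqrt(1 - rho); sr <- sqrt(rho)
  acc <- numeric(length(cvals))
  for (s in sv) {
    # inner_n x Nc matrices of band probabilities
    up <- pnorm(outer(-sr * x, cvals * s, "+") / sq)
    lo <- pnorm(outer(-sr * x, -cvals * s, "+") / sq)
    acc <- acc + as.vector(crossprod(wphi, (up - lo)^k))
  }
  p <- 1 - acc / length(sv)
  pmin(pmax(p, 0), 1)
}

#' Dunnett's many-to-one test against the control
#'
#' Two-sided comparisons of every group mean against the control mean using
#' the pooled within-group error variance, with family-wise adjustment over
#' the k contrasts via the multivariate-t distribution of the maximum
#' absolute statistic.  Balanced designs (equal group sizes, hence
#' equicorrelation 0.5) use an exact double-quadrature evaluation; unbalanced
#' designs fall back to seeded Monte-Carlo integration
#' ([mvtnorm::pmvt()]) over the one-factor correlation structure
#' `rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`.
#'
#' @param y Numeric response vector (log scale).
#' @param group Group labels, same length as `y`.
#' @param control_id Control group label.
#' @param seed Seed for the Monte-Carlo branch (ignored by the exact branch).
#' @return `data.frame(genotype, n, estimate, t, p_raw, p_adj)` with one row
#'   per non-control group; `estimate` is the mean difference vs control on
#'   the input scale.
#' @export
dunnett_test <- function(y, group, control_id = "M82", seed = 1) {
  g <- factor(group)
  if (!control_id %in% levels(g)) .fail("control group '", control_id,
                                        "' absent")
  ni <- table(g)
  if (any(ni < 2)) .fail("every compared group needs >= 2 replicates")
  means <- tapply(y, g, mean)
  N <- length(y); k_tot <- nlevels(g)
  df <- N - k_tot
  s2 <- sum((y - means[g])^2) / df
  others <- setdiff(levels(g), control_id)
  est <- means[others] - means[control_id]
  n0 <- ni[[control_id]]
  se <- sqrt(s2 * (1 / ni[others] + 1 / n0))
  if (s2 == 0) {
    if (all(est == 0)) {
      return(data.frame(genotype = others, n = as.vector(ni[others]),
                        estimate = 0, t = 0, p_raw = 1, p_adj = 1,
                        stringsAsFactors = FALSE))
    }
    .fail("zero pooled variance with unequal group means")
  }
  tval <- est / se
  p_raw <- 2 * pt(-abs(tval), df)
  lam <- sqrt(as.vector(ni[others]) / (as.vector(ni[others]) + n0))
  k <- length(others)
  if (k == 1L) {
    p_adj <- p_raw
  } else if (length(unique(as.vector(ni))) == 1L) {
    p_adj <- .dunnett_p_equicorr(tval, k = k, df = df, rho = 0.5)
  } else {
    corr <- tcrossprod(lam)
    diag(corr) <- 1
    p_adj <- vapply(abs(tval), function(cc) {
      set.seed(seed)
      1 - mvtnorm::pmvt(lower = rep(-cc, k), upper = rep(cc, k),
                        corr = corr, df = df,
                        algorithm = mvtnorm::GenzBretz(abseps = 1e-4))[1]
    }, 0)
  }
  p_adj <- pmin(pmax(p_adj, p_raw), 1)
  data.frame(genotype = others, n = as.vector(ni[others]),
             estimate = as.vector(est), t = as.vector(tval),
             p_raw = as.vector(p_raw), p_adj = as.vector(p_adj),
             stringsAsFactors = FALSE)
}

#' Dunnett testing across metabolites
#'
#' Applies [dunnett_test()] to the log10 responses of every metabolite that
#' passed the ANOVA screen (or every metabolite, if `screen` is `NULL`).
#'
#' @param profiles Normalized profile table for one season/tissue stratum.
#' @param screen Optional result of [anova_screen()]; only metabolites with
#'   `pass == TRUE` are tested.
#' @param control_id Control genotype.
#' @param season,tissue Optional stratum filters.
#' @param seed Seed passed to [dunnett_test()].
#' @return Long `data.frame` with `metabolite` plus the [dunnett_test()]
#'   columns; attribute `"n_screened"` records how many metabolites entered.
#' @export
dunnett_screen <- function(profiles, screen = NULL, control_id = "M82",
                           season = NULL, tissue = NULL, seed = 1) {
  if (!is.null(season)) profiles <- profiles[profiles$season %in% season, ]
  if (!is.null(tissue)) profiles <- profiles[profiles$tissue %in% tissue, ]
  mets <- if (is.null(screen)) unique(profiles$metabolite)
  else screen$metabolite[screen$pass]
  out <- lapply(mets, function(m) {
    d <- profiles[profiles$metabolite == m, ]
    tab <- dunnett_test(log10(d$response), d$genotype,
                        control_id = control_id, seed = seed)
    cbind(metabolite = m, tab, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_screened") <- length(mets)
  res
}

#' Call metabolite QTL from Dunnett-adjusted p-values
#'
#' Calls every (IL, metabolite) whose Dunnett-adjusted p-value is at or below
#' the Bonferroni critical value `alpha / n_tests`; additionally reports the
#' permissive tier (`p_adj <= permissive_p`) used for heat-map display.  The
#' Bonferroni family size defaults to the number of metabolites tested
#' (recorded, together with the critical value, as attributes).
#'
#' @param dunnett_tab Result of [dunnett_screen()].
#' @param alpha Family-wise level before Bonferroni division (default 0.05).
#' @param n_tests Bonferroni family size; default `attr(dunnett_tab,
#'   "n_screened")` (the screened metabolite count), falling back to the
#'   number of distinct metabolites present.
#' @param permissive_p Permissive display tier (default 0.01).
#' @return `data.frame(il_id, metabolite, direction, relative_change, p_raw,
#'   p_adjusted, significant)` containing every permissive-tier row;
#'   `significant` marks the Bonferroni-level calls (always a subset).
#'   Attributes `"critical_value"` and `"n_tests"`.
#' @export
call_mqtl <- function(dunnett_tab, alpha = 0.05, n_tests = NULL,
                      permissive_p = 0.01) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    .fail("alpha must lie in (0, 1)")
  if (is.null(n_tests)) {
    n_tests <- attr(dunnett_tab, "n_screened")
    if (is.null(n_tests)) n_tests <- length(unique(dunnett_tab$metabolite))
  }
  crit <- alpha / n_tests
  keep <- dunnett_tab$p_adj <= max(permissive_p, crit)
  tab <- dunnett_tab[keep, , drop = FALSE]
  ratio <- 10^tab$estimate
  out <- data.frame(
    il_id = tab$genotype,
    metabolite = tab$metabolite,
    direction = ifelse(tab$estimate > 0, "increase", "decrease"),
    relative_change = fold_change_display(ratio),
    p_raw = tab$p_raw,
    p_adjusted = tab$p_adj,
    significant = tab$p_adj <= crit,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "critical_value") <- crit
  attr(out, "n_tests") <- n_tests
  out
}

#' Shared mQTL across seasons
#'
#' Intersects per-season Bonferroni-level calls on (IL, metabolite) with a
#' consistent direction of change; only such season-reproducible calls count
#' as shared mQTL.
#'
#' @param calls_by_season Named list of [call_mqtl()] tables, one per season.
#' @param significant_only Use only Bonferroni-level rows (default `TRUE`).
#' @return `data.frame(il_id, metabolite, direction, seasons_supporting)`
#'   where `seasons_supporting` joins the supporting season names with `";"`.
#' @export
conserved_across_seasons <- function(calls_by_season,
                                     significant_only = TRUE) {
  stopifnot(length(calls_by_season) >= 2)
  if (is.null(names(calls_by_season)))
    names(calls_by_season) <- paste0("season", seq_along(calls_by_season))
  keys <- lapply(calls_by_season, function(tab) {
    if (significant_only) tab <- tab[tab$significant, , drop = FALSE]
    unique(paste(tab$il_id, tab$metabolite, tab$direction, sep = "\r"))
  })
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0L)
    return(data.frame(il_id = character(), metabolite = character(),
                      direction = character(),
                      seasons_supporting = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(shared, "\r", fixed = TRUE))
  data.frame(il_id = parts[, 1], metabolite = parts[, 2],
             direction = parts[, 3],
             seasons_supporting = paste(names(calls_by_season),
                                        collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Two-way ANOVA confirmation of shared calls
#'
#' For each shared call, fits a fixed-effects two-way ANOVA (genotype, season
#' and their interaction) on the subset containing only that IL and the
#' control across all seasons, and flags the call as confirmed by the
#' genotype main effect and/or by the genotype-x-season interaction at
#' `alpha`.  Calls without data for the IL or control in every season are
#' flagged unconfirmable.
#'
#' @param profiles Normalized profile table covering all seasons.
#' @param shared_calls Result of [conserved_across_seasons()].
#' @param control_id Control genotype.
#' @param alpha Per-term significance level (default 0.05).
#' @return `shared_calls` with `p_genotype`, `p_interaction`,
#'   `confirmed_genotype`, `confirmed_interaction`, `confirmable` appended.
#' @export
confirm_two_way <- function(profiles, shared_calls, control_id = "M82",
                            alpha = 0.05) {
  seasons <- unique(profiles$season)
  res <- shared_calls
  res$p_genotype <- NA_real_
  res$p_interaction <- NA_real_
  res$confirmable <- FALSE
  for (i in seq_len(nrow(res))) {
    d <- profiles[profiles$metabolite == res$metabolite[i] &
                    profiles$genotype %in% c(res$il_id[i], control_id), ]
    have <- with(d, table(genotype, season))
    if (!all(dim(have) == c(2, length(seasons))) || any(have < 2)) next
    d$genotype <- factor(d$genotype)
    d$season <- factor(d$season)
    fit <- lm(log10(response) ~ genotype * season, data = d)
    a <- car::Anova(fit, type = 2)
    res$p_genotype[i] <- a["genotype", "Pr(>F)"]
    res$p_interaction[i] <- a["genotype:season", "Pr(>F)"]
    res$confirmable[i] <- TRUE
  }
  res$confirmed_genotype <- !is.na(res$p_genotype) & res$p_genotype <= alpha
  res$confirmed_interaction <- !is.na(res$p_interaction) &
    res$p_interaction <= alpha
  res
}

#' Localize calls onto introgressed segments
#'
#' Annotates each call with its IL's segment and collapses same-metabolite,
#' same-direction calls on overlapping segments (positive-length interval
#' intersection on the same chromosome) into single putative loci, proposing
#' the common intersection as the refined locus.  Groups are connected
#' components of the pairwise-overlap graph; for overlap chains whose common
#' intersection is empty the refined interval is reported as `NA` with the
#' group retained as one locus.
#'
#' @param calls A call table with `il_id`, `metabolite`, `direction`.
#' @param map A segment map ([read_segment_map()]).
#' @return A list: `calls` (annotated; unmapped ILs get `NA` coordinates and
#'   a warning) and `loci` (`data.frame(metabolite, direction, chromosome,
#'   ils, n_ils, refined_start, refined_end)`).
#' @export
map_to_segments <- function(calls, map) {
  map <- validate_segment_map(map)
  idx <- match(calls$il_id, map$il_id)
  if (anyNA(idx))
    warning("IL(s) without a mapped segment: ",
            paste(unique(calls$il_id[is.na(idx)]), collapse = ", "),
            call. = FALSE)
  ann <- cbind(calls,
               chromosome = map$chromosome[idx],
               seg_start = map$start[idx],
               seg_end = map$end[idx],
               stringsAsFactors = FALSE)
  mapped <- ann[!is.na(ann$chromosome), , drop = FALSE]
  loci <- list()
  for (key in unique(paste(mapped$metabolite, mapped$direction, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    grp <- mapped[mapped$metabolite == parts[1] &
                    mapped$direction == parts[2], , drop = FALSE]
    grp <- grp[!duplicated(grp$il_id), , drop = FALSE]
    n <- nrow(grp)
    adj <- matrix(FALSE, n, n)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      adj[a, b] <- grp$chromosome[a] == grp$chromosome[b] &&
        min(grp$seg_end[a], grp$seg_end[b]) -
        max(grp$seg_start[a], grp$seg_start[b]) > 0
    }
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    for (cc in seq_len(comp$no)) {
      members <- which(comp$membership == cc)
      lo <- max(grp$seg_start[members])
      hi <- min(grp$seg_end[members])
      empty <- !(lo < hi)
      loci[[length(loci) + 1L]] <- data.frame(
        metabolite = parts[1], direction = parts[2],
        chromosome = grp$chromosome[members[1]],
        ils = paste(grp$il_id[members], collapse = ";"),
        n_ils = length(members),
        refined_start = if (empty) NA_real_ else lo,
        refined_end = if (empty) NA_real_ else hi,
        stringsAsFactors = FALSE)
    }
  }
  loci <- if (length(loci) > 0) do.call(rbind, loci) else
    data.frame(metabolite = character(), direction = character(),
               chromosome = character(), ils = character(),
               n_ils = integer(), refined_start = numeric(),
               refined_end = numeric(), stringsAsFactors = FALSE)
  list(calls = ann, loci = loci)
}
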