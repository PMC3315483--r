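# Seed-vs-fruit topology comparison: variance-matched IL ranking,
# incremental subset networks, permutation nulls for measure differences,
# and modularity significance tests.
#
# Conventions inside this module: measures are computed over the FULL node
# set (so permuted and observed networks are always commensurable), and the
# diameter is the strict all-pairs "longest shortest path" -- infinite for a
# disconnected or edgeless graph.  This is the convention under which the
# permutation criterion reproduces the characteristic floor/1.0 split:
# shuffled data leave density, degree and clustering below any structured
# network's, while their fragmented graphs have infinite diameter.

# thresholded sign-blind adjacency from a genotype x variable matrix
.cor_adjacency <- function(X, r_min = 0.3, p_max = 0.01) {
  n <- nrow(X)
  C <- suppressWarnings(cor(X))
  C[is.na(C)] <- 0
  diag(C) <- 0
  r_cl <- pmin(pmax(C, -1), 1)
  tt <- abs(r_cl) * sqrt((n - 2) / pmax(1 - r_cl^2, .Machine$double.eps))
  P <- 2 * pt(-tt, n - 2)
  P[abs(r_cl) == 1] <- 0
  A <- (abs(C) >= r_min & P <= p_max) * 1
  diag(A) <- 0
  A
}

.measures_from_adjacency <- function(A, measures = c(
  "density", "mean_degree", "clustering_coefficient", "diameter")) {
  n <- ncol(A)
  deg <- rowSums(A)
  e <- sum(deg) / 2
  out <- c(density = e / (n * (n - 1) / 2), mean_degree = 2 * e / n,
           clustering_coefficient = NA_real_, diameter = NA_real_)
  if ("clustering_coefficient" %in% measures) {
    out["clustering_coefficient"] <- if (e == 0) 0 else {
      A2 <- A %*% A
      tri2 <- rowSums(A2 * A)          # 2 x triangles through each node
      denom <- deg * (deg - 1)
      mean(ifelse(denom > 0, tri2 / denom, 0))
    }
  }
  if ("diameter" %in% measures) {
    out["diameter"] <- if (e == 0) Inf else {
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
      if (!igraph::is_connected(g)) Inf else igraph::diameter(g)
    }
  }
  out[measures]
}

#' Comparison-convention topology measures of a data matrix
#'
#' Builds the thresholded correlation network of `X` and returns density,
#' mean degree, clustering coefficient and diameter computed over all
#' columns (isolated nodes included), with the strict all-pairs diameter
#' (`Inf` when disconnected).  This is the measure set the permutation
#' comparison operates on; for display-convention measures see
#' [network_measures()].
#'
#' @param X Genotype x variable numeric matrix.
#' @param r_min,p_max Edge thresholds.
#' @param measures Which of `density`, `mean_degree`,
#'   `clustering_coefficient`, `diameter` to compute.
#' @return Named numeric vector of the requested measures.
#' @export
comparison_measures <- function(X, r_min = 0.3, p_max = 0.01,
                                measures = c("density", "mean_degree",
                                             "clustering_coefficient",
                                             "diameter")) {
  .measures_from_adjacency(.cor_adjacency(X, r_min, p_max), measures)
}

#' Average replicate-level variance of a profile set
#'
#' The reference scale for variance matching: the variance of each
#' metabolite's log10 responses across replicates is computed independently
#' for every (IL, metabolite, season) cell and averaged.
#'
#' @param profiles Normalized profile table.
#' @param control_id Control genotype to exclude (`NULL` keeps it).
#' @return `list(variance = mean cell variance, df = pooled degrees of
#'   freedom over cells)`.
#' @export
average_replicate_variance <- function(profiles, control_id = "M82") {
  if (!is.null(control_id))
    profiles <- profiles[profiles$genotype != control_id, ]
  key <- interaction(profiles$genotype, profiles$metabolite, profiles$season,
                     sep = "\r", drop = TRUE)
  y <- log10(profiles$response)
  v <- tapply(y, key, var)
  n <- tapply(y, key, length)
  ok <- !is.na(v) & n >= 2
  list(variance = mean(v[ok]), df = sum(n[ok] - 1))
}

#' Rank ILs by closeness of their variance to a reference
#'
#' Computes each IL's average replicate variance (mean over metabolite and
#' season cells, log10 scale), compares it to the reference variance by a
#' two-sided variance-ratio F test, and orders ILs by the absolute distance
#' of their variance from the reference ("closest to furthest"), the order
#' in which incremental subset networks are grown.
#'
#' @param profiles Profile table of the dataset to rank (e.g. fruit).
#' @param reference Result of [average_replicate_variance()] on the
#'   reference dataset (e.g. seed season I), or a single variance (then the
#'   reference df is taken as infinite).
#' @param control_id Control genotype to exclude from ranking.
#' @return `data.frame(il_id, avg_variance, df, f, p)` sorted by
#'   `|avg_variance - reference|` ascending.  ILs without any replicated
#'   cell are dropped with a warning.
#' @export
rank_ils_by_variance <- function(profiles, reference, control_id = "M82") {
  if (is.numeric(reference)) reference <- list(variance = reference, df = Inf)
  if (!is.null(control_id))
    profiles <- profiles[profiles$genotype != control_id, ]
  ils <- unique(profiles$genotype)
  rows <- lapply(ils, function(il) {
    d <- profiles[profiles$genotype == il, ]
    key <- interaction(d$metabolite, d$season, sep = "\r", drop = TRUE)
    y <- log10(d$response)
    v <- tapply(y, key, var)
    n <- tapply(y, key, length)
    ok <- !is.na(v) & n >= 2
    if (!any(ok)) return(NULL)
    data.frame(il_id = il, avg_variance = mean(v[ok]),
               df = sum(n[ok] - 1), stringsAsFactors = FALSE)
  })
  dropped <- ils[vapply(rows, is.null, TRUE)]
  if (length(dropped) > 0L)
    warning("IL(s) without replicate variance excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  f <- out$avg_variance / reference$variance
  pl <- pf(f, out$df, reference$df)
  out$f <- f
  out$p <- 2 * pmin(pl, 1 - pl)
  out <- out[order(abs(out$avg_variance - reference$variance)), ]
  rownames(out) <- NULL
  out
}

#' Topology measures of incremental IL subset networks
#'
#' For each subset size, correlations are recomputed from only the first
#' `n` ranked ILs' mean values and the network rebuilt at the standard
#' thresholds.  Measures are reported in the comparison convention
#' ([comparison_measures()]).
#'
#' @param mat Genotype x metabolite mean matrix (rows named by IL).
#' @param ranked_ils IL order, e.g. `rank_ils_by_variance(...)$il_id`.
#' @param sizes Subset sizes (default the first 15..25, 50 and all 76).
#' @param r_min,p_max Edge thresholds.
#' @return `data.frame` with `size` and the four measure columns.
#' @export
subset_network_measures <- function(mat, ranked_ils,
                                    sizes = c(15:25, 50, 76),
                                    r_min = 0.3, p_max = 0.01) {
  ranked_ils <- ranked_ils[ranked_ils %in% rownames(mat)]
  if (max(sizes) > length(ranked_ils))
    .fail("largest subset size exceeds the ", length(ranked_ils),
          " available ranked ILs")
  rows <- lapply(sizes, function(nn) {
    m <- comparison_measures(mat[ranked_ils[seq_len(nn)], , drop = FALSE],
                             r_min, p_max)
    data.frame(size = nn, t(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation test for network-measure differences
#'
#' Compares a reference ("seed") network's measures with those of a subset
#' matrix by the metabolite-shuffling null: in each permutation every
#' metabolite's values are independently shuffled across the subset's ILs,
#' the network is rebuilt and its measures recomputed.  A permutation meets
#' the criterion when the permuted reference-minus-subset difference is at
#' most the observed difference (equivalently, the permuted measure is at
#' least the observed subset measure); the number of such occurrences gives
#' the empirical p-value `max(count, 1)/B`, floored at `1/B`.  The opposite
#' direction (`p_opposite`, counting permuted differences at least the
#' observed) is reported alongside so the one-sidedness of the criterion is
#' explicit.
#'
#' @param subset_mat Genotype x metabolite matrix of the subset's IL means.
#' @param seed_measures Named measure vector of the reference network
#'   ([comparison_measures()]), or a one-row [network_measures()] frame.
#' @param B Number of permutations (default 1000; fewer than 100 warns).
#' @param seed Integer seed for the permutation stream.
#' @param r_min,p_max Edge thresholds.
#' @param measures Which measures to test (restricting saves the per-
#'   permutation triangle/shortest-path work).
#' @return `data.frame(measure, seed_value, subset_value, observed_diff, B,
#'   exceedances, p_empirical, p_opposite)`.
#' @export
permutation_measure_test <- function(subset_mat, seed_measures, B = 1000,
                                     seed = 1, r_min = 0.3, p_max = 0.01,
                                     measures = c("density", "mean_degree",
                                                  "clustering_coefficient",
                                                  "diameter")) {
  if (B <= 0) .fail("B must be positive")
  if (B < 100) warning("B < 100 gives a coarse empirical p", call. = FALSE)
  if (is.data.frame(seed_measures)) {
    sm <- c(density = seed_measures$density,
            mean_degree = seed_measures$mean_degree,
            clustering_coefficient = seed_measures$clustering_coefficient,
            diameter = seed_measures$diameter)
  } else sm <- seed_measures
  keep <- measures
  sm <- sm[keep]
  obs <- comparison_measures(subset_mat, r_min, p_max, measures = keep)
  counts <- with_seed(seed, {
    exceed <- setNames(numeric(length(keep)), keep)
    opposite <- setNames(numeric(length(keep)), keep)
    for (b in seq_len(B)) {
      Xp <- apply(subset_mat, 2, sample)
      pm <- comparison_measures(Xp, r_min, p_max, measures = keep)
      # permuted diff (seed - perm) <= observed diff (seed - obs)
      # <=> permuted measure >= observed subset measure
      exceed <- exceed + (pm >= obs)
      opposite <- opposite + (pm <= obs)
    }
    list(exceed = exceed, opposite = opposite)
  })
  exceed <- counts$exceed
  opposite <- counts$opposite
  data.frame(measure = keep,
             seed_value = as.vector(sm),
             subset_value = as.vector(obs),
             observed_diff = as.vector(sm) - as.vector(obs),
             B = B,
             exceedances = as.vector(exceed),
             p_empirical = pmax(exceed, 1) / B,
             p_opposite = pmax(opposite, 1) / B,
             row.names = NULL)
}

#' Full seed-vs-fruit topology comparison
#'
#' Orchestrates the variance-matched comparison: the reference dataset's
#' average replicate variance ranks the other tissue's ILs; incremental
#' subsets of the ranked ILs yield networks whose measures are tested
#' against the reference network by [permutation_measure_test()].
#'
#' @param reference_profiles Profile table of the reference tissue (seed).
#' @param subset_profiles Profile table of the ranked tissue (fruit).
#' @param season Season used for both datasets (default the first season of
#'   the reference; `NULL` pools seasons).
#' @param sizes Subset sizes.
#' @param B Permutations per subset.
#' @param seed Integer seed.
#' @param r_min,p_max Edge thresholds.
#' @param control_id Control genotype (excluded from ranking and matrices).
#' @return A list: `table` (one row per size with measure values and
#'   p-values), `reference_measures`, `ranking`, and `settings`.
#' @export
compare_networks <- function(reference_profiles, subset_profiles,
                             season = NULL, sizes = c(15:25, 50, 76),
                             B = 1000, seed = 1, r_min = 0.3, p_max = 0.01,
                             control_id = "M82") {
  if (is.null(season)) season <- unique(reference_profiles$season)[1]
  ref_prof <- reference_profiles[reference_profiles$season == season, ]
  sub_season <- if (season %in% subset_profiles$season) season
  else unique(subset_profiles$season)[1]
  sub_prof <- subset_profiles[subset_profiles$season == sub_season, ]
  ref <- average_replicate_variance(ref_prof, control_id)
  ranking <- rank_ils_by_variance(sub_prof, ref, control_id)
  ref_mat <- genotype_means(ref_prof)
  ref_mat <- ref_mat[setdiff(rownames(ref_mat), control_id), , drop = FALSE]
  sub_mat <- genotype_means(sub_prof)
  ref_meas <- comparison_measures(ref_mat, r_min, p_max)
  rows <- lapply(seq_along(sizes), function(i) {
    nn <- sizes[i]
    X <- sub_mat[ranking$il_id[seq_len(nn)], , drop = FALSE]
    pt <- permutation_measure_test(X, ref_meas, B = B, seed = seed + i,
                                   r_min = r_min, p_max = p_max)
    data.frame(size = nn,
               density = pt$subset_value[1], density_p = pt$p_empirical[1],
               degree = pt$subset_value[2], degree_p = pt$p_empirical[2],
               clustering = pt$subset_value[3],
               clustering_p = pt$p_empirical[3],
               diameter = pt$subset_value[4],
               diameter_p = pt$p_empirical[4])
  })
  list(table = do.call(rbind, rows),
       reference_measures = ref_meas,
       ranking = ranking,
       settings = list(season = season, sizes = sizes, B = B, seed = seed,
                       r_min = r_min, p_max = p_max))
}

#' Modularity of a predefined two-community membership
#'
#' Newman-Girvan modularity Q of the given membership (e.g. seed vs fruit
#' node sets in a combined network), with significance from uniformly random
#' permutations of the membership vector: `p = max(#\{Q_perm >= Q\}, 1)/B`.
#'
#' @param net A [cor_network()] or igraph graph.
#' @param membership Named vector (by node name) or vector in node order,
#'   giving each node's community label.
#' @param B Number of membership permutations (default 1e5).
#' @param seed Integer seed.
#' @return `list(Q, B, exceedances, p_empirical)`.
#' @export
modularity_membership_test <- function(net, membership, B = 1e5, seed = 1) {
  g <- if (inherits(net, "cor_network")) as_igraph(net) else net
  vn <- igraph::V(g)$name
  if (!is.null(names(membership))) {
    if (!all(vn %in% names(membership)))
      .fail("membership must cover all nodes")
    membership <- membership[vn]
  } else if (length(membership) != length(vn)) {
    .fail("membership must cover all nodes")
  }
  memb <- as.integer(factor(membership))
  if (length(unique(memb)) < 2) {
    warning("single community: Q = 0", call. = FALSE)
    return(list(Q = 0, B = B, exceedances = B, p_empirical = 1))
  }
  q_obs <- igraph::modularity(g, memb)
  exc <- with_seed(seed, {
    n_exc <- 0L
    for (b in seq_len(B))
      n_exc <- n_exc + (igraph::modularity(g, sample(memb)) >= q_obs)
    n_exc
  })
  list(Q = q_obs, B = B, exceedances = as.integer(exc),
       p_empirical = max(exc, 1) / B)
}

#' Maximal fast-greedy modularity with a rewiring null
#'
#' Runs greedy agglomerative modularity maximization, records the maximal Q,
#' and compares it against degree-preserving randomizations of the graph
#' (edge rewiring, `10 |E|` swaps per replicate; an Erdos-Renyi null with the
#' same node and edge counts is available instead).
#'
#' @param net A [cor_network()] or igraph graph with >= 2 edges.
#' @param B Number of randomized replicates (default 1e4).
#' @param seed Integer seed.
#' @param null `"rewire"` (degree-preserving) or `"erdos"`.
#' @return `list(maxQ, membership, B, exceedances, p_empirical)`.
#' @export
maxq_randomization_test <- function(net, B = 1e4, seed = 1,
                                    null = c("rewire", "erdos")) {
  null <- match.arg(null)
  g <- if (inherits(net, "cor_network")) as_igraph(net) else net
  if (igraph::ecount(g) < 2) .fail("need >= 2 edges")
  fg <- igraph::cluster_fast_greedy(igraph::simplify(g))
  q_obs <- max(fg$modularity)
  exc <- with_seed(seed, {
    n_exc <- 0L
    for (b in seq_len(B)) {
      gr <- if (null == "rewire")
        igraph::rewire(g, igraph::keeping_degseq(
          niter = 10 * igraph::ecount(g)))
      else igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g))
      fgr <- igraph::cluster_fast_greedy(igraph::simplify(gr))
      n_exc <- n_exc + (max(fgr$modularity) >= q_obs)
    }
    n_exc
  })
  list(maxQ = q_obs, membership = igraph::membership(fg), B = B,
       exceedances = as.integer(exc), p_empirical = max(exc, 1) / B)
}
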