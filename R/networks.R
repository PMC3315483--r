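# Correlation-network construction and topology measures: Pearson r over
# genotype means, t-distribution p-values, inclusive |r| >= r_min and
# p <= p_max thresholds, signed edges.

#' All pairwise Pearson correlations
#'
#' Computes Pearson's product-moment correlation and its two-sided p-value
#' (t distribution, n - 2 df) for every unordered pair of columns.  Rows are
#' observation units (genotype means: replicates are averaged before any
#' population-level correlation).  Constant columns yield undefined pairs,
#' which are flagged with `NA` and excluded by [build_network()].
#'
#' @param mat Numeric matrix, rows = genotypes, columns = variables.
#' @return `data.frame(var_a, var_b, r, p, n)` with `choose(ncol, 2)` rows.
#' @export
pairwise_correlations <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) .fail("need >= 3 observation rows")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("V", seq_len(ncol(mat)))
  n <- nrow(mat)
  C <- suppressWarnings(cor(mat))
  idx <- which(upper.tri(C), arr.ind = TRUE)
  r <- C[idx]
  r_cl <- pmin(pmax(r, -1), 1)
  tt <- abs(r_cl) * sqrt((n - 2) / pmax(1 - r_cl^2, .Machine$double.eps))
  p <- 2 * pt(-tt, n - 2)
  p[abs(r_cl) == 1] <- 0
  data.frame(var_a = colnames(mat)[idx[, 1]],
             var_b = colnames(mat)[idx[, 2]],
             r = r, p = p, n = n, stringsAsFactors = FALSE)
}

#' Build a thresholded correlation network
#'
#' Retains an edge iff `|r| >= r_min` and `p <= p_max` (both inclusive);
#' negative correlations are kept as negative-sign edges.  Undefined pairs
#' (`NA` correlation) never become edges.
#'
#' @param cortab Result of [pairwise_correlations()].
#' @param r_min Correlation magnitude threshold (default 0.3).
#' @param p_max Significance threshold (default 0.01).
#' @param nodes Optional node metadata `data.frame` (column `metabolite`,
#'   plus e.g. `compound_class`, `tissue`, `season`); defaults to all
#'   variables appearing in `cortab`, so isolated metabolites stay in the
#'   node set.
#' @return A [cor_network()].
#' @export
build_network <- function(cortab, r_min = 0.3, p_max = 0.01, nodes = NULL) {
  if (is.null(nodes))
    nodes <- sort(unique(c(cortab$var_a, cortab$var_b)))
  keep <- !is.na(cortab$r) & abs(cortab$r) >= r_min & cortab$p <= p_max
  edges <- data.frame(node_a = cortab$var_a[keep],
                      node_b = cortab$var_b[keep],
                      r = cortab$r[keep], p = cortab$p[keep],
                      stringsAsFactors = FALSE)
  cor_network(nodes, edges, thresholds = c(r_min = r_min, p_max = p_max))
}

#' Topology measures of a correlation network
#'
#' Density, mean degree, average local clustering coefficient and diameter of
#' the (sign-blind, simple, undirected) graph.  By convention measures are
#' computed over non-isolated nodes -- the convention under which a 689-edge,
#' 63-connected-node network reports density 0.35 and mean degree 21.87 --
#' with `n_nodes_used` recording the node count actually used.  Nodes of
#' degree < 2 contribute a local clustering of 0 (`clustering = "zero"`);
#' `"exclude"` averages over the remaining nodes instead.  The diameter is
#' the longest finite shortest path (i.e., of the largest component when the
#' graph is disconnected), with `connected` flagging disconnectedness; an
#' edgeless network reports `NA` diameter.
#'
#' @param net A [cor_network()] or an igraph graph.
#' @param drop_isolated Compute over non-isolated nodes (default `TRUE`).
#' @param clustering `"zero"` or `"exclude"` (treatment of degree < 2 nodes).
#' @return `data.frame(density, mean_degree, clustering_coefficient,
#'   diameter, n_nodes_used, n_edges, connected)`.
#' @export
network_measures <- function(net, drop_isolated = TRUE,
                             clustering = c("zero", "exclude")) {
  clustering <- match.arg(clustering)
  g <- if (inherits(net, "cor_network")) as_igraph(net) else net
  if (drop_isolated)
    g <- igraph::induced_subgraph(g, igraph::V(g)[igraph::degree(g) > 0])
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n < 2 || e == 0) {
    return(data.frame(density = 0, mean_degree = 0,
                      clustering_coefficient = 0, diameter = NA_real_,
                      n_nodes_used = n, n_edges = e, connected = FALSE))
  }
  loc <- igraph::transitivity(g, type = "local")
  cc <- if (clustering == "zero") {
    loc[is.na(loc)] <- 0
    mean(loc)
  } else mean(loc, na.rm = TRUE)
  data.frame(density = e / (n * (n - 1) / 2),
             mean_degree = 2 * e / n,
             clustering_coefficient = cc,
             diameter = igraph::diameter(g, unconnected = TRUE),
             n_nodes_used = n, n_edges = e,
             connected = igraph::is_connected(g))
}

#' Combine two tissue matrices into one tissue-tagged matrix
#'
#' Standardizes each tissue's columns (z-score, the analogue of putting both
#' datasets on a common per-tissue scale), restricts to the genotypes shared
#' by both, and concatenates columns with tissue-tagged names.  Within-tissue
#' correlations are unchanged by the standardization; cross-tissue pairs
#' become comparable.
#'
#' @param seed_mat,fruit_mat Genotype x metabolite matrices with genotype
#'   row names.
#' @param tags Length-2 tissue tags prefixed to column names.
#' @return Combined genotype x (tagged metabolite) matrix.
#' @export
combine_tissues <- function(seed_mat, fruit_mat, tags = c("seed", "fruit")) {
  shared <- intersect(rownames(seed_mat), rownames(fruit_mat))
  if (length(shared) == 0L) .fail("no shared genotypes between tissues")
  a <- zscore(seed_mat[shared, , drop = FALSE])
  b <- zscore(fruit_mat[shared, , drop = FALSE])
  colnames(a) <- paste(tags[1], colnames(a), sep = ":")
  colnames(b) <- paste(tags[2], colnames(b), sep = ":")
  cbind(a, b)
}

#' Bipartite cross-season correlation network
#'
#' Correlates every season-1 metabolite against every season-2 metabolite
#' (only cross-season pairs are tested) over the shared genotypes, at the
#' standard thresholds.  Nodes are season-tagged.
#'
#' @param mat_s1,mat_s2 Genotype x metabolite matrices for the two seasons.
#' @param r_min,p_max Edge thresholds.
#' @param tags Length-2 season tags.
#' @return A bipartite [cor_network()].
#' @export
bipartite_cross_season <- function(mat_s1, mat_s2, r_min = 0.3, p_max = 0.01,
                                   tags = c("I", "II")) {
  shared <- intersect(rownames(mat_s1), rownames(mat_s2))
  if (length(shared) < 3) .fail("need >= 3 shared genotypes")
  a <- mat_s1[shared, , drop = FALSE]
  b <- mat_s2[shared, , drop = FALSE]
  n <- length(shared)
  C <- suppressWarnings(cor(a, b))
  r <- as.vector(C)
  r_cl <- pmin(pmax(r, -1), 1)
  tt <- abs(r_cl) * sqrt((n - 2) / pmax(1 - r_cl^2, .Machine$double.eps))
  p <- 2 * pt(-tt, n - 2)
  p[abs(r_cl) == 1] <- 0
  na <- paste(tags[1], rownames(C)[row(C)], sep = ":")
  nb <- paste(tags[2], colnames(C)[col(C)], sep = ":")
  keep <- !is.na(r) & abs(r) >= r_min & p <= p_max
  nodes <- data.frame(
    metabolite = c(paste(tags[1], colnames(a), sep = ":"),
                   paste(tags[2], colnames(b), sep = ":")),
    season = rep(tags, c(ncol(a), ncol(b))),
    stringsAsFactors = FALSE)
  cor_network(nodes,
              data.frame(node_a = na[keep], node_b = nb[keep],
                         r = r[keep], p = p[keep], stringsAsFactors = FALSE),
              thresholds = c(r_min = r_min, p_max = p_max))
}

#' Conserved correlations across networks
#'
#' Restricts a set of networks to their common metabolites (synchronization,
#' which by itself discards edges touching unshared nodes) and keeps the
#' edges present with the same sign in every network.
#'
#' @param networks A list of >= 2 [cor_network()] objects.
#' @return A list: `nodes` (synchronized node names), `conserved` (edge
#'   `data.frame` with the first network's r/p and the shared `sign`), and
#'   `counts` (`data.frame(network, edges_total, edges_after_sync)`).
#' @export
conserved_correlations <- function(networks) {
  stopifnot(length(networks) >= 2)
  node_sets <- lapply(networks, function(nw) nw$nodes$metabolite)
  shared <- Reduce(intersect, node_sets)
  if (length(shared) == 0L) .fail("no metabolites shared by all networks")
  sync_edges <- lapply(networks, function(nw) {
    e <- nw$edges
    e[e$node_a %in% shared & e$node_b %in% shared, , drop = FALSE]
  })
  keys <- lapply(sync_edges, function(e)
    paste(e$node_a, e$node_b, e$sign, sep = "\r"))
  conserved_keys <- Reduce(intersect, keys)
  first <- sync_edges[[1]]
  conserved <- first[paste(first$node_a, first$node_b, first$sign,
                           sep = "\r") %in% conserved_keys, , drop = FALSE]
  rownames(conserved) <- NULL
  counts <- data.frame(
    network = if (!is.null(names(networks))) names(networks)
    else paste0("network", seq_along(networks)),
    edges_total = vapply(networks, function(nw) nrow(nw$edges), 0L),
    edges_after_sync = vapply(sync_edges, nrow, 0L),
    stringsAsFactors = FALSE)
  list(nodes = shared, conserved = conserved, counts = counts)
}
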