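test_that("pairwise correlations enumerate all unordered pairs", {
  set.seed(61)
  X <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(NULL, paste0("V", 1:8)))
  tab <- pairwise_correlations(X)
  expect_equal(nrow(tab), choose(8, 2))
  # brute-force covariance-formula oracle
  for (i in sample(nrow(tab), 10)) {
    a <- X[, tab$var_a[i]]; b <- X[, tab$var_b[i]]
    expect_equal(tab$r[i], oracle_pearson(a, b), tolerance = 1e-12)
    rr <- tab$r[i]
    tt <- abs(rr) * sqrt((10 - 2) / (1 - rr^2))
    expect_equal(tab$p[i], 2 * pt(-tt, 8), tolerance = 1e-12)
  }
})

test_that("perfect and perfectly opposed columns hit the bounds", {
  x <- rnorm(12)
  X <- cbind(a = x, b = x, c = -x)
  tab <- pairwise_correlations(X)
  expect_equal(tab$r[tab$var_a == "a" & tab$var_b == "b"], 1)
  expect_equal(tab$r[tab$var_a == "a" & tab$var_b == "c"], -1)
  expect_equal(tab$p[tab$var_a == "a" & tab$var_b == "b"], 0)
  # constant column flagged undefined
  X2 <- cbind(X, d = rep(2, 12))
  tab2 <- pairwise_correlations(X2)
  expect_true(all(is.na(tab2$r[tab2$var_a == "d" | tab2$var_b == "d"])))
})

test_that("network thresholds are inclusive and signed", {
  tab <- data.frame(var_a = c("a", "a", "b"), var_b = c("b", "c", "c"),
                    r = c(0.30, 0.29, -0.55), p = c(0.01, 0.001, 0.001),
                    n = 20, stringsAsFactors = FALSE)
  nw <- build_network(tab)
  expect_equal(nrow(nw$edges), 2L)                      # 0.30/0.01 kept
  expect_false(any(nw$edges$node_a == "a" & nw$edges$node_b == "c"))
  expect_equal(nw$edges$sign[nw$edges$r < 0], -1L)
  # monotone in thresholds
  nw2 <- build_network(tab, r_min = 0.5)
  nw3 <- build_network(tab, p_max = 0.005)
  expect_lte(nrow(nw2$edges), nrow(nw$edges))
  expect_lte(nrow(nw3$edges), nrow(nw$edges))
})

test_that("measures are exact on canonical graphs", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  m <- network_measures(k5)
  expect_equal(m$density, 1)
  expect_equal(m$mean_degree, 4)
  expect_equal(m$clustering_coefficient, 1)
  expect_equal(m$diameter, 1)
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  m2 <- network_measures(p4)
  expect_equal(m2$density, 0.5)
  expect_equal(m2$mean_degree, 1.5)
  expect_equal(m2$clustering_coefficient, 0)
  expect_equal(m2$diameter, 3)
})

test_that("the printed seed-row arithmetic is reproduced at 63 nodes", {
  g <- with_seed(62, igraph::sample_gnm(63, 689))
  igraph::V(g)$name <- paste0("m", 1:63)
  expect_true(all(igraph::degree(g) > 0))
  m <- network_measures(g)
  expect_equal(m$density, 0.353, tolerance = 0.002)
  expect_equal(m$mean_degree, 21.87, tolerance = 0.001)
  expect_equal(m$n_edges, 689L)
})

test_that("measures equal brute-force oracles on random graphs", {
  with_seed(63, {
    for (i in 1:10) {
      n <- sample(5:30, 1)
      A <- random_adjacency(n, runif(1, 0.05, 0.5))
      rownames(A) <- colnames(A) <- paste0("v", seq_len(n))
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
      m <- network_measures(g)
      o <- oracle_measures(A)
      expect_identical(m$density, o$density)
      expect_identical(m$mean_degree, o$mean_degree)
      expect_equal(m$clustering_coefficient, o$clustering, tolerance = 1e-12)
      expect_identical(as.numeric(m$diameter), as.numeric(o$diameter))
    }
  })
})

test_that("measures are invariant to node relabeling", {
  with_seed(64, {
    A <- random_adjacency(15, 0.3)
    rownames(A) <- colnames(A) <- paste0("v", 1:15)
    perm <- sample(15)
    B <- A[perm, perm]
    ga <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    gb <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
    expect_equal(network_measures(ga), network_measures(gb))
  })
})

test_that("networks are invariant to column standardization", {
  set.seed(65)
  X <- matrix(rlnorm(20 * 12), 20, 12,
              dimnames = list(NULL, paste0("m", 1:12)))
  n1 <- build_network(pairwise_correlations(X))
  n2 <- build_network(pairwise_correlations(zscore(X)))
  expect_equal(n1$edges[, c("node_a", "node_b", "sign")],
               n2$edges[, c("node_a", "node_b", "sign")])
  expect_equal(n1$edges$r, n2$edges$r, tolerance = 1e-12)
})

test_that("tissue combination preserves within-tissue structure", {
  set.seed(66)
  X <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(paste0("IL", 1:30), paste0("m", 1:6)))
  comb <- combine_tissues(X, X)
  # cross-tissue self-pairs correlate exactly 1
  for (m in paste0("m", 1:3)) {
    expect_equal(cor(comb[, paste0("seed:", m)], comb[, paste0("fruit:", m)]),
                 1)
  }
  # within-tissue correlations unchanged
  expect_equal(unname(cor(comb[, 1:6])), unname(cor(X)), tolerance = 1e-12)
  Y <- X; rownames(Y) <- paste0("XX", 1:30)
  expect_error(combine_tissues(X, Y), "shared")
})

test_that("independent tissues yield only threshold-level cross edges", {
  set.seed(67)
  n_edge_frac <- replicate(20, {
    A <- matrix(rnorm(40 * 15), 40, 15,
                dimnames = list(paste0("IL", 1:40), paste0("a", 1:15)))
    B <- matrix(rnorm(40 * 15), 40, 15,
                dimnames = list(paste0("IL", 1:40), paste0("b", 1:15)))
    comb <- combine_tissues(A, B)
    tab <- pairwise_correlations(comb)
    cross <- xor(grepl("^seed", tab$var_a), grepl("^seed", tab$var_b))
    mean(tab$p[cross] <= 0.01)
  })
  expect_lte(mean(n_edge_frac), 2 * 0.01)
})

test_that("bipartite cross-season networks link identical seasons 1:1", {
  set.seed(68)
  X <- matrix(rnorm(25 * 8), 25, 8,
              dimnames = list(paste0("IL", 1:25), paste0("m", 1:8)))
  bp <- bipartite_cross_season(X, X)
  self <- bp$edges[sub("^I:", "", bp$edges$node_a) ==
                     sub("^II:", "", bp$edges$node_b), ]
  expect_equal(nrow(self), 8L)
  expect_equal(self$r, rep(1, 8), tolerance = 1e-12)
  # only cross-season pairs are ever tested
  expect_true(all(grepl("^I:", bp$edges$node_a)))
  expect_true(all(grepl("^II:", bp$edges$node_b)))
})

test_that("a season-stable module dominates cross-season connectivity", {
  pop <- generate_population(scenario_seed_like(4))
  prof <- normalize_profiles(pop$profiles)
  m1 <- genotype_means(prof, season = "I")
  m2 <- genotype_means(prof, season = "II")
  bp <- bipartite_cross_season(m1, m2)
  sub <- c("Gly", "Ser", "Thr", "Ile", "Val", "Pro")
  in_sub_a <- sub("^I:", "", bp$edges$node_a) %in% sub
  in_sub_b <- sub("^II:", "", bp$edges$node_b) %in% sub
  sub_edges <- sum(in_sub_a & in_sub_b)
  sub_density <- sub_edges / 36
  bg_density <- (nrow(bp$edges) - sub_edges) / (64 * 64 - 36)
  expect_gte(sub_density / bg_density, 5)
})

test_that("conserved correlations require same-sign presence everywhere", {
  nodes <- paste0("m", 1:4)
  e1 <- data.frame(node_a = c("m1", "m2"), node_b = c("m2", "m3"),
                   r = c(0.8, -0.6), p = 0.001, stringsAsFactors = FALSE)
  n1 <- cor_network(nodes, e1)
  cc <- conserved_correlations(list(a = n1, b = n1))
  expect_equal(nrow(cc$conserved), 2L)
  # sign flip is not conserved
  e2 <- e1; e2$r <- c(0.8, 0.6)
  n2 <- cor_network(nodes, e2)
  expect_equal(nrow(conserved_correlations(list(n1, n2))$conserved), 1L)
  # disjoint edge sets conserve nothing
  e3 <- data.frame(node_a = "m3", node_b = "m4", r = 0.9, p = 1e-4,
                   stringsAsFactors = FALSE)
  expect_equal(nrow(conserved_correlations(
    list(n1, cor_network(nodes, e3)))$conserved), 0L)
  # synchronization drops edges touching unshared nodes
  n4 <- cor_network(paste0("m", 1:3), e1)
  n5 <- cor_network(paste0("m", 2:4), e3)
  cc2 <- conserved_correlations(list(n4, n5))
  expect_equal(sort(cc2$nodes), c("m2", "m3"))
  expect_true(all(cc2$counts$edges_after_sync <= cc2$counts$edges_total))
})

test_that("conserved edges concentrate in a shared module", {
  with_seed(69, {
    n <- 60
    lat_shared <- rnorm(n)
    lat_season <- rnorm(n)
    mk <- function(own_lat_weight) {
      X <- matrix(rnorm(n * 18, 0, 1), n, 18)
      X[, 1:6] <- X[, 1:6] * 0.5 + lat_shared        # module in both seasons
      X[, 7:12] <- X[, 7:12] + own_lat_weight * lat_season  # season I only
      colnames(X) <- paste0("m", 1:18)
      rownames(X) <- paste0("IL", 1:n)
      X
    }
    n1 <- build_network(pairwise_correlations(mk(2)))
    n2 <- build_network(pairwise_correlations(mk(0)))
    cc <- conserved_correlations(list(n1, n2))
    intra <- cc$conserved$node_a %in% paste0("m", 1:6) &
      cc$conserved$node_b %in% paste0("m", 1:6)
    expect_gte(mean(intra), 0.8)
  })
})
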