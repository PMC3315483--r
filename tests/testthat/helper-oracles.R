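# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own code paths (and igraph where the package uses it).

# --- graph measures ---------------------------------------------------------

# density / mean degree / average local clustering (triangle enumeration,
# degree<2 -> 0) / diameter (Floyd-Warshall over the largest component)
oracle_measures <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  used <- which(deg > 0)
  m <- length(used)
  e <- sum(A) / 2
  if (m < 2 || e == 0) {
    return(list(density = 0, mean_degree = 0, clustering = 0,
                diameter = NA_real_))
  }
  B <- A[used, used, drop = FALSE]
  degu <- rowSums(B)
  loc <- numeric(m)
  for (i in seq_len(m)) {
    nb <- which(B[i, ] == 1)
    if (length(nb) < 2) { loc[i] <- 0; next }
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && B[nb[a], nb[b]] == 1) links <- links + 1
    }
    loc[i] <- links / (length(nb) * (length(nb) - 1) / 2)
  }
  D <- matrix(Inf, m, m)
  diag(D) <- 0
  D[B == 1] <- 1
  for (k in seq_len(m)) for (i in seq_len(m)) for (j in seq_len(m)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  finite <- D[is.finite(D)]
  list(density = e / (m * (m - 1) / 2), mean_degree = 2 * e / m,
       clustering = mean(loc), diameter = max(finite))
}

random_adjacency <- function(n, p = 0.2) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(runif(length(up)) < p)
  A + t(A)
}

# --- ANOVA sums of squares --------------------------------------------------

oracle_oneway_F <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ni <- tapply(y, g, length)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((y - means[g])^2)
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

# balanced two-way ANOVA by cell means
oracle_twoway <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y)
  gm <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  na <- tapply(y, a, length); nb <- tapply(y, b, length)
  nab <- table(a, b)
  ss_a <- sum(na * (ma - gm)^2)
  ss_b <- sum(nb * (mb - gm)^2)
  ss_ab <- sum(nab * (mab - outer(ma - gm, mb - gm, "+") - gm)^2)
  ss_e <- sum((y - mab[cbind(a, b)])^2)
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_e <- n - nlevels(a) * nlevels(b)
  list(ms = c(a = ss_a / df_a, b = ss_b / df_b, ab = ss_ab / df_ab,
              e = ss_e / df_e),
       F = c(a = (ss_a / df_a) / (ss_e / df_e),
             b = (ss_b / df_b) / (ss_e / df_e),
             ab = (ss_ab / df_ab) / (ss_e / df_e)),
       df = c(a = df_a, b = df_b, ab = df_ab, e = df_e))
}

# --- misc -------------------------------------------------------------------

# sort-based median (independent of stats::median)
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# all set partitions of 1..n (for exhaustive modularity maximization)
oracle_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- oracle_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

oracle_modularity <- function(A, membership) {
  m <- sum(A) / 2
  deg <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A))) {
    if (membership[i] == membership[j])
      q <- q + A[i, j] - deg[i] * deg[j] / (2 * m)
  }
  q / (2 * m)
}

# --- fixtures ---------------------------------------------------------------

# a tiny hand-built profile table: 2 ILs + control, 1 season, 2 reps
tiny_profiles <- function() {
  g <- rep(c("M82", "IL1-1", "IL2-1"), each = 2)
  rep_id <- rep(1:2, 3)
  rows <- expand.grid(i = seq_along(g), metabolite = c("mA", "mB", "mC"),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = paste(g[rows$i], "I", "seed", rep_id[rows$i], sep = "_"),
    genotype = g[rows$i], season = "I", tissue = "seed",
    replicate = rep_id[rows$i], metabolite = rows$metabolite,
    response = seq(1, 2, length.out = nrow(rows)),
    stringsAsFactors = FALSE)
}

# a quick small scenario for structural tests
small_scenario <- function(seed = 1, ...) {
  cat64 <- il_metabolites("seed")
  met <- cat64[cat64$metabolite %in% c("Gly", "Ile", "Pro", "Ser", "Thr",
                                       "Val", "glucose", "fructose",
                                       "citrate", "malate"), ]
  il_scenario(n_ils = 12, metabolites = met, n_replicates = 3,
              n_planted = 4, n_submodule_ils = 2,
              submodule = list(members = c("Gly", "Ile", "Pro"), r = 0.8),
              seed = seed, ...)
}
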