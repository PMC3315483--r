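test_that("one-way screen matches the sum-of-squares oracle", {
  set.seed(31)
  tab <- data.frame(
    sample_id = paste0("s", 1:12), genotype = rep(c("M82", "IL1", "IL2"), 4),
    season = "I", tissue = "seed", replicate = rep(1:4, each = 3),
    metabolite = "m1", response = rlnorm(12), stringsAsFactors = FALSE)
  scr <- anova_screen(tab)
  oracle <- oracle_oneway_F(log10(tab$response), tab$genotype)
  expect_equal(scr$p_anova, oracle$p, tolerance = 1e-10)
})

test_that("one extreme group produces a tiny screen p-value", {
  set.seed(32)
  y <- c(rnorm(10), rnorm(5, 10))
  tab <- data.frame(sample_id = paste0("s", 1:15),
                    genotype = rep(c("M82", "IL1", "IL2"), each = 5),
                    season = "I", tissue = "seed",
                    replicate = rep(1:5, 3), metabolite = "m1",
                    response = 10^y, stringsAsFactors = FALSE)
  expect_lt(anova_screen(tab)$p_anova, 1e-6)
})

test_that("screen p-values are uniform under the null", {
  sc <- il_scenario(n_ils = 15,
                    metabolites = data.frame(metabolite = paste0("m", 1:120),
                                             compound_class = "x"),
                    n_replicates = 3, seasons = "I", submodule = NULL,
                    seed = 33)
  scr <- anova_screen(null_population(sc))
  ks <- suppressWarnings(stats::ks.test(scr$p_anova, "punif"))
  expect_lt(unname(ks$statistic), 0.12)
})

test_that("Dunnett handles degenerate and well-separated inputs", {
  # identical constants: adjusted p = 1 everywhere
  res <- dunnett_test(rep(5, 12), rep(c("M82", "A", "B"), each = 4))
  expect_equal(res$p_adj, rep(1, 2))
  # zero variance with unequal means is a guarded error
  expect_error(dunnett_test(rep(c(1, 2, 1), each = 4),
                            rep(c("M82", "A", "B"), each = 4)),
               "zero pooled variance")
  # one shifted group stands out, the rest stay null
  set.seed(34)
  y <- c(rnorm(5), rnorm(5, 10), rnorm(5), rnorm(5))
  res <- dunnett_test(y, rep(c("M82", "A", "B", "C"), each = 5))
  expect_lt(res$p_adj[res$genotype == "A"], 0.001)
  expect_true(all(res$p_adj[res$genotype != "A"] > 0.5))
  expect_true(all(res$p_adj >= res$p_raw))
})

test_that("Dunnett adjusted p matches a 1e6-draw max-|t| oracle", {
  set.seed(35)
  y <- rnorm(20, rep(c(0, 0.8, -0.4, 0.2), each = 5))
  g <- rep(c("M82", "A", "B", "C"), each = 5)
  res <- dunnett_test(y, g)
  B <- 1e6
  oracle <- with_seed(36, {
    Z0 <- rnorm(B)
    Zi <- matrix(rnorm(3 * B), B, 3)
    S <- sqrt(stats::rchisq(B, 16) / 16)
    mx <- apply(abs(sqrt(0.5) * Z0 + sqrt(0.5) * Zi) / S, 1, max)
    vapply(abs(res$t), function(cc) mean(mx >= cc), 0)
  })
  expect_equal(res$p_adj, oracle, tolerance = 0.005)
})

test_that("unbalanced Dunnett agrees with multcomp", {
  set.seed(37)
  g <- factor(rep(c("M82", "A", "B", "C"), times = c(8, 5, 6, 4)),
              levels = c("M82", "A", "B", "C"))
  y <- rnorm(length(g), as.numeric(g == "B"))
  res <- dunnett_test(y, as.character(g))
  fit <- stats::aov(y ~ g)
  mc <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(res$p_adj[match(c("A", "B", "C"), res$genotype)],
               as.vector(mc$test$pvalues), tolerance = 2e-3)
})

test_that("mQTL calling respects the Bonferroni boundary inclusively", {
  tab <- data.frame(metabolite = c("m1", "m2", "m3"),
                    genotype = "IL1", n = 6,
                    estimate = c(0.3, 0.3, -0.3), t = 5,
                    p_raw = c(1e-4, 1.1e-3, 1e-4),
                    p_adj = c(0.05 / 50, 0.05 / 50 + 1e-9, 0.002),
                    stringsAsFactors = FALSE)
  calls <- call_mqtl(tab, alpha = 0.05, n_tests = 50)
  expect_equal(attr(calls, "critical_value"), 0.001)
  expect_true(calls$significant[calls$metabolite == "m1"])    # p == alpha/n
  expect_false(calls$significant[calls$metabolite == "m2"])   # just above
  expect_equal(calls$direction[calls$metabolite == "m3"], "decrease")
  # significant calls are a subset of the permissive tier
  expect_true(all(calls$metabolite[calls$significant] %in% calls$metabolite))
  expect_error(call_mqtl(tab, alpha = 1.2), "alpha")
})

test_that("cross-season sharing intersects on IL, metabolite and direction", {
  a <- data.frame(il_id = c("IL1", "IL2", "IL3"),
                  metabolite = c("m1", "m2", "m3"),
                  direction = c("increase", "decrease", "increase"),
                  significant = TRUE, stringsAsFactors = FALSE)
  b <- a
  shared <- conserved_across_seasons(list(I = a, II = b))
  expect_equal(nrow(shared), 3L)
  expect_equal(unique(shared$seasons_supporting), "I;II")
  b2 <- a
  b2$il_id <- c("IL4", "IL5", "IL6")
  expect_equal(nrow(conserved_across_seasons(list(I = a, II = b2))), 0L)
  # direction flip breaks sharing
  b3 <- a
  b3$direction <- c("decrease", "decrease", "increase")
  expect_equal(nrow(conserved_across_seasons(list(I = a, II = b3))), 2L)
})

test_that("shared calls from two seasons of planted effects mostly persist", {
  sc <- scenario_mqtl_recovery(38, n_planted = 12)
  prof <- normalize_profiles(generate_population(sc)$profiles)
  calls <- lapply(c("I", "II"), function(s) {
    scr <- anova_screen(prof, season = s)
    call_mqtl(dunnett_screen(prof, scr, season = s))
  })
  names(calls) <- c("I", "II")
  season1 <- calls$I[calls$I$significant, ]
  shared <- conserved_across_seasons(calls)
  expect_gte(nrow(shared) / max(nrow(season1), 1), 0.9)
})

test_that("two-way confirmation separates main effects from interactions", {
  mk <- function(gen_eff, int_eff, seed) {
    with_seed(seed, {
      d <- expand.grid(genotype = c("M82", "IL1"), season = c("I", "II"),
                       replicate = 1:5, stringsAsFactors = FALSE)
      mu <- gen_eff * (d$genotype == "IL1") +
        int_eff * (d$genotype == "IL1") * ifelse(d$season == "I", 1, -1)
      d$sample_id <- paste(d$genotype, d$season, d$replicate, sep = "_")
      d$tissue <- "seed"
      d$metabolite <- "m1"
      d$response <- 10^(mu + rnorm(nrow(d), 0, 0.25))
      d
    })
  }
  shared <- data.frame(il_id = "IL1", metabolite = "m1",
                       direction = "increase", seasons_supporting = "I;II",
                       stringsAsFactors = FALSE)
  n_gen <- 0; n_int_when_gen <- 0; n_int <- 0
  for (s in 1:40) {
    cg <- confirm_two_way(mk(0.8, 0, s), shared)
    n_gen <- n_gen + cg$confirmed_genotype
    n_int_when_gen <- n_int_when_gen + cg$confirmed_interaction
    ci <- confirm_two_way(mk(0, 0.8, s + 1000), shared)
    n_int <- n_int + ci$confirmed_interaction
  }
  expect_gte(n_gen / 40, 0.9)          # planted main effect found
  expect_lte(n_int_when_gen / 40, 0.2) # no spurious interaction
  expect_gte(n_int / 40, 0.9)          # opposite-sign season pattern found
})

test_that("two-way mean squares match the cell-mean oracle", {
  set.seed(39)
  d <- expand.grid(genotype = c("M82", "IL1"), season = c("I", "II"),
                   replicate = 1:4, stringsAsFactors = FALSE)
  d$sample_id <- paste(d$genotype, d$season, d$replicate, sep = "_")
  d$tissue <- "seed"; d$metabolite <- "m1"
  d$response <- rlnorm(nrow(d))
  shared <- data.frame(il_id = "IL1", metabolite = "m1",
                       direction = "increase", seasons_supporting = "I;II",
                       stringsAsFactors = FALSE)
  conf <- confirm_two_way(d, shared)
  o <- oracle_twoway(log10(d$response), d$genotype, d$season)
  expect_equal(conf$p_genotype,
               pf(o$F[["a"]], o$df[["a"]], o$df[["e"]], lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(conf$p_interaction,
               pf(o$F[["ab"]], o$df[["ab"]], o$df[["e"]], lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("overlapping same-call segments merge into refined loci", {
  map <- data.frame(il_id = c("IL1", "IL2", "IL3"),
                    chromosome = c("chr1", "chr1", "chr2"),
                    start = c(10, 30, 5), end = c(40, 60, 25),
                    stringsAsFactors = FALSE)
  calls <- data.frame(il_id = c("IL1", "IL2", "IL3"), metabolite = "m1",
                      direction = "increase", stringsAsFactors = FALSE)
  res <- map_to_segments(calls, map)
  expect_equal(nrow(res$loci), 2L)
  ovl <- res$loci[res$loci$n_ils == 2, ]
  expect_equal(c(ovl$refined_start, ovl$refined_end), c(30, 40))
  # same metabolite, opposite direction: never merged
  calls2 <- calls
  calls2$direction <- c("increase", "decrease", "increase")
  expect_equal(nrow(map_to_segments(calls2, map)$loci), 3L)
  # unmapped IL retained with empty localization
  calls3 <- rbind(calls, data.frame(il_id = "IL9", metabolite = "m1",
                                    direction = "increase"))
  expect_warning(res3 <- map_to_segments(calls3, map), "IL9")
  expect_true(is.na(res3$calls$chromosome[res3$calls$il_id == "IL9"]))
})

test_that("locus counts match a transitive-closure interval oracle", {
  for (s in 41:45) {
    set.seed(s)
    n <- 10
    map <- data.frame(il_id = paste0("IL", 1:n),
                      chromosome = sample(c("chr1", "chr2"), n, TRUE),
                      start = runif(n, 0, 80), stringsAsFactors = FALSE)
    map$end <- map$start + runif(n, 1, 30)
    calls <- data.frame(il_id = map$il_id, metabolite = "m1",
                        direction = "increase", stringsAsFactors = FALSE)
    res <- map_to_segments(calls, map)
    # brute-force connected components by repeated merging
    groups <- as.list(seq_len(n))
    overlap <- function(i, j) map$chromosome[i] == map$chromosome[j] &&
      min(map$end[i], map$end[j]) - max(map$start[i], map$start[j]) > 0
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (a in seq_along(groups)) for (b in seq_along(groups)) {
        if (a < b && length(groups[[a]]) && length(groups[[b]]) &&
            any(outer(groups[[a]], groups[[b]],
                      Vectorize(overlap)))) {
          groups[[a]] <- c(groups[[a]], groups[[b]])
          groups[[b]] <- integer()
          changed <- TRUE
        }
      }
    }
    n_loci <- sum(lengths(groups) > 0)
    expect_equal(nrow(res$loci), n_loci)
  }
})

test_that("recovery rate is monotone in effect size", {
  rates <- vapply(c(0.05, log10(2), 0.6), function(delta) {
    ids <- paste0("IL", 1:10)
    planted <- data.frame(il_id = ids[1:5],
                          metabolite = paste0("m", 1:5),
                          season = "all", delta = delta,
                          stringsAsFactors = FALSE)
    sc <- il_scenario(n_ils = 10,
                      metabolites = data.frame(
                        metabolite = paste0("m", 1:8), compound_class = "x"),
                      n_replicates = 5, seasons = "I",
                      planted_effects = planted, genotype_sd = 0,
                      interaction_sd = 0, submodule = NULL,
                      class_cor = c(x = 0), seed = 46)
    sc$il_ids <- ids
    prof <- normalize_profiles(generate_population(sc)$profiles)
    calls <- call_mqtl(dunnett_screen(prof), n_tests = 8)
    hits <- paste(calls$il_id[calls$significant],
                  calls$metabolite[calls$significant])
    mean(paste(planted$il_id, planted$metabolite) %in% hits)
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.8)
})
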