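# Synthetic introgression-line populations.
#
# The generator draws log10 responses as
#   baseline + planted genotype effect + season shift
#   + season-stable polygenic genotype effect (sd genotype_sd)
#   + N(0, interaction_sd) genotype-x-season wobble
#   + correlated residual
# and exponentiates to the positive relative-response scale.  The polygenic
# component, the interaction wobble and the replicate residual all share the
# same block correlation matrix (covariance by compound class), so
# population-level (IL-mean) correlations converge to the block targets
# irrespective of replicate number, while the planted effects stay sparse
# and independent -- except for the amino-acid submodule, which receives
# coordinated planting on a few ILs, the mechanism that produces its
# exceptionally high pairwise correlations.

#' Evaluate an expression under a fixed seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded simulations do not disturb the surrounding
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Metabolite catalogs for synthetic populations
#'
#' Compound-class-annotated metabolite lists sized like the two tissues of a
#' field-grown tomato IL study: 64 seed metabolites (2016 unordered pairs) and
#' 86 fruit metabolites (3655 pairs).  The seed catalog contains the
#' six-member amino-acid submodule (Gly, Ser, Thr, Ile, Val, Pro) that the
#' generator can wire to an elevated correlation target.
#'
#' @param tissue `"seed"` or `"fruit"`.
#' @return A `data.frame` with columns `metabolite` and `compound_class`.
#' @export
il_metabolites <- function(tissue = c("seed", "fruit")) {
  tissue <- match.arg(tissue)
  amino <- c("Ala", "Arg", "Asn", "Asp", "beta-Ala", "GABA", "Gln", "Glu",
             "Gly", "Ile", "Lys", "Met", "ornithine", "Phe", "Pro", "Ser",
             "Thr", "Tyr", "Val")
  sugars <- c("glucose", "fructose", "sucrose", "raffinose", "maltotriose",
              "isomaltose", "melezitose", "trehalose", "maltose", "xylose",
              "ribose", "fucose", "rhamnose", "galactose")
  organic <- c("citrate", "malate", "fumarate", "succinate", "glycolate",
               "glycerate", "pyruvate", "benzoate", "4-OH-benzoate",
               "salicylate", "nicotinate", "threonate")
  polyols <- c("glycerol", "erythritol", "sorbitol", "inositol", "mannitol",
               "xylitol", "arabitol", "maltitol")
  ncomp <- c("urea", "putrescine", "tyramine", "adenine", "uracil",
             "spermidine")
  fatty <- c("nonanoate", "octadecanoate", "hexadecenoate")
  phos <- c("glycerol-3-phosphate", "phosphorate")
  cat_seed <- data.frame(
    metabolite = c(amino, sugars, organic, polyols, ncomp, fatty, phos),
    compound_class = rep(c("amino acids", "sugars", "organic acids",
                           "polyols", "N compounds", "fatty acids",
                           "phosphates"),
                         c(length(amino), length(sugars), length(organic),
                           length(polyols), length(ncomp), length(fatty),
                           length(phos))),
    stringsAsFactors = FALSE)
  if (tissue == "seed") return(cat_seed)
  extra <- data.frame(
    metabolite = c(paste0("sugar-like-", 1:8), paste0("acid-like-", 1:6),
                   paste0("polyol-like-", 1:4), paste0("amine-like-", 1:4)),
    compound_class = rep(c("sugars", "organic acids", "polyols",
                           "N compounds"), c(8, 6, 4, 4)),
    stringsAsFactors = FALSE)
  rbind(cat_seed, extra)
}

#' Synthetic IL segment maps
#'
#' Tiles ILs across chromosomes as contiguous, mutually overlapping
#' centimorgan intervals, emulating a population in which adjacent lines share
#' part of their introgressed segment (the situation mQTL localization must
#' resolve).
#'
#' @param il_ids Character vector of IL identifiers.
#' @param n_chromosomes Number of chromosomes to tile (default 12).
#' @param chrom_length Chromosome length in cM (default 100).
#' @param overlap Half-width, in cM, by which adjacent segments extend into
#'   one another (default 4).
#' @return A validated segment-map `data.frame`.
#' @export
synthetic_segment_map <- function(il_ids, n_chromosomes = 12,
                                  chrom_length = 100, overlap = 4) {
  n <- length(il_ids)
  per <- rep(n %/% n_chromosomes, n_chromosomes)
  extra <- n %% n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  rows <- vector("list", n_chromosomes)
  idx <- 0L
  for (ch in seq_len(n_chromosomes)) {
    m <- per[ch]
    if (m == 0L) next
    step <- chrom_length / m
    i <- seq_len(m)
    rows[[ch]] <- data.frame(
      il_id = il_ids[idx + i],
      chromosome = paste0("chr", ch),
      start = pmax(0, (i - 1) * step - overlap),
      end = pmin(chrom_length, i * step + overlap),
      stringsAsFactors = FALSE)
    idx <- idx + m
  }
  validate_segment_map(do.call(rbind, rows))
}

#' Define a synthetic IL population scenario
#'
#' A scenario bundles everything that determines a synthetic dataset: the
#' metabolite catalog, population size, replication, seasons, the
#' block-structured correlation targets (per compound class, plus an optional
#' high-correlation submodule), planted IL-specific fold-change effects,
#' season and genotype-x-season effect scales, the residual scale, the
#' morphological-trait loading scheme, and the seed.  A dataset is a pure
#' function of (scenario, seed).
#'
#' Defaults emulate the seed tissue of a two-season tomato IL field study:
#' 76 ILs plus the M82 control, 64 metabolites, 6 replicates, within-class
#' correlation targets around 0.4-0.5 with a six-amino-acid submodule at
#' r = 0.87, sparse planted effects with fold changes spanning 0.25x-8x, and
#' a residual SD of 0.08 log10 units (about 20% CV, typical GC-MS replicate
#' scatter).
#'
#' @param n_ils Number of introgression lines (control added on top).
#' @param metabolites Catalog `data.frame` (`metabolite`, `compound_class`).
#' @param n_replicates Replicates per genotype x season.
#' @param seasons Season labels.
#' @param tissue Tissue label stored with the records.
#' @param control_id Control genotype name.
#' @param baseline Per-metabolite baseline log10 abundance (recycled).
#' @param class_cor Named vector of within-class correlation targets; classes
#'   not named fall back to `default_class_cor`.
#' @param default_class_cor Fallback within-class target.
#' @param between_cor Between-class correlation target (single number), or a
#'   symmetric class x class matrix for per-pair control.
#' @param submodule `list(members =, r =)` overriding the pairwise target
#'   inside one tightly co-regulated group, or `NULL`.
#' @param planted_effects `data.frame(il_id, metabolite, season, delta)` of
#'   log10 genotype effects (`season = "all"` applies to every season), or
#'   `NULL` to draw `n_planted` effects from `fold_range` under `seed`.
#' @param n_planted Number of planted (IL, metabolite) effects drawn when
#'   `planted_effects` is `NULL`.
#' @param fold_range Fold-change range for drawn effects (log-uniform).
#' @param n_submodule_ils Number of ILs receiving a coordinated planted
#'   effect on every submodule member (shared fold change per IL, emulating
#'   co-localization of the group onto the same QTL); drawn only when
#'   `planted_effects` is `NULL`.
#' @param submodule_fold_range Fold-change range for coordinated submodule
#'   effects.
#' @param season_sd SD of per-metabolite season shifts (log10); sugars get
#'   `sugar_season_sd` to emulate their stronger seasonal swing.
#' @param sugar_season_sd Season-shift SD for the sugar class.
#' @param genotype_sd SD of the season-stable polygenic genotype effect
#'   (log10), correlated across metabolites via the class covariance; the
#'   control genotype sits at 0.
#' @param interaction_sd SD of genotype-x-season effects (log10).
#' @param residual_sd Replicate residual SD (log10).
#' @param n_traits Number of morphological traits to generate.
#' @param trait_neg_fraction Fraction of traits loading negatively on the
#'   amino-acid latent factor (the predominantly negative trait-metabolite
#'   association structure).
#' @param trait_noise_sd SD of trait-specific noise relative to a unit-SD
#'   latent factor.
#' @param seed Integer seed; all drawn scenario components and the dataset
#'   derive from it.
#' @return An object of class `il_scenario`.
#' @export
il_scenario <- function(n_ils = 76,
                        metabolites = il_metabolites("seed"),
                        n_replicates = 6,
                        seasons = c("I", "II"),
                        tissue = "seed",
                        control_id = "M82",
                        baseline = NULL,
                        class_cor = c("amino acids" = 0.5),
                        default_class_cor = 0.45,
                        between_cor = 0.2,
                        submodule = list(
                          members = c("Gly", "Ser", "Thr", "Ile", "Val", "Pro"),
                          r = 0.87),
                        planted_effects = NULL,
                        n_planted = 40,
                        fold_range = c(0.25, 8),
                        n_submodule_ils = 5,
                        submodule_fold_range = c(1.5, 3),
                        season_sd = 0.1,
                        sugar_season_sd = 0.25,
                        genotype_sd = 0.2,
                        interaction_sd = 0.05,
                        residual_sd = 0.08,
                        n_traits = 35,
                        trait_neg_fraction = 0.7,
                        trait_noise_sd = 0.7,
                        seed = 1) {
  stopifnot(n_ils >= 1, n_replicates >= 2, length(seasons) >= 1,
            residual_sd > 0, nrow(metabolites) >= 2)
  n_met <- nrow(metabolites)
  if (is.null(baseline)) baseline <- seq(1.2, 3.2, length.out = n_met)
  baseline <- rep_len(baseline, n_met)
  il_ids <- .make_il_ids(n_ils)
  if (!is.null(submodule)) {
    missing_m <- setdiff(submodule$members, metabolites$metabolite)
    if (length(missing_m) > 0L) submodule <- NULL
  }
  sc <- structure(list(
    n_ils = n_ils, il_ids = il_ids, metabolites = metabolites,
    n_replicates = n_replicates, seasons = seasons, tissue = tissue,
    control_id = control_id, baseline = baseline,
    class_cor = class_cor, default_class_cor = default_class_cor,
    between_cor = between_cor, submodule = submodule,
    planted_effects = planted_effects,
    season_sd = season_sd, sugar_season_sd = sugar_season_sd,
    genotype_sd = genotype_sd,
    interaction_sd = interaction_sd, residual_sd = residual_sd,
    n_traits = n_traits, trait_neg_fraction = trait_neg_fraction,
    trait_noise_sd = trait_noise_sd, seed = as.integer(seed)),
    class = "il_scenario")
  if (is.null(planted_effects)) {
    sc$planted_effects <- with_seed(sc$seed + 101L, {
      pairs <- data.frame(
        il_id = sample(il_ids, n_planted, replace = TRUE),
        metabolite = sample(metabolites$metabolite, n_planted, replace = TRUE),
        stringsAsFactors = FALSE)
      pairs <- unique(pairs)
      pairs$season <- "all"
      pairs$delta <- runif(nrow(pairs), log10(fold_range[1]),
                           log10(fold_range[2]))
      if (!is.null(submodule) && n_submodule_ils > 0) {
        # co-localized QTL for the submodule group: one shared fold change
        # per chosen IL, applied to every member with small jitter
        sub_ils <- sample(il_ids, n_submodule_ils)
        shared <- runif(n_submodule_ils, log10(submodule_fold_range[1]),
                        log10(submodule_fold_range[2]))
        k <- length(submodule$members)
        co <- data.frame(
          il_id = rep(sub_ils, each = k),
          metabolite = rep(submodule$members, times = n_submodule_ils),
          season = "all",
          delta = rep(shared, each = k) +
            rnorm(n_submodule_ils * k, 0, 0.03),
          stringsAsFactors = FALSE)
        pairs <- rbind(pairs, co)
        pairs <- pairs[!duplicated(pairs[, c("il_id", "metabolite")]), ]
      }
      pairs
    })
  } else {
    stopifnot(all(c("il_id", "metabolite", "season", "delta") %in%
                    names(planted_effects)))
  }
  sc
}

.make_il_ids <- function(n, n_chromosomes = 12) {
  per <- rep(n %/% n_chromosomes, n_chromosomes)
  extra <- n %% n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  unlist(lapply(seq_len(n_chromosomes), function(ch)
    if (per[ch] > 0) paste0("IL", ch, "-", seq_len(per[ch])) else character()))
}

#' @export
print.il_scenario <- function(x, ...) {
  cat(sprintf(
    "il_scenario: %d ILs + %s, %d metabolites (%s), %d reps x seasons {%s}, %d planted effects, seed %d\n",
    x$n_ils, x$control_id, nrow(x$metabolites), x$tissue, x$n_replicates,
    paste(x$seasons, collapse = ","), nrow(x$planted_effects), x$seed))
  invisible(x)
}

#' Block correlation matrix of a scenario
#'
#' Builds the metabolite correlation matrix implied by the scenario's
#' class-level targets: within-class off-diagonals equal the class target,
#' between-class entries the between-class target, and submodule pairs the
#' submodule target.  The result is checked for positive semi-definiteness;
#' a mildly indefinite matrix is repaired by eigenvalue clipping (with a
#' message), while an infeasible within-class target (below `-1/(m-1)` for an
#' m-member class) is an error naming the block.
#'
#' @param scenario An [il_scenario()].
#' @param repair_tol Eigenvalues above `-repair_tol` count as numerical noise
#'   and are silently clipped; more negative ones trigger the logged repair.
#' @return A symmetric PSD correlation matrix with metabolite dimnames.
#' @export
build_class_covariance <- function(scenario, repair_tol = 1e-8) {
  met <- scenario$metabolites
  n <- nrow(met)
  classes <- unique(met$compound_class)
  target <- function(cl) {
    if (cl %in% names(scenario$class_cor)) scenario$class_cor[[cl]]
    else scenario$default_class_cor
  }
  # feasibility per block
  for (cl in classes) {
    m <- sum(met$compound_class == cl)
    if (m >= 2 && target(cl) < -1 / (m - 1))
      .fail(sprintf("infeasible correlation target %.3f for class '%s' (m=%d)",
                    target(cl), cl, m))
  }
  bc <- scenario$between_cor
  if (is.matrix(bc)) {
    if (!all(classes %in% rownames(bc)) || !all(classes %in% colnames(bc)))
      .fail("between_cor matrix must cover all compound classes")
  }
  R <- matrix(0, n, n, dimnames = list(met$metabolite, met$metabolite))
  for (i in seq_len(n)) {
    ci <- met$compound_class[i]
    for (j in seq_len(n)) {
      cj <- met$compound_class[j]
      R[i, j] <- if (ci == cj) target(ci)
      else if (is.matrix(bc)) bc[ci, cj] else bc
    }
  }
  if (!is.null(scenario$submodule)) {
    sub <- scenario$submodule$members
    R[sub, sub] <- scenario$submodule$r
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -repair_tol) {
    message(sprintf(
      "correlation spec indefinite (min eigenvalue %.3g); repaired by eigenvalue clipping",
      min(ev$values)))
  }
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 0)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    dimnames(R) <- list(met$metabolite, met$metabolite)
  }
  (R + t(R)) / 2
}

# delta matrix (genotype x metabolite) for one season
.delta_matrix <- function(scenario, season, genotypes) {
  met <- scenario$metabolites$metabolite
  D <- matrix(0, length(genotypes), length(met),
              dimnames = list(genotypes, met))
  pe <- scenario$planted_effects
  pe <- pe[pe$season == "all" | pe$season == season, , drop = FALSE]
  for (i in seq_len(nrow(pe))) {
    if (pe$il_id[i] %in% genotypes)
      D[pe$il_id[i], pe$metabolite[i]] <- D[pe$il_id[i], pe$metabolite[i]] +
        pe$delta[i]
  }
  D
}

#' Generate a synthetic IL population
#'
#' Draws a full replicate-level dataset under the scenario's model (see
#' [il_scenario()]), together with the segment map, a morphological trait
#' matrix, and the effect truth table against which recovery of planted mQTL
#' can be scored.  Traits are linear combinations of the population's
#' amino-acid latent factor (the per-genotype mean of standardized amino-acid
#' levels) with predominantly negative loadings, plus trait-specific noise.
#'
#' @param scenario An [il_scenario()].
#' @param seed Seed override; defaults to `scenario$seed`.
#' @return A list of class `il_population` with components `profiles`
#'   (validated long-form table), `segment_map`, `traits` (genotype x trait
#'   matrix), and `effects` (truth table: `il_id`, `metabolite`, `season`,
#'   `delta`, `fold`).
#' @export
generate_population <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "il_scenario"))
  R <- build_class_covariance(scenario)
  gen <- with_seed(seed, .draw_population(scenario, R))
  gen
}

.draw_population <- function(scenario, R) {
  met <- scenario$metabolites$metabolite
  n_met <- length(met)
  genotypes <- c(scenario$control_id, scenario$il_ids)
  n_gen <- length(genotypes)
  seasons <- scenario$seasons
  n_rep <- scenario$n_replicates

  # season shifts: first season is the reference level
  is_sugar <- scenario$metabolites$compound_class == "sugars"
  ssd <- ifelse(is_sugar, scenario$sugar_season_sd, scenario$season_sd)
  season_shift <- matrix(0, length(seasons), n_met,
                         dimnames = list(seasons, met))
  if (length(seasons) > 1) {
    for (s in 2:length(seasons))
      season_shift[s, ] <- rnorm(n_met, 0, ssd)
  }

  L <- chol(R + diag(1e-10, n_met))
  # season-stable polygenic genotype effects (control at 0), correlated like
  # the residual so IL-mean correlations converge to the block targets
  U <- (matrix(rnorm(n_gen * n_met), n_gen, n_met) %*% L) *
    scenario$genotype_sd
  U[1, ] <- 0
  rows <- vector("list", length(seasons))
  for (si in seq_along(seasons)) {
    s <- seasons[si]
    D <- .delta_matrix(scenario, s, genotypes)      # planted effects
    GS <- (matrix(rnorm(n_gen * n_met), n_gen, n_met) %*% L) *
      scenario$interaction_sd
    mu <- sweep(U + D + GS, 2, scenario$baseline + season_shift[si, ], "+")
    Z <- matrix(rnorm(n_gen * n_rep * n_met), n_gen * n_rep, n_met)
    E <- (Z %*% L) * scenario$residual_sd
    gi <- rep(seq_len(n_gen), each = n_rep)
    logy <- mu[gi, , drop = FALSE] + E
    rep_id <- rep(seq_len(n_rep), times = n_gen)
    sample_id <- paste(genotypes[gi], s, scenario$tissue, rep_id, sep = "_")
    rows[[si]] <- data.frame(
      sample_id = rep(sample_id, times = n_met),
      genotype = rep(genotypes[gi], times = n_met),
      season = s,
      tissue = scenario$tissue,
      replicate = rep(rep_id, times = n_met),
      metabolite = rep(met, each = n_gen * n_rep),
      response = 10^as.vector(logy),
      stringsAsFactors = FALSE)
  }
  profiles <- do.call(rbind, rows)
  rownames(profiles) <- NULL

  segment_map <- synthetic_segment_map(scenario$il_ids)

  # traits from the amino-acid latent factor of genotype means
  M <- genotype_means(profiles, log10 = TRUE)
  amino <- intersect(
    scenario$metabolites$metabolite[
      scenario$metabolites$compound_class == "amino acids"], colnames(M))
  factor_vals <- if (length(amino) >= 2) {
    f <- rowMeans(scale(M[, amino, drop = FALSE]))
    as.vector(scale(f))
  } else rnorm(nrow(M))
  n_tr <- scenario$n_traits
  n_neg <- round(scenario$trait_neg_fraction * n_tr)
  loading <- runif(n_tr, 0.3, 0.9) *
    sample(rep(c(-1, 1), c(n_neg, n_tr - n_neg)))
  trait_names <- c("harvest_index", "plant_weight", "fruit_weight",
                   "total_yield", "brix", "seed_weight_per_fruit",
                   "seed_number_per_fruit",
                   sprintf("trait_%02d", seq_len(max(0, n_tr - 7)) + 7))
  trait_names <- trait_names[seq_len(n_tr)]
  traits <- sapply(seq_len(n_tr), function(t)
    loading[t] * factor_vals + rnorm(length(factor_vals),
                                     0, scenario$trait_noise_sd))
  dimnames(traits) <- list(rownames(M), trait_names)

  effects <- scenario$planted_effects
  effects$fold <- 10^effects$delta
  structure(list(profiles = validate_profiles(profiles,
                                              scenario$control_id),
                 segment_map = segment_map, traits = traits,
                 effects = effects),
            class = "il_population")
}

#' @export
print.il_population <- function(x, ...) {
  cat(sprintf(
    "il_population: %d records, %d genotypes, %d metabolites, %d planted effects\n",
    nrow(x$profiles), length(unique(x$profiles$genotype)),
    length(unique(x$profiles$metabolite)), nrow(x$effects)))
  invisible(x)
}

#' Null population (no structure)
#'
#' The scenario with every genotype effect removed, season shifts zeroed, and
#' a diagonal covariance: per-metabolite ANOVA p-values are Uniform(0,1) and
#' pairwise correlations fluctuate around zero.  Used for calibration tests.
#'
#' @inheritParams generate_population
#' @return A validated profile `data.frame`.
#' @export
null_population <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "il_scenario"))
  sc <- scenario
  sc$planted_effects <- sc$planted_effects[0, , drop = FALSE]
  sc$season_sd <- 0
  sc$sugar_season_sd <- 0
  sc$genotype_sd <- 0
  sc$interaction_sd <- 0
  sc$class_cor <- c()
  sc$default_class_cor <- 0
  sc$between_cor <- 0
  sc$submodule <- NULL
  gen <- generate_population(sc, seed = seed)
  gen$profiles
}

#' Canonical study scenarios
#'
#' `scenario_seed_like()` is the default two-season, 64-metabolite seed
#' scenario with its dense block covariance.  `scenario_fruit_like()` is the
#' three-season, 86-metabolite counterpart with weaker correlation targets
#' (within-class 0.45 without a submodule, between-class 0.05), emulating the
#' sparser fruit-pericarp network.  `scenario_mqtl_recovery()` plants exactly
#' `n_planted` twofold increases on distinct (IL, metabolite) pairs and turns
#' off genotype-x-season wobble so the truth table is the only genotype
#' signal, the setting in which caller sensitivity and false-positive rate
#' are scored.
#'
#' @param seed Integer seed.
#' @param n_planted Number of planted twofold effects (recovery scenario).
#' @return An [il_scenario()].
#' @export
scenario_seed_like <- function(seed = 1) il_scenario(seed = seed)

#' @rdname scenario_seed_like
#' @export
scenario_fruit_like <- function(seed = 1) {
  il_scenario(metabolites = il_metabolites("fruit"),
              seasons = c("I", "III", "IV"),
              tissue = "fruit",
              class_cor = c(),
              default_class_cor = 0.45,
              between_cor = 0.05,
              submodule = NULL,
              seed = seed)
}

#' @rdname scenario_seed_like
#' @export
scenario_mqtl_recovery <- function(seed = 1, n_planted = 20) {
  ids <- .make_il_ids(76)
  met <- il_metabolites("seed")
  planted <- with_seed(seed + 202L, {
    ii <- sample(length(ids), n_planted, replace = FALSE)
    mm <- sample(nrow(met), n_planted, replace = FALSE)
    data.frame(il_id = ids[ii], metabolite = met$metabolite[mm],
               season = "all", delta = log10(2), stringsAsFactors = FALSE)
  })
  il_scenario(planted_effects = planted, genotype_sd = 0, interaction_sd = 0,
              seed = seed)
}

#' Simulate a variance-components dataset for heritability recovery
#'
#' Draws log10 values under the heritability model
#' `y = M + S + R(S) + G + GS + e` with independent normal components, for a
#' single metabolite, and returns them as a profile table (responses
#' exponentiated).  Used to check that the mean-squares estimator recovers a
#' known broad-sense heritability.
#'
#' @param n_genotypes Number of genotype levels (ILs plus control).
#' @param s Number of seasons.
#' @param r Replicates per genotype x season.
#' @param sigma2_g,sigma2_gs,sigma2_e Genotype, genotype-x-season and residual
#'   variance components (log10 scale).
#' @param sigma2_rs Replicate-within-season variance component (default 0).
#' @param grand_mean Grand mean on the log10 scale.
#' @param seed Integer seed.
#' @return A profile `data.frame` (tissue `"sim"`, metabolite `"m1"`), with
#'   attribute `"realized"`: the sample variances of the component draws
#'   actually used (`var_g`, `var_gs`, `var_e`) and the implied entry-mean
#'   heritability `h2` of the simulated population,
#'   `var_g / (var_g + var_gs/s + var_e/(r s))`.
#' @export
simulate_h2_data <- function(n_genotypes = 77, s = 2, r = 3,
                             sigma2_g = 1, sigma2_gs = 0.5, sigma2_e = 1,
                             sigma2_rs = 0, grand_mean = 2, seed = 1) {
  with_seed(seed, {
    genotypes <- c("M82", .make_il_ids(n_genotypes - 1))
    seasons <- as.roman(seq_len(s))
    G <- rnorm(n_genotypes, 0, sqrt(sigma2_g))
    S <- rnorm(s, 0, 0.1)
    out <- vector("list", s)
    gs_draws <- numeric(0)
    e_draws <- numeric(0)
    for (si in seq_len(s)) {
      GS <- rnorm(n_genotypes, 0, sqrt(sigma2_gs))
      RS <- rnorm(r, 0, sqrt(sigma2_rs))
      gi <- rep(seq_len(n_genotypes), each = r)
      ri <- rep(seq_len(r), times = n_genotypes)
      eps <- rnorm(n_genotypes * r, 0, sqrt(sigma2_e))
      y <- grand_mean + S[si] + RS[ri] + G[gi] + GS[gi] + eps
      gs_draws <- c(gs_draws, GS)
      e_draws <- c(e_draws, eps)
      out[[si]] <- data.frame(
        sample_id = paste(genotypes[gi], seasons[si], "sim", ri, sep = "_"),
        genotype = genotypes[gi], season = as.character(seasons[si]),
        tissue = "sim", replicate = ri, metabolite = "m1",
        response = 10^y, stringsAsFactors = FALSE)
    }
    prof <- do.call(rbind, out)
    var_g <- if (n_genotypes > 1) var(G) else 0
    var_gs <- if (length(gs_draws) > 1) var(gs_draws) else 0
    var_e <- if (length(e_draws) > 1) var(e_draws) else 0
    attr(prof, "realized") <- list(
      var_g = var_g, var_gs = var_gs, var_e = var_e,
      h2 = var_g / (var_g + var_gs / s + var_e / (r * s)))
    prof
  })
}
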