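#' Default mammalian species tree
#'
#' A rooted nine-species tree (eight mammals plus chicken as outgroup) with
#' approximate divergence-time branch lengths (millions of years) and
#' labelled internal nodes, matching the ladder of sister comparisons used
#' throughout the package: human-chimpanzee out to human-chicken.
#'
#' @return Newick string.
#' @export
mammal_species_tree <- function() {
  paste0(
    "((((((((human:6,chimpanzee:6)hc:2,gorilla:8)hcg:7,orangutan:15)",
    "hcgo:14,macaque:29)primates:61,mouse:90)euarchontoglires:70,",
    "opossum:160)theria:20,platypus:180)mammals:130,chicken:310)amniota;"
  )
}

#' Default species-pair K_s table for the generator
#'
#' Median synonymous divergence between human and each other species.
#' Human-chimpanzee (0.01) and human-platypus (1.41) anchor the range;
#' the remaining values are literature-scale interpolations.
#'
#' @return data.frame with columns `focal`, `outgroup`, `ks`.
#' @export
default_ks_pairs <- function() {
  data.frame(
    focal = "human",
    outgroup = c("chimpanzee", "gorilla", "orangutan", "macaque",
                 "mouse", "opossum", "platypus", "chicken"),
    ks = c(0.01, 0.016, 0.036, 0.07, 0.45, 1.0, 1.41, 1.66),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic-data generator
#'
#' Builds a validated configuration object. The generator plants
#' ground-truth retention classes with a geometry the classifier should
#' recover: conserved copies track the ancestral profile within
#' measurement noise; neofunctionalized copies adopt a freshly drawn
#' tissue-spiky profile; subfunctionalized copies partition the ancestral
#' tissues (their absolute sum reconstructs the ancestral row exactly,
#' before noise); specialized copies adopt two spiky profiles with
#' distinct top tissues. Single-copy ortholog pairs -- the baseline that
#' sets the divergence cutoff -- carry evolutionary divergence
#' (`base_divergence + drift_per_ks * ks`) on top of measurement noise.
#'
#' @param seed Integer RNG seed; a fixed seed reproduces the bundle
#'   bit-identically.
#' @param tissues Tissue labels (default [canonical_tissues()]).
#' @param n_single_copy Single-copy ortholog genes per species pair.
#' @param n_background Background transcriptome genes per species (present
#'   in the matrices but in no ortholog or trio table). Real expression
#'   matrices are dominated by genes outside any duplicate-pair analysis;
#'   without this bulk, joint quantile normalization would be driven by
#'   the atypical marginal distribution of the analyzed genes themselves.
#' @param background_specific_fraction Fraction of background genes drawn
#'   tissue-specific (concentration `neo_concentration`) rather than broad.
#'   Real transcriptomes contain tissue-specific genes in every species;
#'   without them, near-zero expression values would occur only in species
#'   carrying diverged duplicates, skewing the normalization.
#' @param n_trios_per_class Duplicate trios planted per class (balanced
#'   design; ignored when `n_trios_per_pair` is set).
#' @param n_trios_per_pair If set, trios per species pair with classes
#'   drawn by the divergence-rate model: a trio diverges with probability
#'   1 - exp(-`divergence_rate_per_ks` * ks), divergence classes sampled
#'   by `class_weights`.
#' @param noise_sd Log-normal sd of per-tissue multiplicative measurement
#'   noise (applied to every emitted expression row).
#' @param base_divergence K_s-independent evolutionary divergence (extra
#'   log-normal sd) of single-copy ortholog pairs.
#' @param drift_per_ks Additional per-unit-K_s divergence of single-copy
#'   ortholog pairs, making baseline divergence (and the cutoff) grow with
#'   evolutionary distance.
#' @param divergence_rate_per_ks Rate at which class-divergence events
#'   accumulate with K_s (rate model only).
#' @param class_weights Relative frequencies of the four divergence
#'   classes in the rate model.
#' @param ancestral_concentration Dirichlet concentration of ancestral
#'   relative profiles (large = broadly expressed).
#' @param neo_concentration Dirichlet concentration of novel profiles
#'   (small = tissue-spiky).
#' @param expression_scale,expression_sdlog Log-normal location (FPKM-like
#'   units) and sd of per-gene total expression.
#' @param neo_tissue_weights Sampling weights of the top tissue of novel
#'   profiles; the default plants an excess of male-kidney and an absence
#'   of testis neofunctionalization.
#' @param species_tree Newick text of the rooted species tree.
#' @param ks_pairs data.frame `focal`, `outgroup`, `ks`: the species pairs
#'   (and their planted duplication branches) the bundle covers.
#' @return Object of class `generator_config` (a validated list).
#' @export
generator_config <- function(seed = 1L,
                             tissues = canonical_tissues(),
                             n_single_copy = 200L,
                             n_background = 2000L,
                             background_specific_fraction = 0.2,
                             n_trios_per_class = 50L,
                             n_trios_per_pair = NULL,
                             noise_sd = 0.1,
                             base_divergence = 0.1,
                             drift_per_ks = 0,
                             divergence_rate_per_ks = 1,
                             class_weights = c(NEOFUNC_PARENT = 0.35,
                                               NEOFUNC_CHILD = 0.35,
                                               SUBFUNC = 0.10,
                                               SPECIALIZED = 0.20),
                             ancestral_concentration = 5,
                             neo_concentration = 0.1,
                             expression_scale = 100,
                             expression_sdlog = 0.5,
                             neo_tissue_weights = NULL,
                             species_tree = mammal_species_tree(),
                             ks_pairs = default_ks_pairs()) {
  if (is.null(neo_tissue_weights)) {
    neo_tissue_weights <- setNames(rep(1, length(tissues)), tissues)
    if ("kidney-M" %in% tissues) neo_tissue_weights[["kidney-M"]] <- 3
    if ("testis" %in% tissues) neo_tissue_weights[["testis"]] <- 0
  }
  cfg <- list(
    seed = as.integer(seed), tissues = tissues,
    n_single_copy = as.integer(n_single_copy),
    n_background = as.integer(n_background),
    background_specific_fraction = background_specific_fraction,
    n_trios_per_class = as.integer(n_trios_per_class),
    n_trios_per_pair = if (is.null(n_trios_per_pair)) NULL else
      as.integer(n_trios_per_pair),
    noise_sd = noise_sd, base_divergence = base_divergence,
    drift_per_ks = drift_per_ks,
    divergence_rate_per_ks = divergence_rate_per_ks,
    class_weights = class_weights,
    ancestral_concentration = ancestral_concentration,
    neo_concentration = neo_concentration,
    expression_scale = expression_scale,
    expression_sdlog = expression_sdlog,
    neo_tissue_weights = neo_tissue_weights,
    species_tree = species_tree, ks_pairs = ks_pairs
  )
  rates <- c(cfg$noise_sd, cfg$base_divergence, cfg$drift_per_ks,
             cfg$divergence_rate_per_ks, cfg$ancestral_concentration,
             cfg$neo_concentration)
  if (any(rates < 0)) stop("rates, sds and concentrations must be >= 0")
  if (!all(c("focal", "outgroup", "ks") %in% names(ks_pairs))) {
    stop("ks_pairs needs columns focal, outgroup, ks")
  }
  tree <- ape::read.tree(text = species_tree)
  missing <- setdiff(unique(c(ks_pairs$focal, ks_pairs$outgroup)),
                     tree$tip.label)
  if (length(missing)) {
    stop("ks_pairs species not on tree: ", paste(missing, collapse = ", "))
  }
  if (!all(names(neo_tissue_weights) == tissues)) {
    stop("neo_tissue_weights must be named by the configured tissues")
  }
  structure(cfg, class = "generator_config")
}

# One Dirichlet draw via normalized gammas. Very small concentrations can
# underflow to an all-zero gamma vector; redraw in that case.
rdirichlet_one <- function(alpha) {
  repeat {
    g <- rgamma(length(alpha), shape = alpha)
    s <- sum(g)
    if (s > 0) return(g / s)
  }
}

# Per-tissue multiplicative log-normal noise.
lognormal_noise <- function(row, sd) {
  if (sd <= 0) return(row)
  row * exp(rnorm(length(row), 0, sd))
}

#' Simulate ancestral absolute expression rows
#'
#' Relative profiles are drawn from a symmetric Dirichlet with
#' concentration `ancestral_concentration` and scaled by per-gene total
#' expression drawn log-normally around `expression_scale`.
#'
#' @param config A [generator_config()]. Seed the RNG with `set.seed()`
#'   before calling (or use [simulate_dataset()], which seeds once).
#' @param n Number of rows.
#' @return n x n_tissues matrix of non-negative absolute expression
#'   values, columns named by tissue.
#' @export
simulate_ancestral_profile <- function(config, n = 1L) {
  nt <- length(config$tissues)
  rows <- t(vapply(seq_len(n), function(i) {
    rel <- rdirichlet_one(rep(config$ancestral_concentration, nt))
    total <- rlnorm(1L, meanlog = log(config$expression_scale),
                    sdlog = config$expression_sdlog)
    rel * total
  }, numeric(nt)))
  colnames(rows) <- config$tissues
  rows
}

#' Simulate a single-copy ortholog pair
#'
#' Each species' row is the ancestral row perturbed by per-tissue
#' log-normal noise with sd `noise_sd + base_divergence +
#' drift_per_ks * ks`, so expected expression divergence between the two
#' species increases with K_s.
#'
#' @param ancestral_row Absolute ancestral expression row.
#' @param ks Synonymous divergence of the species pair (>= 0).
#' @param config A [generator_config()].
#' @return List with `row_1`, `row_2`.
#' @export
simulate_single_copy_pair <- function(ancestral_row, ks, config) {
  if (ks < 0) stop("ks must be >= 0")
  sd <- config$noise_sd + config$base_divergence + config$drift_per_ks * ks
  list(row_1 = lognormal_noise(ancestral_row, sd),
       row_2 = lognormal_noise(ancestral_row, sd))
}

# Draw a novel (tissue-spiky) absolute expression row whose top tissue is
# sampled by the configured weights: draw Dirichlet(neo_concentration),
# then swap the maximum entry into the chosen tissue's position.
draw_neo_row <- function(config) {
  nt <- length(config$tissues)
  w <- config$neo_tissue_weights
  top <- sample.int(nt, 1L, prob = w)
  rel <- rdirichlet_one(rep(config$neo_concentration, nt))
  j <- which.max(rel)
  tmp <- rel[top]; rel[top] <- rel[j]; rel[j] <- tmp
  total <- rlnorm(1L, meanlog = log(config$expression_scale),
                  sdlog = config$expression_sdlog)
  rel * total
}

#' Simulate a duplicate-gene trio with a planted retention class
#'
#' The outgroup row is the ancestral row plus measurement noise. Copies
#' follow the planted class: CONSERVED copies track the ancestral row;
#' the diverged copy of a NEOFUNC class adopts a fresh tissue-spiky
#' profile; SUBFUNC copies partition the expressed ancestral tissues into
#' two disjoint non-empty sets (each tissue independently with probability
#' 1/2, empty sides rejected) so that parent + child reconstruct the
#' ancestral row exactly before noise; SPECIALIZED copies adopt two spiky
#' profiles redrawn until their top tissues differ.
#'
#' @param planted_class One of [retention_classes()].
#' @param ancestral_row Absolute ancestral expression row (at least two
#'   tissues with nonzero expression for SUBFUNC).
#' @param config A [generator_config()].
#' @return List with `parent`, `child`, `outgroup` (absolute rows) and
#'   `planted_class`.
#' @export
simulate_trio <- function(planted_class, ancestral_row, config) {
  planted_class <- match.arg(planted_class, retention_classes())
  nt <- length(ancestral_row)
  sd <- config$noise_sd
  outgroup <- lognormal_noise(ancestral_row, sd)
  if (planted_class == "CONSERVED") {
    parent <- lognormal_noise(ancestral_row, sd)
    child <- lognormal_noise(ancestral_row, sd)
  } else if (planted_class == "NEOFUNC_PARENT") {
    parent <- lognormal_noise(draw_neo_row(config), sd)
    child <- lognormal_noise(ancestral_row, sd)
  } else if (planted_class == "NEOFUNC_CHILD") {
    parent <- lognormal_noise(ancestral_row, sd)
    child <- lognormal_noise(draw_neo_row(config), sd)
  } else if (planted_class == "SUBFUNC") {
    expressed <- which(ancestral_row > 0)
    if (length(expressed) < 2L) {
      stop("ancestral profile with < 2 expressed tissues cannot be subfunctionalized")
    }
    repeat {
      to_parent <- runif(length(expressed)) < 0.5
      if (any(to_parent) && !all(to_parent)) break
    }
    mask_p <- mask_c <- rep(0, nt)
    mask_p[expressed[to_parent]] <- 1
    mask_c[expressed[!to_parent]] <- 1
    parent <- lognormal_noise(ancestral_row * mask_p, sd)
    child <- lognormal_noise(ancestral_row * mask_c, sd)
  } else {  # SPECIALIZED
    repeat {
      p_row <- draw_neo_row(config)
      c_row <- draw_neo_row(config)
      if (which.max(p_row) != which.max(c_row)) break
    }
    parent <- lognormal_noise(p_row, sd)
    child <- lognormal_noise(c_row, sd)
  }
  names(parent) <- names(child) <- names(outgroup) <- config$tissues
  list(parent = parent, child = child, outgroup = outgroup,
       planted_class = planted_class)
}

# The branch on which a duplication shared by `focal` but not `outgroup`
# arose: the child clade of mrca(focal, outgroup) that contains focal.
# Returns list(node, tips, label).
origin_clade <- function(tree, focal, outgroup) {
  mrca <- ape::getMRCA(tree, c(focal, outgroup))
  children <- tree$edge[tree$edge[, 1L] == mrca, 2L]
  ntip <- length(tree$tip.label)
  for (ch in children) {
    tips <- if (ch <= ntip) tree$tip.label[ch] else
      ape::extract.clade(tree, ch)$tip.label
    if (focal %in% tips) {
      return(list(node = ch, tips = tips, label = branch_label(tree, ch)))
    }
  }
  stop("focal species not under its own mrca child; malformed tree")
}

#' Simulate a complete, internally consistent input bundle
#'
#' Generates, for every species pair in the configuration: single-copy
#' ortholog genes (the baseline), duplicate trios with planted retention
#' classes, copy-number patterns consistent with the planted duplication
#' branch, parent/child outgroup-alignment flags, per-species expression
#' matrices containing every emitted gene, a K_s table and a ground-truth
#' table. The whole bundle is a deterministic function of the seed.
#'
#' With `n_trios_per_pair` unset, each class receives `n_trios_per_class`
#' trios distributed round-robin over the species pairs (balanced design).
#' With it set, each pair receives `n_trios_per_pair` trios whose classes
#' follow the divergence-rate model, so divergence events accumulate with
#' K_s.
#'
#' @param config A [generator_config()].
#' @param dir Optional directory; when given, the bundle is also written
#'   as TSV/Newick/JSON files via [write_bundle()].
#' @return Object of class `dup_bundle`: list with `matrices`,
#'   `orthologs`, `trios`, `copy_number`, `alignment_flags`, `ks`,
#'   `ground_truth`, `tree` (Newick text) and `config`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  tree <- ape::read.tree(text = config$species_tree)
  pairs <- config$ks_pairs
  npairs <- nrow(pairs)
  tissues <- config$tissues

  rows_by_species <- list()  # species -> list of named rows
  add_row <- function(species, gene_id, row) {
    if (is.null(rows_by_species[[species]])) {
      rows_by_species[[species]] <<- list()
    }
    rows_by_species[[species]][[gene_id]] <<- row
  }

  orthologs <- list()
  trio_rows <- list()
  truth_rows <- list()
  cn_rows <- list()
  flag_rows <- list()

  # planted classes per pair
  classes_for_pair <- vector("list", npairs)
  if (is.null(config$n_trios_per_pair)) {
    for (cl in retention_classes()) {
      for (i in seq_len(config$n_trios_per_class)) {
        j <- (i - 1L) %% npairs + 1L
        classes_for_pair[[j]] <- c(classes_for_pair[[j]], cl)
      }
    }
  } else {
    for (j in seq_len(npairs)) {
      ks <- pairs$ks[j]
      p_div <- 1 - exp(-config$divergence_rate_per_ks * ks)
      n <- config$n_trios_per_pair
      diverged <- runif(n) < p_div
      cls <- rep("CONSERVED", n)
      if (any(diverged)) {
        cls[diverged] <- sample(names(config$class_weights), sum(diverged),
                                replace = TRUE, prob = config$class_weights)
      }
      classes_for_pair[[j]] <- cls
    }
  }

  for (j in seq_len(npairs)) {
    focal <- pairs$focal[j]
    outgrp <- pairs$outgroup[j]
    ks <- pairs$ks[j]
    tag <- outgrp
    oc <- origin_clade(tree, focal, outgrp)

    # single-copy ortholog baseline
    key <- pair_key(focal, outgrp)
    sp1 <- sort(c(focal, outgrp))[1L]
    anc_sc <- simulate_ancestral_profile(config, config$n_single_copy)
    g1 <- g2 <- character(config$n_single_copy)
    for (i in seq_len(config$n_single_copy)) {
      base <- sprintf("sc_%s_%04d", tag, i)
      pair_rows <- simulate_single_copy_pair(anc_sc[i, ], ks, config)
      id_f <- paste0(base, "_", focal)
      id_o <- paste0(base, "_", outgrp)
      add_row(focal, id_f, pair_rows$row_1)
      add_row(outgrp, id_o, pair_rows$row_2)
      if (sp1 == focal) { g1[i] <- id_f; g2[i] <- id_o }
      else { g1[i] <- id_o; g2[i] <- id_f }
    }
    orthologs[[key]] <- data.frame(gene_1 = g1, gene_2 = g2,
                                   stringsAsFactors = FALSE)

    # duplicate trios
    cls <- classes_for_pair[[j]]
    if (length(cls)) {
      anc_tr <- simulate_ancestral_profile(config, length(cls))
      for (i in seq_along(cls)) {
        pid <- sprintf("dup_%s_%04d", tag, i)
        trio <- simulate_trio(cls[i], anc_tr[i, ], config)
        pg <- paste0(pid, "_P"); cg <- paste0(pid, "_C"); og <- paste0(pid, "_O")
        add_row(focal, pg, trio$parent)
        add_row(focal, cg, trio$child)
        add_row(outgrp, og, trio$outgroup)
        trio_rows[[length(trio_rows) + 1L]] <- data.frame(
          pair_id = pid, focal_species = focal, parent_gene = pg,
          child_gene = cg, outgroup_species = outgrp, outgroup_gene = og,
          stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          pair_id = pid, planted_class = cls[i],
          planted_origin_branch = oc$label, planted_parent = pg,
          stringsAsFactors = FALSE)
        cn_rows[[length(cn_rows) + 1L]] <- data.frame(
          family_id = pid, species = tree$tip.label,
          copy_number = ifelse(tree$tip.label %in% oc$tips, 2L, 1L),
          stringsAsFactors = FALSE)
        flag_rows[[length(flag_rows) + 1L]] <- data.frame(
          family_id = pid, copy_id = c(pg, cg),
          aligns_to_outgroup = c(1L, 0L), stringsAsFactors = FALSE)
      }
    }
  }

  # background transcriptome per species: a mixture of broadly expressed
  # and tissue-specific genes outside the analysis, so every species'
  # expression marginal is dominated by the same bulk composition
  if (config$n_background > 0L) {
    nt <- length(tissues)
    for (sp in names(rows_by_species)) {
      for (i in seq_len(config$n_background)) {
        conc <- if (runif(1L) < config$background_specific_fraction)
          config$neo_concentration else config$ancestral_concentration
        rel <- rdirichlet_one(rep(conc, nt))
        total <- rlnorm(1L, meanlog = log(config$expression_scale),
                        sdlog = config$expression_sdlog)
        add_row(sp, sprintf("bg_%s_%04d", sp, i),
                lognormal_noise(rel * total, config$noise_sd))
      }
    }
  }

  matrices <- lapply(rows_by_species, function(rl) {
    m <- do.call(rbind, rl)
    colnames(m) <- tissues
    m
  })

  ks_tab <- data.frame(
    species_1 = pmin(pairs$focal, pairs$outgroup),
    species_2 = pmax(pairs$focal, pairs$outgroup),
    ks_median = pairs$ks,
    ka_median = 0.25 * pairs$ks,
    stringsAsFactors = FALSE
  )

  bundle <- structure(
    list(
      matrices = matrices,
      orthologs = orthologs,
      trios = do.call(rbind, trio_rows),
      copy_number = do.call(rbind, cn_rows),
      alignment_flags = do.call(rbind, flag_rows),
      ks = ks_tab,
      ground_truth = do.call(rbind, truth_rows),
      tree = config$species_tree,
      config = config
    ),
    class = "dup_bundle"
  )
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' @export
print.dup_bundle <- function(x, ...) {
  cat("Synthetic duplicate-gene bundle\n")
  cat("  species matrices:", length(x$matrices),
      "| trios:", if (is.null(x$trios)) 0L else nrow(x$trios),
      "| ortholog tables:", length(x$orthologs), "\n")
  invisible(x)
}
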