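test_that("profile distance is Euclidean and bounded by sqrt(2)", {
  p <- c(0.5, 0.5, 0)
  expect_equal(profile_distance(p, p), 0)
  expect_equal(profile_distance(c(1, 0, 0), c(0, 1, 0)), sqrt(2))
  expect_equal(profile_distance(c(0.5, 0.5, 0), c(0.25, 0.75, 0)), sqrt(0.125))
  expect_error(profile_distance(c(1, 0), c(1, 0, 0)), "mismatched")
  expect_error(
    profile_distance(setNames(c(1, 0), c("testis", "heart-F")),
                     setNames(c(1, 0), c("heart-F", "testis"))),
    "mismatched")
})

test_that("divergence cutoff is median plus SIQR under the configured quantile rule", {
  co <- divergence_cutoff(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(co$median, 0.3)
  expect_equal(co$q1, 0.2)
  expect_equal(co$q3, 0.4)
  expect_equal(co$siqr, 0.1)
  expect_equal(co$cutoff, 0.4)

  # single observation: all quantiles collapse
  co1 <- divergence_cutoff(0.3)
  expect_equal(co1$cutoff, 0.3)
  expect_equal(co1$siqr, 0)

  # zero spread
  expect_equal(divergence_cutoff(rep(0.25, 9))$cutoff, 0.25)

  # multiplier scales only the SIQR term; quantile convention is honoured
  expect_equal(divergence_cutoff(c(0.1, 0.2, 0.3, 0.4, 0.5), multiplier = 2)$cutoff, 0.5)
  expect_equal(divergence_cutoff(c(0.1, 0.2, 0.3, 0.4, 0.5), quantile_type = 6)$cutoff,
               0.3 + (0.45 - 0.15) / 2)
  expect_error(divergence_cutoff(numeric(0)), "empty")
})

test_that("the five-way rule table matches its definition, with ties conserved", {
  expect_equal(classify_trio(0.1, 0.2, 0.9, 0.3), "CONSERVED")
  expect_equal(classify_trio(0.5, 0.1, 0.9, 0.3), "NEOFUNC_PARENT")
  expect_equal(classify_trio(0.1, 0.5, 0.9, 0.3), "NEOFUNC_CHILD")
  expect_equal(classify_trio(0.5, 0.4, 0.2, 0.3), "SUBFUNC")
  expect_equal(classify_trio(0.5, 0.4, 0.6, 0.3), "SPECIALIZED")
  # distances exactly at the cutoff count as NOT diverged
  expect_equal(classify_trio(0.3, 0.3, 0.3, 0.3), "CONSERVED")
  expect_equal(classify_trio(0.3 + 1e-12, 0.3, 0.3, 0.3), "NEOFUNC_PARENT")
  expect_error(classify_trio(-0.1, 0.2, 0.3, 0.3), "non-negative")
})

test_that("classification regions partition distance space", {
  set.seed(101)
  n <- 1e5
  e_po <- runif(n, 0, sqrt(2)); e_co <- runif(n, 0, sqrt(2))
  e_pco <- runif(n, 0, sqrt(2)); cut <- runif(n, 0.01, 1)
  labels <- classify_trio(e_po, e_co, e_pco, cut)
  # independent restatement of the five regions
  regions <- cbind(
    e_po <= cut & e_co <= cut,
    e_po > cut & e_co <= cut,
    e_po <= cut & e_co > cut,
    e_po > cut & e_co > cut & e_pco <= cut,
    e_po > cut & e_co > cut & e_pco > cut
  )
  expect_true(all(rowSums(regions) == 1))
  expect_equal(unname(labels), retention_classes()[apply(regions, 1, which)])
})

test_that("raising the cutoff only moves labels toward CONSERVED", {
  set.seed(77)
  n <- 2000
  e_po <- runif(n, 0, 1.2); e_co <- runif(n, 0, 1.2); e_pco <- runif(n, 0, 1.2)
  rank_of <- c(CONSERVED = 1, NEOFUNC_PARENT = 2, NEOFUNC_CHILD = 2,
               SUBFUNC = 3, SPECIALIZED = 4)
  cuts <- seq(0.05, 1.2, by = 0.05)
  prev_cons <- -1
  for (cut in cuts) {
    lab <- classify_trio(e_po, e_co, e_pco, cut)
    cons <- sum(lab == "CONSERVED")
    expect_gte(cons, prev_cons)
    prev_cons <- cons
  }
})

test_that("baseline distances match per-pair direct computation", {
  set.seed(5)
  tis <- canonical_tissues()
  n <- 20
  m1 <- matrix(rlnorm(n * 11, log(50), 1), n, 11,
               dimnames = list(sprintf("g%02d_a", 1:n), tis))
  m2 <- m1 * exp(matrix(rnorm(n * 11, 0, 0.3), n, 11))
  rownames(m2) <- sprintf("g%02d_b", 1:n)
  m2[1, ] <- 0.2  # unexpressed in species 2 -> pair dropped
  ort <- data.frame(gene_1 = rownames(m1), gene_2 = rownames(m2))
  d <- baseline_distances(ort, m1, m2)
  expect_equal(length(d), n - 1)
  for (i in 2:n) {
    expect_equal(unname(d[i - 1]),
                 profile_distance(relative_profile(m1[i, ]),
                                  relative_profile(m2[i, ])))
  }
  # identical matrices give all-zero baseline
  expect_equal(max(baseline_distances(
    data.frame(gene_1 = rownames(m1), gene_2 = rownames(m1)), m1, m1)), 0)
  expect_error(
    baseline_distances(ort, m1 * 0 + 0.1, m2), "empty baseline")
})

test_that("classify_dataset agrees with a straight-line per-trio oracle", {
  cfg <- generator_config(seed = 23, n_single_copy = 40, n_trios_per_class = 8,
                          n_background = 0)
  b <- simulate_dataset(cfg)
  res <- classify_dataset(b$matrices, b$trios, b$orthologs, normalize = "none")
  orc <- oracle_classify(b$matrices, b$trios, b$orthologs)
  merged <- merge(res$records[, c("pair_id", "label")], orc, by = "pair_id",
                  suffixes = c("_pkg", "_oracle"))
  expect_equal(nrow(merged), nrow(res$records))
  expect_equal(merged$label_pkg, merged$label_oracle)
})

test_that("trios with unexpressed members are excluded with a reason", {
  cfg <- generator_config(seed = 2, n_single_copy = 30, n_trios_per_class = 4,
                          n_background = 0)
  b <- simulate_dataset(cfg)
  # silence one child gene
  g <- b$trios$child_gene[1]
  b$matrices[[b$trios$focal_species[1]]][g, ] <- 0.01
  res <- classify_dataset(b$matrices, b$trios, b$orthologs, normalize = "none")
  expect_true(b$trios$pair_id[1] %in% res$exclusions$pair_id)
  expect_equal(res$exclusions$reason[res$exclusions$pair_id == b$trios$pair_id[1]],
               "child unexpressed")
  expect_false(b$trios$pair_id[1] %in% res$records$pair_id)
})

test_that("a noise-free conserved dataset is classified 100% CONSERVED", {
  cfg <- generator_config(seed = 13, n_single_copy = 30, n_trios_per_class = 10,
                          noise_sd = 0, base_divergence = 0, n_background = 0)
  b <- simulate_dataset(cfg)
  keep <- b$ground_truth$pair_id[b$ground_truth$planted_class == "CONSERVED"]
  trios <- b$trios[b$trios$pair_id %in% keep, ]
  res <- classify_dataset(b$matrices, trios, b$orthologs, normalize = "none")
  expect_equal(nrow(res$records), length(keep))
  expect_true(all(res$records$label == "CONSERVED"))
  expect_true(all(res$records$e_po == 0))
})

test_that("cutoff sensitivity is monotone and consistent with classification", {
  cfg <- generator_config(seed = 31, n_single_copy = 60, n_trios_per_class = 20,
                          n_background = 300)
  b <- simulate_dataset(cfg)
  res <- classify_dataset(b$matrices, b$trios, b$orthologs)
  mult <- c(0.25, 0.5, 1, 1.5, 2, 4, 100)
  sens <- cutoff_sensitivity(res, mult)
  expect_equal(sens$total, rep(nrow(res$records), length(mult)))
  expect_true(all(diff(sens$CONSERVED) >= 0))
  # the unit multiplier row reproduces the classification counts
  counts <- table(factor(res$records$label, levels = retention_classes()))
  expect_equal(unlist(sens[sens$multiplier == 1, retention_classes()]),
               unlist(as.list(counts)), ignore_attr = TRUE)
  # an extreme multiplier leaves no distance above the cutoff
  expect_equal(sens$CONSERVED[sens$multiplier == 100], nrow(res$records))
  expect_error(cutoff_sensitivity(res, c(1, -1)), "positive")
})
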