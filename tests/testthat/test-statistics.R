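test_that("least-squares fit recovers exact linear relationships", {
  fit <- fit_linear_regression(c(0, 1, 2, 3), c(0, 2, 4, 6))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)

  fit2 <- fit_linear_regression(c(0, 1, 2), c(1, 3, 5))
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 1)

  # residuals orthogonal to x
  set.seed(3)
  x <- runif(50); y <- 1 + 0.5 * x + rnorm(50, 0, 0.2)
  fit3 <- fit_linear_regression(x, y)
  expect_lt(abs(sum(fit3$residuals * x)), 1e-8)
  expect_error(fit_linear_regression(rep(1, 5), 1:5), "constant")
  expect_error(fit_linear_regression(1:3, 1:4), "lengths differ")
})

test_that("slope t-test holds its nominal size under the null", {
  set.seed(17)
  nsim <- 400
  p <- replicate(nsim, {
    x <- rnorm(100); y <- rnorm(100)  # independent
    fit_linear_regression(x, y)$slope_t_pvalue
  })
  # rejection rate compatible with alpha = 0.05 (binomial 99.9% bounds)
  expect_gt(mean(p < 0.05), 0.05 - 3.3 * sqrt(0.05 * 0.95 / nsim))
  expect_lt(mean(p < 0.05), 0.05 + 3.3 * sqrt(0.05 * 0.95 / nsim))
})

test_that("Mann-Whitney U matches exhaustive rank-assignment enumeration", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 1 / 3)
  expect_equal(mw$method, "exact")

  set.seed(29)
  for (na in c(2, 4, 6, 8)) {
    for (nb in c(3, 5, 8)) {
      a <- rnorm(na); b <- rnorm(nb, 0.5)
      got <- mann_whitney_u(a, b)
      want <- oracle_mwu(a, b)
      expect_equal(got$U, want$U)
      expect_equal(got$p_value, want$p)
    }
  }
})

test_that("Mann-Whitney approximation is close to exact at moderate n, identical samples give p near 1", {
  set.seed(41)
  a <- rnorm(8); b <- rnorm(8, 0.8)
  exact <- oracle_mwu(a, b)$p
  approx <- suppressWarnings(
    wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(exact - approx), 0.01)

  # tied data fall back to the tie-corrected normal approximation
  mw <- mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 3, 3))
  expect_equal(mw$method, "normal approximation")
  expect_gt(mw$p_value, 0.5)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty sample")
})

test_that("Fisher exact p matches brute-force hypergeometric enumeration", {
  ft <- fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))
  expect_equal(ft$p_value, 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)

  set.seed(53)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4), 2)
    if (all(tab == 0)) tab[1, 1] <- 1
    got <- fisher_exact_2x2(tab)$p_value
    want <- oracle_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(got, want)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 2), 2)), "negative")
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "nonzero")
})

test_that("Bonferroni correction multiplies and caps at 1", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 10), 1)
  expect_equal(bonferroni(c(0.2, 0.9), m = 1), c(0.2, 0.9))
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  # monotone
  p <- sort(runif(10))
  expect_true(all(diff(bonferroni(p)) >= 0))
  expect_error(bonferroni(1.2), "0, 1")
})

test_that("tissue enrichment detects planted excess and is null on identical groups", {
  tis <- canonical_tissues()
  same <- setNames(c(rep(5, 10), 8), tis)
  res <- highest_tissue_enrichment(list(a = same, b = same))
  expect_true(all(res$p == 1))
  expect_true(all(res$stars == ""))

  # extreme separation: all of group A in one tissue, none of group B
  g_a <- setNames(c(10, rep(0, 10)), tis)
  g_b <- setNames(c(0, rep(1, 10)), tis)
  res2 <- highest_tissue_enrichment(list(a = g_a, b = g_b))
  row <- res2[res2$tissue == tis[1], ]
  expect_equal(row$p, 2 / choose(20, 10))

  # generator-planted kidney-M excess in neofunctionalized profiles
  set.seed(61)
  cfg <- generator_config(seed = 61)
  anc <- simulate_ancestral_profile(cfg, 300)
  neo_top <- vapply(seq_len(300), function(i) {
    trio <- simulate_trio("NEOFUNC_PARENT", anc[i, ], cfg)
    tissue_specificity(relative_profile(trio$parent))$top_tissue
  }, character(1))
  sc_top <- vapply(seq_len(300), function(i) {
    tissue_specificity(relative_profile(anc[i, ]))$top_tissue
  }, character(1))
  counts <- lapply(list(neo = neo_top, single_copy = sc_top), function(tt) {
    tab <- table(factor(tt, levels = tis))
    setNames(as.integer(tab), tis)
  })
  res3 <- highest_tissue_enrichment(counts)
  km <- res3[res3$tissue == "kidney-M", ]
  expect_lt(km$p_adjusted, 0.05)
  expect_gt(km$odds_ratio, 1)  # direction matches the planted excess
  # testis is excluded from novel-profile top-tissue sampling; only noise
  # flips can place a neofunctionalized gene there
  expect_lt(counts$neo[["testis"]], counts$single_copy[["testis"]] / 2)
  expect_error(highest_tissue_enrichment(list(a = same)), "at least two")
})

test_that("specificity comparison flags separated groups and not resampled ones", {
  set.seed(71)
  single <- runif(500, 1 / 11, 1)
  resampled <- sample(single, 50)
  spiky <- rep(1, 25)
  res <- specificity_comparison(list(null_group = resampled, spiky = spiky),
                                single)
  expect_gt(res$p[res$group == "null_group"], 0.05)
  expect_lt(res$p_adjusted[res$group == "spiky"], 0.001)
  expect_equal(res$stars[res$group == "spiky"], "***")
  # two identical singleton groups cannot be distinguished
  one <- specificity_comparison(list(g = 0.5), 0.5)
  expect_equal(one$p, 1)
  expect_error(specificity_comparison(list(g = numeric(0)), single), "empty group")
})

test_that("per-pair conserved proportions join the Ks metadata", {
  records <- data.frame(
    focal_species = rep("human", 10),
    outgroup_species = rep(c("chimpanzee", "mouse"), each = 5),
    label = c("CONSERVED", "CONSERVED", "CONSERVED", "CONSERVED", "SUBFUNC",
              rep("SPECIALIZED", 3), "CONSERVED", "NEOFUNC_PARENT")
  )
  ks <- data.frame(species_1 = c("chimpanzee", "human"),
                   species_2 = c("human", "mouse"),
                   ks_median = c(0.01, 0.45))
  out <- conserved_proportion_by_pair(records, ks)
  expect_equal(out$proportion_conserved, c(0.8, 0.2))
  expect_equal(out$ks_median, c(0.01, 0.45))
  expect_error(conserved_proportion_by_pair(
    records, ks[1, , drop = FALSE]), "missing K_s")
})
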