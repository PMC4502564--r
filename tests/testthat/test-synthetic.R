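test_that("generator configuration validates its inputs", {
  cfg <- generator_config()
  expect_s3_class(cfg, "generator_config")
  expect_equal(length(cfg$tissues), 11)
  expect_equal(cfg$neo_tissue_weights[["testis"]], 0)
  expect_equal(cfg$neo_tissue_weights[["kidney-M"]], 3)
  expect_error(generator_config(noise_sd = -1), ">= 0")
  expect_error(generator_config(ks_pairs = data.frame(
    focal = "human", outgroup = "dog", ks = 0.5)), "not on tree")
})

test_that("ancestral profiles are Dirichlet draws scaled by total expression", {
  cfg <- generator_config(seed = 1)
  set.seed(1)
  rows <- simulate_ancestral_profile(cfg, 1e4)
  expect_true(all(rows >= 0))
  props <- rows / rowSums(rows)
  # symmetric Dirichlet mean is 1/11 per tissue; 3-SE band
  se <- sd(props[, 1]) / sqrt(nrow(props))
  for (j in 1:11) expect_lt(abs(mean(props[, j]) - 1 / 11), 3.3 * se)
  # determinism
  set.seed(42); a <- simulate_ancestral_profile(cfg, 5)
  set.seed(42); b <- simulate_ancestral_profile(cfg, 5)
  expect_identical(a, b)
  # high concentration approaches uniformity
  cfg_u <- generator_config(ancestral_concentration = 1e5)
  set.seed(2)
  u <- simulate_ancestral_profile(cfg_u, 50)
  expect_lt(max(abs(u / rowSums(u) - 1 / 11)), 0.01)
})

test_that("single-copy pair divergence increases with ks", {
  cfg <- generator_config(seed = 1, drift_per_ks = 0.3)
  mean_dist <- vapply(c(0.01, 0.5, 1.4), function(ks) {
    set.seed(100)
    mean(replicate(500, {
      anc <- simulate_ancestral_profile(cfg)[1, ]
      pr <- simulate_single_copy_pair(anc, ks, cfg)
      profile_distance(relative_profile(pr$row_1), relative_profile(pr$row_2))
    }))
  }, numeric(1))
  expect_true(all(diff(mean_dist) > 0))

  # no stochastic terms: identical rows, zero divergence
  cfg0 <- generator_config(noise_sd = 0, base_divergence = 0, drift_per_ks = 0)
  anc <- c(setNames(rep(10, 11), canonical_tissues()))
  pr <- simulate_single_copy_pair(anc, 1.4, cfg0)
  expect_identical(pr$row_1, pr$row_2)
})

test_that("planted trios realize the class geometry exactly at zero noise", {
  cfg <- generator_config(seed = 1, noise_sd = 0)
  set.seed(11)
  anc <- simulate_ancestral_profile(cfg)[1, ]

  cons <- simulate_trio("CONSERVED", anc, cfg)
  o <- relative_profile(cons$outgroup)
  expect_equal(profile_distance(relative_profile(cons$parent), o), 0)
  expect_equal(profile_distance(relative_profile(cons$child), o), 0)

  sub <- simulate_trio("SUBFUNC", anc, cfg)
  expect_gt(profile_distance(relative_profile(sub$parent), o), 0)
  expect_gt(profile_distance(relative_profile(sub$child), o), 0)
  # the copies partition the ancestral row: their sum reconstructs it
  expect_equal(sub$parent + sub$child, anc, ignore_attr = TRUE)
  expect_equal(profile_distance(combine_profiles(sub$parent, sub$child), o), 0)
  # disjoint tissue sets
  expect_true(all(pmin(sub$parent, sub$child) == 0))

  neo <- simulate_trio("NEOFUNC_CHILD", anc, cfg)
  expect_equal(profile_distance(relative_profile(neo$parent), o), 0)
  expect_gt(profile_distance(relative_profile(neo$child), o), 0.3)

  spc <- simulate_trio("SPECIALIZED", anc, cfg)
  expect_true(which.max(spc$parent) != which.max(spc$child))
  expect_gt(profile_distance(combine_profiles(spc$parent, spc$child), o), 0)

  expect_error(simulate_trio("SUBFUNC", c(1, 0, 0), generator_config()),
               "< 2 expressed tissues")
})

test_that("the bundle is internally consistent and deterministic", {
  cfg <- generator_config(seed = 99, n_single_copy = 20, n_trios_per_class = 4,
                          n_background = 50)
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  expect_identical(b1$matrices, b2$matrices)
  expect_identical(b1$ground_truth, b2$ground_truth)

  # every trio gene exists in its species' matrix; validators pass
  issues <- validate_inputs(b1)
  expect_true(attr(issues, "ok"))

  # copy-number patterns recover the planted origin branch for every family
  tree <- ape::read.tree(text = b1$tree)
  for (f in unique(b1$copy_number$family_id)) {
    sub <- b1$copy_number[b1$copy_number$family_id == f, ]
    dd <- infer_duplication_branch(setNames(sub$copy_number, sub$species), tree)
    expect_true(dd$resolved)
    expect_equal(dd$origin_branch,
                 b1$ground_truth$planted_origin_branch[b1$ground_truth$pair_id == f])
  }

  # alignment flags recover the planted parent
  for (f in b1$ground_truth$pair_id) {
    fl <- b1$alignment_flags[b1$alignment_flags$family_id == f, ]
    pc <- assign_parent_child(fl$copy_id, as.logical(fl$aligns_to_outgroup))
    expect_true(pc$resolved)
    expect_equal(pc$parent,
                 b1$ground_truth$planted_parent[b1$ground_truth$pair_id == f])
  }

  # balanced design: n_trios_per_class trios of each class
  expect_equal(unname(table(b1$ground_truth$planted_class)),
               rep(4, 5), ignore_attr = TRUE)
})

test_that("bundles round-trip through the on-disk TSV dialect byte-identically", {
  cfg <- generator_config(seed = 8, n_single_copy = 10, n_trios_per_class = 2,
                          n_background = 20)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir = dir1)
  simulate_dataset(cfg, dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  back <- read_bundle(dir1)
  b <- simulate_dataset(cfg)
  expect_equal(back$matrices[order(names(back$matrices))],
               b$matrices[order(names(b$matrices))], tolerance = 1e-12)
  expect_equal(back$trios, b$trios)
  expect_equal(back$ks, b$ks)
})

test_that("baseline cutoffs are non-decreasing in ks under positive drift", {
  ksp <- data.frame(focal = "human",
                    outgroup = c("chimpanzee", "mouse", "platypus"),
                    ks = c(0.01, 0.5, 1.4))
  cfg <- generator_config(seed = 15, n_single_copy = 150, n_trios_per_class = 5,
                          drift_per_ks = 0.15, n_background = 100)
  cfg$ks_pairs <- ksp
  b <- simulate_dataset(cfg)
  res <- classify_dataset(b$matrices, b$trios, b$orthologs, normalize = "none")
  keys <- pairapply <- sapply(seq_len(nrow(ksp)), function(i)
    paste(sort(c(ksp$focal[i], ksp$outgroup[i])), collapse = "|"))
  cuts <- sapply(res$cutoffs[keys], function(x) x$cutoff)
  expect_true(all(diff(cuts) > 0))
})
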