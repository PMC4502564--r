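# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Two-sided Fisher exact p by enumerating all 2x2 tables with the observed
# margins and summing hypergeometric probabilities <= that of the observed
# table (with the customary relative-error guard for float comparison).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, c1, r1 + r2 - c1, r1)
  p_obs <- dhyper(a, c1, r1 + r2 - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled observations to the two samples.
oracle_mwu <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- combn(na + nb, na)
  us <- apply(sets, 2L, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(U = u_obs, p = p)
}

# Branch -> implied-leaf-state table for every non-root branch of a tree.
branch_state_table <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nodes <- setdiff(c(seq_len(ntip), (ntip + 1L):(ntip + tree$Nnode)), root)
  lapply(nodes, function(nd) {
    tips <- if (nd <= ntip) tree$tip.label[nd] else
      ape::extract.clade(tree, nd)$tip.label
    states <- ifelse(tree$tip.label %in% tips, 2L, 1L)
    names(states) <- tree$tip.label
    list(node = nd, states = states)
  })
}

# Single-gain placement oracle: try every branch as the origin of one
# duplication and keep those whose implied leaf states match the observed
# pattern (restricted to observed species). Resolved iff exactly one
# branch matches.
oracle_gain_placement <- function(pattern, tree, table = branch_state_table(tree)) {
  obs <- pattern[!is.na(pattern)]
  hits <- Filter(function(entry) {
    all(entry$states[names(obs)] == obs)
  }, table)
  if (length(hits) == 1L) {
    list(origin_branch = dupliclass::branch_label(tree, hits[[1L]]$node),
         resolved = TRUE)
  } else {
    list(origin_branch = "UNRESOLVED", resolved = FALSE)
  }
}

# Straight-line reimplementation of the classification stage (no
# normalization): filter -> shared tissues -> relative profiles ->
# distances -> median/SIQR cutoff -> rule table, one trio at a time.
oracle_classify <- function(matrices, trios, orthologs, threshold = 1,
                            multiplier = 1) {
  relp <- function(x) x / sum(x)
  ed <- function(p, q) sqrt(sum((p - q)^2))
  is_expr <- function(m, g) any(m[g, ] >= threshold)

  cutoffs <- list()
  for (key in names(orthologs)) {
    sp <- strsplit(key, "|", fixed = TRUE)[[1L]]
    m1 <- matrices[[sp[1L]]]; m2 <- matrices[[sp[2L]]]
    shared <- intersect(colnames(m1), colnames(m2))
    ds <- c()
    ot <- orthologs[[key]]
    for (i in seq_len(nrow(ot))) {
      g1 <- ot$gene_1[i]; g2 <- ot$gene_2[i]
      if (is_expr(m1, g1) && is_expr(m2, g2)) {
        r1 <- m1[g1, shared]; r2 <- m2[g2, shared]
        if (sum(r1) > 0 && sum(r2) > 0) ds <- c(ds, ed(relp(r1), relp(r2)))
      }
    }
    med <- median(ds)
    qs <- quantile(ds, c(0.25, 0.75), type = 7, names = FALSE)
    cutoffs[[key]] <- med + multiplier * (qs[2] - qs[1]) / 2
  }

  labels <- character(0); ids <- character(0)
  for (i in seq_len(nrow(trios))) {
    t <- trios[i, ]
    mf <- matrices[[t$focal_species]]; mo <- matrices[[t$outgroup_species]]
    if (!is_expr(mf, t$parent_gene) || !is_expr(mf, t$child_gene) ||
        !is_expr(mo, t$outgroup_gene)) next
    shared <- intersect(colnames(mf), colnames(mo))
    p <- mf[t$parent_gene, shared]; ch <- mf[t$child_gene, shared]
    o <- mo[t$outgroup_gene, shared]
    if (sum(p) <= 0 || sum(ch) <= 0 || sum(o) <= 0) next
    key <- paste(sort(c(t$focal_species, t$outgroup_species)), collapse = "|")
    cut <- cutoffs[[key]]
    e_po <- ed(relp(p), relp(o)); e_co <- ed(relp(ch), relp(o))
    e_pco <- ed(relp(p + ch), relp(o))
    lab <- if (e_po <= cut && e_co <= cut) "CONSERVED"
      else if (e_po > cut && e_co <= cut) "NEOFUNC_PARENT"
      else if (e_po <= cut && e_co > cut) "NEOFUNC_CHILD"
      else if (e_pco <= cut) "SUBFUNC" else "SPECIALIZED"
    ids <- c(ids, t$pair_id); labels <- c(labels, lab)
  }
  data.frame(pair_id = ids, label = labels, stringsAsFactors = FALSE)
}
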