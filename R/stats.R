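#' Proportion of functionally conserved genes per species pair
#'
#' For each (focal, outgroup) species pair, the fraction of classified
#' duplicate pairs labelled CONSERVED, joined with the pair's median
#' synonymous divergence K_s (input metadata). When baseline distances and
#' cutoffs are supplied, the single-copy analogue is also reported: the
#' fraction of single-copy ortholog pairs whose expression divergence
#' E_S1,S2 is at or below that pair's cutoff (functionally conserved
#' single-copy genes).
#'
#' @param records Classification records (data.frame with
#'   `focal_species`, `outgroup_species`, `label`), as produced by
#'   [classify_dataset()].
#' @param ks_table data.frame with `species_1`, `species_2`, `ks_median`
#'   and optionally `ka_median`.
#' @param baselines Optional named list of baseline distance vectors keyed
#'   by `"speciesA|speciesB"` (alphabetical).
#' @param cutoffs Optional named list of [divergence_cutoff()] objects with
#'   the same keys.
#' @return data.frame with one row per species pair: `species_pair`,
#'   `ks_median` (and `ka_median` if present), `n_total`, `n_conserved`,
#'   `proportion_conserved`, and, if baselines are given,
#'   `sc_proportion_conserved`.
#' @export
conserved_proportion_by_pair <- function(records, ks_table,
                                         baselines = NULL, cutoffs = NULL) {
  keys <- pair_key(records$focal_species, records$outgroup_species)
  ks_keys <- pair_key(ks_table$species_1, ks_table$species_2)
  out <- lapply(unique(keys), function(k) {
    sub <- records[keys == k, , drop = FALSE]
    i <- match(k, ks_keys)
    if (is.na(i)) stop("missing K_s for species pair ", k)
    row <- data.frame(
      species_pair = k,
      ks_median = ks_table$ks_median[i],
      n_total = nrow(sub),
      n_conserved = sum(sub$label == "CONSERVED"),
      stringsAsFactors = FALSE
    )
    if ("ka_median" %in% names(ks_table)) row$ka_median <- ks_table$ka_median[i]
    row$proportion_conserved <- row$n_conserved / row$n_total
    if (!is.null(baselines) && !is.null(cutoffs)) {
      row$sc_proportion_conserved <-
        mean(baselines[[k]] <= cutoffs[[k]]$cutoff)
    }
    row
  })
  do.call(rbind, out)
}

#' Ordinary least-squares regression with F and t tests
#'
#' Fits y = a + b x by least squares; the fit is tested with the
#' regression F statistic and the slope with a two-sided t test.
#'
#' @param x,y Numeric vectors of equal length (>= 2 points, x not
#'   constant). P-values require >= 3 points.
#' @return Object of class `regression_fit`: list with `slope`,
#'   `intercept`, `f_pvalue`, `slope_t_pvalue`, `n_points`.
#' @export
#' @examples
#' fit_linear_regression(c(0, 1, 2), c(1, 3, 5))  # slope 2, intercept 1
fit_linear_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2L) stop("at least two points required")
  if (diff(range(x)) == 0) stop("x is constant")
  fit <- lm(y ~ x)
  # an exact fit makes summary.lm warn that p-values are unreliable; the
  # degenerate cases are handled below, so the warning is noise here
  sm <- suppressWarnings(summary(fit))
  f_p <- slope_p <- NA_real_
  if (length(x) >= 3L) {
    fs <- sm$fstatistic
    if (!is.null(fs)) f_p <- unname(pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
    ct <- coef(sm)
    if (nrow(ct) == 2L && ncol(ct) == 4L) slope_p <- ct["x", 4L]
  }
  structure(
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         f_pvalue = f_p, slope_t_pvalue = unname(slope_p),
         n_points = length(x), residuals = unname(fit$residuals)),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "Least-squares fit (n = %d): slope %.6g (t p = %.4g), intercept %.6g, F p = %.4g\n",
    x$n_points, x$slope, x$slope_t_pvalue, x$intercept, x$f_pvalue))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Compares two distributions by ranks. The p-value is exact (full
#' enumeration of rank assignments) when both samples have at most
#' `exact_max` observations and there are no ties; otherwise the normal
#' approximation with tie correction is used.
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @param exact_max Largest per-sample size for the exact p-value
#'   (default 10).
#' @return List with `U` (number of (a, b) pairs with a > b, i.e. the W
#'   statistic for `sample_a`), `p_value` (two-sided) and `method`.
#' @export
mann_whitney_u <- function(sample_a, sample_b, exact_max = 10) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (!length(a) || !length(b)) stop("empty sample")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact)
  )
  p <- wt$p.value
  # degenerate case (e.g. all observations tied): no evidence of difference
  if (is.na(p)) p <- 1
  list(U = unname(wt$statistic), p_value = min(1, p),
       method = if (exact) "exact" else "normal approximation")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all
#' tables with the same margins whose probability does not exceed that of
#' the observed table; the conditional maximum-likelihood odds ratio is
#' reported.
#'
#' @param table 2x2 matrix of non-negative integer counts with at least
#'   one nonzero entry.
#' @return List with `odds_ratio` and `p_value`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p_value  # 1/3
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0)) stop("negative entries")
  if (all(tab == 0)) stop("at least one nonzero entry required")
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Bonferroni correction
#'
#' Adjusted p-values are min(1, p * m), with m the number of comparisons
#' in the family (defaults to the number of p-values supplied).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param m Family size (default `length(pvalues)`).
#' @return Numeric vector of adjusted p-values.
#' @export
bonferroni <- function(pvalues, m = length(pvalues)) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < 1) stop("family size must be >= 1")
  pmin(1, p * m)
}

# Significance stars at adjusted 0.05 / 0.01 / 0.001.
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Highest-expressed-tissue enrichment between gene groups
#'
#' For every tissue and every unordered pair of gene groups, tests whether
#' the proportion of genes with highest relative expression in that tissue
#' differs between the groups, using a 2x2 Fisher's exact test (in-tissue
#' vs not, group A vs group B). The Bonferroni family is all tissue x
#' group-pair tests of the analysis; stars mark adjusted p < 0.05 / 0.01 /
#' 0.001.
#'
#' @param tables Named list of named integer vectors: per group, counts of
#'   genes whose top tissue is each tissue. All groups must share the same
#'   tissue vocabulary and have at least one gene.
#' @return data.frame with one row per tissue x group pair: `tissue`,
#'   `group_a`, `group_b`, counts `a`, `b`, `c`, `d`, `odds_ratio`, `p`,
#'   `p_adjusted`, `stars`.
#' @export
highest_tissue_enrichment <- function(tables) {
  if (length(tables) < 2L) stop("at least two groups required")
  tissues <- names(tables[[1L]])
  for (g in names(tables)) {
    if (!identical(names(tables[[g]]), tissues)) {
      stop("groups do not share a tissue vocabulary")
    }
    if (sum(tables[[g]]) == 0) stop("group with zero genes: ", g)
  }
  groups <- names(tables)
  idx <- combn(length(groups), 2L)
  rows <- list()
  for (t in tissues) {
    for (j in seq_len(ncol(idx))) {
      ga <- groups[idx[1L, j]]; gb <- groups[idx[2L, j]]
      a <- tables[[ga]][[t]]; b <- sum(tables[[ga]]) - a
      c_ <- tables[[gb]][[t]]; d <- sum(tables[[gb]]) - c_
      ft <- fisher_exact_2x2(matrix(c(a, c_, b, d), 2L))
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = t, group_a = ga, group_b = gb,
        a = a, b = b, c = c_, d = d,
        odds_ratio = ft$odds_ratio, p = ft$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p, m = nrow(out))
  out$stars <- significance_stars(out$p_adjusted)
  out
}

#' Tissue-specificity comparison of gene groups against single-copy genes
#'
#' Each group's distribution of tissue specificities (highest relative
#' expression levels) is compared to the pooled single-copy distribution
#' with a two-sided Mann-Whitney U test; the Bonferroni family is the set
#' of group comparisons.
#'
#' @param groups Named list of numeric vectors of tissue-specificity
#'   scores (one vector per class x role group); all non-empty.
#' @param single_copy Numeric vector of single-copy gene specificities.
#' @return data.frame with `group`, `n`, `median_specificity`,
#'   `single_copy_median`, `U`, `p`, `p_adjusted`, `stars`.
#' @export
specificity_comparison <- function(groups, single_copy) {
  if (!length(single_copy)) stop("empty single-copy reference")
  rows <- lapply(names(groups), function(g) {
    if (!length(groups[[g]])) stop("empty group: ", g)
    mw <- mann_whitney_u(groups[[g]], single_copy)
    data.frame(group = g, n = length(groups[[g]]),
               median_specificity = median(groups[[g]]),
               single_copy_median = median(single_copy),
               U = mw$U, p = mw$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p, m = nrow(out))
  out$stars <- significance_stars(out$p_adjusted)
  out
}
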