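#' Retention class labels
#'
#' The five mutually exclusive retention classes assigned by
#' [classify_trio()].
#'
#' @return Character vector of the five class labels.
#' @export
retention_classes <- function() {
  c("CONSERVED", "NEOFUNC_PARENT", "NEOFUNC_CHILD", "SUBFUNC", "SPECIALIZED")
}

#' Euclidean distance between two relative expression profiles
#'
#' For proportion vectors the distance lies in \[0, sqrt(2)\]: 0 for
#' identical profiles, sqrt(2) for profiles concentrated in disjoint
#' tissues.
#'
#' @param p,q Relative expression profiles over the same tissues, in the
#'   same order (names, if present, must match).
#' @return Non-negative scalar distance.
#' @export
#' @examples
#' profile_distance(c(0.5, 0.5, 0), c(0.25, 0.75, 0))  # sqrt(0.125)
profile_distance <- function(p, q) {
  if (length(p) != length(q)) stop("mismatched tissue sets")
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q))) {
    stop("mismatched tissue sets")
  }
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}

#' Baseline expression divergence of single-copy ortholog pairs
#'
#' Computes the Euclidean distance between relative expression profiles of
#' single-copy genes present in both species of a pair (E_S1,S2). Only
#' ortholog pairs expressed in both species (at `threshold`) contribute;
#' profiles are restricted to the species' shared tissues and renormalized
#' before the distance is taken.
#'
#' @param ortholog_pairs data.frame with columns `gene_1`, `gene_2` (gene
#'   identifiers in species 1 and species 2).
#' @param matrix_1,matrix_2 Absolute expression matrices (normally quantile
#'   normalized) of the two species, gene ids as row names.
#' @param threshold Expression threshold passed to [filter_expressed()].
#' @return Numeric vector of distances, one per qualifying ortholog pair,
#'   in input order; names are `gene_1` identifiers.
#' @export
baseline_distances <- function(ortholog_pairs, matrix_1, matrix_2,
                               threshold = 1) {
  stopifnot(all(c("gene_1", "gene_2") %in% names(ortholog_pairs)))
  shared <- order_tissues(intersect(colnames(matrix_1), colnames(matrix_2)))
  if (!length(shared)) stop("no shared tissues")
  expr1 <- filter_expressed(matrix_1, threshold)
  expr2 <- filter_expressed(matrix_2, threshold)
  keep <- ortholog_pairs$gene_1 %in% expr1 & ortholog_pairs$gene_2 %in% expr2
  op <- ortholog_pairs[keep, , drop = FALSE]
  if (!nrow(op)) stop("empty baseline")
  m1 <- matrix_1[op$gene_1, shared, drop = FALSE]
  m2 <- matrix_2[op$gene_2, shared, drop = FALSE]
  # restriction can zero out a row if a gene is expressed only in
  # non-shared tissues; such pairs are dropped
  ok <- rowSums(m1) > 0 & rowSums(m2) > 0
  if (!any(ok)) stop("empty baseline")
  p1 <- relative_profiles(m1[ok, , drop = FALSE])
  p2 <- relative_profiles(m2[ok, , drop = FALSE])
  d <- sqrt(rowSums((p1 - p2)^2))
  names(d) <- op$gene_1[ok]
  d
}

#' Divergence cutoff from a baseline distance distribution
#'
#' The cutoff for declaring expression divergence is the median of the
#' single-copy baseline distances plus (a multiple of) their
#' semi-interquartile range, SIQR = (Q3 - Q1) / 2 -- a criterion robust to
#' outliers and to differences in distribution shape between species pairs.
#' Quartiles use linear interpolation between order statistics by default
#' (R quantile type 7); the convention is configurable because the
#' subfunctionalized class is sensitive to the cutoff.
#'
#' @param distances Non-empty numeric vector of baseline distances.
#' @param multiplier Multiplier m of the SIQR term: cutoff = median +
#'   m * SIQR (default 1).
#' @param quantile_type Quantile algorithm (see [stats::quantile()];
#'   default 7).
#' @return Object of class `divergence_cutoff`: list with `median`, `q1`,
#'   `q3`, `siqr`, `multiplier`, `cutoff`, `n`.
#' @export
#' @examples
#' divergence_cutoff(c(0.1, 0.2, 0.3, 0.4, 0.5))$cutoff  # 0.4
divergence_cutoff <- function(distances, multiplier = 1, quantile_type = 7) {
  d <- as.numeric(distances)
  if (!length(d)) stop("empty baseline distance list")
  if (anyNA(d) || any(d < 0)) stop("distances must be non-negative")
  med <- median(d)
  qs <- unname(quantile(d, c(0.25, 0.75), type = quantile_type, names = FALSE))
  siqr <- (qs[2L] - qs[1L]) / 2
  structure(
    list(median = med, q1 = qs[1L], q3 = qs[2L], siqr = siqr,
         multiplier = multiplier, cutoff = med + multiplier * siqr,
         n = length(d)),
    class = "divergence_cutoff"
  )
}

#' @export
print.divergence_cutoff <- function(x, ...) {
  cat(sprintf(
    "Divergence cutoff: %.6g (median %.6g + %g x SIQR %.6g; n = %d)\n",
    x$cutoff, x$median, x$multiplier, x$siqr, x$n))
  invisible(x)
}

#' Classify a duplicate-gene trio from its profile distances
#'
#' Applies the five-way rule table to the distances between the parent (P),
#' child (C) and combined (P+C) relative expression profiles and that of
#' the single-copy outgroup ortholog (O), with E the Euclidean distance and
#' `cutoff` the species-pair divergence cutoff standing in for typical
#' single-copy divergence E_S1,S2:
#'
#' * `CONSERVED`: E_P,O <= cutoff and E_C,O <= cutoff
#' * `NEOFUNC_PARENT`: E_P,O > cutoff and E_C,O <= cutoff
#' * `NEOFUNC_CHILD`: E_P,O <= cutoff and E_C,O > cutoff
#' * `SUBFUNC`: E_P,O > cutoff, E_C,O > cutoff, E_P+C,O <= cutoff
#' * `SPECIALIZED`: E_P,O > cutoff, E_C,O > cutoff, E_P+C,O > cutoff
#'
#' Exactly one label applies to any input; distances equal to the cutoff
#' count as NOT diverged. All arguments are vectorized.
#'
#' @param e_po,e_co,e_pco Non-negative distances E_P,O, E_C,O, E_P+C,O.
#' @param cutoff Divergence cutoff (scalar or vector recycled to length).
#' @return Character vector of class labels (see [retention_classes()]).
#' @export
classify_trio <- function(e_po, e_co, e_pco, cutoff) {
  n <- max(length(e_po), length(e_co), length(e_pco), length(cutoff))
  e_po <- rep_len(as.numeric(e_po), n)
  e_co <- rep_len(as.numeric(e_co), n)
  e_pco <- rep_len(as.numeric(e_pco), n)
  cutoff <- rep_len(as.numeric(cutoff), n)
  if (anyNA(c(e_po, e_co, e_pco)) || any(c(e_po, e_co, e_pco) < 0)) {
    stop("distances must be non-negative")
  }
  if (any(cutoff < 0)) stop("cutoff must be non-negative")
  p_div <- e_po > cutoff
  c_div <- e_co > cutoff
  pc_div <- e_pco > cutoff
  ifelse(!p_div & !c_div, "CONSERVED",
  ifelse(p_div & !c_div, "NEOFUNC_PARENT",
  ifelse(!p_div & c_div, "NEOFUNC_CHILD",
  ifelse(!pc_div, "SUBFUNC", "SPECIALIZED"))))
}

# Internal: compute per-trio distances (no classification yet).
# Returns records data.frame (with NA distances for excluded trios removed)
# and exclusions data.frame.
trio_distances <- function(trios, matrices, expressed, threshold = 1) {
  req <- c("pair_id", "focal_species", "parent_gene", "child_gene",
           "outgroup_species", "outgroup_gene")
  stopifnot(all(req %in% names(trios)))
  n <- nrow(trios)
  e_po <- e_co <- e_pco <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    t <- trios[i, ]
    mf <- matrices[[t$focal_species]]
    mo <- matrices[[t$outgroup_species]]
    if (is.null(mf) || is.null(mo)) { reason[i] <- "missing species matrix"; next }
    if (!(t$parent_gene %in% rownames(mf)) ||
        !(t$child_gene %in% rownames(mf))) { reason[i] <- "gene missing from matrix"; next }
    if (!(t$outgroup_gene %in% rownames(mo))) { reason[i] <- "gene missing from matrix"; next }
    if (!(t$parent_gene %in% expressed[[t$focal_species]])) { reason[i] <- "parent unexpressed"; next }
    if (!(t$child_gene %in% expressed[[t$focal_species]])) { reason[i] <- "child unexpressed"; next }
    if (!(t$outgroup_gene %in% expressed[[t$outgroup_species]])) { reason[i] <- "outgroup unexpressed"; next }
    shared <- order_tissues(intersect(colnames(mf), colnames(mo)))
    if (!length(shared)) { reason[i] <- "no shared tissues"; next }
    p_row <- mf[t$parent_gene, shared]
    c_row <- mf[t$child_gene, shared]
    o_row <- mo[t$outgroup_gene, shared]
    if (sum(p_row) <= 0 || sum(c_row) <= 0 || sum(o_row) <= 0) {
      reason[i] <- "zero expression on shared tissues"; next
    }
    o_prof <- relative_profile(o_row)
    e_po[i] <- profile_distance(relative_profile(p_row), o_prof)
    e_co[i] <- profile_distance(relative_profile(c_row), o_prof)
    e_pco[i] <- profile_distance(combine_profiles(p_row, c_row), o_prof)
  }
  keep <- is.na(reason)
  list(
    records = data.frame(
      pair_id = trios$pair_id[keep],
      focal_species = trios$focal_species[keep],
      outgroup_species = trios$outgroup_species[keep],
      e_po = e_po[keep], e_co = e_co[keep], e_pco = e_pco[keep],
      stringsAsFactors = FALSE
    ),
    exclusions = data.frame(
      pair_id = trios$pair_id[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}

# Internal: unordered species-pair key.
pair_key <- function(s1, s2) {
  paste(pmin(s1, s2), pmax(s1, s2), sep = "|")
}

#' Classify a full dataset of duplicate-gene trios
#'
#' Runs the complete classification stage: (optional) joint quantile
#' normalization of all species' matrices, expression filtering, baseline
#' distance distributions and divergence cutoffs per (focal, outgroup)
#' species pair, per-trio distance computation on shared tissues, and the
#' five-way rule table. Trios whose parent, child or outgroup gene fails
#' the expression filter are dropped with a logged reason.
#'
#' @param matrices Named list of absolute expression matrices, one per
#'   species.
#' @param trios data.frame with columns `pair_id`, `focal_species`,
#'   `parent_gene`, `child_gene`, `outgroup_species`, `outgroup_gene`.
#' @param orthologs Named list of single-copy ortholog tables (columns
#'   `gene_1`, `gene_2`, genes of the alphabetically first species of the
#'   pair in `gene_1`), keyed by `pair_key(sp1, sp2)` i.e.
#'   `"speciesA|speciesB"` with species sorted alphabetically.
#' @param threshold Expression threshold (default 1).
#' @param siqr_multiplier Multiplier of the SIQR term in the cutoff
#'   (default 1).
#' @param quantile_type Quartile convention for the cutoff (default 7).
#' @param normalize `"joint"` (default) quantile-normalizes all matrices in
#'   one pool, `"per_matrix"` per species, `"none"` skips normalization.
#' @return List of class `classification_result`: `records` (data.frame
#'   with `pair_id`, distances, `cutoff_used`, `label`), `exclusions`
#'   (data.frame `pair_id`, `reason`), `cutoffs` (named list of
#'   [divergence_cutoff()] objects per species pair), `baselines` (named
#'   list of baseline distance vectors).
#' @export
classify_dataset <- function(matrices, trios, orthologs, threshold = 1,
                             siqr_multiplier = 1, quantile_type = 7,
                             normalize = c("joint", "per_matrix", "none")) {
  normalize <- match.arg(normalize)
  if (normalize != "none") {
    matrices <- quantile_normalize(matrices, pool = if (normalize == "joint")
      "joint" else "per_matrix")
  }
  expressed <- lapply(matrices, filter_expressed, threshold = threshold)

  keys <- unique(pair_key(trios$focal_species, trios$outgroup_species))
  baselines <- list()
  cutoffs <- list()
  for (k in keys) {
    if (is.null(orthologs[[k]])) stop("missing ortholog table for species pair ", k)
    sp <- strsplit(k, "|", fixed = TRUE)[[1L]]
    if (is.null(matrices[[sp[1L]]]) || is.null(matrices[[sp[2L]]])) {
      stop("missing expression matrix for species pair ", k)
    }
    baselines[[k]] <- baseline_distances(orthologs[[k]], matrices[[sp[1L]]],
                                         matrices[[sp[2L]]], threshold)
    cutoffs[[k]] <- divergence_cutoff(baselines[[k]], siqr_multiplier,
                                      quantile_type)
  }

  td <- trio_distances(trios, matrices, expressed, threshold)
  rec <- td$records
  if (nrow(rec)) {
    rec$cutoff_used <- vapply(
      pair_key(rec$focal_species, rec$outgroup_species),
      function(k) cutoffs[[k]]$cutoff, numeric(1L))
    rec$label <- classify_trio(rec$e_po, rec$e_co, rec$e_pco, rec$cutoff_used)
  } else {
    rec$cutoff_used <- numeric(0)
    rec$label <- character(0)
  }
  structure(
    list(records = rec, exclusions = td$exclusions, cutoffs = cutoffs,
         baselines = baselines, matrices = matrices, threshold = threshold),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat("Duplicate-gene retention classification\n")
  cat("  classified trios:", nrow(x$records),
      " excluded:", nrow(x$exclusions), "\n")
  if (nrow(x$records)) {
    tab <- table(factor(x$records$label, levels = retention_classes()))
    for (cl in names(tab)) cat(sprintf("  %-15s %d\n", cl, tab[[cl]]))
  }
  invisible(x)
}

#' Class counts under a range of cutoff stringencies
#'
#' Reclassifies an already-computed dataset with the divergence cutoff set
#' to median + m * SIQR for each multiplier m, reporting the five class
#' counts per multiplier. More stringent (larger) cutoffs can only move
#' labels toward CONSERVED, so the conserved count is non-decreasing in m;
#' the total count is constant across rows.
#'
#' @param result A `classification_result` from [classify_dataset()].
#' @param multipliers Positive SIQR multipliers to explore.
#' @return data.frame with columns `multiplier`, one column per class, and
#'   `total`.
#' @export
cutoff_sensitivity <- function(result, multipliers = c(0.5, 1, 1.5, 2)) {
  stopifnot(inherits(result, "classification_result"))
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  rec <- result$records
  keys <- pair_key(rec$focal_species, rec$outgroup_species)
  out <- lapply(multipliers, function(m) {
    cut_m <- vapply(result$cutoffs, function(co) co$median + m * co$siqr,
                    numeric(1L))
    labels <- classify_trio(rec$e_po, rec$e_co, rec$e_pco, cut_m[keys])
    counts <- table(factor(labels, levels = retention_classes()))
    c(multiplier = m, as.list(counts), total = length(labels))
  })
  do.call(rbind.data.frame, out)
}
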