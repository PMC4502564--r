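#' Quantile-normalize one or more expression matrices
#'
#' Every column (tissue sample) of every matrix is treated as one sample and
#' all samples are pooled into a single normalization set: after
#' normalization the sorted values of every sample are identical, equal to
#' the per-rank mean of the input samples' order statistics. Ties within a
#' sample receive the mean of the reference values at their tied ranks.
#' Gene and tissue ordering is preserved.
#'
#' When samples differ in length (matrices with different gene counts share
#' one pool), each sample is mapped through the reference quantile function
#' by linear interpolation at probabilities (i-1)/(n-1); for equal-length
#' samples this reduces exactly to the per-rank mean and the operation is
#' idempotent.
#'
#' @param matrices A single numeric matrix (genes x tissues) or a list of
#'   such matrices (typically one per species), with row names giving gene
#'   identifiers and column names giving tissue labels.
#' @param pool `"joint"` (default) pools all samples of all matrices into
#'   one normalization set; `"per_matrix"` normalizes each matrix's columns
#'   against each other only.
#' @return An object of the same shape as the input (matrix or list of
#'   matrices) with normalized values.
#' @export
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 6, 8))
#' quantile_normalize(m)  # both columns become (2.5, 4, 5.5)
quantile_normalize <- function(matrices, pool = c("joint", "per_matrix")) {
  pool <- match.arg(pool)
  single <- is.matrix(matrices)
  mats <- if (single) list(matrices) else matrices
  if (!length(mats)) stop("no samples")
  for (m in mats) {
    if (!is.matrix(m) || !is.numeric(m) || nrow(m) == 0L || ncol(m) == 0L) {
      stop("no samples")
    }
    if (anyNA(m) || any(!is.finite(m))) stop("non-finite expression value")
    if (any(m < 0)) stop("negative expression")
  }
  if (pool == "per_matrix") {
    out <- lapply(mats, function(m) qn_pool(list(m))[[1L]])
  } else {
    out <- qn_pool(mats)
  }
  if (single) out[[1L]] else out
}

# Core pooled quantile normalization over a list of matrices.
qn_pool <- function(mats) {
  samples <- list()
  for (k in seq_along(mats)) {
    for (j in seq_len(ncol(mats[[k]]))) {
      samples[[length(samples) + 1L]] <- mats[[k]][, j]
    }
  }
  lens <- vapply(samples, length, 1L)
  L <- max(lens)
  probs <- if (L == 1L) 0.5 else (seq_len(L) - 1) / (L - 1)
  # reference: per-rank mean of type-7 quantiles of each sample; for
  # full-length samples the quantiles are the exact order statistics
  ref <- rowMeans(vapply(
    samples,
    function(s) {
      if (length(s) == L) sort(s)
      else unname(quantile(s, probs = probs, type = 7, names = FALSE))
    },
    numeric(L)
  ))
  ref <- sort(ref)  # guard against numeric jitter; ref is monotone already
  norm_one <- function(x) {
    n <- length(x)
    v <- if (n == L) {
      ref
    } else if (n == 1L) {
      # single value maps to the reference median
      unname(quantile(ref, 0.5, type = 7, names = FALSE))
    } else {
      unname(quantile(ref, probs = (seq_len(n) - 1) / (n - 1), type = 7,
                      names = FALSE))
    }
    assigned <- v[rank(x, ties.method = "first")]
    # ties share the mean of their assigned reference values
    if (anyDuplicated(x)) assigned <- stats::ave(assigned, x, FUN = mean)
    assigned
  }
  i <- 0L
  lapply(mats, function(m) {
    for (j in seq_len(ncol(m))) {
      i <<- i + 1L
      m[, j] <- norm_one(samples[[i]])
    }
    m
  })
}

#' Identify expressed genes
#'
#' A gene is expressed if its value is at or above `threshold` (FPKM-like
#' units, default 1) in at least one tissue; the boundary is inclusive.
#'
#' @param matrix Numeric gene x tissue matrix with gene identifiers as row
#'   names.
#' @param threshold Positive expression threshold (default 1).
#' @return Character vector of expressed gene identifiers (possibly empty),
#'   in matrix row order.
#' @export
filter_expressed <- function(matrix, threshold = 1) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number")
  }
  keep <- apply(matrix, 1L, function(x) any(x >= threshold))
  rownames(matrix)[keep]
}

#' Convert an absolute expression row to a relative expression profile
#'
#' Each tissue's value is divided by the row total, giving the proportion of
#' the gene's total expression contributed by that tissue. The resulting
#' profile sums to 1 and is invariant to positive rescaling of the input.
#'
#' @param absolute_row Numeric vector of non-negative absolute expression
#'   values, optionally named by tissue.
#' @param tissue_labels Optional tissue labels (defaults to
#'   `names(absolute_row)`).
#' @return Named numeric vector of proportions summing to 1.
#' @export
#' @examples
#' relative_profile(c(10, 30, 60))  # 0.1 0.3 0.6
relative_profile <- function(absolute_row, tissue_labels = names(absolute_row)) {
  x <- as.numeric(absolute_row)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite expression value")
  if (any(x < 0)) stop("negative expression")
  total <- sum(x)
  if (total <= 0) stop("zero total expression")
  p <- x / total
  if (!is.null(tissue_labels)) names(p) <- tissue_labels
  p
}

#' Relative profiles for every row of a matrix
#'
#' @param matrix Numeric gene x tissue matrix; every row must have positive
#'   total expression (apply [filter_expressed()] first).
#' @return Matrix of the same shape whose rows each sum to 1.
#' @export
relative_profiles <- function(matrix) {
  totals <- rowSums(matrix)
  if (any(totals <= 0)) {
    stop("zero total expression for gene(s): ",
         paste(rownames(matrix)[totals <= 0], collapse = ", "))
  }
  sweep(matrix, 1L, totals, "/")
}

#' Combined parent-child expression profile
#'
#' The per-tissue absolute expression of the two copies is summed -- the
#' total expression output of the pair, the natural proxy for the ancestral
#' single gene's output -- and converted to a relative profile.
#'
#' @param parent_row,child_row Absolute expression rows over the same
#'   tissues, in the same order.
#' @param tissue_labels Optional tissue labels.
#' @return Named numeric vector of proportions summing to 1.
#' @export
combine_profiles <- function(parent_row, child_row,
                             tissue_labels = names(parent_row)) {
  if (length(parent_row) != length(child_row)) {
    stop("parent and child rows cover different tissue sets")
  }
  if (!is.null(names(parent_row)) && !is.null(names(child_row)) &&
      !identical(names(parent_row), names(child_row))) {
    stop("parent and child rows cover different tissue sets")
  }
  relative_profile(as.numeric(parent_row) + as.numeric(child_row),
                   tissue_labels)
}

#' Tissue specificity of a relative expression profile
#'
#' The highest relative expression level of a gene measures its tissue
#' specificity: 1 for a single-tissue gene, 1/n for a uniformly expressed
#' gene over n tissues. Argmax ties are broken by the canonical tissue
#' order (first tissue wins).
#'
#' @param profile Relative expression profile (named numeric vector summing
#'   to 1, as from [relative_profile()]).
#' @return List with `max_proportion` and `top_tissue`.
#' @export
tissue_specificity <- function(profile) {
  i <- which.max(profile)  # first maximum under the input (canonical) order
  list(max_proportion = unname(profile[i]),
       top_tissue = if (!is.null(names(profile))) names(profile)[i] else i)
}

#' Tissue-specificity table for a profile matrix
#'
#' @param profile_matrix Matrix of relative profiles (rows sum to 1),
#'   columns in canonical tissue order.
#' @return data.frame with columns `gene_id`, `max_proportion`,
#'   `top_tissue`.
#' @export
tissue_specificity_table <- function(profile_matrix) {
  idx <- apply(profile_matrix, 1L, which.max)
  data.frame(
    gene_id = rownames(profile_matrix),
    max_proportion = profile_matrix[cbind(seq_len(nrow(profile_matrix)), idx)],
    top_tissue = colnames(profile_matrix)[idx],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Restrict two absolute expression rows to their shared tissues
#'
#' Cross-species comparisons require a common tissue set: both rows are
#' restricted to the ordered intersection of their tissue labels (canonical
#' order) and relative profiles must then be recomputed on the restricted
#' rows.
#'
#' @param row_a,row_b Absolute expression rows.
#' @param labels_a,labels_b Tissue labels of the two rows (default: names).
#' @return List with `a`, `b` (restricted absolute rows) and `tissues`
#'   (the shared ordered label vector).
#' @export
restrict_to_shared_tissues <- function(row_a, row_b,
                                       labels_a = names(row_a),
                                       labels_b = names(row_b)) {
  shared <- order_tissues(intersect(labels_a, labels_b))
  if (!length(shared)) stop("no shared tissues")
  a <- as.numeric(row_a)[match(shared, labels_a)]
  b <- as.numeric(row_b)[match(shared, labels_b)]
  names(a) <- shared
  names(b) <- shared
  list(a = a, b = b, tissues = shared)
}
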