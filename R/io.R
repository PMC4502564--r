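#' Read a per-species expression matrix from TSV
#'
#' Expected dialect: tab-separated, first column `gene_id`, header row of
#' tissue labels, numeric body. Gzip-compressed files are read
#' transparently.
#'
#' @param path Path to the TSV (or .tsv.gz) file.
#' @return Numeric gene x tissue matrix with gene ids as row names.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") stop("first column must be gene_id: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- df$gene_id
  m
}

#' Write an expression matrix to TSV
#'
#' @param matrix Numeric gene x tissue matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# File-name conventions of a bundle directory.
bundle_paths <- function(dir) {
  list(
    tree = file.path(dir, "tree.nwk"),
    trios = file.path(dir, "trios.tsv"),
    copy_number = file.path(dir, "copy_number.tsv"),
    alignment_flags = file.path(dir, "alignment_flags.tsv"),
    ks = file.path(dir, "ks.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv"),
    config = file.path(dir, "config.json")
  )
}

#' Write a data bundle to a directory
#'
#' Writes the TSV/Newick/JSON dialect consumed by [read_bundle()] and
#' [run_pipeline()]: `expression_<species>.tsv` per species,
#' `orthologs_<sp1>__<sp2>.tsv` per species pair, `trios.tsv`,
#' `copy_number.tsv`, `alignment_flags.tsv`, `ks.tsv`, `tree.nwk`, plus
#' `ground_truth.tsv` and `config.json` when present.
#'
#' @param bundle A `dup_bundle` (or compatible list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bp <- bundle_paths(dir)
  for (sp in names(bundle$matrices)) {
    write_expression_matrix(bundle$matrices[[sp]],
                            file.path(dir, paste0("expression_", sp, ".tsv")))
  }
  for (key in names(bundle$orthologs)) {
    sp <- strsplit(key, "|", fixed = TRUE)[[1L]]
    write_tsv(bundle$orthologs[[key]],
              file.path(dir, paste0("orthologs_", sp[1L], "__", sp[2L], ".tsv")))
  }
  write_tsv(bundle$trios, bp$trios)
  write_tsv(bundle$copy_number, bp$copy_number)
  write_tsv(bundle$alignment_flags, bp$alignment_flags)
  write_tsv(bundle$ks, bp$ks)
  writeLines(bundle$tree, bp$tree)
  if (!is.null(bundle$ground_truth)) write_tsv(bundle$ground_truth, bp$ground_truth)
  if (!is.null(bundle$config)) {
    cfg <- bundle$config
    cfg$ks_pairs <- as.list(cfg$ks_pairs)
    jsonlite::write_json(unclass(cfg), bp$config, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a data bundle from a directory
#'
#' @param dir Directory written by [write_bundle()] (or assembled by hand
#'   in the same dialect).
#' @return A `dup_bundle` list (without a generator config).
#' @export
read_bundle <- function(dir) {
  bp <- bundle_paths(dir)
  expr_files <- list.files(dir, pattern = "^expression_.*\\.tsv(\\.gz)?$",
                           full.names = TRUE)
  matrices <- list()
  for (f in expr_files) {
    sp <- sub("^expression_", "", sub("\\.tsv(\\.gz)?$", "", basename(f)))
    matrices[[sp]] <- read_expression_matrix(f)
  }
  orth_files <- list.files(dir, pattern = "^orthologs_.*\\.tsv(\\.gz)?$",
                           full.names = TRUE)
  orthologs <- list()
  for (f in orth_files) {
    nm <- sub("^orthologs_", "", sub("\\.tsv(\\.gz)?$", "", basename(f)))
    sp <- strsplit(nm, "__", fixed = TRUE)[[1L]]
    orthologs[[pair_key(sp[1L], sp[2L])]] <- read_tsv(f)
  }
  structure(
    list(
      matrices = matrices,
      orthologs = orthologs,
      trios = if (file.exists(bp$trios)) read_tsv(bp$trios),
      copy_number = if (file.exists(bp$copy_number)) read_tsv(bp$copy_number),
      alignment_flags = if (file.exists(bp$alignment_flags))
        read_tsv(bp$alignment_flags),
      ks = if (file.exists(bp$ks)) read_tsv(bp$ks),
      ground_truth = if (file.exists(bp$ground_truth)) read_tsv(bp$ground_truth),
      tree = if (file.exists(bp$tree)) paste(readLines(bp$tree), collapse = "\n"),
      config = NULL
    ),
    class = "dup_bundle"
  )
}

#' Validate an input bundle
#'
#' Checks TSV schemas, the tissue vocabulary, species-tree leaf
#' consistency, and the presence of every trio gene in its species'
#' matrix. Issues are classified as `"fatal"` (the pipeline cannot run) or
#' `"warning"` (non-fatal).
#'
#' @param input A bundle directory path or a `dup_bundle` list.
#' @return data.frame with columns `severity` and `message` (zero rows if
#'   the bundle is clean), with attribute `ok` (no fatal issues).
#' @export
validate_inputs <- function(input) {
  issues <- list()
  note <- function(severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, message = message, stringsAsFactors = FALSE)
  }
  bundle <- tryCatch(
    if (is.character(input)) read_bundle(input) else input,
    error = function(e) {
      note("fatal", paste("unreadable bundle:", conditionMessage(e)))
      NULL
    }
  )
  if (!is.null(bundle)) {
    if (!length(bundle$matrices)) note("fatal", "no expression matrices")
    for (sp in names(bundle$matrices)) {
      m <- bundle$matrices[[sp]]
      bad <- setdiff(colnames(m), canonical_tissues())
      if (length(bad)) {
        note("fatal", paste0("unknown tissue label(s) in ", sp, ": ",
                             paste(bad, collapse = ", ")))
      }
      if (any(m < 0)) note("fatal", paste0("negative expression in ", sp))
      if (anyDuplicated(rownames(m))) {
        note("fatal", paste0("duplicated gene ids in ", sp))
      }
    }
    tree <- tryCatch(ape::read.tree(text = bundle$tree), error = function(e) NULL)
    if (is.null(tree)) {
      note("fatal", "species tree missing or unparseable")
    } else {
      if (!is.null(bundle$copy_number)) {
        bad <- setdiff(unique(bundle$copy_number$species), tree$tip.label)
        if (length(bad)) {
          note("fatal", paste0("copy-number species not on tree: ",
                               paste(bad, collapse = ", ")))
        }
      }
      sp_mat <- setdiff(names(bundle$matrices), tree$tip.label)
      if (length(sp_mat)) {
        note("warning", paste0("expression matrices for species not on tree: ",
                               paste(sp_mat, collapse = ", ")))
      }
    }
    if (is.null(bundle$trios)) {
      note("fatal", "trios.tsv missing")
    } else {
      req <- c("pair_id", "focal_species", "parent_gene", "child_gene",
               "outgroup_species", "outgroup_gene")
      miss <- setdiff(req, names(bundle$trios))
      if (length(miss)) {
        note("fatal", paste0("trios.tsv missing column(s): ",
                             paste(miss, collapse = ", ")))
      } else {
        for (i in seq_len(nrow(bundle$trios))) {
          t <- bundle$trios[i, ]
          mf <- bundle$matrices[[t$focal_species]]
          mo <- bundle$matrices[[t$outgroup_species]]
          if (is.null(mf) || !all(c(t$parent_gene, t$child_gene) %in% rownames(mf)) ||
              is.null(mo) || !(t$outgroup_gene %in% rownames(mo))) {
            note("fatal", paste0("trio gene absent from species matrix: ",
                                 t$pair_id))
          }
        }
      }
    }
    if (is.null(bundle$ks)) {
      note("warning", "ks.tsv missing; statistics stage will fail")
    }
    if (!length(bundle$orthologs)) note("fatal", "no ortholog tables")
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(0), message = character(0),
               stringsAsFactors = FALSE)
  attr(out, "ok") <- !any(out$severity == "fatal")
  out
}
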