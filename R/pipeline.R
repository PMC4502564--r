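# Tissue-specificity scores for all expressed genes of every species,
# computed on each species' full tissue set.
specificity_by_species <- function(matrices, threshold = 1) {
  out <- list()
  for (sp in names(matrices)) {
    expr <- filter_expressed(matrices[[sp]], threshold)
    if (!length(expr)) next
    prof <- relative_profiles(matrices[[sp]][expr, , drop = FALSE])
    tab <- tissue_specificity_table(prof)
    tab$species <- sp
    out[[sp]] <- tab
  }
  do.call(rbind, out)
}

# Lookup helper: specificity rows for (species, gene) pairs.
spec_lookup <- function(spec_tab, species, genes) {
  key <- paste(spec_tab$species, spec_tab$gene_id)
  spec_tab[match(paste(species, genes), key), , drop = FALSE]
}

#' Group genes for tissue-specificity and enrichment analyses
#'
#' Builds the gene groups compared in the downstream statistics:
#' per-(class x role) groups of outgroup/parent/child genes of classified
#' trios, the pooled single-copy reference (genes of the baseline ortholog
#' tables), plus the four coarse groups used for highest-tissue
#' enrichment: `single_copy`, `outgroup`, `conserved` (copies with
#' conserved profiles, from the conserved class and the conserved copy of
#' each neofunctionalized class) and `neofunctionalized` (the diverged
#' copies).
#'
#' @param result A `classification_result` from [classify_dataset()]
#'   (its matrices slot holds the normalized matrices).
#' @param trios The trio table used for classification.
#' @param orthologs Named list of ortholog tables (single-copy reference).
#' @return List with `spec_table` (per-gene specificity), `role_groups`
#'   and `coarse_groups` (named lists of specificity-score vectors) and
#'   `top_tissue_counts` (named list of per-tissue counts for the coarse
#'   groups).
#' @export
specificity_groups <- function(result, trios, orthologs) {
  stopifnot(inherits(result, "classification_result"))
  spec_tab <- specificity_by_species(result$matrices, result$threshold)
  rec <- merge(result$records, trios, by = "pair_id",
               suffixes = c("", ".trio"))

  par_spec <- spec_lookup(spec_tab, rec$focal_species, rec$parent_gene)
  chi_spec <- spec_lookup(spec_tab, rec$focal_species, rec$child_gene)
  out_spec <- spec_lookup(spec_tab, rec$outgroup_species, rec$outgroup_gene)

  role_groups <- list()
  for (cl in intersect(retention_classes(), unique(rec$label))) {
    sel <- rec$label == cl
    role_groups[[paste0(cl, ".outgroup")]] <- out_spec$max_proportion[sel]
    role_groups[[paste0(cl, ".parent")]] <- par_spec$max_proportion[sel]
    role_groups[[paste0(cl, ".child")]] <- chi_spec$max_proportion[sel]
  }

  # single-copy reference: genes of the baseline ortholog tables
  sc_rows <- list()
  for (key in names(orthologs)) {
    sp <- strsplit(key, "|", fixed = TRUE)[[1L]]
    sc_rows[[length(sc_rows) + 1L]] <-
      spec_lookup(spec_tab, sp[1L], orthologs[[key]]$gene_1)
    sc_rows[[length(sc_rows) + 1L]] <-
      spec_lookup(spec_tab, sp[2L], orthologs[[key]]$gene_2)
  }
  sc_spec <- do.call(rbind, sc_rows)
  sc_spec <- sc_spec[!is.na(sc_spec$max_proportion), , drop = FALSE]

  # coarse groups: diverged copies are neofunctionalized, their partners
  # (and conserved-class copies) are functionally conserved
  neo_p <- rec$label == "NEOFUNC_PARENT"
  neo_c <- rec$label == "NEOFUNC_CHILD"
  cons <- rec$label == "CONSERVED"
  coarse_spec <- list(
    single_copy = sc_spec,
    outgroup = out_spec,
    conserved = rbind(par_spec[cons | neo_c, , drop = FALSE],
                      chi_spec[cons | neo_p, , drop = FALSE]),
    neofunctionalized = rbind(par_spec[neo_p, , drop = FALSE],
                              chi_spec[neo_c, , drop = FALSE])
  )
  coarse_groups <- lapply(coarse_spec, function(s) s$max_proportion)
  top_counts <- lapply(coarse_spec, function(s) {
    tab <- table(factor(s$top_tissue, levels = canonical_tissues()))
    setNames(as.integer(tab), names(tab))
  })
  list(spec_table = spec_tab, role_groups = role_groups,
       coarse_groups = coarse_groups, top_tissue_counts = top_counts)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: validate, quantile-normalize, parsimony
#' dating and parent/child designation, baseline distances and divergence
#' cutoffs, five-way trio classification, and downstream statistics
#' (conserved-proportion regression against K_s, tissue-specificity
#' comparisons, highest-tissue enrichment). When `outdir` is given, writes
#' `classification.tsv`, `exclusions.tsv`, `dating.tsv`, `cutoffs.tsv`,
#' `regression.tsv`, `specificity_tests.tsv`, `enrichment.tsv`,
#' `pair_summaries.tsv` and `manifest.json`.
#'
#' @param input Bundle directory path or `dup_bundle` list (e.g. from
#'   [simulate_dataset()]).
#' @param outdir Optional output directory.
#' @param threshold Expression threshold (default 1).
#' @param siqr_multiplier SIQR multiplier of the divergence cutoff.
#' @param quantile_type Quartile convention (default 7).
#' @param normalize Normalization pooling (`"joint"`, `"per_matrix"`,
#'   `"none"`).
#' @return List of class `pipeline_result` with `classification`
#'   (a `classification_result`), `dating`, `pair_summaries`,
#'   `regression`, `specificity_tests`, `enrichment` and `manifest`.
#' @export
run_pipeline <- function(input, outdir = NULL, threshold = 1,
                         siqr_multiplier = 1, quantile_type = 7,
                         normalize = "joint") {
  bundle <- if (is.character(input)) read_bundle(input) else input
  issues <- validate_inputs(bundle)
  if (!attr(issues, "ok")) {
    stop("validation: ", paste(issues$message[issues$severity == "fatal"],
                               collapse = "; "))
  }

  # dating stage: parsimony placement + parent/child from alignment flags
  tree <- ape::read.tree(text = bundle$tree)
  dating <- NULL
  if (!is.null(bundle$copy_number)) {
    fams <- unique(bundle$copy_number$family_id)
    rows <- lapply(fams, function(f) {
      sub <- bundle$copy_number[bundle$copy_number$family_id == f, ]
      pattern <- setNames(sub$copy_number, sub$species)
      dd <- infer_duplication_branch(pattern, tree)
      fl <- bundle$alignment_flags[bundle$alignment_flags$family_id == f, ]
      pc <- if (nrow(fl) == 2L) {
        assign_parent_child(fl$copy_id, as.logical(fl$aligns_to_outgroup))
      } else {
        list(parent = NA_character_, child = NA_character_, resolved = FALSE)
      }
      data.frame(family_id = f, origin_branch = dd$origin_branch,
                 date_resolved = dd$resolved, parent = pc$parent,
                 child = pc$child, parent_child_resolved = pc$resolved,
                 stringsAsFactors = FALSE)
    })
    dating <- do.call(rbind, rows)
  }

  # classification stage (includes normalization, baselines, cutoffs)
  cls <- classify_dataset(bundle$matrices, bundle$trios, bundle$orthologs,
                          threshold = threshold,
                          siqr_multiplier = siqr_multiplier,
                          quantile_type = quantile_type,
                          normalize = normalize)

  # statistics stage
  if (is.null(bundle$ks)) stop("statistics: missing input ks.tsv")
  summaries <- conserved_proportion_by_pair(cls$records, bundle$ks,
                                            cls$baselines, cls$cutoffs)
  regression <- NULL
  if (nrow(summaries) >= 3L && diff(range(summaries$ks_median)) > 0) {
    dup_fit <- fit_linear_regression(summaries$ks_median,
                                     summaries$proportion_conserved)
    sc_fit <- fit_linear_regression(summaries$ks_median,
                                    summaries$sc_proportion_conserved)
    regression <- data.frame(
      gene_set = c("duplicate", "single_copy"),
      slope = c(dup_fit$slope, sc_fit$slope),
      intercept = c(dup_fit$intercept, sc_fit$intercept),
      f_pvalue = c(dup_fit$f_pvalue, sc_fit$f_pvalue),
      slope_t_pvalue = c(dup_fit$slope_t_pvalue, sc_fit$slope_t_pvalue),
      n_points = c(dup_fit$n_points, sc_fit$n_points),
      stringsAsFactors = FALSE
    )
  }
  groups <- specificity_groups(cls, bundle$trios, bundle$orthologs)
  spec_tests <- specificity_comparison(groups$role_groups,
                                       groups$coarse_groups$single_copy)
  enrichment <- highest_tissue_enrichment(groups$top_tissue_counts)

  manifest <- list(
    package_version = as.character(packageVersion("dupliclass")),
    parameters = list(threshold = threshold,
                      siqr_multiplier = siqr_multiplier,
                      quantile_type = quantile_type, normalize = normalize),
    input_checksums = if (is.character(input)) {
      files <- sort(list.files(input, full.names = TRUE))
      as.list(tools::md5sum(files))
    } else NULL,
    stages = list(
      trios_in = nrow(bundle$trios),
      trios_classified = nrow(cls$records),
      trios_excluded = nrow(cls$exclusions),
      exclusion_reasons = as.list(table(cls$exclusions$reason)),
      families_dated = if (is.null(dating)) 0L else sum(dating$date_resolved),
      species_pairs = length(cls$cutoffs)
    )
  )

  result <- structure(
    list(classification = cls, dating = dating, pair_summaries = summaries,
         regression = regression, specificity_tests = spec_tests,
         enrichment = enrichment, groups = groups, manifest = manifest),
    class = "pipeline_result"
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(cls$records, file.path(outdir, "classification.tsv"))
    write_tsv(cls$exclusions, file.path(outdir, "exclusions.tsv"))
    if (!is.null(dating)) write_tsv(dating, file.path(outdir, "dating.tsv"))
    cut_df <- do.call(rbind, lapply(names(cls$cutoffs), function(k) {
      co <- cls$cutoffs[[k]]
      data.frame(species_pair = k, n = co$n, median = co$median,
                 q1 = co$q1, q3 = co$q3, siqr = co$siqr, cutoff = co$cutoff,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(cut_df, file.path(outdir, "cutoffs.tsv"))
    write_tsv(summaries, file.path(outdir, "pair_summaries.tsv"))
    if (!is.null(regression)) {
      write_tsv(regression, file.path(outdir, "regression.tsv"))
    }
    write_tsv(spec_tests, file.path(outdir, "specificity_tests.tsv"))
    write_tsv(enrichment, file.path(outdir, "enrichment.tsv"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("dupliclass pipeline result\n")
  print(x$classification)
  if (!is.null(x$regression)) {
    cat(sprintf("  conserved-vs-Ks slope (duplicates): %.4g (t p = %.3g)\n",
                x$regression$slope[1L], x$regression$slope_t_pvalue[1L]))
  }
  invisible(x)
}
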