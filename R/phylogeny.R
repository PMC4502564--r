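#' Label of the branch subtending a node
#'
#' Branches are identified by their child node: a tip name for terminal
#' branches, the internal node label if present, otherwise the sorted tip
#' names of the subtended clade joined by `"+"`.
#'
#' @param tree A rooted `phylo` tree.
#' @param node Node number (tip or internal).
#' @return Character branch identifier.
#' @export
branch_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  lab <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
  if (!is.na(lab) && nzchar(lab)) return(lab)
  tips <- ape::extract.clade(tree, node)$tip.label
  paste(sort(tips), collapse = "+")
}

#' Date a duplication event by single-gain parsimony
#'
#' A duplication is placed on the branch subtending a clade when the set of
#' species carrying two gene copies is exactly the leaf set of that clade
#' and every other species carries a single copy: a single gain on the stem
#' branch of the clade then explains the pattern with no losses. Patterns
#' requiring losses (copy number 0 anywhere, or a non-monophyletic
#' two-copy set) and duplicates present in all species (which would date to
#' the root) are returned as unresolved, matching a parsimony criterion
#' that does not invoke loss events.
#'
#' Species missing from `pattern` (or with `NA` copy number) are treated as
#' uninformative: the clade test is applied to the observed species only,
#' unless `require_complete = TRUE`.
#'
#' @param pattern Named integer vector of copy numbers (0, 1 or 2) with
#'   species identifiers as names; `NA` marks missing annotation.
#' @param tree Rooted `phylo` species tree (or Newick string).
#' @param require_complete If `TRUE`, error when any tree leaf is absent
#'   from `pattern`.
#' @return List with `origin_branch` (branch identifier or
#'   `"UNRESOLVED"`) and `resolved` (logical).
#' @export
#' @examples
#' tree <- ape::read.tree(text = "((A,B),C);")
#' infer_duplication_branch(c(A = 2, B = 1, C = 1), tree)$origin_branch  # "A"
infer_duplication_branch <- function(pattern, tree, require_complete = FALSE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(pattern))) stop("pattern must be named by species")
  if (!all(names(pattern) %in% tree$tip.label)) {
    stop("pattern species not on tree: ",
         paste(setdiff(names(pattern), tree$tip.label), collapse = ", "))
  }
  observed <- pattern[!is.na(pattern)]
  if (require_complete && !all(tree$tip.label %in% names(observed))) {
    stop("pattern does not cover all tree leaves: ",
         paste(setdiff(tree$tip.label, names(observed)), collapse = ", "))
  }
  unresolved <- list(origin_branch = "UNRESOLVED", resolved = FALSE)
  if (!all(observed %in% c(1L, 2L))) return(unresolved)  # losses required
  two <- names(observed)[observed == 2L]
  if (!length(two)) return(unresolved)
  obs_sp <- names(observed)
  if (length(two) == length(obs_sp)) return(unresolved)  # present in all: root
  node <- if (length(two) == 1L) {
    match(two, tree$tip.label)
  } else {
    ape::getMRCA(tree, two)
  }
  clade_tips <- if (node <= length(tree$tip.label)) {
    tree$tip.label[node]
  } else {
    ape::extract.clade(tree, node)$tip.label
  }
  # observed clade members must be exactly the two-copy set
  if (!setequal(intersect(clade_tips, obs_sp), two)) return(unresolved)
  list(origin_branch = branch_label(tree, node), resolved = TRUE)
}

#' Designate parent and child copies from outgroup-alignment evidence
#'
#' The copy whose genomic region aligns to the outgroup genomes sits at the
#' ancestral locus and is designated the parent; the copy that aligns to no
#' outgroup region occupies a novel locus and is the child. When both or
#' neither copy aligns (e.g. tandem duplicates), the assignment cannot be
#' resolved and the pair is flagged for exclusion.
#'
#' @param copy_ids Character vector of exactly two copy identifiers.
#' @param aligns_to_outgroup Logical vector: does each copy align to the
#'   outgroup genomes?
#' @return List with `parent`, `child` (identifiers or `NA`) and
#'   `resolved` (logical).
#' @export
assign_parent_child <- function(copy_ids, aligns_to_outgroup) {
  if (length(copy_ids) != 2L || length(aligns_to_outgroup) != 2L) {
    stop("exactly two copies required")
  }
  flags <- as.logical(aligns_to_outgroup)
  if (anyNA(flags)) stop("alignment flags must be TRUE/FALSE")
  if (sum(flags) != 1L) {
    return(list(parent = NA_character_, child = NA_character_,
                resolved = FALSE))
  }
  list(parent = copy_ids[flags], child = copy_ids[!flags], resolved = TRUE)
}

#' Select the closest outgroup species with available data
#'
#' Chooses, among species with available expression data, the one with the
#' smallest path distance on the species tree to the focal species
#' (branch-length sum if the tree has lengths, node count otherwise).
#' Ties are broken by a configured priority order.
#'
#' @param tree Rooted `phylo` species tree (or Newick string).
#' @param focal Focal species (a tree leaf).
#' @param available Candidate species (tree leaves, not containing
#'   `focal`).
#' @param priority Species priority order for tie-breaks; defaults to the
#'   tree's tip order.
#' @return Single species identifier.
#' @export
select_outgroup_species <- function(tree, focal, available, priority = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!length(available)) stop("no available outgroup species")
  if (focal %in% available) available <- setdiff(available, focal)
  if (!length(available)) stop("no available outgroup species")
  stopifnot(focal %in% tree$tip.label, all(available %in% tree$tip.label))
  dtree <- tree
  if (is.null(dtree$edge.length)) {
    dtree$edge.length <- rep(1, nrow(dtree$edge))
  }
  dmat <- ape::dist.nodes(dtree)
  idx_f <- match(focal, tree$tip.label)
  d <- dmat[idx_f, match(available, tree$tip.label)]
  best <- available[d <= min(d) + 1e-12]
  if (length(best) == 1L) return(best)
  if (is.null(priority)) priority <- tree$tip.label
  best[order(match(best, priority))][1L]
}

#' Enumerate unordered species pairs
#'
#' All n * (n - 1) / 2 unordered pairs of species, in deterministic
#' lexicographic-by-input-order sequence. With the nine expression-profiled
#' vertebrate species this yields the 36 species-pair baseline
#' distributions of the analysis.
#'
#' @param species Character vector of at least two distinct species.
#' @return data.frame with columns `species_1`, `species_2`.
#' @export
#' @examples
#' nrow(enumerate_species_pairs(letters[1:9]))  # 36
enumerate_species_pairs <- function(species) {
  if (length(species) < 2L) stop("at least two species required")
  if (anyDuplicated(species)) stop("species must be distinct")
  idx <- combn(length(species), 2L)
  data.frame(species_1 = species[idx[1L, ]], species_2 = species[idx[2L, ]],
             stringsAsFactors = FALSE)
}
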