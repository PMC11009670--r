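# Clade-level statistics on individual locus trees.

# Tip-label sets below each edge (child side), for bipartition matching.
.edge_tipsets <- function(tree) {
  d <- phangorn::Descendants(tree, tree$edge[, 2L], type = "tips")
  lapply(d, function(i) tree$tip.label[i])
}

# Index of the edge separating exactly `taxa` from the rest, or NA.
.separating_edge <- function(tree, taxa) {
  target <- sort(taxa)
  tips <- tree$tip.label
  sides <- .edge_tipsets(tree)
  for (e in seq_along(sides)) {
    s <- sides[[e]]
    if (length(s) == length(target) && identical(sort(s), target)) return(e)
    if (length(s) == length(tips) - length(target) &&
        identical(sort(setdiff(tips, s)), target)) return(e)
  }
  NA_integer_
}

#' Monophyly of a clade in a locus tree
#'
#' A clade is recovered as monophyletic when some edge of the (unrooted) locus
#' tree separates the clade taxa present in that tree from all other present
#' taxa, the outgroup included; taxa missing from the tree are ignored. The
#' result is defined only when at least one clade taxon and one outgroup taxon
#' are present (use [monophyly_track()] for the stricter one-taxon-per-group
#' qualification used in quadripartition screens). A clade with a single
#' present taxon is trivially monophyletic.
#'
#' @inheritParams qqs
#' @param clade character vector of clade taxon labels.
#' @param outgroup character vector of outgroup taxon labels; must be disjoint
#'   from `clade`.
#' @return `1L`, `0L`, or `NA` when the locus does not qualify.
#' @examples
#' tr <- ape::read.tree(text = "((f,g),((p,q),o));")
#' is_monophyletic(tr, c("f", "g"), "o")
#' @export
is_monophyletic <- function(tree, clade, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (length(intersect(clade, outgroup)) > 0L)
    stop("clade and outgroup overlap")
  tips <- tree$tip.label
  cl <- intersect(clade, tips)
  og <- intersect(outgroup, tips)
  if (length(cl) == 0L || length(og) == 0L) return(NA_integer_)
  if (length(setdiff(tips, cl)) == 0L) return(NA_integer_)
  if (length(cl) == 1L) return(1L)
  if (is.na(.separating_edge(tree, cl))) 0L else 1L
}

#' Length of the branch uniting a clade
#'
#' For a locus tree in which the clade is monophyletic (ignoring missing
#' taxa), returns the length of the edge whose removal separates the present
#' clade taxa from everything else - the clade's uniting branch, in the tree's
#' branch-length units (expected substitutions per site for estimated locus
#' trees). For a clade with a single present taxon this is its terminal edge.
#' The distribution of this length across loci carries coalescent-time
#' information: loci that recover a clade through deep, discordance-free
#' histories show systematically longer uniting branches than loci that
#' recover it by chance under ILS.
#'
#' @inheritParams is_monophyletic
#' @return the edge length, or `NA` when the clade is not monophyletic in this
#'   tree (or the locus does not qualify).
#' @examples
#' tr <- ape::read.tree(text = "((f:1,g:1):0.5,(p:1,o:1):0.2);")
#' clade_branch_length(tr, c("f", "g"), "o")
#' @export
clade_branch_length <- function(tree, clade, outgroup) {
  mono <- is_monophyletic(tree, clade, outgroup)
  if (is.na(mono) || mono == 0L) return(NA_real_)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  cl <- intersect(clade, tree$tip.label)
  e <- .separating_edge(tree, cl)
  if (is.na(e)) return(NA_real_)  # unreachable given mono == 1
  tree$edge.length[e]
}

#' Taxon-removal quartet-score experiment
#'
#' Prunes a fixed set of taxa from every locus tree and compares the quartet
#' scores of two candidate species trees on the pruned loci. The per-locus
#' statistic is `quartet_score(tree', candidate_a) - quartet_score(tree',
#' candidate_b)`; a mean above zero indicates a quartet-based species-tree
#' method would favour candidate A. Repeating over a grid of removal sets
#' shows how taxon sampling interacts with outlier loci: heavy-tailed locus
#' collections make the mean (outlier-sensitive) and median (robust) diverge.
#'
#' @param trees a list or `multiPhylo` of locus trees.
#' @param candidate_a,candidate_b candidate species trees (`"phylo"`).
#' @param removal_sets named list of character vectors of taxa to prune; use
#'   `character(0)` for the unpruned baseline.
#' @return a data.frame with one row per removal set: `removal`, `n_used`,
#'   `n_missing` (loci with undefined scores), `mean`, `median`, and `se`
#'   (standard error of the mean over loci).
#' @export
taxon_removal_experiment <- function(trees, candidate_a, candidate_b,
                                     removal_sets = list(none = character(0))) {
  stopifnot(length(trees) > 0L, is.list(removal_sets))
  if (is.null(names(removal_sets)))
    names(removal_sets) <- paste0("removal_", seq_along(removal_sets))
  rows <- lapply(names(removal_sets), function(nm) {
    rm_taxa <- removal_sets[[nm]]
    diffs <- vapply(trees, function(tr) {
      keep <- setdiff(tr$tip.label, rm_taxa)
      if (length(keep) < 4L) return(NA_real_)
      if (length(keep) < length(tr$tip.label)) tr <- ape::keep.tip(tr, keep)
      sa <- quartet_score(tr, candidate_a)
      sb <- quartet_score(tr, candidate_b)
      if (is.na(sa) || is.na(sb)) return(NA_real_)
      sa - sb
    }, numeric(1L))
    d <- diffs[!is.na(diffs)]
    if (length(d) == 0L)
      stop("removal set '", nm, "' leaves no locus with a defined score")
    data.frame(removal = nm, n_used = length(d),
               n_missing = sum(is.na(diffs)),
               mean = mean(d), median = stats::median(d),
               se = stats::sd(d) / sqrt(length(d)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Branch-length scale factor between two trees
#'
#' Zero-intercept least-squares slope regressing the pairwise patristic
#' distances of `tree_target` on those of `tree_ref`, over all pairs of shared
#' taxa. Used to rescale trees estimated from data with systematically
#' compressed branch lengths (for example, trees built from conserved
#' elements) against a reference tree: multiplying `tree_ref`'s branch lengths
#' by the returned slope matches it to `tree_target` in the least-squares
#' sense.
#'
#' @param tree_ref,tree_target objects of class `"phylo"` with branch lengths.
#' @return the positive slope (exactly 2 when `tree_target` equals `tree_ref`
#'   with every branch doubled).
#' @export
tree_scale_factor <- function(tree_ref, tree_target) {
  stopifnot(inherits(tree_ref, "phylo"), inherits(tree_target, "phylo"))
  if (is.null(tree_ref$edge.length) || is.null(tree_target$edge.length))
    stop("both trees must have branch lengths")
  shared <- intersect(tree_ref$tip.label, tree_target$tip.label)
  if (length(shared) < 3L) stop("fewer than 3 shared taxa")
  da <- ape::cophenetic.phylo(tree_ref)[shared, shared]
  db <- ape::cophenetic.phylo(tree_target)[shared, shared]
  x <- da[upper.tri(da)]
  y <- db[upper.tri(db)]
  if (all(x == 0)) stop("all reference patristic distances are zero")
  sum(x * y) / sum(x * x)
}
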