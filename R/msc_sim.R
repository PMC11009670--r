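# Multispecies-coalescent gene-tree sampling. Lineages are traced tipward to
# rootward through an ultrametric species tree with branch lengths in
# coalescent units (2Ne generations): within a species-tree branch of
# duration T, k lineages coalesce at rate k(k-1)/2 per unit, pairs chosen
# uniformly; lineages that fail to coalesce enter the ancestral branch, and
# everything merges above the root. Genealogies are emitted as newick with
# coalescent-unit branch lengths, convertible to substitution units by a
# scale factor.

# Preprocess a species tree into the structure the per-draw code needs.
.msc_prep <- function(species_tree, samples = 1) {
  stopifnot(inherits(species_tree, "phylo"))
  if (is.null(species_tree$edge.length))
    stop("species tree must have branch lengths (coalescent units)")
  if (any(species_tree$edge.length < 0))
    stop("negative branch length in species tree")
  ntip <- length(species_tree$tip.label)
  depth <- ape::node.depth.edgelength(species_tree)
  height <- max(depth) - depth
  if (max(abs(height[seq_len(ntip)])) > 1e-6 * max(max(depth), 1))
    stop("species tree must be ultrametric (tips contemporaneous)")
  height[seq_len(ntip)] <- 0
  if (is.null(names(samples)) && length(samples) == 1L)
    samples <- stats::setNames(rep(samples, ntip), species_tree$tip.label)
  miss <- setdiff(species_tree$tip.label, names(samples))
  if (length(miss) > 0L) stop("no sample count for tip ", miss[1L])
  labels <- lapply(species_tree$tip.label, function(tp) {
    k <- samples[[tp]]
    if (k == 1L) tp else paste0(tp, "_", seq_len(k))
  })
  po <- ape::reorder.phylo(species_tree, "postorder")
  # internal nodes in completion order: all of a node's child subtrees are
  # processed before the node itself; the root comes last
  ord <- unique(po$edge[, 1L], fromLast = TRUE)
  n_nodes <- ntip + species_tree$Nnode
  children <- rep(list(integer(0)), n_nodes)
  byp <- split(species_tree$edge[, 2L], species_tree$edge[, 1L])
  children[as.integer(names(byp))] <- lapply(byp, as.integer)
  list(ntip = ntip, height = height, order = as.integer(ord),
       children = children, labels = labels,
       root = ntip + 1L)
}

# One genealogy as a phylo object, via the compiled sampler. `keep_labels`
# restricts the sampled lineages (marginal consistency of the coalescent
# makes sampling the subset equivalent to sampling all tips and pruning).
.msc_draw_phylo <- function(pp, keep_labels = NULL) {
  labs_per_tip <- pp$labels
  if (!is.null(keep_labels))
    labs_per_tip <- lapply(labs_per_tip, function(x) x[x %in% keep_labels])
  all_labs <- unlist(labs_per_tip, use.names = FALSE)
  nl <- length(all_labs)
  if (nl < 2L) stop("fewer than 2 lineages")
  counts <- lengths(labs_per_tip)
  ends <- cumsum(counts)
  tip_lineages <- lapply(seq_along(counts), function(i) {
    if (counts[i] == 0L) integer(0)
    else seq.int(ends[i] - counts[i] + 1L, ends[i])
  })
  res <- .msc_draw_edges(pp$order, pp$children, pp$height, tip_lineages)
  tr <- structure(list(edge = res$edge, edge.length = res$edge.length,
                       tip.label = all_labs, Nnode = nl - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

# Pure-R reference drawer (newick assembly). Retained as an independent
# implementation of the same process for cross-checking the compiled
# sampler's distribution in the test suite; not used on the hot path.
# Coalesce lineages (newick fragments `labs` with heights `h`) from time t0
# to t1; returns the surviving fragments and their heights.
.coal_interval <- function(labs, h, t0, t1) {
  k <- length(labs)
  t <- t0
  while (k >= 2L) {
    t <- t + stats::rexp(1L, k * (k - 1L) / 2)
    if (t >= t1) break
    ij <- sample.int(k, 2L)
    merged <- paste0("(", labs[ij[1L]], ":", sprintf("%.10g", t - h[ij[1L]]),
                     ",", labs[ij[2L]], ":", sprintf("%.10g", t - h[ij[2L]]),
                     ")")
    labs <- c(labs[-ij], merged)
    h <- c(h[-ij], t)
    k <- k - 1L
  }
  list(labs = labs, h = h)
}

.msc_draw_newick <- function(pp) {
  labs <- vector("list", pp$ntip + length(pp$order))
  hts <- vector("list", length(labs))
  for (i in seq_len(pp$ntip)) {
    labs[[i]] <- pp$labels[[i]]
    hts[[i]] <- rep(pp$height[i], length(pp$labels[[i]]))
  }
  for (v in pp$order) {
    lv <- character(0)
    hv <- numeric(0)
    for (u in pp$children[[v]]) {
      r <- .coal_interval(labs[[u]], hts[[u]], pp$height[u], pp$height[v])
      lv <- c(lv, r$labs)
      hv <- c(hv, r$h)
    }
    labs[[v]] <- lv
    hts[[v]] <- hv
  }
  r <- .coal_interval(labs[[pp$root]], hts[[pp$root]], pp$height[pp$root], Inf)
  paste0(r$labs, ";")
}

#' Sample gene trees under the multispecies coalescent
#'
#' Draws genealogies within an ultrametric species tree whose branch lengths
#' are in coalescent units. For a quartet with internal branch length `T`,
#' the concordant topology is recovered with probability `1 - (2/3) exp(-T)`
#' and each discordant topology with `(1/3) exp(-T)`; `T = 0` is the polytomy
#' limit with all three topologies at 1/3.
#'
#' @param species_tree a `"phylo"` (or newick string) with coalescent-unit
#'   branch lengths; must be ultrametric.
#' @param n number of independent gene trees.
#' @param samples lineages sampled per species-tree tip: a single integer or
#'   a named vector. With one sample the gene-tree tip keeps the species
#'   label; with `k > 1` labels are `<species>_1 .. <species>_k`.
#' @param scale multiplier converting coalescent-unit branch lengths to the
#'   output units (e.g. expected substitutions per site); default 1.
#' @return a `multiPhylo` of `n` gene trees (`sample_msc_gene_tree()` returns
#'   a single `"phylo"`).
#' @examples
#' st <- ape::read.tree(text = "((a:1,b:1):2,(c:2,d:2):1);")
#' trs <- sample_msc_gene_trees(st, n = 5)
#' @export
sample_msc_gene_trees <- function(species_tree, n = 1, samples = 1,
                                  scale = 1) {
  if (is.character(species_tree))
    species_tree <- ape::read.tree(text = species_tree)
  stopifnot(n >= 1, scale > 0)
  pp <- .msc_prep(species_tree, samples)
  trees <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- .msc_draw_phylo(pp)
    if (scale != 1) tr$edge.length <- tr$edge.length * scale
    trees[[i]] <- tr
  }
  class(trees) <- "multiPhylo"
  trees
}

#' @rdname sample_msc_gene_trees
#' @export
sample_msc_gene_tree <- function(species_tree, samples = 1, scale = 1) {
  sample_msc_gene_trees(species_tree, n = 1L, samples = samples,
                        scale = scale)[[1L]]
}

#' Expected recombination-free window size
#'
#' At drift-recombination equilibrium the expected length of a genomic
#' segment sharing a single genealogy is `1 / (2 * Ne * r)` bp; for
#' plausible vertebrate values this measures in thousands of bp at most, so
#' megabase-scale single-topology regions are incompatible with neutral
#' expectations.
#'
#' @param Ne effective population size (> 0).
#' @param r per-bp, per-generation recombination rate (> 0).
#' @return expected window size in bp.
#' @examples
#' recombination_free_window(1e6, 1e-7) # 5 bp
#' @export
recombination_free_window <- function(Ne, r) {
  if (!is.numeric(Ne) || !is.numeric(r) || Ne <= 0 || r <= 0)
    stop("Ne and r must be positive")
  1 / (2 * Ne * r)
}
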