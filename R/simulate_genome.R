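# Genome-scale synthetic data: loci ordered along chromosomes, i.i.d. MSC
# gene trees with high discordance in the background, and one contiguous
# planted block in which every locus displays a single forced topology drawn
# from a deepened (time-stretched) version of that topology - the
# suppressed-recombination signature. Gene-tree estimation error is modelled
# as random NNI moves and missing taxa as per-taxon dropout, both applied
# after topology assignment.

# Default 12-taxon trees, assembled from group subtrees (all heights in
# coalescent units; every group's crown is at height 0.8, the outgroup pair
# at 0.5, the root at 3.0).
.GRP_A <- "((A1:0.3,A2:0.3):0.5,A3:0.8)"
.GRP_B <- "((B1:0.3,B2:0.3):0.5,B3:0.8)"
.GRP_C <- "((C1:0.3,C2:0.3):0.5,(C3:0.3,C4:0.3):0.5)"
.GRP_O <- "(O1:0.5,O2:0.5)"

# Background species tree: B sister to (A, C); the focal stem (A+C vs B) is 0.03
# units, so quartets across it are near the polytomy limit.
.DEFAULT_SPECIES_TREE <- paste0(
  "(((", .GRP_A, ":1.2,", .GRP_C, ":1.2):0.03,", .GRP_B, ":1.23):0.97,",
  .GRP_O, ":2.5);")

# Forced alternative topology for the planted block: A and B mutually monophyletic.
.DEFAULT_BLOCK_TOPOLOGY <- paste0(
  "(((", .GRP_A, ":1.0,", .GRP_B, ":1.0):0.7,", .GRP_C, ":1.7):0.5,",
  .GRP_O, ":2.5);")

#' Simulation configuration
#'
#' Defaults define the study conditions the package's tests exercise: a
#' 12-taxon species tree (B sister to A + C) whose focal stem is 0.03
#' coalescent units, so the conflicting focal quadripartition A.B | C.D has
#' expected support (1/3)exp(-0.03), i.e. polytomy-level ~1/3; 10,000 loci on
#' two chromosomes; and a 200-locus planted block (2% of loci, mirroring the
#' empirical share of outlier loci) on chr1 forcing the alternative topology
#' (A and B sisters) with its species tree time-stretched 4-fold (deep,
#' essentially discordance-free coalescence). Estimation error is a
#' Poisson(1) number of random NNI moves per tree; each taxon drops out of
#' each locus with probability 0.1.
#'
#' @param species_tree newick string or `"phylo"`; ultrametric, coalescent
#'   units.
#' @param n_loci total locus count.
#' @param n_chrom number of chromosomes (loci split as evenly as possible,
#'   named `chr1 ..`).
#' @param locus_length,locus_spacing bp length of each locus and distance
#'   between consecutive locus starts.
#' @param block_chrom,block_start_locus,block_n_loci planted-block placement:
#'   chromosome name, 1-based index of the first block locus on that
#'   chromosome, and block length in loci (0 disables the block).
#' @param block_topology forced topology (newick or `"phylo"`; ultrametric,
#'   coalescent units) shared by every block locus.
#' @param block_stretch time-stretch factor applied to `block_topology`
#'   before sampling block genealogies: deepens coalescent times and
#'   suppresses discordance (block trees are additionally rejection-sampled
#'   to display the forced topology exactly).
#' @param nni_lambda mean of the Poisson number of random NNI moves applied
#'   to each gene tree (0 = no error).
#' @param dropout per-taxon, per-locus missingness probability (each locus
#'   keeps at least 4 taxa).
#' @param subs_per_coal branch-length scale: expected substitutions per site
#'   per coalescent unit.
#' @param autocorrelation probability that a background locus reuses its
#'   predecessor's genealogy instead of an independent draw (0 = i.i.d., the
#'   conservative null).
#' @param seed integer RNG seed; identical configurations give bit-identical
#'   genomes.
#' @return an object of class `"sim_config"` (a list of the above).
#' @export
sim_config <- function(species_tree = .DEFAULT_SPECIES_TREE,
                       n_loci = 10000, n_chrom = 2,
                       locus_length = 1000, locus_spacing = 10000,
                       block_chrom = "chr1", block_start_locus = 2401,
                       block_n_loci = 200,
                       block_topology = .DEFAULT_BLOCK_TOPOLOGY,
                       block_stretch = 4,
                       nni_lambda = 1, dropout = 0.1,
                       subs_per_coal = 0.01,
                       autocorrelation = 0, seed = 1) {
  stopifnot(n_loci >= 1, n_chrom >= 1, locus_length >= 1,
            locus_spacing >= locus_length, block_n_loci >= 0,
            block_stretch > 0, nni_lambda >= 0,
            dropout >= 0, dropout < 1, subs_per_coal > 0,
            autocorrelation >= 0, autocorrelation < 1)
  structure(list(species_tree = species_tree, n_loci = n_loci,
                 n_chrom = n_chrom, locus_length = locus_length,
                 locus_spacing = locus_spacing, block_chrom = block_chrom,
                 block_start_locus = block_start_locus,
                 block_n_loci = block_n_loci,
                 block_topology = block_topology,
                 block_stretch = block_stretch, nni_lambda = nni_lambda,
                 dropout = dropout, subs_per_coal = subs_per_coal,
                 autocorrelation = autocorrelation, seed = seed),
            class = "sim_config")
}

#' Simulate a genome of locus trees with a planted block
#'
#' Generates the locus table, per-locus gene trees and truth labels under a
#' [sim_config()]. Background loci are independent MSC draws from the
#' species tree; block loci all display the forced topology, with coalescent
#' times drawn from its time-stretched species tree (rejection-sampled to
#' match the topology exactly). NNI error and taxon dropout are applied
#' afterwards, so with `nni_lambda = 0` and `dropout = 0` every block locus
#' has `q_main = 1` for the forced quadripartition by construction.
#'
#' @param config a [sim_config()].
#' @return list with `trees` (named `multiPhylo`), `table` (locus table),
#'   `truth` (data.frame `locus_id`, `chrom`, `start`, `end`, `in_block`)
#'   and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  st <- config$species_tree
  if (is.character(st)) st <- ape::read.tree(text = st)
  n <- config$n_loci
  per <- rep(n %/% config$n_chrom, config$n_chrom)
  if (n %% config$n_chrom > 0)
    per[seq_len(n %% config$n_chrom)] <- per[seq_len(n %% config$n_chrom)] + 1L
  chrom <- rep(paste0("chr", seq_len(config$n_chrom)), per)
  idx_on_chrom <- unlist(lapply(per, seq_len))
  start <- (idx_on_chrom - 1) * config$locus_spacing + 1
  table <- data.frame(
    locus_id = sprintf("L%05d", seq_len(n)),
    chrom = chrom, start = start,
    end = start + config$locus_length - 1,
    stringsAsFactors = FALSE)

  in_block <- rep(FALSE, n)
  if (config$block_n_loci > 0) {
    on_chrom <- which(table$chrom == config$block_chrom)
    if (length(on_chrom) == 0L)
      stop("block chromosome ", config$block_chrom, " has no loci")
    lo <- config$block_start_locus
    hi <- lo + config$block_n_loci - 1L
    if (lo < 1L || hi > length(on_chrom))
      stop("planted block does not fit on ", config$block_chrom)
    in_block[on_chrom[lo:hi]] <- TRUE
  }

  pp <- .msc_prep(st, samples = 1)
  all_labels <- unlist(pp$labels, use.names = FALSE)
  n_taxa <- length(all_labels)

  ppb <- NULL
  if (any(in_block)) {
    bt <- config$block_topology
    if (is.character(bt)) bt <- ape::read.tree(text = bt)
    missing_taxa <- setdiff(st$tip.label, bt$tip.label)
    if (length(missing_taxa) > 0L)
      stop("forced topology lacks taxa: ",
           paste(missing_taxa, collapse = ", "))
    bts <- bt
    bts$edge.length <- bts$edge.length * config$block_stretch
    ppb <- .msc_prep(bts, samples = 1)
    target <- ape::unroot(bt)
  }

  all_trees <- vector("list", n)
  prev_bg <- NULL
  for (i in seq_len(n)) {
    keep <- NULL
    if (config$dropout > 0) {
      drop <- which(stats::runif(n_taxa) < config$dropout)
      if (n_taxa - length(drop) < 4L)
        drop <- drop[seq_len(max(n_taxa - 4L, 0L))]
      if (length(drop) > 0L) keep <- all_labels[-drop]
    }
    if (in_block[i]) {
      # rejection-sample a genealogy displaying the forced topology exactly
      for (attempt in seq_len(1000L)) {
        g <- .msc_draw_phylo(ppb)
        if (ape::dist.topo(ape::unroot(g), target) == 0) break
      }
      if (!is.null(keep)) g <- ape::keep.tip(g, keep)
    } else if (!is.null(prev_bg) && config$autocorrelation > 0 &&
               stats::runif(1L) < config$autocorrelation) {
      g <- prev_bg
    } else {
      # dropout applied at the sampling stage: by the marginal consistency
      # of the coalescent this equals sampling all tips and pruning
      g <- .msc_draw_phylo(pp, keep)
    }
    if (!in_block[i]) prev_bg <- g
    if (config$nni_lambda > 0) {
      m <- stats::rpois(1L, config$nni_lambda)
      if (m > 0L) g <- phangorn::rNNI(g, moves = m, n = 1L)
    }
    g$edge.length <- g$edge.length * config$subs_per_coal
    all_trees[[i]] <- g
  }
  names(all_trees) <- table$locus_id
  class(all_trees) <- "multiPhylo"

  truth <- cbind(table, in_block = in_block)
  list(trees = all_trees, table = table, truth = truth, config = config)
}

#' Default clade model matching the simulator's taxa
#'
#' Groups `grpA` (A1-A3), `grpB` (B1-B3), `grpC` (C1-C4) and outgroup
#' (O1, O2); the `planted` quadripartition A.B | C.D scores the block's
#' forced clade (mutual monophyly of A and B), and the `species`
#' quadripartition A.C | B.D tracks the background species-tree arrangement.
#'
#' @return a [clade_model()].
#' @export
sim_clade_model <- function() {
  clade_model(
    groups = list(grpA = c("A1", "A2", "A3"), grpB = c("B1", "B2", "B3"),
                  grpC = c("C1", "C2", "C3", "C4"), grpO = c("O1", "O2")),
    outgroup = c("O1", "O2"),
    quadripartitions = list(
      planted = list(A = "grpA", B = "grpB", C = "grpC", D = "grpO"),
      species = list(A = "grpA", B = "grpC", C = "grpB", D = "grpO")),
    bipartitions = list(
      planted = list(X = c("grpA", "grpB"), Y = c("grpC", "grpO"))))
}
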