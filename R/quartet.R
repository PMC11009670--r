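# Core quartet-topology machinery.
#
# A quartet {a,b,c,d} induced by an unrooted tree is resolved as ab|cd exactly
# when some edge separates {a,b} from {c,d}. With unit branch lengths, the
# four-point condition on path lengths identifies the split: among the three
# pairings, the two sums that do not correspond to the displayed split are
# equal and maximal; all three are equal iff the restricted tree is a star
# (polytomy). This gives an exact, fully vectorised counter; the brute-force
# alternative prunes each quartet and inspects its cherry.

# Topological (unit-branch-length) tip-to-tip path lengths.
.topo_dist <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  n <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# Vectorised quartet states from a distance matrix; tips may be given as
# labels (dimname lookup) or integer indices.
# Returns 1 = ab|cd, 2 = ac|bd, 3 = ad|bc, 0 = unresolved.
.quartet_states <- function(d, a, b, c4, d4) {
  if (is.character(a)) {
    lab <- rownames(d)
    a <- match(a, lab); b <- match(b, lab)
    c4 <- match(c4, lab); d4 <- match(d4, lab)
  }
  n <- nrow(d)
  s1 <- d[(b - 1L) * n + a] + d[(d4 - 1L) * n + c4]
  s2 <- d[(c4 - 1L) * n + a] + d[(d4 - 1L) * n + b]
  s3 <- d[(d4 - 1L) * n + a] + d[(c4 - 1L) * n + b]
  out <- integer(length(s1))
  out[s1 < pmin(s2, s3)] <- 1L
  out[s2 < pmin(s1, s3)] <- 2L
  out[s3 < pmin(s1, s2)] <- 3L
  out
}

# All one-per-group index combinations (the order is immaterial: every
# combination appears exactly once).
.grid4 <- function(a, b, c4, d4) {
  na <- length(a); nb <- length(b); nc <- length(c4); nd <- length(d4)
  list(a = rep(a, times = nb * nc * nd),
       b = rep(rep(b, each = na), times = nc * nd),
       c = rep(rep(c4, each = na * nb), times = nd),
       d = rep(d4, each = na * nb * nc))
}

# Brute-force state of a single quartet: prune to the four tips and find the
# cherry on either side of the internal edge. Independent of .quartet_states.
.quartet_state_brute <- function(tree, tips) {
  t4 <- ape::unroot(ape::keep.tip(tree, tips))
  nt <- length(t4$tip.label)
  child <- t4$edge[, 2L]
  for (nd in child[child > nt]) {
    side <- phangorn::Descendants(t4, nd, type = "tips")[[1L]]
    if (length(side) == 2L) {
      i <- sort(match(t4$tip.label[side], tips))
      if (i[1L] == 1L && i[2L] == 2L) return(1L)
      if (i[1L] == 3L && i[2L] == 4L) return(1L)
      if ((i[1L] == 1L && i[2L] == 3L) || (i[1L] == 2L && i[2L] == 4L)) return(2L)
      return(3L)
    }
  }
  0L
}

.states_brute <- function(tree, a, b, c4, d4) {
  vapply(seq_along(a),
         function(i) .quartet_state_brute(tree, c(a[i], b[i], c4[i], d4[i])),
         integer(1L))
}

#' Quadripartition quartet support (QQS)
#'
#' An internal branch of an unrooted species tree together with its four
#' adjacent branches partitions the taxa into four groups, written
#' `A.B | C.D`. For a locus tree, QQS is the fraction of quartets with exactly
#' one taxon drawn from each group that display the topology `ab|cd`. Counts
#' are normalised over resolved qualifying quartets so the support values of
#' the three alternative pairings sum to one; a value of 1/3 per alternative is
#' the polytomy (maximal-ILS) signal, and `q_main == 1` is equivalent to
#' mutual monophyly of A and B among the taxa present.
#'
#' Quartets left unresolved by polytomies in the locus tree are counted
#' separately (`n_unresolved`) and excluded from the normalisation. Groups
#' with no representative in the tree, or trees where every qualifying quartet
#' is unresolved, give a missing result (`NA`), never zero.
#'
#' @param tree an object of class `"phylo"` (may be non-binary; rooted or
#'   unrooted).
#' @param quad a quadripartition: list with character vectors `A`, `B`, `C`,
#'   `D` of taxon labels. The outgroup is conventionally part of `D`.
#' @param method `"fast"` for the vectorised four-point-condition counter
#'   (default) or `"brute"` for per-quartet pruning (the verification path).
#' @param strict if `TRUE`, reject non-binary trees instead of tracking
#'   unresolved quartets.
#' @return an object of class `"qqs"`: list with `q` (named numeric,
#'   `q_main`, `q_alt1`, `q_alt2`, `NA` when undefined), `counts` (named
#'   integer `n_main`, `n_alt1`, `n_alt2`, `n_unresolved`) and `n_qualifying`.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' qqs(tr, list(A = "a", B = "b", C = "c", D = "d"))$q
#' @seealso [bqs()], [qqs_track()], [is_monophyletic()]
#' @export
qqs <- function(tree, quad, method = c("fast", "brute"), strict = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(tree, "phylo"))
  if (strict && !ape::is.binary(tree))
    stop("non-binary tree rejected in strict mode")
  quad <- .check_quad(quad)
  tips <- tree$tip.label
  gi <- lapply(quad, function(s) which(tips %in% s))
  empty_counts <- c(n_main = 0L, n_alt1 = 0L, n_alt2 = 0L, n_unresolved = 0L)
  if (any(lengths(gi) == 0L))
    return(.qqs_obj(rep(NA_real_, 3L), empty_counts, 0L))
  ix <- .grid4(gi$A, gi$B, gi$C, gi$D)
  n_quartets <- length(ix$a)
  st <- if (method == "fast") {
    .quartet_states(.topo_dist(tree), ix$a, ix$b, ix$c, ix$d)
  } else {
    .states_brute(tree, tips[ix$a], tips[ix$b], tips[ix$c], tips[ix$d])
  }
  counts <- c(n_main = sum(st == 1L), n_alt1 = sum(st == 2L),
              n_alt2 = sum(st == 3L), n_unresolved = sum(st == 0L))
  resolved <- n_quartets - counts[["n_unresolved"]]
  q <- if (resolved > 0L) unname(counts[1:3]) / resolved else rep(NA_real_, 3L)
  .qqs_obj(q, counts, n_quartets)
}

.qqs_obj <- function(q, counts, n) {
  structure(list(q = stats::setNames(as.numeric(q),
                                     c("q_main", "q_alt1", "q_alt2")),
                 counts = counts, n_qualifying = as.integer(n)),
            class = "qqs")
}

.check_quad <- function(quad) {
  if (!all(c("A", "B", "C", "D") %in% names(quad)))
    stop("quadripartition must have elements A, B, C, D")
  quad <- lapply(quad[c("A", "B", "C", "D")], as.character)
  all_taxa <- unlist(quad, use.names = FALSE)
  if (anyDuplicated(all_taxa))
    stop("quadripartition groups must be pairwise disjoint")
  if (any(lengths(quad) == 0L)) stop("empty quadripartition group")
  quad
}

#' @export
print.qqs <- function(x, ...) {
  cat("QQS over", x$n_qualifying, "qualifying quartets\n")
  print(round(x$q, 4))
  invisible(x)
}

#' Branch quartet support (BQS)
#'
#' A single branch defines a bipartition `X | Y` of the taxa. BQS is the
#' fraction of quartets with exactly two taxa from `X` and two from `Y` that
#' display `ab|cd` (a, b in X; c, d in Y) in the locus tree, computed over
#' resolved quartets only. Unlike QQS it depends on one branch only, but its
#' absolute value is not comparable across clades because many of its quartets
#' are near-trivially concordant.
#'
#' @inheritParams qqs
#' @param bip a bipartition: list with character vectors `X` and `Y`.
#' @return a single value in `[0, 1]`, or `NA` if fewer than two taxa of
#'   either side are present (or no qualifying quartet is resolved).
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' bqs(tr, list(X = c("a", "b"), Y = c("c", "d")))
#' @export
bqs <- function(tree, bip, method = c("fast", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(tree, "phylo"))
  if (!all(c("X", "Y") %in% names(bip))) stop("bipartition must have X and Y")
  x <- intersect(as.character(bip$X), tree$tip.label)
  y <- intersect(as.character(bip$Y), tree$tip.label)
  if (length(intersect(x, y)) > 0L) stop("bipartition sides overlap")
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  px <- utils::combn(x, 2L)
  py <- utils::combn(y, 2L)
  ix <- rep(seq_len(ncol(px)), each = ncol(py))
  iy <- rep(seq_len(ncol(py)), times = ncol(px))
  a <- px[1L, ix]; b <- px[2L, ix]
  c4 <- py[1L, iy]; d4 <- py[2L, iy]
  st <- if (method == "fast") {
    .quartet_states(.topo_dist(tree), a, b, c4, d4)
  } else {
    .states_brute(tree, a, b, c4, d4)
  }
  resolved <- sum(st != 0L)
  if (resolved == 0L) return(NA_real_)
  sum(st == 1L) / resolved
}

#' Quartet score of a candidate species tree
#'
#' The fraction of quartets over the taxa shared by a locus tree and a
#' candidate species tree whose induced topology in the locus tree matches the
#' candidate's. Quartets unresolved in either tree are excluded from the
#' denominator. This is the per-locus quantity whose sum ASTRAL-style methods
#' maximise; comparing the score of two candidate trees across loci shows
#' which resolution the locus collection favours.
#'
#' @inheritParams qqs
#' @param candidate an object of class `"phylo"`: the candidate species tree.
#' @return a value in `[0, 1]`, or `NA` when fewer than 4 taxa are shared or
#'   no shared quartet is resolved in both trees.
#' @examples
#' tr <- ape::read.tree(text = "(((a,b),(c,d)),(e,f));")
#' quartet_score(tr, tr)
#' @export
quartet_score <- function(tree, candidate, method = c("fast", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(tree, "phylo"), inherits(candidate, "phylo"))
  shared <- intersect(tree$tip.label, candidate$tip.label)
  if (length(shared) < 4L) return(NA_real_)
  qs <- utils::combn(shared, 4L)
  a <- qs[1L, ]; b <- qs[2L, ]; c4 <- qs[3L, ]; d4 <- qs[4L, ]
  if (method == "fast") {
    st <- .quartet_states(.topo_dist(tree), a, b, c4, d4)
    sc <- .quartet_states(.topo_dist(candidate), a, b, c4, d4)
  } else {
    st <- .states_brute(tree, a, b, c4, d4)
    sc <- .states_brute(candidate, a, b, c4, d4)
  }
  ok <- st != 0L & sc != 0L
  if (!any(ok)) return(NA_real_)
  mean(st[ok] == sc[ok])
}
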