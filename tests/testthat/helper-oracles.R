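# Independent oracles used across the suite. These deliberately avoid the
# package's counting machinery: quartet topologies are read off pruned
# 4-taxon trees via Robinson-Foulds comparison against the three reference
# resolutions, and the Wright-Fisher persistence probability comes from an
# exact absorbing Markov chain.

# 1 = ab|cd, 2 = ac|bd, 3 = ad|bc, 0 = unresolved, for tips = c(a, b, c, d)
oracle_quartet_state <- function(tree, tips) {
  t4 <- ape::unroot(ape::keep.tip(tree, tips))
  refs <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))
  for (k in 1:3) {
    o <- refs[[k]]
    ref <- ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                         tips[o[1]], tips[o[2]],
                                         tips[o[3]], tips[o[4]]))
    if (ape::dist.topo(t4, ape::unroot(ref)) == 0) return(k)
  }
  0L
}

oracle_qqs_counts <- function(tree, quad) {
  g <- lapply(quad, function(s) intersect(s, tree$tip.label))
  combos <- expand.grid(a = g$A, b = g$B, c = g$C, d = g$D,
                        stringsAsFactors = FALSE)
  st <- apply(combos, 1L, function(r) oracle_quartet_state(tree, unname(r)))
  c(n_main = sum(st == 1L), n_alt1 = sum(st == 2L),
    n_alt2 = sum(st == 3L), n_unresolved = sum(st == 0L))
}

oracle_bqs <- function(tree, bip) {
  x <- intersect(bip$X, tree$tip.label)
  y <- intersect(bip$Y, tree$tip.label)
  px <- utils::combn(x, 2L, simplify = FALSE)
  py <- utils::combn(y, 2L, simplify = FALSE)
  st <- unlist(lapply(px, function(p) {
    vapply(py, function(q) oracle_quartet_state(tree, c(p, q)), integer(1L))
  }))
  sum(st == 1L) / sum(st != 0L)
}

oracle_quartet_score <- function(tree, candidate) {
  shared <- intersect(tree$tip.label, candidate$tip.label)
  qs <- utils::combn(shared, 4L, simplify = FALSE)
  st <- vapply(qs, function(q) oracle_quartet_state(tree, q), integer(1L))
  sc <- vapply(qs, function(q) oracle_quartet_state(candidate, q), integer(1L))
  ok <- st != 0L & sc != 0L
  mean(st[ok] == sc[ok])
}

# Exact persistence probability: (2N+1)-state binomial chain with absorbing
# boundaries, powered t times.
wf_exact_persistence <- function(N, k0, t) {
  two_n <- 2L * N
  states <- 0:two_n
  P <- outer(states, states,
             function(i, j) stats::dbinom(j, two_n, i / two_n))
  P[1L, ] <- 0; P[1L, 1L] <- 1
  P[two_n + 1L, ] <- 0; P[two_n + 1L, two_n + 1L] <- 1
  v <- numeric(two_n + 1L)
  v[k0 + 1L] <- 1
  for (g in seq_len(t)) v <- as.vector(v %*% P)
  sum(v[2:two_n])
}

# Random binary tree with unique labels t1..tn and random branch lengths.
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# A small locus table: n loci split over chromosomes.
toy_table <- function(n, chroms = "chr1", spacing = 1000L, len = 500L) {
  per <- rep(ceiling(n / length(chroms)), length(chroms))
  per[length(per)] <- n - sum(per[-length(per)])
  chrom <- rep(chroms, per)
  idx <- unlist(lapply(per, seq_len))
  data.frame(locus_id = sprintf("L%04d", seq_len(n)), chrom = chrom,
             start = (idx - 1L) * spacing + 1L,
             end = (idx - 1L) * spacing + len, stringsAsFactors = FALSE)
}
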