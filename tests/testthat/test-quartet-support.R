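quad1 <- list(A = "a", B = "b", C = "c", D = "d")

test_that("qqs on a single concordant quartet is (1, 0, 0)", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  r <- qqs(tr, quad1)
  expect_equal(unname(r$q), c(1, 0, 0))
  expect_equal(sum(r$q), 1)
  expect_equal(r$n_qualifying, 1L)
})

test_that("qqs handles polytomies: unresolved quartets are not zeros", {
  star <- ape::read.tree(text = "(a,b,c,d);")
  r <- qqs(star, quad1)
  expect_true(all(is.na(r$q)))
  expect_equal(r$counts[["n_unresolved"]], 1L)
  expect_error(qqs(star, quad1, strict = TRUE), "non-binary")

  # partial resolution: ((a,b),c,d,e) resolves ab|cd but not acd-only sets
  tr <- ape::read.tree(text = "((a,b),c,d,e);")
  r2 <- qqs(tr, list(A = "a", B = "b", C = "c", D = c("d", "e")))
  expect_equal(unname(r2$q), c(1, 0, 0))
})

test_that("missing groups give missing values, never zeros", {
  tr <- ape::read.tree(text = "((a,b),(c,e));")
  r <- qqs(tr, quad1)  # group D ('d') absent
  expect_true(all(is.na(r$q)))
})

test_that("qqs normalisation and group-swap symmetries hold on random trees", {
  set.seed(202)
  for (i in 1:40) {
    tr <- random_tree(12)
    tips <- sample(tr$tip.label)
    quad <- list(A = tips[1:3], B = tips[4:6], C = tips[7:9], D = tips[10:12])
    r <- qqs(tr, quad)
    expect_equal(sum(r$q), 1, tolerance = 1e-12)
    swap_ab <- qqs(tr, list(A = quad$B, B = quad$A, C = quad$C, D = quad$D))
    swap_cd <- qqs(tr, list(A = quad$A, B = quad$B, C = quad$D, D = quad$C))
    swap_bc <- qqs(tr, list(A = quad$A, B = quad$C, C = quad$B, D = quad$D))
    expect_equal(r$q[["q_main"]], swap_ab$q[["q_main"]])
    expect_equal(r$q[["q_main"]], swap_cd$q[["q_main"]])
    expect_equal(r$q[["q_main"]], swap_bc$q[["q_alt1"]])
  }
})

test_that("fast and brute counters match the pruning oracle exactly", {
  set.seed(303)
  for (i in 1:25) {
    n <- sample(8:13, 1L)
    tr <- random_tree(n)
    tips <- sample(tr$tip.label)
    quad <- list(A = tips[1:2], B = tips[3:4], C = tips[5:6],
                 D = tips[7:n])
    fast <- qqs(tr, quad, method = "fast")$counts
    brute <- qqs(tr, quad, method = "brute")$counts
    orc <- oracle_qqs_counts(tr, quad)
    expect_identical(fast, brute)
    expect_identical(fast, orc)
  }
})

test_that("bqs matches hand-worked and oracle values", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(bqs(tr, list(X = c("a", "b"), Y = c("c", "d"))), 1)

  cat4 <- ape::read.tree(text = "(a,(c,(b,d)));")
  expect_equal(bqs(cat4, list(X = c("a", "b"), Y = c("c", "d"))), 0)

  # fewer than 2 per side -> missing
  expect_true(is.na(bqs(tr, list(X = "a", Y = c("c", "d")))))

  set.seed(404)
  for (i in 1:10) {
    tr <- random_tree(14)
    tips <- sample(tr$tip.label)
    bip <- list(X = tips[1:5], Y = tips[6:14])
    expect_equal(bqs(tr, bip), oracle_bqs(tr, bip))
    expect_equal(bqs(tr, bip), bqs(tr, bip, method = "brute"))
  }
})

test_that("monophyly detection matches the defining examples", {
  yes <- ape::read.tree(text = "((f,g),((p,q),o));")
  no <- ape::read.tree(text = "((f,p),((g,q),o));")
  expect_identical(is_monophyletic(yes, c("f", "g"), "o"), 1L)
  expect_identical(is_monophyletic(no, c("f", "g"), "o"), 0L)
  expect_identical(is_monophyletic(yes, c("f", "g", "zz"), "o"), 1L)
  expect_true(is.na(is_monophyletic(yes, c("f", "g"), "missing_og")))
  expect_error(is_monophyletic(yes, c("f", "o"), "o"), "overlap")
  # single present taxon is trivially monophyletic
  expect_identical(is_monophyletic(yes, "f", "o"), 1L)
})

test_that("monophyly of A+B implies QQS exactly 1", {
  set.seed(505)
  found <- 0L
  for (i in 1:200) {
    tr <- random_tree(10)
    tips <- sample(tr$tip.label)
    quad <- list(A = tips[1:2], B = tips[3:4], C = tips[5:7], D = tips[8:10])
    mono <- is_monophyletic(tr, c(quad$A, quad$B), quad$D)
    if (identical(mono, 1L)) {
      found <- found + 1L
      expect_equal(qqs(tr, quad)$q[["q_main"]], 1)
    }
  }
  expect_gt(found, 0L)  # the property was actually exercised
})

test_that("clade branch length recovers the separating edge", {
  tr <- ape::read.tree(text = "((f:1,g:1):0.5,(p:1,o:1):0.2);")
  expect_equal(clade_branch_length(tr, c("f", "g"), "o"), 0.5)
  # single present taxon -> terminal edge
  expect_equal(clade_branch_length(tr, "f", "o"), 1)
  # non-monophyletic clade -> missing
  expect_true(is.na(clade_branch_length(tr, c("f", "p"), "o")))
})

test_that("simulated planted clade edge length is recovered on average", {
  set.seed(606)
  n <- 400
  base <- ape::read.tree(text = "((f:1,g:1):0.5,(p:1,o:1):0.2);")
  lens <- vapply(1:n, function(i) {
    tr <- base
    tr$edge.length <- tr$edge.length *
      exp(stats::rnorm(length(tr$edge.length), 0, 0.2))
    clade_branch_length(tr, c("f", "g"), "o")
  }, numeric(1))
  # lognormal noise: E[l] = 0.5 * exp(0.02); 3 SE band
  expect_lt(abs(mean(lens) - 0.5 * exp(0.02)), 3 * sd(lens) / sqrt(n))
})

test_that("quartet_score agrees with the enumeration oracle", {
  tr6 <- ape::read.tree(text = "(((a,b),(c,d)),(e,f));")
  expect_equal(quartet_score(tr6, tr6), 1)
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(quartet_score(t1, t2), 0)
  expect_true(is.na(quartet_score(t1, ape::read.tree(text = "((a,b),(x,y));"))))

  set.seed(707)
  for (i in 1:8) {
    ta <- random_tree(8)
    tb <- random_tree(8)
    expect_equal(quartet_score(ta, tb), oracle_quartet_score(ta, tb))
    expect_equal(quartet_score(ta, tb), quartet_score(ta, tb, method = "brute"))
  }
})

test_that("quartet_score of any binary tree against itself is 1", {
  set.seed(808)
  for (n in c(5, 9, 14)) {
    tr <- random_tree(n)
    expect_equal(quartet_score(tr, tr), 1)
  }
})

test_that("taxon removal experiment tracks mixture composition", {
  set.seed(909)
  cand_a <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  cand_b <- ape::read.tree(text = "(((a,c),(b,d)),((e,g),(f,h)));")
  mix <- function(p_a, n = 50) {
    trees <- lapply(seq_len(n), function(i)
      if (i <= round(p_a * n)) cand_a else cand_b)
    names(trees) <- sprintf("L%03d", seq_len(n))
    trees
  }
  up <- taxon_removal_experiment(mix(0.8), cand_a, cand_b)
  dn <- taxon_removal_experiment(mix(0.2), cand_a, cand_b)
  expect_gt(up$mean, 0)
  expect_lt(dn$mean, 0)
  expect_equal(up$n_used, 50L)

  # removing taxa from one side shrinks but keeps sign; degenerate removal
  # leaving < 4 taxa everywhere errors
  grid <- list(none = character(0), drop_ef = c("e", "f"))
  tab <- taxon_removal_experiment(mix(0.8), cand_a, cand_b, grid)
  expect_equal(nrow(tab), 2L)
  expect_error(
    taxon_removal_experiment(mix(0.8), cand_a, cand_b,
                             list(all = letters[1:5])),
    "no locus")
})

test_that("tree_scale_factor is exact on rescalings and validates input", {
  set.seed(111)
  tr <- random_tree(10)
  doubled <- tr
  doubled$edge.length <- tr$edge.length * 2
  expect_equal(tree_scale_factor(tr, doubled), 2)
  expect_equal(tree_scale_factor(tr, tr), 1)
  expect_error(tree_scale_factor(ape::read.tree(text = "((a:1,b:1):1,(x:1,y:1):1);"),
                                 ape::read.tree(text = "((a:1,b:1):1,(w:1,z:1):1);")),
               "shared taxa")
  zero <- tr
  zero$edge.length[] <- 0
  expect_error(tree_scale_factor(zero, tr), "zero")
})
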