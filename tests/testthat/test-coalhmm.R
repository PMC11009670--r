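make_posteriors <- function(n, chrom = "chr1", seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rexp(4L * n), ncol = 4L)
  m <- m / rowSums(m)
  data.frame(chrom = chrom, pos = seq_len(n) * 10L,
             pS = m[, 1], pD1 = m[, 2], pD2 = m[, 3], pD3 = m[, 4],
             stringsAsFactors = FALSE)
}

test_that("posterior tables are validated on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  post <- make_posteriors(50)
  write.table(post, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_site_posteriors(path)
  expect_equal(back$pS, post$pS, tolerance = 1e-9)

  bad <- post
  bad$pS[7] <- bad$pS[7] + 0.1
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_site_posteriors(path), "row 7")

  dec <- post
  dec$pos[10] <- dec$pos[9]
  write.table(dec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_site_posteriors(path), "strictly increasing")

  write.table(post[, -3], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_site_posteriors(path), "pS")
})

test_that("state assignment is argmax with the documented tie-break", {
  post <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                     pS = c(0.7, 0.25, 0.1), pD1 = c(0.1, 0.25, 0.1),
                     pD2 = c(0.1, 0.25, 0.4), pD3 = c(0.1, 0.25, 0.4),
                     stringsAsFactors = FALSE)
  st <- assign_states(post)
  expect_equal(as.character(st$state), c("S", "S", "D2"))
})

test_that("vectorised assignment matches a scalar argmax oracle", {
  post <- make_posteriors(5000, seed = 7)
  st <- assign_states(post)
  lab <- c("S", "D1", "D2", "D3")
  oracle <- vapply(seq_len(nrow(post)), function(i) {
    p <- c(post$pS[i], post$pD1[i], post$pD2[i], post$pD3[i])
    lab[which.max(p)]
  }, character(1))
  expect_identical(as.character(st$state), oracle)
})

test_that("window fractions follow the counting arithmetic", {
  # 100 sites in one window: S=10, D1=20, D2=40, D3=30
  states <- data.frame(
    chrom = "chr1", pos = 1:100,
    state = factor(rep(c("S", "D1", "D2", "D3"), times = c(10, 20, 40, 30)),
                   levels = c("S", "D1", "D2", "D3")),
    stringsAsFactors = FALSE)
  fr <- window_fractions(states, window_bp = 100000)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$main, 0.3)
  expect_equal(fr$alt2, 0.4)
  expect_equal(fr$alt3, 0.3)
  expect_equal(fr$shallow, 0.1)
  expect_equal(fr$deep1, 0.2)
})

test_that("windows tile from coordinate zero and conserve fractions", {
  post <- make_posteriors(4000, seed = 11)
  post$pos <- post$pos * 37L  # spread over several windows
  st <- assign_states(post)
  fr <- window_fractions(st, window_bp = 100000)
  expect_true(all(fr$start %% 100000 == 1))
  expect_true(all(fr$end - fr$start == 99999))
  expect_equal(fr$main + fr$alt2 + fr$alt3, rep(1, nrow(fr)))
  expect_equal(sum(fr$total), nrow(post))
  # boundary sites: pos 100000 belongs to window 1, pos 100001 to window 2
  b <- data.frame(chrom = "chr1", pos = c(100000L, 100001L),
                  state = factor(c("S", "S"), levels = c("S", "D1", "D2", "D3")))
  fb <- window_fractions(b, window_bp = 100000)
  expect_equal(nrow(fb), 2L)
})

test_that("ILS level reports deep and discordant-only fractions", {
  all_s <- data.frame(S = 100, D1 = 0, D2 = 0, D3 = 0)
  expect_equal(ils_level(all_s)$deep, 0)
  expect_equal(ils_level(all_s)$discordant, 0)

  x <- data.frame(S = 36, D1 = 0, D2 = 32, D3 = 32)
  expect_equal(ils_level(x)$discordant, 0.64)
  expect_equal(ils_level(x)$deep, 0.64)

  # adding deep sites never decreases either level
  lv1 <- ils_level(data.frame(S = 50, D1 = 10, D2 = 5, D3 = 5))
  lv2 <- ils_level(data.frame(S = 50, D1 = 10, D2 = 15, D3 = 5))
  expect_gte(lv2$deep, lv1$deep)
  expect_gte(lv2$discordant, lv1$discordant)

  expect_true(is.na(ils_level(data.frame(S = 0, D1 = 0, D2 = 0, D3 = 0))$deep))
})

test_that("the MSC admissibility bound is the closed-form 2/3 limit", {
  expect_identical(msc_discordance_bound(0), 2 / 3)
  expect_equal(msc_discordance_bound(1), (2 / 3) * exp(-1))
  expect_identical(as.character(msc_admissible(0.64)), "admissible")
  expect_identical(as.character(msc_admissible(0.71)), "violation")
  expect_equal(attr(msc_admissible(0.5), "bound"), 2 / 3)
})

test_that("simulated MSC genomes respect the bound; planted blocks break it", {
  set.seed(151)
  # site states derived from simulated quartet genealogies: the species-tree
  # window stays under 2/3 discordance, the forced-alternative window exceeds
  # it when scored against the same species tree
  st <- ape::read.tree(text = "(((a:1,b:1):0.1,c:1.1):1,d:2.1);")
  trs <- sample_msc_gene_trees(st, n = 2000)
  code <- vapply(unclass(trs), function(g)
    quartetscan:::.quartet_states(quartetscan:::.topo_dist(g),
                                  "a", "b", "c", "d"), integer(1))
  disc <- mean(code != 1L)
  expect_lte(disc, 2 / 3 + 3 * sqrt(disc * (1 - disc) / 2000))
  # a block fixed on one discordant topology scores 100% discordant
  expect_identical(as.character(msc_admissible(1)), "violation")
})
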