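test_that("trailing moving average has percent-of-preceding semantics", {
  tab <- toy_table(4)
  tk <- support_track(tab, c(1, 1, 0, 0))
  ma <- moving_average(tk, 2)
  expect_equal(ma$value, c(NA, 1, 0.5, 0))

  const <- moving_average(support_track(toy_table(6), rep(0.4, 6)), 3)
  expect_equal(const$value, c(NA, NA, rep(0.4, 4)))
})

test_that("moving averages skip missing loci and never bridge chromosomes", {
  tab <- toy_table(6)
  tk <- support_track(tab, c(1, NA, 0, 1, NA, 0))
  ma <- moving_average(tk, 2)
  # non-missing sequence is 1,0,1,0 at rows 1,3,4,6
  expect_equal(ma$value, c(NA, NA, 0.5, 0.5, NA, 0.5))

  tab2 <- toy_table(8, chroms = c("chr1", "chr2"))
  tk2 <- support_track(tab2, c(1, 1, 1, 1, 0, 0, 0, 0))
  ma2 <- moving_average(tk2, 3)
  # chr2 restarts: its first two loci are NA, never averaging chr1 values
  expect_true(all(is.na(ma2$value[5:6])))
  expect_equal(ma2$value[7:8], c(0, 0))

  expect_warning(moving_average(support_track(toy_table(3), rep(1, 3)), 10),
                 "exceeds")
})

test_that("window means cover exactly w qualifying loci with unit step", {
  tab <- toy_table(25)
  tk <- support_track(tab, rep(1, 25))
  wm <- window_means(tk, w = 20)
  expect_equal(nrow(wm), 6L)
  expect_true(all(wm$Q == 1))
  expect_equal(wm$qi_first, 1:6)
  expect_equal(wm$qi_last, 20:25)

  set.seed(121)
  vals <- runif(25)
  vals[c(3, 17)] <- NA
  wm2 <- window_means(support_track(tab, vals), w = 10)
  kept <- vals[!is.na(vals)]
  hand <- vapply(seq_len(length(kept) - 9L),
                 function(i) mean(kept[i:(i + 9L)]), numeric(1))
  expect_equal(wm2$Q, hand)
  # bp span maps back to the first/last qualifying locus
  expect_equal(wm2$start[1], tab$start[which(!is.na(vals))[1]])

  expect_message(none <- window_means(support_track(toy_table(5), rep(1, 5)),
                                      w = 20), "no windows")
  expect_equal(nrow(none), 0L)
})

test_that("the window Z-test matches the normal CDF construction", {
  tab <- toy_table(30)
  wm <- window_means(support_track(tab, rep(0.4, 30)), w = 10)
  tested <- msc_window_test(wm, mu = 0.4, sigma = 0.1)
  expect_equal(tested$Z, rep(0, nrow(tested)))
  expect_equal(tested$p, rep(0.5, nrow(tested)))

  wm$Q[1] <- 0.4 + 2.5758 * 0.1
  tested <- msc_window_test(wm, mu = 0.4, sigma = 0.1)
  expect_equal(tested$p[1], 0.005, tolerance = 1e-4)
  expect_true(all(tested$p > 0 & tested$p <= 0.5))

  expect_error(msc_window_test(wm, mu = 0.4, sigma = 0), "positive")
})

test_that("BH adjustment reproduces the hand-applied step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(131)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

fake_windows <- function(qi_first, p_adj, chrom = "chr1", w = 20L,
                         spacing = 1000L) {
  qi_last <- qi_first + w - 1L
  data.frame(chrom = chrom, qi_first = qi_first, qi_last = qi_last,
             row_first = qi_first, row_last = qi_last,
             locus_first = sprintf("L%04d", qi_first),
             locus_last = sprintf("L%04d", qi_last),
             start = (qi_first - 1L) * spacing + 1L,
             end = (qi_last - 1L) * spacing + 500L,
             Q = 0.9, Z = 4, p = p_adj / 2, p_adj = p_adj,
             stringsAsFactors = FALSE)
}

test_that("outlier regions merge overlapping significant windows", {
  expect_equal(nrow(call_outlier_regions(fake_windows(1:30, rep(0.5, 30)))),
               0L)

  one <- call_outlier_regions(fake_windows(1:30, rep(1e-4, 30)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_windows, 30L)
  expect_equal(one$n_loci, 49L)  # loci 1..49 for 30 windows of w = 20
  expect_equal(one$start, 1)
  expect_equal(one$end, 48L * 1000L + 500L)

  # two blocks separated by > max_gap_loci stay apart; <= gap merges
  wdf <- fake_windows(c(1:5, 40:44), rep(1e-4, 10))
  expect_equal(nrow(call_outlier_regions(wdf, max_gap_loci = 0)), 2L)
  # gap between covered loci 24 and 40 is 15 loci
  expect_equal(nrow(call_outlier_regions(wdf, max_gap_loci = 14)), 2L)
  expect_equal(nrow(call_outlier_regions(wdf, max_gap_loci = 15)), 1L)
})

test_that("region calls are invariant to chromosome processing order", {
  a <- fake_windows(1:5, rep(1e-4, 5), chrom = "chr2")
  b <- fake_windows(1:5, rep(1e-4, 5), chrom = "chr1")
  r1 <- call_outlier_regions(rbind(a, b))
  r2 <- call_outlier_regions(rbind(b, a))
  expect_identical(r1, r2)
  expect_identical(r1$chrom, c("chr1", "chr2"))
})

test_that("genome_scan is deterministic and excludes sex chromosomes", {
  set.seed(141)
  cfg <- sim_config(n_loci = 400, n_chrom = 2, block_n_loci = 0,
                    seed = 99, dropout = 0, nni_lambda = 0)
  sim <- simulate_genome(cfg)
  tab <- sim$table
  tab$chrom[tab$chrom == "chr2"] <- "chrZ"
  model <- sim_clade_model()
  s1 <- suppressMessages(genome_scan(sim$trees, tab, model,
                                     quads = "planted",
                                     sex_chromosomes = "chrZ"))
  s2 <- suppressMessages(genome_scan(sim$trees, tab, model,
                                     quads = "planted",
                                     sex_chromosomes = "chrZ"))
  expect_identical(s1$branches$planted$windows, s2$branches$planted$windows)
  expect_false(any(s1$branches$planted$windows$chrom == "chrZ"))
  # the full-genome track still covers the excluded chromosome
  expect_true(any(s1$branches$planted$track$chrom == "chrZ"))
})
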