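# Sliding-window MSC-conformity scan. Under the MSC, per-locus quartet
# support is a stochastic draw around a genome-wide mean; the mean Q_i of w
# consecutive loci is approximately normal, so standardised deviates
# Z_i = (Q_i - mu)/sigma give each window a two-sided p-value
# min(F(Z_i), 1 - F(Z_i)) against the null that the window's loci are drawn
# from the same distribution as the rest of the genome. Consistent rejection
# across a run of windows flags a region that violates MSC expectations.

#' Trailing moving average of a track
#'
#' The value at each locus is the mean of the `k` most recent non-missing
#' values on the same chromosome, the current locus included; loci preceded by
#' fewer than `k` non-missing values (and missing loci) get `NA`. Averages
#' never bridge a chromosome boundary.
#'
#' @param track a [support_track()].
#' @param k window length in (qualifying) loci.
#' @return a `support_track` of moving averages.
#' @export
moving_average <- function(track, k) {
  stopifnot(k >= 1)
  out <- rep(NA_real_, nrow(track))
  for (ch in unique(track$chrom)) {
    i <- which(track$chrom == ch)
    j <- i[!is.na(track$value[i])]
    if (length(j) < k) next
    cs <- cumsum(track$value[j])
    m <- (cs[k:length(j)] - c(0, cs[seq_len(length(j) - k)])) / k
    out[j[k:length(j)]] <- m
  }
  if (all(is.na(out)))
    warning("window length k exceeds every chromosome's qualifying locus count")
  support_track(track, out)
}

#' Sliding-window means of a track
#'
#' Windows cover exactly `w` consecutive qualifying (non-missing) loci on one
#' chromosome, sliding one locus at a time; missing loci are dropped before
#' windowing so every window averages `w` values. Chromosomes with fewer than
#' `w` qualifying loci contribute no windows.
#'
#' @param track a [support_track()].
#' @param w window size in qualifying loci.
#' @return a data.frame with one row per window: `chrom`, `qi_first` /
#'   `qi_last` (indices among the chromosome's qualifying loci), `row_first` /
#'   `row_last` (row indices into `track`), `locus_first` / `locus_last`,
#'   `start` / `end` (bp span from first locus start to last locus end), `Q`.
#' @export
window_means <- function(track, w = 20) {
  stopifnot(w >= 1)
  res <- list()
  for (ch in unique(track$chrom)) {
    i <- which(track$chrom == ch)
    q <- i[!is.na(track$value[i])]
    nq <- length(q)
    if (nq < w) {
      message("chromosome ", ch, ": ", nq, " qualifying loci < w = ", w,
              "; no windows")
      next
    }
    cs <- cumsum(track$value[q])
    qmean <- (cs[w:nq] - c(0, cs[seq_len(nq - w)])) / w
    first <- seq_len(nq - w + 1L)
    last <- first + w - 1L
    res[[ch]] <- data.frame(
      chrom = ch, qi_first = first, qi_last = last,
      row_first = q[first], row_last = q[last],
      locus_first = track$locus_id[q[first]],
      locus_last = track$locus_id[q[last]],
      start = track$start[q[first]], end = track$end[q[last]],
      Q = qmean, stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(chrom = character(0), qi_first = integer(0),
                      qi_last = integer(0), row_first = integer(0),
                      row_last = integer(0), locus_first = character(0),
                      locus_last = character(0), start = numeric(0),
                      end = numeric(0), Q = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Null parameters for the window test
#'
#' `mu` is the genome-wide mean of the per-locus statistic. `sigma` is, by
#' default, the standard deviation of the window means themselves
#' (`sigma_method = "window"`), which makes the standardised deviates
#' approximately standard normal by construction; `sigma_method = "locus"`
#' instead uses the per-locus standard deviation (the more literal reading of
#' a genome-wide SD, but then Z is not unit-scaled for window means).
#'
#' @param track a [support_track()].
#' @param w window size used for the scan.
#' @param sigma_method `"window"` or `"locus"`.
#' @param windows optional precomputed [window_means()] result (avoids
#'   recomputation).
#' @return list with `mu` and `sigma`.
#' @export
scan_null_params <- function(track, w = 20,
                             sigma_method = c("window", "locus"),
                             windows = NULL) {
  sigma_method <- match.arg(sigma_method)
  mu <- mean(track$value, na.rm = TRUE)
  sigma <- if (sigma_method == "window") {
    if (is.null(windows)) windows <- window_means(track, w)
    stats::sd(windows$Q)
  } else {
    stats::sd(track$value, na.rm = TRUE)
  }
  list(mu = mu, sigma = sigma)
}

#' Window-level MSC conformity test
#'
#' Standardises each window mean, `Z_i = (Q_i - mu) / sigma`, and assigns the
#' p-value `min(F(Z_i), 1 - F(Z_i))` with `F` the standard normal CDF. The
#' p-value lies in (0, 0.5]; at threshold `alpha` the construction is a
#' two-tailed test of size `2 * alpha`.
#'
#' @param windows a [window_means()] data.frame.
#' @param mu,sigma null parameters (see [scan_null_params()]); `sigma` must be
#'   positive.
#' @return `windows` with added columns `Z` and `p`.
#' @export
msc_window_test <- function(windows, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be positive (degenerate genome?)")
  windows$Z <- (windows$Q - mu) / sigma
  windows$p <- pmin(stats::pnorm(windows$Z),
                    stats::pnorm(windows$Z, lower.tail = FALSE))
  windows
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values (a thin
#' wrapper over [stats::p.adjust()], applied per scanned branch across all of
#' that branch's windows).
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Call outlier regions from tested windows
#'
#' Significant windows (`p_adj < alpha`) are merged, per chromosome, into
#' maximal runs over the qualifying-locus axis: two significant windows join
#' the same region when the gap between the loci they cover is at most
#' `max_gap_loci` (0 = only overlapping or abutting windows merge). A
#' region's bp span runs from the start of the first covered locus to the end
#' of the last.
#'
#' @param windows output of [msc_window_test()] with a `p_adj` column (add one
#'   with [bh_adjust()]).
#' @param alpha significance level on the adjusted p-values.
#' @param max_gap_loci largest locus gap bridged when merging windows.
#' @return a data.frame with one row per region: `chrom`, `start`, `end`,
#'   `n_windows`, `n_loci`, `min_p_adj`.
#' @export
call_outlier_regions <- function(windows, alpha = 0.01, max_gap_loci = 0) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      n_loci = integer(0), min_p_adj = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(windows) == 0L) return(empty)
  if (is.null(windows$p_adj)) stop("windows must carry a p_adj column")
  sig <- windows[!is.na(windows$p_adj) & windows$p_adj < alpha, ]
  if (nrow(sig) == 0L) return(empty)
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, ]
    s <- s[order(s$qi_first), ]
    grp <- integer(nrow(s))
    g <- 1L
    covered_last <- s$qi_last[1L]
    grp[1L] <- g
    for (i in seq_len(nrow(s))[-1L]) {
      if (s$qi_first[i] > covered_last + 1L + max_gap_loci) {
        g <- g + 1L
        covered_last <- s$qi_last[i]
      } else {
        covered_last <- max(covered_last, s$qi_last[i])
      }
      grp[i] <- g
    }
    for (k in seq_len(g)) {
      r <- s[grp == k, ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = r$start[1L], end = r$end[nrow(r)],
        n_windows = nrow(r),
        n_loci = r$qi_last[nrow(r)] - r$qi_first[1L] + 1L,
        min_p_adj = min(r$p_adj), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Genome-wide MSC-conformity scan
#'
#' Runs the full scan for each configured quadripartition ("branch"): builds
#' the per-locus QQS track, drops sex chromosomes from testing (their
#' coalescent histories are atypical), forms sliding windows, estimates the
#' null parameters from the whole tested genome (the focal windows included),
#' tests every window, applies the Benjamini-Hochberg correction per branch,
#' and calls outlier regions. The scan is deterministic: identical inputs and
#' parameters give identical output.
#'
#' @param trees named list / `multiPhylo` of locus trees.
#' @param table a locus table.
#' @param model a [clade_model()] with at least one quadripartition.
#' @param quads names of the model's quadripartitions to scan (default: all).
#' @param w window size in qualifying loci.
#' @param alpha significance level on BH-adjusted p-values.
#' @param sex_chromosomes chromosome names excluded from testing.
#' @param sigma_method see [scan_null_params()].
#' @param max_gap_loci see [call_outlier_regions()].
#' @return an object of class `"genome_scan"`: list with `branches` (per
#'   branch: `track` (full genome), `windows`, `regions`, `mu`, `sigma`,
#'   `n_windows`, `n_significant`), `summary` (one row per branch) and
#'   `params`.
#' @export
genome_scan <- function(trees, table, model,
                        quads = names(model$quadripartitions),
                        w = 20, alpha = 0.01,
                        sex_chromosomes = character(0),
                        sigma_method = c("window", "locus"),
                        max_gap_loci = 0) {
  sigma_method <- match.arg(sigma_method)
  stopifnot(inherits(model, "clade_model"), length(quads) > 0L)
  keep <- !(table$chrom %in% sex_chromosomes)
  branches <- list()
  for (qn in quads) {
    quad <- model$quadripartitions[[qn]]
    if (is.null(quad)) stop("unknown quadripartition: ", qn)
    track_full <- qqs_track(trees, table, quad)
    track <- track_full[keep, ]
    class(track) <- class(track_full)
    wm <- window_means(track, w)
    np <- scan_null_params(track, w, sigma_method, windows = wm)
    wr <- msc_window_test(wm, np$mu, np$sigma)
    wr$p_adj <- bh_adjust(wr$p)
    regions <- call_outlier_regions(wr, alpha, max_gap_loci)
    branches[[qn]] <- list(track = track_full, windows = wr,
                           regions = regions, mu = np$mu, sigma = np$sigma,
                           n_windows = nrow(wr),
                           n_significant = sum(wr$p_adj < alpha))
  }
  summary <- data.frame(
    branch = names(branches),
    n_windows = vapply(branches, function(b) b$n_windows, integer(1L)),
    n_significant = vapply(branches, function(b) b$n_significant, integer(1L)),
    pct_significant = vapply(branches, function(b)
      if (b$n_windows > 0L) 100 * b$n_significant / b$n_windows else NA_real_,
      numeric(1L)),
    n_regions = vapply(branches, function(b) nrow(b$regions), integer(1L)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(branches = branches, summary = summary,
                 params = list(w = w, alpha = alpha,
                               sex_chromosomes = sex_chromosomes,
                               sigma_method = sigma_method,
                               max_gap_loci = max_gap_loci)),
            class = "genome_scan")
}

#' @export
print.genome_scan <- function(x, ...) {
  cat("MSC-conformity genome scan (w =", x$params$w,
      ", alpha =", x$params$alpha, ")\n")
  print(x$summary)
  invisible(x)
}
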