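# Post-processing of coalescent-HMM site posteriors. The HMM itself is
# consumed, never run: input is a table of per-site posterior probabilities
# over four states - S (shallow coalescence, species tree guaranteed), D1
# (deep coalescence, topology matches the species tree) and D2/D3 (deep
# coalescence, the two discordant topologies).

.COALHMM_STATES <- c("S", "D1", "D2", "D3")

#' Read per-site state posteriors
#'
#' TSV with header and columns `chrom`, `pos`, `pS`, `pD1`, `pD2`, `pD3`.
#' Each site's probabilities must sum to one (within `tol`) and positions
#' must be strictly increasing within a chromosome.
#'
#' @param path file path.
#' @param tol tolerance on each row's probability sum.
#' @return a data.frame with the six columns above.
#' @export
read_site_posteriors <- function(path, tol = 1e-6) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "pS", "pD1", "pD2", "pD3")
  if (!all(need %in% names(tab))) {
    miss <- setdiff(need, names(tab))
    stop("posterior table missing column(s): ", paste(miss, collapse = ", "))
  }
  tab <- tab[need]
  .check_posteriors(tab, tol)
  tab
}

.check_posteriors <- function(tab, tol = 1e-6) {
  s <- tab$pS + tab$pD1 + tab$pD2 + tab$pD3
  bad <- which(abs(s - 1) > tol)
  if (length(bad) > 0L)
    stop("posteriors do not sum to 1 at row ", bad[1L],
         " (sum = ", format(s[bad[1L]]), ")")
  dec <- tapply(tab$pos, tab$chrom, function(p) any(diff(p) <= 0))
  if (any(unlist(dec)))
    stop("site coordinates must be strictly increasing within a chromosome")
  invisible(tab)
}

#' Assign each site to its maximum-posterior state
#'
#' Ties are broken by the fixed order S > D1 > D2 > D3 (a measure-zero event
#' for continuous posteriors, but the rule is deterministic and documented).
#'
#' @param posteriors data.frame as returned by [read_site_posteriors()].
#' @param tol tolerance on each row's probability sum.
#' @return `posteriors` with the probability columns replaced by a `state`
#'   factor with levels `S`, `D1`, `D2`, `D3`.
#' @export
assign_states <- function(posteriors, tol = 1e-6) {
  .check_posteriors(posteriors, tol)
  m <- as.matrix(posteriors[, c("pS", "pD1", "pD2", "pD3")])
  lab <- .COALHMM_STATES[max.col(m, ties.method = "first")]
  data.frame(chrom = posteriors$chrom, pos = posteriors$pos,
             state = factor(lab, levels = .COALHMM_STATES),
             stringsAsFactors = FALSE)
}

#' Windowed state-count fractions
#'
#' Counts sites per state in non-overlapping windows tiled from coordinate 0
#' (window k covers bp `k*window_bp + 1 .. (k+1)*window_bp`, 1-based
#' inclusive) and reports the support fractions: `main = (S + D1) / total`
#' (species-tree topology, shallow or deep), `alt2 = D2 / total`,
#' `alt3 = D3 / total`, and the split of the main support into
#' `shallow = S / total` and `deep1 = D1 / total`. Empty windows are omitted.
#'
#' @param states data.frame from [assign_states()] (`chrom`, `pos`, `state`).
#' @param window_bp window width in bp.
#' @return a data.frame with one row per non-empty window: `chrom`, `start`,
#'   `end`, counts `S`, `D1`, `D2`, `D3`, `total`, and the five fractions.
#' @export
window_fractions <- function(states, window_bp = 100000) {
  stopifnot(window_bp >= 1)
  win <- (states$pos - 1) %/% window_bp
  key <- paste(states$chrom, win, sep = "\r")
  counts <- table(key, states$state)
  keys <- rownames(counts)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1L), 1L)
  k <- as.numeric(vapply(parts, `[`, character(1L), 2L))
  cm <- matrix(as.integer(counts), nrow = nrow(counts),
               dimnames = dimnames(counts))
  total <- rowSums(cm)
  out <- data.frame(chrom = chrom, start = k * window_bp + 1,
                    end = (k + 1) * window_bp,
                    S = cm[, "S"], D1 = cm[, "D1"],
                    D2 = cm[, "D2"], D3 = cm[, "D3"],
                    total = total,
                    main = (cm[, "S"] + cm[, "D1"]) / total,
                    alt2 = cm[, "D2"] / total,
                    alt3 = cm[, "D3"] / total,
                    shallow = cm[, "S"] / total,
                    deep1 = cm[, "D1"] / total,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' ILS level of a window or region
#'
#' Aggregates state counts and reports two measures: the deep-coalescence
#' fraction `(D1 + D2 + D3) / total` (any site whose genealogy coalesced
#' deeper than the terminal speciation, the usual "amount of ILS") and the
#' discordant-only fraction `(D2 + D3) / total` (sites whose topology
#' conflicts with the species tree - the quantity bounded by 2/3 under the
#' MSC).
#'
#' @param x a data.frame with count columns `S`, `D1`, `D2`, `D3` (for
#'   example rows of [window_fractions()]); counts are summed before dividing.
#' @return list with `deep` and `discordant` fractions (`NA` when no sites).
#' @export
ils_level <- function(x) {
  s <- sum(x$S); d1 <- sum(x$D1); d2 <- sum(x$D2); d3 <- sum(x$D3)
  total <- s + d1 + d2 + d3
  if (total == 0) return(list(deep = NA_real_, discordant = NA_real_))
  list(deep = (d1 + d2 + d3) / total, discordant = (d2 + d3) / total)
}

#' MSC bound on discordant-topology probability
#'
#' Under the MSC, a quartet's internal branch of length `T` (coalescent
#' units) leaves each discordant topology with probability `(1/3) exp(-T)`,
#' so the total discordant probability is `(2/3) exp(-T)`; the bound is its
#' supremum, attained in the `T -> 0` limit. The value is computed from the
#' closed form, not hard-coded.
#'
#' @param T internal branch length in coalescent units (default 0, the
#'   polytomy limit).
#' @return the total discordant-topology probability at `T`.
#' @export
msc_discordance_bound <- function(T = 0) {
  stopifnot(T >= 0)
  2 * (1 / 3) * exp(-T)
}

#' MSC admissibility of an observed discordant fraction
#'
#' A region whose discordant-topology fraction exceeds the 2/3 bound (see
#' [msc_discordance_bound()]) cannot be produced by ILS alone under the MSC,
#' whatever the branch lengths; such a region is a violation. The check uses
#' the discordant-only fraction (`D2 + D3` sites), since the 2/3 bound is a
#' statement about conflicting quartet topologies.
#'
#' @param discordant_fraction observed fraction in `[0, 1]`.
#' @return `"admissible"` or `"violation"` (character), with the bound as
#'   attribute `"bound"`.
#' @export
msc_admissible <- function(discordant_fraction) {
  stopifnot(discordant_fraction >= 0, discordant_fraction <= 1)
  bound <- msc_discordance_bound(0)
  structure(if (discordant_fraction > bound) "violation" else "admissible",
            bound = bound)
}
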