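# Neutral Wright-Fisher persistence of a polymorphism: the probability that
# an allele (for example a chromosomal rearrangement segregating in an
# ancestral population) is still polymorphic after t generations of binomial
# resampling in a diploid population of size N.

#' Wright-Fisher polymorphism persistence
#'
#' Monte-Carlo estimate of the probability that an allele starting at count
#' `k0` out of `2N` chromosomes is neither lost nor fixed after `t`
#' generations of neutral binomial resampling. Fixation and loss are
#' absorbing. The default initial frequency is 1/2 (`k0 = N`), an explicit
#' modelling assumption: a rearrangement must reach appreciable frequency
#' before its persistence through successive speciations is the question.
#'
#' @param N diploid population size.
#' @param k0 initial allele count out of `2N` chromosomes (default `N`,
#'   frequency 1/2). If `k0` is 0 or `2N` the allele is already fixed/lost
#'   and the probability is exactly 0.
#' @param t number of generations (>= 0).
#' @param reps Monte-Carlo replicates.
#' @return list with `estimate`, `se` (binomial standard error), `reps`, and
#'   the inputs.
#' @examples
#' set.seed(1)
#' wf_persistence(N = 5, k0 = 5, t = 10, reps = 2000)$estimate
#' @export
wf_persistence <- function(N, k0 = N, t, reps = 10000) {
  stopifnot(N >= 1, t >= 0, reps >= 1, k0 >= 0, k0 <= 2 * N)
  if (k0 == 0 || k0 == 2 * N)
    return(list(estimate = 0, se = 0, reps = reps, N = N, k0 = k0, t = t))
  two_n <- 2L * as.integer(N)
  k <- rep(as.integer(k0), reps)
  for (g in seq_len(t)) {
    active <- k > 0L & k < two_n
    if (!any(active)) break
    k[active] <- stats::rbinom(sum(active), two_n, k[active] / two_n)
  }
  p <- mean(k > 0L & k < two_n)
  list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = reps,
       N = N, k0 = k0, t = t)
}
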