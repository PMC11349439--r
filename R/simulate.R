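#' Simulate original/replication study pairs
#'
#' Draws study pairs from the normal model underlying all operating
#' characteristics in this package: `zo ~ N(muo, 1)` and, independently,
#' `zr ~ N(d * sqrt(c) * muo, 1)`, converted to one-sided p-values by
#' `p = 1 - pnorm(z)`.  With `muo = 0` both p-values are standard uniform
#' regardless of `d` — the intersection null used for Type-I error
#' checks.  For an original study with power `1 - beta` at level `alpha`,
#' set `muo = qnorm(1 - alpha) + qnorm(1 - beta)`.
#'
#' Randomness is fully determined by `seed`: the generator kind is pinned
#' (Mersenne-Twister with inversion sampling for normals) and the caller's
#' RNG state is saved and restored, so repeated calls with the same
#' arguments return identical pairs and never perturb the session RNG.
#'
#' @param npairs number of pairs to draw (at least 1).
#' @param muo noncentrality of the original z-value (0 under the null).
#' @param c relative sample size `nr / no`, attached to each pair.
#' @param d ratio of true effect sizes `theta_r / theta_o`.
#' @param seed integer seed.
#' @return a `data.frame` with columns `po`, `pr`, `c`.
#' @export
simulatePairs <- function(npairs, muo = 0, c = 1, d = 1, seed = 1) {
  if (npairs < 1) stop("'npairs' must be at least 1", call. = FALSE)
  c <- .checkPositive(c)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  zo <- stats::rnorm(npairs, mean = muo)
  zr <- stats::rnorm(npairs, mean = d * sqrt(c) * muo)
  data.frame(po = stats::pnorm(zo, lower.tail = FALSE),
             pr = stats::pnorm(zr, lower.tail = FALSE),
             c = c)
}

#' Monte-Carlo success rate of a combination method
#'
#' Empirical proportion of study pairs declared successful at the overall
#' level, with its binomial standard error — the simulation oracle used to
#' cross-check Type-I error rates and project power.
#'
#' @param pairs a `data.frame` with columns `po`, `pr` and, for the
#'   meta-analysis criterion, `c` (e.g. from [simulatePairs()]).
#' @param method combination method, see [combinePValues()].
#' @param level overall level (default `0.025^2`).
#' @param wo,wr weights for the weighted Edgington method.
#' @return list with `rate`, `se` (binomial standard error) and `n`.
#' @export
mcSuccessRate <- function(pairs, method, level = 0.025^2, wo = 1, wr = 2) {
  method <- .checkMethod(method)
  if (nrow(pairs) == 0) stop("'pairs' must be nonempty", call. = FALSE)
  p <- switch(method,
    edgington          = pEdgington(pairs$po, pairs$pr),
    edgington_weighted = pEdgingtonWeighted(pairs$po, pairs$pr, wo, wr),
    two_trials         = pTwoTrials(pairs$po, pairs$pr),
    fisher             = pFisher(pairs$po, pairs$pr),
    meta               = pMeta(pairs$po, pairs$pr, pairs$c))
  rate <- mean(p <= level)
  list(rate = rate, se = sqrt(rate * (1 - rate) / length(p)), n = length(p))
}
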