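#' Conditional replication level / conditional Type-I error rate
#'
#' Given the original one-sided p-value `po`, returns the largest
#' replication p-value `pr` that still yields replication success at the
#' overall level `alpha^2`.  Because `pr` is uniform when the replication
#' effect is truly null, this threshold equals the conditional Type-I error
#' rate of the procedure given the original result.
#'
#' The thresholds are `b - po` (Edgington, budget `b = sqrt(2) * alpha`),
#' `(bw - wo*po) / wr` (weighted Edgington), `min(cF / po, 1)` (Fisher),
#' `1 - pnorm(qnorm(1 - alpha^2) * sqrt(c + 1) - zo * sqrt(c))`
#' (meta-analysis), and `alpha` for the two-trials rule whenever
#' `po <= alpha` (0 otherwise, since success is then impossible).  The
#' Edgington thresholds are bounded by `b` and `bw / wr` respectively,
#' while the Fisher and meta-analysis thresholds tend to 1 as `po -> 0`:
#' those methods can declare success even when the replication itself is
#' entirely unconvincing.
#'
#' @param po numeric vector of original one-sided p-values in (0, 1).
#' @param method combination method, see [combinePValues()].
#' @param alpha one-sided level; overall level `alpha^2`.
#' @param wo,wr weights for `method = "edgington_weighted"`.
#' @param c variance ratio, required for `method = "meta"`.
#' @return numeric vector of conditional levels in `[0, 1]`.
#' @examples
#' conditionalLevel(0.001, "edgington")                  # ~ 3.4%
#' conditionalLevel(0.001, "edgington_weighted")         # 2.45%
#' conditionalLevel(0.0001, "fisher")                    # ~ 58.1%
#' conditionalLevel(0.0001, "meta", c = 1)               # ~ 19.9%
#' @export
conditionalLevel <- function(po, method = c("edgington", "edgington_weighted",
                                            "two_trials", "fisher", "meta"),
                             alpha = 0.025, wo = 1, wr = 2, c = NULL) {
  method <- .checkMethod(method)
  alpha <- .checkLevel(alpha)
  po <- .checkP(po)
  switch(method,
    edgington = pmin(pmax(successBudget(alpha) - po, 0), 1),
    edgington_weighted = {
      bw <- successBudget(alpha, wo, wr)
      pmin(pmax((bw - wo * po) / wr, 0), 1)
    },
    two_trials = ifelse(po <= alpha, alpha, 0),
    fisher = pmin(fisherCriticalProduct(alpha) / po, 1),
    meta = {
      if (is.null(c)) stop("the meta-analysis criterion requires 'c'",
                           call. = FALSE)
      c <- .checkPositive(c)
      zo <- stats::qnorm(1 - po)
      stats::pnorm(stats::qnorm(1 - alpha^2) * sqrt(c + 1) - zo * sqrt(c),
                   lower.tail = FALSE)
    })
}

#' Overall Type-I error rate by Monte-Carlo simulation
#'
#' Simulates independent uniform p-value pairs (the intersection null
#' hypothesis), applies the method's success rule at overall level
#' `alpha^2` and returns the empirical rejection rate with its binomial
#' standard error.  All five methods are calibrated so the rate equals
#' `alpha^2` (0.000625 at the standard `alpha = 0.025`).
#'
#' @inheritParams conditionalLevel
#' @param nsim number of simulated pairs, at least 1e5 (rejection is a rare
#'   event at the target magnitude).
#' @param seed integer seed for reproducibility.
#' @return list with elements `rate`, `se`, `nsim`.
#' @export
overallTypeI <- function(method, alpha = 0.025, nsim = 1e6, seed = 1,
                         wo = 1, wr = 2, c = 1) {
  method <- .checkMethod(method)
  if (nsim < 1e5) stop("'nsim' must be at least 1e5", call. = FALSE)
  pairs <- simulatePairs(nsim, muo = 0, c = c, seed = seed)
  mcSuccessRate(pairs, method, level = alpha^2, wo = wo, wr = wr)
}

# success probability of the replication given the original z-value, under
# z_r ~ N(mur, 1) and a replication-level threshold L on p_r
.prSuccess <- function(L, mur) {
  out <- numeric(length(L))
  out[L >= 1] <- 1
  mid <- L > 0 & L < 1
  out[mid] <- stats::pnorm(mur - stats::qnorm(1 - L[mid]))
  out
}

#' Project power of a replication success criterion
#'
#' Probability of correctly declaring replication success over the
#' randomness of both studies, under the normal model `zo ~ N(mu_o, 1)`,
#' `zr ~ N(d * sqrt(c) * mu_o, 1)` with `mu_o = qnorm(1 - alpha) +
#' qnorm(originalPower)` the noncentrality implied by the power of the
#' original study, `c = nr/no` the relative sample size and `d = theta_r /
#' theta_o` the ratio of true effect sizes (`d = 1/2` mimics the shrinkage
#' seen in replication projects).
#'
#' The two-trials rule and the meta-analysis criterion admit closed forms
#' (a product of two normal tails, and a single normal tail at the shifted
#' mean of `zMA`).  The Edgington variants and Fisher's method integrate
#' the conditional success probability over the distribution of `zo` by
#' adaptive quadrature on the z-scale (the integrand is smooth there,
#' unlike on the p-scale), truncated at `mu_o` plus/minus 8.5.
#'
#' @inheritParams conditionalLevel
#' @param originalPower power of the original study at level `alpha`, in
#'   (0, 1).
#' @param c positive relative sample size `nr / no`.
#' @param d ratio of true effect sizes `theta_r / theta_o` (default 1).
#' @param tol absolute quadrature tolerance.
#' @return project power, a probability.
#' @seealso [projectPowerLimit()] for the exact `c -> Inf` limit.
#' @export
projectPower <- function(method, originalPower = 0.8, c = 1, d = 1,
                         alpha = 0.025, wo = 1, wr = 2, tol = 1e-6) {
  method <- .checkMethod(method)
  alpha <- .checkLevel(alpha)
  if (originalPower <= 0 || originalPower >= 1)
    stop("'originalPower' must be in (0, 1)", call. = FALSE)
  c <- .checkPositive(c)
  if (d < 0) stop("'d' must be nonnegative", call. = FALSE)
  muo <- stats::qnorm(1 - alpha) + stats::qnorm(originalPower)
  mur <- d * sqrt(c) * muo
  if (method == "two_trials")
    return(stats::pnorm(muo - stats::qnorm(1 - alpha)) *
           stats::pnorm(mur - stats::qnorm(1 - alpha)))
  if (method == "meta") {
    m <- (muo + c * d * muo) / sqrt(1 + c)
    return(stats::pnorm(m - stats::qnorm(1 - alpha^2)))
  }
  levelFun <- switch(method,
    edgington = function(po) conditionalLevel(po, "edgington", alpha),
    edgington_weighted = function(po)
      conditionalLevel(po, "edgington_weighted", alpha, wo = wo, wr = wr),
    fisher = function(po) conditionalLevel(po, "fisher", alpha))
  integrand <- function(z) {
    po <- stats::pnorm(z, lower.tail = FALSE)
    stats::dnorm(z, mean = muo) * .prSuccess(levelFun(po), mur)
  }
  res <- tryCatch(
    stats::integrate(integrand, lower = muo - 8.5, upper = muo + 8.5,
                     abs.tol = tol, subdivisions = 500L),
    error = function(e)
      stop("project-power quadrature failed to converge: ",
           conditionMessage(e), call. = FALSE))
  min(max(res$value, 0), 1)
}

#' Limiting project power as the replication grows without bound
#'
#' For `c -> Inf` and a nonzero true replication effect (`d > 0`), the
#' replication p-value tends to 0 almost surely, so success only requires
#' the original study to stay within its share of the budget: `po <= alpha`
#' for the two-trials rule and `po <= bw / wo` for the Edgington variants.
#' The limit is the exact normal tail `pnorm(mu_o - qnorm(1 - L))`, which
#' is reported as a closed form rather than by evaluating the quadrature at
#' a huge `c`.
#'
#' For the two-trials rule the limit equals the original power itself: the
#' rule can never beat the original study.  Unweighted Edgington exceeds it
#' (limit 84% for 80% original power at `alpha = 0.025`) and the (1, 2)
#' weighted version more so (87.6%).
#'
#' @inheritParams projectPower
#' @return the limiting project power.
#' @export
projectPowerLimit <- function(method = c("two_trials", "edgington",
                                         "edgington_weighted"),
                              originalPower = 0.8, d = 1, alpha = 0.025,
                              wo = 1, wr = 2) {
  method <- match.arg(method)
  alpha <- .checkLevel(alpha)
  if (d <= 0)
    stop("the limit requires a nonzero replication effect (d > 0); ",
         "with d = 0 the replication p-value stays uniform and no limit ",
         "simplification applies", call. = FALSE)
  muo <- stats::qnorm(1 - alpha) + stats::qnorm(originalPower)
  L <- switch(method,
    two_trials = alpha,
    edgington = successBudget(alpha),
    edgington_weighted = successBudget(alpha, wo, wr) / wo)
  L <- min(L, 1)
  stats::pnorm(muo - stats::qnorm(1 - L))
}
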