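#' Significance level for the replication study at the design stage
#'
#' The level the replication study must reach for overall success, given
#' the original p-value: numerically identical to [conditionalLevel()] but
#' intended for planning, so an original result for which success has
#' become impossible raises an error instead of returning 0.  For
#' unweighted Edgington the level is `sqrt(2)*alpha - po` (about
#' `0.035 - po`), for the (1, 2) weighted version `alpha - po/2`, and for
#' the two-trials rule it is `alpha` regardless of `po`.
#'
#' @inheritParams conditionalLevel
#' @return the replication-study significance level `alpha'` in (0, 1).
#' @examples
#' replicationLevel(0.035, "edgington_weighted")   # 0.0075
#' replicationLevel(0.025 * (sqrt(2) - 1), "edgington")  # exactly 0.025
#' @export
replicationLevel <- function(po, method = c("edgington",
                                            "edgington_weighted",
                                            "two_trials", "fisher", "meta"),
                             alpha = 0.025, wo = 1, wr = 2, c = NULL) {
  method <- .checkMethod(method)
  lev <- conditionalLevel(po, method, alpha = alpha, wo = wo, wr = wr, c = c)
  if (any(lev <= 0)) {
    bound <- switch(method,
      edgington = successBudget(alpha),
      edgington_weighted = successBudget(alpha, wo, wr) / wo,
      two_trials = alpha,
      fisher = , meta = 1)
    stop("replication success is impossible for this original result ",
         "(admissibility bound on po: ", format(bound), ")", call. = FALSE)
  }
  lev
}

#' Absolute replication sample size per group
#'
#' Standard sample-size formula for a balanced two-sample z-test,
#' `nr = 2 * tau^2 * (z_{1-level} + z_{1-beta})^2 / thetaHat^2`, with the
#' minimal clinically important difference replaced by the original effect
#' estimate `thetaHat` and the significance level replaced by the
#' method-specific replication level from [replicationLevel()].  The
#' estimate can be shrunk (typically by 25% or 50%) before use, to offset
#' the inflation of published effect estimates.
#'
#' @param thetaHat original effect estimate (nonzero).
#' @param tau common standard deviation of the measurements.
#' @param po original one-sided p-value; determines the replication level
#'   for Edgington-type methods.  Ignored for `method = "two_trials"`.
#' @param method combination method the replication will be analysed with.
#' @param power target conditional power `1 - beta`.
#' @param alpha one-sided level.
#' @param wo,wr weights for the weighted method.
#' @param shrinkage fraction in `[0, 1)` by which `thetaHat` is reduced
#'   before the calculation.
#' @return list with `nr` (real-valued per-group size), `n` (rounded up)
#'   and `level` (the replication significance level used).
#' @examples
#' sampleSizeReplication(thetaHat = 0.5, tau = 1, method = "two_trials")
#' @export
sampleSizeReplication <- function(thetaHat, tau, po = NULL,
                                  method = "two_trials", power = 0.8,
                                  alpha = 0.025, wo = 1, wr = 2,
                                  shrinkage = 0) {
  method <- .checkMethod(method)
  if (thetaHat == 0) stop("'thetaHat' must be nonzero", call. = FALSE)
  tau <- .checkPositive(tau)
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)", call. = FALSE)
  if (shrinkage < 0 || shrinkage >= 1)
    stop("'shrinkage' must be in [0, 1)", call. = FALSE)
  level <- if (method == "two_trials") alpha
           else replicationLevel(po, method, alpha, wo, wr)
  theta <- thetaHat * (1 - shrinkage)
  nr <- 2 * tau^2 * (stats::qnorm(1 - level) + stats::qnorm(power))^2 / theta^2
  list(nr = nr, n = ceiling(nr), level = level)
}

#' Relative replication sample size
#'
#' The required relative sample size `c = nr / no` of the replication
#' study.  Under conditional power (treating the original estimate as the
#' truth) this is the closed form `c = (z_{1-level} + z_{1-beta})^2 /
#' zo^2`; under predictive power (averaging over the uncertainty of the
#' original estimate) `c` solves `predictivePower(zo, c, level) = power`
#' by monotone root-finding on `sqrt(c)`.
#'
#' @param po original one-sided p-value (must correspond to `zo > 0`,
#'   i.e. `po < 0.5`); alternatively supply `zo` directly.
#' @param zo original z-value, `qnorm(1 - po)`.
#' @inheritParams sampleSizeReplication
#' @param mode `"conditional"` or `"predictive"` power.
#' @return the relative sample size `c`.
#' @examples
#' # an 80%-powered original needs an equally large replication under the
#' # two-trials rule:
#' relativeSampleSize(zo = qnorm(0.975) + qnorm(0.8), method = "two_trials")
#' @export
relativeSampleSize <- function(po = NULL, zo = NULL, method = "two_trials",
                               power = 0.8, alpha = 0.025, wo = 1, wr = 2,
                               mode = c("conditional", "predictive")) {
  mode <- match.arg(mode)
  method <- .checkMethod(method)
  if (is.null(zo)) {
    if (is.null(po)) stop("supply 'po' or 'zo'", call. = FALSE)
    zo <- stats::qnorm(1 - .checkP(po))
  } else if (is.null(po)) {
    po <- stats::pnorm(zo, lower.tail = FALSE)
  }
  if (zo <= 0)
    stop("'zo' must be positive (original estimate in the right direction)",
         call. = FALSE)
  level <- if (method == "two_trials") alpha
           else replicationLevel(po, method, alpha, wo, wr)
  if (mode == "conditional")
    return((stats::qnorm(1 - level) + stats::qnorm(power))^2 / zo^2)
  .predictiveC(zo, level, power)
}

# root-solve predictive power = target on the sqrt(c) scale, where the
# predictive power is strictly increasing with limit pnorm(zo)
.predictiveC <- function(zo, level, power) {
  if (power >= stats::pnorm(zo))
    stop("target predictive power ", power, " is unattainable: the limit ",
         "for c -> Inf is pnorm(zo) = ", format(stats::pnorm(zo)),
         call. = FALSE)
  f <- function(s) predictivePower(zo, s^2, level) - power
  lo <- 1e-3; hi <- 1e3
  if (f(lo) * f(hi) > 0)
    stop("predictive sample-size root not bracketed on sqrt(c) in [",
         lo, ", ", hi, "]", call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root^2
}

#' Predictive power of a replication study
#'
#' Probability that the replication reaches one-sided significance at
#' `level`, averaged over the normal predictive distribution of the
#' replication estimate given the original one
#' (`thetaHat_r | thetaHat_o ~ N(thetaHat_o, sigma_o^2 + sigma_r^2)`):
#' `pnorm((zo * sqrt(c) - qnorm(1 - level)) / sqrt(c + 1))`.  Predictive
#' power accounts for the uncertainty of the original estimate that
#' conditional power ignores, and leads to generally larger replication
#' sample sizes.
#'
#' @param zo original z-value.
#' @param c relative sample size `nr / no`.
#' @param level one-sided significance level required of the replication.
#' @return a probability.
#' @export
predictivePower <- function(zo, c, level) {
  c <- .checkPositive(c)
  level <- .checkLevel(level, upper = 1)
  stats::pnorm((zo * sqrt(c) - stats::qnorm(1 - level)) / sqrt(c + 1))
}

#' Replication sample-size ratio of Edgington's method vs. the two-trials rule
#'
#' Ratio of the relative sample size required when the replication will be
#' analysed with an Edgington-type method to the one required under the
#' two-trials rule, at the same target power.  In conditional mode this is
#' the closed form
#' `(z_{1-level'} + z_{1-beta})^2 / (z_{1-alpha} + z_{1-beta})^2` with
#' `level'` the method's replication level, and does not depend on `zo`
#' beyond `po`.  In predictive mode both sample sizes are obtained by
#' root-finding and the ratio is taken.  A ratio below 1 means Edgington's
#' method needs a smaller replication: for the unweighted method this
#' happens exactly when `po < alpha * (sqrt(2) - 1)` (about 0.01 at
#' `alpha = 0.025`), with a maximal saving of about 10.6% at 80% power.
#'
#' @inheritParams relativeSampleSize
#' @param method `"edgington"` or `"edgington_weighted"`.
#' @return the sample-size ratio (Edgington / two-trials); the reduction is
#'   one minus the ratio.
#' @export
sampleSizeRatio <- function(po, power = 0.8, alpha = 0.025,
                            method = c("edgington", "edgington_weighted"),
                            wo = 1, wr = 2,
                            mode = c("conditional", "predictive")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  po <- .checkP(po)
  if (any(po > alpha))
    stop("'po' must be at most alpha for the two-trials comparator",
         call. = FALSE)
  level <- replicationLevel(po, method, alpha, wo, wr)
  if (mode == "conditional") {
    zb <- stats::qnorm(power)
    return((stats::qnorm(1 - level) + zb)^2 / (stats::qnorm(1 - alpha) + zb)^2)
  }
  zo <- stats::qnorm(1 - po)
  cE <- mapply(.predictiveC, zo, level, MoreArgs = list(power = power))
  c2 <- mapply(.predictiveC, zo, alpha, MoreArgs = list(power = power))
  cE / c2
}
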