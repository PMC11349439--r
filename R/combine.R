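#' Combined p-value from the sum of two p-values (Edgington's method)
#'
#' Adds the one-sided p-values from the original and the replication study
#' and refers the sum `E = po + pr` to the Irwin-Hall distribution with two
#' summands.  Under the intersection null hypothesis (no effect in either
#' study) the result is uniformly distributed, so `pEdgington(po, pr) <=
#' alpha^2` controls the overall Type-I error rate at the same level
#' `alpha^2` as the two-trials rule while still allowing success when one of
#' the two studies is marginally non-significant.
#'
#' @param po,pr numeric vectors of one-sided p-values in (0, 1).  Values
#'   above 0.5 correspond to effect estimates pointing in the wrong
#'   direction and need no special treatment.
#' @return numeric vector of combined p-values; symmetric in `po` and `pr`.
#' @seealso [pEdgingtonWeighted()] for unequal study weights,
#'   [successBudget()] for the equivalent threshold on the p-value sum.
#' @examples
#' pEdgington(0.026, 0.001)  # succeeds at 0.025^2; the two-trials rule fails
#' pEdgington(0.024, 0.024)  # fails at 0.025^2; the two-trials rule succeeds
#' @export
pEdgington <- function(po, pr) {
  po <- .checkP(po); pr <- .checkP(pr)
  pIrwinHall(po + pr, 2L)
}

#' Weighted Edgington combined p-value
#'
#' Combined p-value for the weighted sum `Ew = wo*po + wr*pr`.  Upweighting
#' the replication study (e.g. `wo = 1`, `wr = 2`) guards against bias in
#' the original study: success then additionally requires `pr <= alpha`,
#' just as under the two-trials rule.  Only the weight ratio `wr/wo`
#' matters; rescaling both weights by a positive constant leaves the
#' p-value unchanged, and equal weights reduce exactly to [pEdgington()].
#'
#' The distribution function of `wo*U1 + wr*U2` is piecewise quadratic /
#' linear / quadratic with break points at the two weights.  It is stated
#' for `wo <= wr`; because the distribution is symmetric in the weight
#' labels, arbitrary positive weights are handled by letting the smaller
#' weight play the `wo` role (together with its paired p-value).  Sums
#' falling exactly on a break point are evaluated with the lower branch
#' (branches closed on the right).
#'
#' @inheritParams pEdgington
#' @param wo,wr positive study weights (original, replication).  Defaults
#'   `(1, 2)` double-weight the replication study.
#' @return numeric vector of combined p-values.
#' @examples
#' pEdgingtonWeighted(0.035, 0.0075, 1, 2)  # exactly 0.025^2: boundary success
#' pEdgingtonWeighted(0.024, 0.024, 3, 3)   # equal weights = pEdgington(0.024, 0.024)
#' @export
pEdgingtonWeighted <- function(po, pr, wo = 1, wr = 2) {
  po <- .checkP(po); pr <- .checkP(pr)
  wo <- .checkPositive(wo); wr <- .checkPositive(wr)
  k <- pmax(length(po), length(pr))
  po <- rep_len(po, k); pr <- rep_len(pr, k)
  wo <- rep_len(wo, k); wr <- rep_len(wr, k)
  # put the smaller weight in the 'wo' slot; the distribution of
  # wo*U1 + wr*U2 does not care which label carries which weight
  swap <- wo > wr
  tmp <- wo[swap]; wo[swap] <- wr[swap]; wr[swap] <- tmp
  ew <- ifelse(swap, wo * pr + wr * po, wo * po + wr * pr)
  p <- numeric(k)
  b1 <- ew <= wo
  b2 <- ew > wo & ew <= wr
  b3 <- ew > wr
  p[b1] <- ew[b1]^2 / (2 * wo[b1] * wr[b1])
  p[b2] <- (ew[b2] - wo[b2] / 2) / wr[b2]
  w <- wo[b3] + wr[b3]
  p[b3] <- 1 + (ew[b3] * w - w^2 / 2 - ew[b3]^2 / 2) / (wo[b3] * wr[b3])
  pmin(pmax(p, 0), 1)
}

#' Combined p-value of the two-trials rule
#'
#' The two-trials rule requires both one-sided p-values to be at most
#' `alpha`; the corresponding valid combined p-value is the squared maximum,
#' so success at overall level `alpha^2` is `max(po, pr)^2 <= alpha^2`.
#'
#' @inheritParams pEdgington
#' @return `pmax(po, pr)^2`.
#' @export
pTwoTrials <- function(po, pr) {
  po <- .checkP(po); pr <- .checkP(pr)
  pmax(po, pr)^2
}

#' Fisher's combination p-value for two studies
#'
#' Refers `-2 log(po * pr)` to a chi-squared distribution with 4 degrees of
#' freedom.  Fisher's method rewards a very small product, so replication
#' success at level `alpha^2` is guaranteed whenever
#' `po < fisherCriticalProduct(alpha)` no matter how unconvincing the
#' replication is — the reason it is kept here only as a calibrated
#' comparator.
#'
#' @inheritParams pEdgington
#' @return upper-tail chi-squared(4) probability at `-2 log(po * pr)`.
#' @export
pFisher <- function(po, pr) {
  po <- .checkP(po); pr <- .checkP(pr)
  stats::pchisq(-2 * log(po * pr), df = 4, lower.tail = FALSE)
}

#' Meta-analytic (pooled) combined p-value
#'
#' Fixed-effect meta-analysis of the two studies, identical to weighted
#' Stouffer's method: the z-values `zo = qnorm(1 - po)` and
#' `zr = qnorm(1 - pr)` are averaged with weights proportional to the
#' inverse standard errors, `zMA = (zo + sqrt(c) * zr) / sqrt(1 + c)`,
#' where `c = sigma_o^2 / sigma_r^2` is the variance ratio (interpretable
#' as the relative sample size `nr/no`).  Like Fisher's method, a large
#' `zMA` can arise from a single overwhelming study, so the criterion does
#' not require the replication itself to be convincing.
#'
#' @inheritParams pEdgington
#' @param c positive variance ratio `sigma_o^2 / sigma_r^2` (equivalently
#'   relative sample size `nr / no`); required.
#' @return `1 - pnorm(zMA)`.
#' @export
pMeta <- function(po, pr, c) {
  if (missing(c) || is.null(c) || anyNA(c))
    stop("the meta-analysis criterion requires the variance ratio 'c' ",
         "(sigma_o^2 / sigma_r^2)", call. = FALSE)
  po <- .checkP(po); pr <- .checkP(pr)
  c <- .checkPositive(c)
  zo <- stats::qnorm(1 - po)
  zr <- stats::qnorm(1 - pr)
  zma <- (zo + sqrt(c) * zr) / sqrt(1 + c)
  stats::pnorm(zma, lower.tail = FALSE)
}

#' Budget for the (weighted) sum of two p-values
#'
#' The largest value of `Ew = wo*po + wr*pr` that still achieves
#' `pEdgingtonWeighted(po, pr, wo, wr) <= alpha^2`:
#' `bw = sqrt(2 * wo * wr) * alpha`.  With equal weights this is the
#' familiar `b = sqrt(2) * alpha` (about 0.035 at `alpha = 0.025`); with
#' weights (1, 2) it is `2 * alpha = 0.05`.  The closed form inverts the
#' first branch of the piecewise CDF and is therefore only valid when
#' `bw <= min(wo, wr)`; other configurations raise an error pointing at
#' numerical inversion.
#'
#' @param alpha one-sided significance level in (0, 0.5); the overall level
#'   is `alpha^2`.
#' @param wo,wr positive study weights.
#' @return the budget `bw` on the weighted p-value sum.
#' @examples
#' successBudget(0.025)        # sqrt(2) * 0.025 ~ 0.0354
#' successBudget(0.025, 1, 2)  # 0.05
#' @export
successBudget <- function(alpha = 0.025, wo = 1, wr = 1) {
  alpha <- .checkLevel(alpha)
  wo <- .checkPositive(wo); wr <- .checkPositive(wr)
  bw <- sqrt(2 * wo * wr) * alpha
  if (any(bw > pmin(wo, wr)))
    stop("budget exceeds the first branch of the piecewise CDF ",
         "(bw > min(wo, wr)); invert pEdgingtonWeighted numerically instead",
         call. = FALSE)
  bw
}

#' Critical p-value product of Fisher's combination method
#'
#' `cF = exp(-qchisq(1 - alpha^2, df = 4) / 2)`: whenever `po * pr <= cF`
#' Fisher's method declares success at overall level `alpha^2`.  At
#' `alpha = 0.025`, `cF` is about 6e-5, so an original study below that
#' value guarantees success regardless of the replication result.
#'
#' @inheritParams successBudget
#' @return the critical product `cF`.
#' @export
fisherCriticalProduct <- function(alpha = 0.025) {
  alpha <- .checkLevel(alpha)
  exp(-0.5 * stats::qchisq(1 - alpha^2, df = 4))
}

#' Combine an original and a replication p-value with a chosen method
#'
#' One-stop front end to the five combination methods.  Returns the
#' combined p-value together with the underlying statistic and the success
#' indicator at the overall level `alpha^2`, with success at exact equality
#' counting as success.
#'
#' @inheritParams pEdgington
#' @param method one of `"edgington"`, `"edgington_weighted"`,
#'   `"two_trials"`, `"fisher"`, `"meta"`.
#' @param wo,wr weights for the weighted Edgington method.
#' @param c variance ratio, required for `method = "meta"`.
#' @param alpha one-sided level; the success threshold is `alpha^2`.
#' @return a `data.frame` with columns `method`, `statistic` (the p-value
#'   sum, weighted sum, maximum p-value, p-value product, or meta-analytic
#'   z-value), `p` (combined p-value) and `success` (logical,
#'   `p <= alpha^2`).
#' @examples
#' combinePValues(0.026, 0.001, method = "edgington")
#' combinePValues(0.024, 0.024, method = "two_trials")
#' @export
combinePValues <- function(po, pr,
                           method = c("edgington", "edgington_weighted",
                                      "two_trials", "fisher", "meta"),
                           wo = 1, wr = 2, c = NULL, alpha = 0.025) {
  method <- .checkMethod(method)
  alpha <- .checkLevel(alpha)
  po <- .checkP(po); pr <- .checkP(pr)
  stat <- switch(method,
    edgington          = po + pr,
    edgington_weighted = wo * po + wr * pr,
    two_trials         = pmax(po, pr),
    fisher             = po * pr,
    meta = {
      if (is.null(c)) stop("the meta-analysis criterion requires 'c'",
                           call. = FALSE)
      (stats::qnorm(1 - po) + sqrt(c) * stats::qnorm(1 - pr)) / sqrt(1 + c)
    })
  p <- switch(method,
    edgington          = pEdgington(po, pr),
    edgington_weighted = pEdgingtonWeighted(po, pr, wo, wr),
    two_trials         = pTwoTrials(po, pr),
    fisher             = pFisher(po, pr),
    meta               = pMeta(po, pr, c))
  data.frame(method = method, statistic = stat, p = p,
             success = p <= alpha^2)
}
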