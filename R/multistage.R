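#' Budget on the sum of p-values from n studies
#'
#' The largest value of the p-value sum `E = p_1 + ... + p_n` whose
#' Irwin-Hall combined p-value is still at most `alpha2`: inverts the
#' small-sum branch `b^n / n!` of the Irwin-Hall CDF, `b = (n! *
#' alpha2)^(1/n)`.  With one original and two replications at overall
#' level `0.025^2` the budget is about 0.155 (typically quoted as 0.16).
#'
#' @param alpha2 overall Type-I error level, e.g. `0.025^2`.
#' @param n number of studies (at least 2).
#' @return the budget `b`; errors if the closed form leaves its branch of
#'   validity (`b > 1`), where full CDF inversion would be needed.
#' @examples
#' budgetN(0.025^2, 2)  # sqrt(2) * 0.025
#' budgetN(0.025^2, 3)  # ~ 0.155
#' @export
budgetN <- function(alpha2, n) {
  if (alpha2 <= 0 || alpha2 >= 1) stop("'alpha2' must be in (0, 1)",
                                       call. = FALSE)
  if (length(n) != 1L || n != round(n) || n < 2)
    stop("'n' must be a single integer >= 2", call. = FALSE)
  b <- (factorial(n) * alpha2)^(1 / n)
  if (b > 1)
    stop("budget exceeds 1; the small-sum branch of the Irwin-Hall CDF no ",
         "longer applies and the full CDF must be inverted numerically",
         call. = FALSE)
  b
}

#' Two-stage alpha-spending plan for sequential replications
#'
#' Distributes the overall level `alpha2` over analyses after the first and
#' the second replication study.  A `fraction` of `alpha2` is spent at
#' stage 1, giving the stage-1 budget `b2 = sqrt(2 * fraction * alpha2)` on
#' `E2 = po + pr1`; the final budget `b3` on `E3 = po + pr1 + pr2` then
#' solves
#' \deqn{\int_{b_2}^{b_3} e\,(b_3 - e)\, de = (1 - fraction)\,\alpha_2,}
#' i.e. `b3*(b3^2 - b2^2)/2 - (b3^3 - b2^3)/3 = (1 - fraction)*alpha2`,
#' so that `Pr(E2 <= b2) + Pr(E2 > b2, E3 <= b3) = alpha2` under the
#' intersection null.  The integrand uses the exact small-sum density
#' `f(e) = e` of the sum of two uniforms, valid because all budgets here
#' are far below 1.  `b3` is found by Brent root-finding on `(b2, 1]` to
#' 1e-10.
#'
#' Spending half of `0.025^2` at stage 1 gives `b2 = 0.025` and `b3` about
#' 0.128 (typically quoted as 0.13).
#'
#' @param alpha2 overall Type-I error level.
#' @param fraction proportion of `alpha2` spent at the first replication,
#'   in (0, 1).
#' @return an object of class `"spendingPlan"`: a list with `alpha2`,
#'   `fraction`, `b2`, `b3`.
#' @seealso [sequentialAssess()] for applying the plan to observed
#'   p-values.
#' @export
spendingPlan <- function(alpha2 = 0.025^2, fraction = 0.5) {
  if (alpha2 <= 0 || alpha2 >= 1) stop("'alpha2' must be in (0, 1)",
                                       call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must be in (0, 1)", call. = FALSE)
  b2 <- sqrt(2 * fraction * alpha2)
  target <- (1 - fraction) * alpha2
  g <- function(b3) b3 * (b3^2 - b2^2) / 2 - (b3^3 - b2^3) / 3 - target
  if (g(1) < 0)
    stop("no stage-2 budget in (b2, 1] satisfies the spending equation",
         call. = FALSE)
  b3 <- stats::uniroot(g, c(b2, 1), tol = 1e-10)$root
  # Newton polish (g' = (b3^2 - b2^2) / 2) to machine precision
  for (i in 1:3) b3 <- b3 - g(b3) / ((b3^2 - b2^2) / 2)
  structure(list(alpha2 = alpha2, fraction = fraction, b2 = b2, b3 = b3),
            class = "spendingPlan")
}

#' @export
print.spendingPlan <- function(x, digits = 4, ...) {
  cat("Two-stage alpha-spending plan\n")
  cat("  overall level alpha2:", format(x$alpha2, digits = digits), "\n")
  cat("  fraction spent at stage 1:", format(x$fraction, digits = digits),
      "\n")
  cat("  stage-1 budget b2 (on po + pr1):    ",
      format(x$b2, digits = digits), "\n")
  cat("  final budget b3 (on po + pr1 + pr2):",
      format(x$b3, digits = digits), "\n")
  invisible(x)
}

#' Sequential assessment of one original and up to two replications
#'
#' Applies a two-stage [spendingPlan()]: after the first replication,
#' success is declared if `E2 = po + pr1 <= b2`; if `E2 > b3` success has
#' become arithmetically impossible and the procedure stops for futility
#' (no predictive futility bound is involved); otherwise a second
#' replication is run at significance level `b3 - E2` and final success
#' requires `E3 = E2 + pr2 <= b3`.
#'
#' @param po,pr1 one-sided p-values of the original and first replication.
#' @param pr2 one-sided p-value of the second replication, or `NULL` if not
#'   (yet) conducted.  Supplying `pr2` after a stage-1 success or futility
#'   stop is an error: the procedure had already terminated.
#' @param plan a [spendingPlan()].
#' @return an object of class `"sequentialDecision"`: a list with `stage`
#'   (1 or 2), `verdict` (`"success"`, `"futility_stop"`, `"continue"` or
#'   `"failure"`), `E2`, `E3` (NA at stage 1) and `remainingLevel` (the
#'   level `b3 - E2` available to the second replication when the verdict
#'   is `"continue"`, otherwise NA).
#' @examples
#' plan <- spendingPlan(0.025^2, 0.5)
#' sequentialAssess(0.01, 0.01, plan = plan)          # stage-1 success
#' sequentialAssess(0.04, 0.05, 0.03, plan = plan)    # success at stage 2
#' @export
sequentialAssess <- function(po, pr1, pr2 = NULL, plan) {
  if (!inherits(plan, "spendingPlan")) stop("'plan' must be a spendingPlan",
                                            call. = FALSE)
  po <- .checkP(po); pr1 <- .checkP(pr1)
  e2 <- po + pr1
  if (e2 <= plan$b2) {
    if (!is.null(pr2))
      stop("invalid sequence: the procedure stopped for success at stage 1; ",
           "no second replication should have been conducted", call. = FALSE)
    return(.seqDecision(1L, "success", e2, NA_real_, NA_real_))
  }
  if (e2 > plan$b3) {
    if (!is.null(pr2))
      stop("invalid sequence: the procedure stopped for futility at stage 1; ",
           "no second replication should have been conducted", call. = FALSE)
    return(.seqDecision(1L, "futility_stop", e2, NA_real_, NA_real_))
  }
  if (is.null(pr2))
    return(.seqDecision(1L, "continue", e2, NA_real_, plan$b3 - e2))
  pr2 <- .checkP(pr2)
  e3 <- e2 + pr2
  .seqDecision(2L, if (e3 <= plan$b3) "success" else "failure",
               e2, e3, NA_real_)
}

.seqDecision <- function(stage, verdict, e2, e3, remaining) {
  structure(list(stage = stage, verdict = verdict, E2 = e2, E3 = e3,
                 remainingLevel = remaining),
            class = "sequentialDecision")
}

#' @export
print.sequentialDecision <- function(x, digits = 4, ...) {
  cat("Sequential replication assessment (stage ", x$stage, ")\n", sep = "")
  cat("  E2 =", format(x$E2, digits = digits))
  if (!is.na(x$E3)) cat(", E3 =", format(x$E3, digits = digits))
  cat("\n  verdict:", x$verdict, "\n")
  if (x$verdict == "continue")
    cat("  second replication to be run at level",
        format(x$remainingLevel, digits = digits), "\n")
  invisible(x)
}
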