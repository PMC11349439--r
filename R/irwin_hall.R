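#' Irwin-Hall cumulative distribution function
#'
#' Distribution function of the sum of `n` independent standard uniform
#' random variables.  The sum of `n` independent p-values follows this
#' distribution under the intersection null hypothesis, which is what turns a
#' p-value sum into a valid combined p-value.
#'
#' The alternating-sum closed form
#' \deqn{F(x) = \frac{1}{n!}\sum_{k=0}^{\lfloor x\rfloor} (-1)^k \binom{n}{k}(x-k)^n}
#' is used with compensated (Kahan) summation.  The closed form suffers
#' catastrophic cancellation for large `n`, so `n` is restricted to at most
#' 10; replication settings need `n` of 2 or 3.
#'
#' @param q numeric vector of quantiles.
#' @param n integer, number of uniform summands (1 to 10).
#' @return `Pr(U_1 + ... + U_n <= q)`, 0 for `q <= 0` and 1 for `q >= n`.
#' @examples
#' pIrwinHall(1, 2)        # 0.5 by symmetry
#' pIrwinHall(0.048, 2)    # 0.048^2 / 2
#' @export
pIrwinHall <- function(q, n) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n != round(n) || n < 1)
    stop("'n' must be a single positive integer", call. = FALSE)
  if (n > 10)
    stop("'n' larger than 10 is not supported (closed form is unstable)",
         call. = FALSE)
  n <- as.integer(n)
  vapply(q, function(x) {
    if (is.na(x)) return(NA_real_)
    if (x <= 0) return(0)
    if (x >= n) return(1)
    # Kahan-compensated alternating sum
    s <- 0; comp <- 0
    for (k in 0:floor(x)) {
      term <- (-1)^k * choose(n, k) * (x - k)^n
      y <- term - comp
      t <- s + y
      comp <- (t - s) - y
      s <- t
    }
    min(max(s / factorial(n), 0), 1)
  }, numeric(1))
}
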