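# internal input checks shared by all user-facing functions

.P_EPS <- 1e-16

## validate a vector of p-values; values exactly 0 or 1 are clipped to
## [.P_EPS, 1 - .P_EPS] with a warning so that z-transforms stay finite,
## anything outside [0, 1] is an error
.checkP <- function(p, name = deparse(substitute(p))) {
  if (!is.numeric(p) || anyNA(p))
    stop("'", name, "' must be numeric without missing values", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("'", name, "' must lie in [0, 1]", call. = FALSE)
  if (any(p == 0 | p == 1)) {
    warning("'", name, "' contains values of exactly 0 or 1; clipping to [",
            .P_EPS, ", ", 1 - .P_EPS, "]", call. = FALSE)
    p <- pmin(pmax(p, .P_EPS), 1 - .P_EPS)
  }
  p
}

.checkPositive <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0))
    stop("'", name, "' must be positive", call. = FALSE)
  x
}

.checkLevel <- function(alpha, upper = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= upper)
    stop("'alpha' must be a single value in (0, ", upper, ")", call. = FALSE)
  alpha
}

.METHODS <- c("edgington", "edgington_weighted", "two_trials", "fisher", "meta")

.checkMethod <- function(method) match.arg(method, .METHODS)
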