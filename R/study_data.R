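#' One-sided p-value from a correlation-scale effect estimate
#'
#' Converts a correlation coefficient and its sample size to a one-sided
#' p-value via Fisher's z-transformation: `p = 1 - pnorm(atanh(r) *
#' sqrt(n - 3))`, using the standard error `1 / sqrt(n - 3)` on the
#' z-scale.  Negative correlations (estimates pointing against the
#' pre-specified direction) give p-values above 0.5.
#'
#' @param r correlation coefficient in (-1, 1).
#' @param n sample size, at least 4 (the standard error is undefined
#'   below).
#' @return one-sided p-value in (0, 1).
#' @examples
#' pFromCorrelation(0.5, 28)
#' @export
pFromCorrelation <- function(r, n) {
  if (any(abs(r) >= 1)) stop("'r' must lie strictly inside (-1, 1)",
                             call. = FALSE)
  if (any(n < 4)) stop("'n' must be at least 4", call. = FALSE)
  stats::pnorm(atanh(r) * sqrt(n - 3), lower.tail = FALSE)
}

#' Read a table of original/replication study pairs
#'
#' Reads a UTF-8 CSV with a header row and one row per study pair, in one
#' of two layouts (mirroring the structure of public replication-project
#' tables):
#' \itemize{
#'   \item direct p-values: columns `study_id, po, pr` and optionally `c`;
#'   \item correlation scale: columns `study_id, ro, no, rr, nr`, from
#'     which one-sided p-values are recomputed with [pFromCorrelation()]
#'     and the variance ratio defaults to `(nr - 3) / (no - 3)` (the ratio
#'     of squared Fisher-z standard errors).
#' }
#' When both direct p-values and correlation columns are present the
#' direct p-values win and a warning is issued.  Without sample sizes the
#' variance ratio defaults to 1.
#'
#' @param file path to the CSV file.
#' @return a `data.frame` with columns `study_id`, `po`, `pr`, `c`.
#' @export
readStudyPairs <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  cols <- names(d)
  if (!"study_id" %in% cols) stop("missing 'study_id' column", call. = FALSE)
  hasP <- all(c("po", "pr") %in% cols)
  hasR <- all(c("ro", "no", "rr", "nr") %in% cols)
  if (!hasP && !hasR)
    stop("need either columns po, pr or columns ro, no, rr, nr",
         call. = FALSE)
  if (hasP && hasR)
    warning("both direct p-values and correlation-scale estimates present; ",
            "using the direct p-values", call. = FALSE)
  if (hasP) {
    po <- d$po; pr <- d$pr
  } else {
    po <- pFromCorrelation(d$ro, d$no)
    pr <- pFromCorrelation(d$rr, d$nr)
  }
  c <- if ("c" %in% cols) d$c
       else if (all(c("no", "nr") %in% cols)) (d$nr - 3) / (d$no - 3)
       else rep(1, nrow(d))
  data.frame(study_id = d$study_id, po = po, pr = pr, c = c,
             stringsAsFactors = FALSE)
}

#' Assess replication success of study pairs under several methods
#'
#' Computes the combined p-value and the success flag at the stated
#' overall level for every study pair and every requested method, plus the
#' project-level success rate per method.  Records with missing or invalid
#' inputs yield `NA` entries (with a warning) rather than aborting the
#' whole table.
#'
#' @param pairs a `data.frame` with columns `po`, `pr` and optionally `c`
#'   (required by the meta-analysis criterion) and `study_id`; e.g. from
#'   [readStudyPairs()] or [simulatePairs()].
#' @param methods character vector of methods to apply.
#' @param level overall Type-I error level (default `0.025^2`).
#' @param wo,wr weights for the weighted Edgington method.
#' @return an object of class `"replicationAssessment"`: a list with
#'   `table` (per-pair combined p-values `p_<method>` and flags
#'   `success_<method>`), `rates` (named success proportions, `NA` when no
#'   pair could be assessed) and `level`.
#' @examples
#' pairs <- data.frame(study_id = c("a", "b"),
#'                     po = c(0.027, 0.024), pr = c(0.006, 0.024), c = 1)
#' assessReplication(pairs)
#' @export
assessReplication <- function(pairs,
                              methods = c("two_trials", "edgington",
                                          "edgington_weighted", "fisher",
                                          "meta"),
                              level = 0.025^2, wo = 1, wr = 2) {
  methods <- vapply(methods, .checkMethod, character(1))
  if (!all(c("po", "pr") %in% names(pairs)))
    stop("'pairs' must have columns 'po' and 'pr'", call. = FALSE)
  out <- if ("study_id" %in% names(pairs))
    data.frame(study_id = pairs$study_id, po = pairs$po, pr = pairs$pr,
               stringsAsFactors = FALSE)
  else data.frame(po = pairs$po, pr = pairs$pr)
  rates <- stats::setNames(numeric(length(methods)), methods)
  for (m in methods) {
    p <- rep(NA_real_, nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      p[i] <- tryCatch(switch(m,
        edgington          = pEdgington(pairs$po[i], pairs$pr[i]),
        edgington_weighted = pEdgingtonWeighted(pairs$po[i], pairs$pr[i],
                                                wo, wr),
        two_trials         = pTwoTrials(pairs$po[i], pairs$pr[i]),
        fisher             = pFisher(pairs$po[i], pairs$pr[i]),
        meta               = pMeta(pairs$po[i], pairs$pr[i], pairs$c[i])),
        error = function(e) { warning("record ", i, " (", m, "): ",
                                      conditionMessage(e), call. = FALSE)
                              NA_real_ })
    }
    out[[paste0("p_", m)]] <- p
    out[[paste0("success_", m)]] <- p <= level
    rates[m] <- if (all(is.na(p))) NA_real_ else mean(p <= level,
                                                      na.rm = TRUE)
  }
  structure(list(table = out, rates = rates, level = level),
            class = "replicationAssessment")
}

#' @export
print.replicationAssessment <- function(x, digits = 4, ...) {
  cat("Replication assessment of", nrow(x$table), "study pairs at overall",
      "level", format(x$level, digits = digits), "\n")
  cat("Success rates:\n")
  print(round(x$rates, digits))
  invisible(x)
}

#' Success rate as a function of the overall level
#'
#' For each method, the proportion of study pairs declared successful at
#' each overall level in `levels`.  The curves are nondecreasing in the
#' level by construction; comparing the two-trials curve with the
#' Edgington curves shows where the methods disagree.
#'
#' @inheritParams assessReplication
#' @param levels numeric vector of overall levels in (0, 1].
#' @return a long `data.frame` with columns `method`, `level`, `rate`.
#' @export
successRateCurve <- function(pairs,
                             methods = c("two_trials", "edgington",
                                         "edgington_weighted"),
                             levels, wo = 1, wr = 2) {
  methods <- vapply(methods, .checkMethod, character(1))
  if (any(levels <= 0 | levels > 1))
    stop("'levels' must lie in (0, 1]", call. = FALSE)
  base <- assessReplication(pairs, methods, level = 1, wo = wo, wr = wr)
  do.call(rbind, lapply(methods, function(m) {
    p <- base$table[[paste0("p_", m)]]
    data.frame(method = m, level = levels,
               rate = vapply(levels,
                             function(l) mean(p <= l, na.rm = TRUE),
                             numeric(1)))
  }))
}

#' Replication significance rate by original p-value threshold
#'
#' Splits the study pairs at each threshold `t` into original studies with
#' `po <= t` and `po > t` and reports, within each group, the proportion
#' of replications significant at `replicationLevel`.  In the large
#' replication projects the below-threshold group replicates markedly more
#' often, the empirical motivation for requiring less of the replication
#' when the original evidence was strong.
#'
#' @inheritParams assessReplication
#' @param replicationLevel one-sided level the replication must reach
#'   (default 0.025).
#' @param thresholds numeric vector of thresholds inside (0, 0.5).
#' @return a `data.frame` with columns `threshold`, `rate_below`,
#'   `rate_above`, `n_below`, `n_above`; a group with no members has rate
#'   `NA`.
#' @export
rateByThreshold <- function(pairs, replicationLevel = 0.025, thresholds) {
  if (any(thresholds <= 0 | thresholds >= 0.5))
    stop("'thresholds' must lie in (0, 0.5)", call. = FALSE)
  sig <- pairs$pr <= replicationLevel
  do.call(rbind, lapply(thresholds, function(t) {
    below <- pairs$po <= t
    data.frame(threshold = t,
               rate_below = if (any(below)) mean(sig[below]) else NA_real_,
               rate_above = if (any(!below)) mean(sig[!below]) else NA_real_,
               n_below = sum(below), n_above = sum(!below))
  }))
}
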