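alpha2 <- 0.025^2

test_that("Edgington's combined p-value reproduces the worked study pairs", {
  # borderline non-significant original with a convincing replication
  expect_equal(pEdgington(0.026, 0.001), 0.027^2 / 2)  # 3.645e-4 < alpha^2
  expect_lt(pEdgington(0.026, 0.001), alpha2)
  # two just-significant studies: more 'successes' but less total evidence
  expect_equal(pEdgington(0.024, 0.024), 0.048^2 / 2)  # 1.152e-3 > alpha^2
  expect_gt(pEdgington(0.024, 0.024), alpha2)
  expect_equal(pEdgington(0.5, 0.5), 0.5)
  expect_equal(pEdgington(0.3, 0.01), pEdgington(0.01, 0.3))  # symmetry
})

test_that("weighted Edgington evaluates all three branches correctly", {
  # boundary pair attains the overall level exactly
  expect_equal(pEdgingtonWeighted(0.035, 0.0075, 1, 2), alpha2)
  # middle (linear) branch, checked against a brute-force oracle
  expect_equal(pEdgingtonWeighted(0.4, 0.4, 1, 2), 1.2 / 2 - 1 / 4)
  mc <- mcWeightedSumProb(1.2, 1, 2, n = 1e6, seed = 3)
  expect_within3SE(pEdgingtonWeighted(0.4, 0.4, 1, 2), mc)
  # upper branch
  mc3 <- mcWeightedSumProb(2.5, 1, 2, n = 1e6, seed = 4)
  expect_within3SE(pEdgingtonWeighted(0.9, 0.8, 1, 2), mc3)
  # random configurations across branches vs the same oracle
  set.seed(42)
  for (i in 1:20) {
    wo <- runif(1, 0.2, 3); wr <- runif(1, 0.2, 3)
    po <- runif(1); pr <- runif(1)
    mc <- mcWeightedSumProb(wo * po + wr * pr, wo, wr, n = 1e5, seed = i)
    expect_within3SE(pEdgingtonWeighted(po, pr, wo, wr), mc)
  }
})

test_that("weighted Edgington reduces to unweighted and is scale invariant", {
  expect_equal(pEdgingtonWeighted(0.024, 0.024, 3, 3),
               pEdgington(0.024, 0.024))
  set.seed(1)
  po <- runif(50); pr <- runif(50)
  expect_equal(pEdgingtonWeighted(po, pr, 1, 1), pEdgington(po, pr))
  for (k in c(0.1, 2, 17)) {
    expect_equal(pEdgingtonWeighted(po, pr, k * 1, k * 2),
                 pEdgingtonWeighted(po, pr, 1, 2))
  }
  # weight labels are exchangeable together with their p-values
  expect_equal(pEdgingtonWeighted(po, pr, 2, 1),
               pEdgingtonWeighted(pr, po, 1, 2))
})

test_that("weighted CDF is continuous at its branch points", {
  eps <- 1e-9
  for (w in list(c(1, 2), c(0.5, 3), c(2, 2.5))) {
    wo <- w[1]; wr <- w[2]
    # function-level continuity: approach each break point from both sides
    # along the line po = pr (so ew = (wo + wr) * p)
    for (bp in c(wo, wr)) {
      pA <- pEdgingtonWeighted((bp - eps) / (wo + wr),
                               (bp - eps) / (wo + wr), wo, wr)
      pB <- pEdgingtonWeighted((bp + eps) / (wo + wr),
                               (bp + eps) / (wo + wr), wo, wr)
      expect_lt(abs(pB - pA), 1e-6)
    }
    # exact continuity of the branch formulas at the break points
    f1 <- function(ew) ew^2 / (2 * wo * wr)
    f2 <- function(ew) (ew - wo / 2) / wr
    f3 <- function(ew) 1 + (ew * (wo + wr) - (wo + wr)^2 / 2 - ew^2 / 2) /
      (wo * wr)
    expect_lt(abs(f1(wo) - f2(wo)), 1e-12)
    expect_lt(abs(f2(wr) - f3(wr)), 1e-12)
    expect_lt(abs(f3(wo + wr) - 1), 1e-12)
  }
})

test_that("two-trials, Fisher and meta combiners match their closed forms", {
  expect_equal(pTwoTrials(0.026, 0.001), 0.026^2)
  expect_gt(pTwoTrials(0.026, 0.001), alpha2)   # 6.76e-4: no success
  expect_lte(pTwoTrials(0.024, 0.024), alpha2)  # 5.76e-4: success
  expect_equal(pTwoTrials(0.5, 0.001), 0.25)
  x <- -2 * log(0.026 * 0.001)
  expect_equal(pFisher(0.026, 0.001), exp(-x / 2) * (1 + x / 2))
  expect_equal(fisherCriticalProduct(0.025), 5.812365e-5,
               tolerance = 1e-6)
  expect_equal(pMeta(0.5, 0.5, c = 1), 0.5)
  expect_equal(pMeta(0.025, 0.025, c = 1),
               1 - pnorm(2 * qnorm(0.975) / sqrt(2)))
  # all weight shifts to the original study as c -> 0
  expect_equal(pMeta(0.07, 0.9, c = 1e-10), 0.07, tolerance = 1e-4)
  expect_error(pMeta(0.1, 0.1), "variance ratio")
})

test_that("every combined p-value is uniform under the intersection null", {
  pairs <- simulatePairs(1e5, muo = 0, c = 1, seed = 99)
  for (m in c("edgington", "edgington_weighted", "two_trials", "fisher",
              "meta")) {
    p <- switch(m,
      edgington = pEdgington(pairs$po, pairs$pr),
      edgington_weighted = pEdgingtonWeighted(pairs$po, pairs$pr, 1, 2),
      two_trials = pTwoTrials(pairs$po, pairs$pr),
      fisher = pFisher(pairs$po, pairs$pr),
      meta = pMeta(pairs$po, pairs$pr, 1))
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
  }
})

test_that("combined p-values are nondecreasing in each argument", {
  grid <- seq(0.01, 0.99, length.out = 25)
  for (m in c("edgington", "edgington_weighted", "two_trials", "fisher",
              "meta")) {
    f <- switch(m,
      edgington = function(a, b) pEdgington(a, b),
      edgington_weighted = function(a, b) pEdgingtonWeighted(a, b, 1, 2),
      two_trials = function(a, b) pTwoTrials(a, b),
      fisher = function(a, b) pFisher(a, b),
      meta = function(a, b) pMeta(a, b, 1))
    set.seed(7)
    for (fixed in runif(5)) {
      expect_true(all(diff(f(grid, fixed)) >= -1e-12), label = m)
      expect_true(all(diff(f(fixed, grid)) >= -1e-12), label = m)
    }
  }
})

test_that("success at level alpha^2 is equivalent to the budget rule", {
  set.seed(5)
  po <- runif(500); pr <- runif(500)
  b <- successBudget(0.025)
  expect_identical(pEdgington(po, pr) <= alpha2, po + pr <= b)
  bw <- successBudget(0.025, 1, 2)
  expect_identical(pEdgingtonWeighted(po, pr, 1, 2) <= alpha2,
                   po + 2 * pr <= bw)
  # boundary: exact equality counts as success
  expect_true(pEdgingtonWeighted(0.035, 0.0075, 1, 2) <= alpha2)
})

test_that("budgets carry the printed values and scale with the weights", {
  expect_equal(successBudget(0.025), sqrt(2) * 0.025)      # ~ 0.0354
  expect_equal(successBudget(0.025, 1, 2), 0.05)
  expect_equal(successBudget(0.025, 2, 4), 0.1)            # same decisions
  expect_error(successBudget(0.4, 1, 100), "first branch")
})

test_that("combinePValues agrees with the scalar combiners and flags success", {
  r <- combinePValues(0.026, 0.001, method = "edgington")
  expect_equal(r$p, pEdgington(0.026, 0.001))
  expect_equal(r$statistic, 0.027)
  expect_true(r$success)
  r2 <- combinePValues(0.026, 0.001, method = "two_trials")
  expect_false(r2$success)
  expect_error(combinePValues(0.1, 0.1, method = "meta"), "'c'")
})

test_that("degenerate p-values of exactly 0 or 1 are clipped with a warning", {
  expect_warning(p <- pEdgington(0, 0.5), "clipping")
  expect_gt(p, 0)
  # both inputs degenerate: one warning per argument
  expect_warning(expect_warning(pf <- pFisher(1, 1), "clipping"), "clipping")
  expect_equal(pf, 1, tolerance = 1e-12)
  expect_error(pEdgington(-0.1, 0.5), "\\[0, 1\\]")
})
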