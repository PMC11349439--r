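---
title: "Assessing replication success with the sum of p-values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing replication success with the sum of p-values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgington)
```

## The model

All methods in this package operate on *one-sided* p-values `po` and `pr`
from an original and a replication study, with the one-sided convention
`p = 1 - pnorm(z)` where `z` is the effect estimate divided by its
standard error in the pre-specified direction.  A p-value above 0.5 means
the estimate points the wrong way; no special casing is applied, the
formulas hold as written.

The reference distribution for calibration is the **intersection null
hypothesis**: both true effects are zero, so `po` and `pr` are
independent standard uniforms.  A combination method is *valid* if its
combined p-value is uniform under this null; success at `alpha^2` then
controls the overall Type-I error rate at the same level as the
two-trials rule at level `alpha`.

Edgington's method refers the sum `E = po + pr` to the Irwin–Hall
distribution.  Success at `alpha^2` is equivalent to `E <= b` with budget
`b = sqrt(2) * alpha`; the weighted variant uses `Ew = wo*po + wr*pr`
with budget `bw = sqrt(2*wo*wr)*alpha`.  Operating characteristics
(project power, sample-size planning, simulation) additionally assume the
standard normal model

* `zo ~ N(mu_o, 1)` with `mu_o = qnorm(1 - alpha) + qnorm(originalPower)`,
  the unique noncentrality consistent with an original study powered at
  `originalPower`;
* `zr ~ N(d * sqrt(c) * mu_o, 1)`, independent, where `c = nr/no` is the
  relative sample size (equivalently the variance ratio
  `sigma_o^2 / sigma_r^2`) and `d = theta_r / theta_o` the ratio of true
  effects.

This is the usual large-sample normal approximation: it treats the
standard errors as known and scaling with `1/sqrt(n)`, and is exact for
z-tests.

## Tunable parameters

* `alpha` (default 0.025): one-sided significance level; the overall
  level is always `alpha^2` (0.000625), matching the conventional
  two-sided 0.05 of the two-trials rule.  All budgets scale linearly in
  `alpha`.
* `wo`, `wr` (defaults 1 and 2 where a weighted method is requested):
  study weights.  Only the ratio `wr/wo` matters — every weighted output
  is invariant under joint rescaling.  The (1, 2) default doubles the
  replication weight, which restores the two-trials property that
  `pr <= alpha` is necessary for success and reflects distrust of
  possibly biased original studies.  Equal weights reduce exactly to the
  unweighted method.
* `c` (relative sample size, dimensionless): enters the meta-analysis
  criterion, project power and the simulator.  For correlation-scale
  data read by `readStudyPairs()` it defaults to `(nr - 3) / (no - 3)`,
  the ratio of squared Fisher-z standard errors.
* `originalPower` (0.8 by default in power functions): 80% is the
  standard design power of original studies; 40% is offered in examples
  because realized power is often far lower.
* `d` (default 1): `d = 0.5` mimics the effect shrinkage observed across
  replication projects.
* `shrinkage` (default 0): deliberate reduction of the original effect
  estimate before sample-size calculation, typically 0.25 or 0.5.
* `power`/`mode` in the design functions: conditional power treats the
  original estimate as true; predictive power averages over its
  uncertainty and generally yields larger replications.

## Numerical choices

* **Irwin–Hall CDF.**  The alternating-sum closed form with
  Kahan-compensated summation, restricted to at most 10 summands — the
  closed form loses digits catastrophically beyond that, and the
  replication setting needs 2 or 3.
* **Weighted CDF with `wo > wr`.**  The three-branch formula is stated
  for `wo <= wr`; since the distribution of `wo*U1 + wr*U2` is symmetric
  in the labels, arbitrary weights are handled by letting the smaller
  weight (with its paired p-value) occupy the `wo` slot.  Sums landing
  exactly on a branch point use the lower branch (branches closed on the
  right); the branch formulas agree there to machine precision, so the
  choice is cosmetic.
* **Degenerate p-values.**  Inputs of exactly 0 or 1 are clipped to
  `[1e-16, 1 - 1e-16]` with a warning, keeping z-transforms finite
  without silently altering ordinary inputs; values outside `[0, 1]` are
  errors.
* **Success at the boundary.**  `p_combined == alpha^2` counts as
  success (`<=` throughout), and the stage-1 spending rule likewise uses
  `E2 <= b2`.
* **Project power quadrature.**  The Edgington and Fisher criteria have
  no closed-form power, so the conditional success probability is
  integrated over the original z-value with `stats::integrate`
  (absolute tolerance `1e-6`) on `mu_o ± 8.5` — the integrand is smooth
  on the z-scale, whereas on the p-scale the density spikes at 0.  The
  `c -> Inf` limit is reported by the exact closed form
  `pnorm(mu_o - qnorm(1 - L))` (with `L` the method's share of the
  budget for the original study) rather than by evaluating the
  quadrature at a huge `c`.
* **Root-finding.**  The predictive sample size is solved by `uniroot`
  on `sqrt(c)` in `[1e-3, 1e3]` (the predictive power is strictly
  increasing in `sqrt(c)`, so the bracket is guaranteed whenever the
  target power is attainable, i.e. below its limit `pnorm(zo)`), to
  tolerance `1e-10`.  The stage-2 spending budget `b3` is solved on
  `(b2, 1]` and polished with Newton steps to machine precision; the
  spending equation uses the exact small-sum density `f(e) = e` of
  `E2`, valid because every budget in play is far below 1.
* **Maxima of the sample-size savings.**  The conditional-power ratio is
  monotone in `po`, so its extremum is the `po -> 0` boundary, evaluated
  at `po = 1e-12`; the predictive-power ratio has an interior minimum
  (near `po = 9e-5` at 80% power), which callers locate by evaluating
  `sampleSizeRatio(..., mode = "predictive")` on a grid.

## Design decisions

* **Predictive power formula.**  Adopted as the normal-normal predictive
  distribution of the replication estimate given the original,
  `thetaHat_r | thetaHat_o ~ N(thetaHat_o, sigma_o^2 + sigma_r^2)`,
  giving `pnorm((zo*sqrt(c) - qnorm(1 - level)) / sqrt(c + 1))`.  This is
  the standard "probability of success" construction and is what the
  package's tests validate against a brute-force average over the
  predictive distribution.
* **Conditional level of the two-trials rule.**  Returns 0 for
  `po > alpha` (success has become impossible) rather than raising an
  error, so that power integrals and curves remain well defined; the
  design-stage wrapper `replicationLevel()` does error there, because
  planning a replication of an inadmissible original is a mistake the
  user should hear about.
* **Futility in the sequential rule.**  Declared only when success is
  arithmetically impossible (`E2 > b3`).  No predictive futility bound
  is layered on top; users wanting one can combine
  `predictivePower()` with the remaining level themselves.
* **Weights in the multi-study rule** are not implemented: the two-stage
  spending construction is specified for unweighted sums, and a weighted
  generalization would need conventions this package does not want to
  invent.
* **Random pair generation** pins R's Mersenne–Twister generator with
  inversion sampling for normals and restores the caller's RNG state, so
  fixtures are bit-reproducible for a given R version and simulation
  never perturbs a session's random stream.
* **CSV precedence.**  When a study table carries both direct p-values
  and correlation-scale estimates, the direct p-values win (explicit
  beats derived) with a warning.

## What the simulator does and does not emulate

`simulatePairs()` draws from exactly the normal model stated above:
independent studies, known variances, a common scalar effect per study,
no selection.  It therefore exercises the calibration claims the methods
actually make — null uniformity of every combined p-value, overall
Type-I error `alpha^2`, agreement of the power quadrature with
simulation — and those are what passing tests demonstrate.  It does
**not** emulate publication bias, questionable research practices,
heterogeneity between original and replication populations, small-sample
or non-normal likelihoods, or dependence between studies.  Conclusions
about real replication projects need the project data themselves;
`readStudyPairs()` and `assessReplication()` accept such tables (with
p-values recomputed from correlations via Fisher's z-transformation),
but no real-project numbers are bundled or asserted here.

## Problem sizes used by the test suite

Distributional checks (Kolmogorov–Smirnov uniformity) use 1e5 simulated
pairs; rates of magnitude `alpha^2 = 6.25e-4` use 1e6 pairs for method
checks and 1e7 uniform triples for the sequential spending rule, giving
binomial standard errors an order of magnitude below the quantity; the
quadrature/simulation cross-validation grid uses 1e6 pairs per
configuration.  These sizes make a 3-standard-error criterion meaningful
at the target magnitudes.

## Known limitations

* The closed-form budget `bw = sqrt(2*wo*wr)*alpha` requires
  `bw <= min(wo, wr)` (first CDF branch); extremely unequal weights or
  large `alpha` fall outside it and currently raise an error rather than
  inverting the full CDF.
* `budgetN()` likewise inverts only the small-sum branch (`b <= 1`),
  which covers any realistic overall level but not, say, `alpha2 > 1/6`
  at `n = 3`.
* Project power assumes the normal model; for t-tests at small degrees
  of freedom the quadrature answer is an approximation (the replication
  *level* functions remain exact, and `power.t.test()` can be fed
  `replicationLevel()` directly for exact t-based sample sizes).
* The meta-analysis criterion's conditional Type-I error converges to 1
  as `po -> 0` only on the z-scale, i.e. very slowly; numerical limits
  quoted at finite `po` reflect that.
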