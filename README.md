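# edgington: replication success from the sum of p-values

`edgington` assesses whether a replication study confirms an original
finding by **adding the two one-sided p-values**.  It is aimed at
statisticians and meta-researchers analysing replication studies or
planning them: large-scale replication projects, drug-regulatory settings
governed by the two-trials rule, and any confirmatory design where one
original and one or more replication studies must jointly support a claim.

## The method

Let `po` and `pr` be the one-sided p-values of the original and the
replication study.  Under the intersection null hypothesis (no effect in
either study) the sum `E = po + pr` follows the Irwin–Hall distribution
with two summands, so

```
pE = Pr(IH(2) <= E) = E^2 / 2          for E <= 1
```

is a valid combined p-value (Edgington's method).  Declaring success when
`pE <= alpha^2` controls the overall Type-I error rate at the same level
as the two-trials rule (`max(po, pr) <= alpha`), but spends it
differently: success requires `E <= b` with budget `b = sqrt(2) * alpha`
(about 0.035 at `alpha = 0.025`), so a marginally non-significant original
study (`po = 0.026`) can still be rescued by a convincing replication
(`pr = 0.001`), while two barely significant studies (`po = pr = 0.024`)
— which the two-trials rule accepts — are rejected.

A weighted variant uses `Ew = wo*po + wr*pr`; with `wo = 1, wr = 2` the
budget becomes `2*alpha = 0.05` and success additionally requires
`pr <= alpha`, which guards against bias in the original study.  The
package also provides, all calibrated to the same overall level:

* the two-trials, Fisher and fixed-effect meta-analysis (Stouffer)
  comparators (`pTwoTrials`, `pFisher`, `pMeta`);
* conditional Type-I error rates and project power, including exact
  `c -> Inf` limits (`conditionalLevel`, `projectPower`,
  `projectPowerLimit`, `overallTypeI`);
* replication sample-size planning under conditional or predictive power
  (`replicationLevel`, `sampleSizeReplication`, `relativeSampleSize`,
  `sampleSizeRatio`);
* budgets and two-stage alpha-spending for a second replication study
  (`budgetN`, `spendingPlan`, `sequentialAssess`);
* assessment of study-pair tables, with one-sided p-values recomputed
  from correlation-scale estimates via Fisher's z-transformation
  (`readStudyPairs`, `pFromCorrelation`, `assessReplication`,
  `successRateCurve`, `rateByThreshold`);
* a seeded generator of synthetic study pairs used as the Monte-Carlo
  oracle throughout (`simulatePairs`, `mcSuccessRate`).

## Worked example

```r
library(edgington)

combinePValues(0.026, 0.001, method = "edgington")
#>      method statistic         p success
#> 1 edgington     0.027 0.0003645    TRUE

combinePValues(0.026, 0.001, method = "two_trials")
#>       method statistic        p success
#> 1 two_trials     0.026 0.000676   FALSE

conditionalLevel(0.001, "edgington")   # level left for the replication
#> [1] 0.03435534

projectPowerLimit("edgington", originalPower = 0.8)
#> [1] 0.8399504

spendingPlan(0.025^2, fraction = 0.5)
#> Two-stage alpha-spending plan
#>   overall level alpha2: 0.000625
#>   fraction spent at stage 1: 0.5
#>   stage-1 budget b2 (on po + pr1):     0.025
#>   final budget b3 (on po + pr1 + pr2): 0.1277
```

The first call shows the sum `E = 0.027` staying inside the budget 0.035,
so the combined p-value 0.00036 is below the overall level `0.025^2 =
0.000625` and success is declared even though the original study missed
significance; the two-trials rule reaches the opposite verdict on the
same data.  The conditional level 0.0344 is the significance level the
replication of a `po = 0.001` original must meet — less stringent than
the fixed 0.025 of the two-trials rule, which is what makes replication
sample sizes up to about 10% smaller when the original evidence is
strong.  The spending plan shows how the overall level is split when a
second replication study may follow the first.

A command-line wrapper is installed with the package
(`exec/edgington`; subcommands `combine`, `design`, `power`, `spend`,
`assess`, `simulate`):

```sh
edgington combine --po 0.026 --pr 0.001
edgington assess --input pairs.csv --level 0.000625
```

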