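Package: edgington
Title: Assessment of Replication Success with the Sum of p-Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines one-sided p-values from an original study and one or
    more replication studies with Edgington's method, which declares
    replication success when the (weighted) sum of p-values falls below a
    budget calibrated to the overall Type-I error rate of the two-trials
    rule.  Provides the combined p-value via the Irwin-Hall distribution,
    a weighted variant, and the calibrated two-trials, Fisher and
    meta-analysis comparators; conditional Type-I error rates, overall
    Type-I error verification by simulation, and project power; replication
    sample-size planning under conditional or predictive power; budgets and
    alpha-spending rules for sequential conduct of two replication studies;
    and utilities to assess study-pair tables from replication projects,
    including recomputation of one-sided p-values from correlation-scale
    effect estimates via Fisher's z-transformation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
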