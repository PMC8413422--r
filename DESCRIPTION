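Package: sigrepro
Title: Reproducibility Benchmarking for Connectivity-Map-Style Perturbation Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the reproducibility of drug-perturbation
    transcriptomic compendia in the Connectivity Map style. Provides a
    synthetic corpus generator with planted ground truth (sparse effect
    vectors, Hill dose-response, cell-line responsiveness, tunable
    cross-platform concordance), a differential-expression engine with
    plate-matched fold-change computation and probe collapsing, signature
    generation under the standard query-size contract, a Kolmogorov-Smirnov
    enrichment query engine with retrieval-rank benchmarking, replicate
    agreement statistics (Spearman rank correlation, ternary Jaccard,
    in-replicate and cross-replicate sample-level agreement), dose-trend
    analysis, and a standardized three-predictor regression linking
    differential-expression strength and sample-level reproducibility to
    replicate agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
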