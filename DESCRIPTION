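Package: dynbind
Title: Dynamic Promoter Binding and Replication-Transcription Conflict
    Analysis for Checkpoint-Kinase ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing cell-cycle-dynamic binding of a
    replication-checkpoint kinase to gene promoters from binned ChIP-seq
    coverage tracks. Implements simple and origin-aware log2 IP/input
    enrichment normalization, promoter-window activity scoring with
    empirical significance, Lorenz/Gini binding-specificity measures,
    regression-residual differential-binding detection with top-K
    selection, replication-origin firing classification from EdU-type
    incorporation signal, gene-to-origin distance and head-on versus
    co-directional orientation analysis with Fisher tests, transcription
    factor target enrichment and binding-expression association
    statistics, and metagene signal matrices around TSSs and origins.
    A negative-binomial synthetic-data generator with planted ground
    truth makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
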