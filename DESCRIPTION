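Package: mirvuln
Title: MicroRNA Biomarker Discovery by Regulatory Network Vulnerability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens candidate microRNA biomarkers from two-group expression
    data and a curated microRNA-mRNA interaction corpus. Builds a
    condition-specific bipartite regulatory network from evidence-tagged edge
    tables, scores each microRNA by its number of single-line regulations
    (NSR), transcription-factor target percentage (TFP) and unique-regulated
    TF percentage (UTP), applies a three-step significance filter based on
    one-sided Wilcoxon signed-rank tests, and evaluates surviving candidates
    by single-marker ROC/AUC and prediction precision against previously
    reported biomarkers. Includes moderated-t differential expression,
    synthetic network/expression generators with planted ground truth, and an
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
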