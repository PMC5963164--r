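# mirvuln — microRNA biomarker discovery by network vulnerability analysis

mirvuln screens candidate microRNA biomarkers for a two-group disease
contrast (e.g. primary vs metastatic prostate cancer) by combining
differential expression with the *vulnerability* structure of a bipartite
microRNA–mRNA regulatory network. It is aimed at systems-biology analysts
who have two-group expression matrices and exported interaction tables from
curated target databases, and want a reproducible, testable implementation
of single-marker network screening.

## The model

In a condition-specific microRNA→gene network, a gene with in-degree 1 is a
*single-line regulation*: its loss cannot be compensated by another
regulator. Transcription-factor (TF) genes propagate any such loss
downstream. Each microRNA *m* with target set *T(m)* is scored by

* **NSR(m)** — number of targets with in-degree exactly 1;
* **TFP(m)** = |T(m) ∩ F| / |T(m)| — fraction of targets that are TF genes
  (TF set *F*);
* **UTP(m)** — fraction of the in-degree-1 targets that are TFs (0 when
  NSR = 0).

The three-step filter keeps microRNAs with significantly high NSR
(one-sided Wilcoxon signed-rank against the network's score population,
p < 0.05), then significantly high TFP, then UTP > 0. The surviving
candidates are evaluated by per-marker ROC/AUC (Mann–Whitney identity,
oriented by the discovery-set fold-change sign) and by *prediction
precision* — the fraction of candidates already reported as biomarkers in
the literature. Up front, the package provides a moderated-t differential
expression stage (empirical-Bayes variance shrinkage, BH-FDR, probe
collapsing, strict adj.p < 0.05 and |log2FC| > 1 cut-offs) and an
evidence-integration rule for building the reference network (a pair needs
low-throughput experimental support or agreement of ≥2 prediction
databases). See the vignette in `vignettes/network-vulnerability.Rmd` for
the full account, including why the significance rule is parameterized.

## Worked example

The package ships the step-2 survivor table of its motivating metastatic
prostate cancer case study. The UTP step reduces seven survivors to five
candidates and lifts precision against the two previously reported
biomarkers among them:

```r
library(mirvuln)
scores <- read_result_table(system.file("extdata", "mpca_step2_scores.tsv",
                                        package = "mirvuln"))
scores[, c("mirna", "n_targets", "nsr", "tfp", "utp")]
#>         mirna n_targets nsr    tfp    utp
#> 1  miR-204-5p        21  13 0.2857 0.3846
#> 2  miR-101-3p        24   3 0.2917 0.3333
#> 3  miR-145-5p        12   3 0.2500 0.3333
#> 4     miR-198        12   5 0.3333 0.2000
#> 5     miR-152        17   6 0.2941 0.1667
#> 6 miR-130a-3p        NA  NA     NA 0.0000
#> 7  miR-363-3p        NA  NA     NA 0.0000

candidates <- utp_filter(scores)   # drops the two UTP = 0 microRNAs
reported <- c("miR-145-5p", "miR-101-3p")
100 * prediction_precision(scores$mirna, reported)  # 28.57143
100 * prediction_precision(candidates, reported)    # 40
```

The two UTP = 0 microRNAs are filtered out; precision rises from 28.6%
(2/7) to 40% (2/5).

On synthetic data with known ground truth, the full filter runs directly on
a generated network:

```r
sim <- simulate_network(80, 600, mean_outdegree = 10,
                        singleline_fraction = 0.3, n_planted = 2, seed = 11)
cs <- microrna_bd_filter(sim$network, sim$tf_set)
cs
#> candidate_set (alpha = 0.05)
#>   step 1 (high NSR):        23 microRNA(s)
#>   step 2 (+ high TFP):      9 microRNA(s)
#>   step 3 (+ UTP > 0):       6 candidate(s)
#>   candidates: miR-sim-003, miR-sim-016, miR-sim-030, miR-sim-036, ...
sim$truth$planted_mirnas
#> [1] "miR-sim-016" "miR-sim-036"
```

Both planted vulnerable microRNAs are among the candidates; the remaining
candidates are background microRNAs whose scores are elevated by chance —
the vignette discusses how the selection rule's power scales with network
size and when to prefer `method = "percentile"`.

A full pipeline run (DE → projection → scoring → filter → evaluation) is
driven by a flat config file via `run_pipeline(read_run_config("run.cfg"))`
or the `inst/exec/netvuln` command-line script
(`netvuln run --config run.cfg`), writing `de_mirna.tsv`, `de_mrna.tsv`,
`network.tsv`, `scores.tsv`, `candidates.tsv`, `eval.tsv` and a
reproducibility manifest.

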