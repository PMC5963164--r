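---
title: "Scoring microRNA biomarkers by regulatory-network vulnerability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring microRNA biomarkers by regulatory-network vulnerability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvuln)
```

## The model

mirvuln screens single-microRNA biomarkers for a disease contrast (its
motivating application is primary vs metastatic prostate cancer) from two
inputs: two-group expression data and a curated microRNA–mRNA interaction
corpus. The premise is *network vulnerability*: in the bipartite regulatory
network, a gene with in-degree 1 is held by a single-line regulation whose
disturbance cannot be compensated by any other regulator, and transcription
factor (TF) genes amplify any such disturbance downstream. MicroRNAs that
concentrate uncompensated regulation — especially over TF genes — sit at the
network's vulnerable points, and their dysregulation is the kind of signal a
biomarker should carry.

Each microRNA $m$ in a condition-specific network receives three
measurements:

* **NSR** — the number of its target genes with in-degree exactly 1
  (its single-line regulations);
* **TFP** — the fraction of its targets that are TF genes,
  $\mathrm{TFP}(m) = |T_m \cap F| / |T_m|$ for target set $T_m$ and TF set
  $F$;
* **UTP** — the fraction of its in-degree-1 targets that are TF genes,
  defined as 0 when NSR = 0.

Candidates are selected in three nested steps: microRNAs with significantly
high NSR (step 1); of those, the ones with significantly high TFP (step 2);
of those, the ones with UTP > 0 (step 3). By construction
`candidates ⊆ step2 ⊆ step1`, and $\mathrm{TFP}\cdot|T_m|$ and
$\mathrm{UTP}\cdot\mathrm{NSR}$ are integer counts — useful invariants that
the test suite checks continuously.

## What "significantly high" means, and why it is a parameter

The underlying method statement — "significantly high values
(p < 0.05, Wilcoxon signed-rank test)" — does not pin down what the test is
paired against. The package's default follows the most direct reading: for
each microRNA $i$, a one-sided signed-rank test on the differences
$\{s_i - s_j : j \ne i,\ s_j \ne s_i\}$ against the network's score
population, exact (full sign-assignment null, tie-averaged ranks) for up to
25 non-zero differences and a tie-corrected, continuity-corrected normal
approximation beyond.

This construction has a property worth understanding before trusting it on
large networks: the $n-1$ differences are treated as one i.i.d. sample, so
its power grows without bound in the number of microRNAs. On a 65-microRNA
condition network it selects a handful of microRNAs per step — the scale of
the motivating study, where seven step-2 survivors were reduced to five
candidates by the UTP step. On a 600-microRNA network the same rule flags
every microRNA even moderately above the score bulk (dozens of step-2
survivors). For that regime `significant_high()` and `microrna_bd_filter()`
accept `method = "percentile"`, which keeps scores strictly above the
empirical $1-\alpha$ population quantile and therefore selects at most a
fraction $\alpha$ of microRNAs at any scale. The signed-rank rule remains
the default because it is the construction closest to the published method;
the choice is surfaced as a parameter precisely because the published text
cannot settle it.

Two smaller conventions: zero differences are dropped before testing
(Wilcoxon's original treatment, matching mainstream implementations and
easing cross-checks), and step 2's comparison population is the full
network's TFP distribution — step 1 constrains the candidates, not the null.

## Differential expression stage

Inputs are assumed to be normalized, log2-scale intensities; fold changes
are plain mean differences (group B − group A, positive = up in the contrast
group). Feature-wise variances are moderated by empirical-Bayes shrinkage:
the pooled variance $s_g^2$ on $d_g$ residual df is replaced by
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, the moderated
$t = \mathrm{lfc}/(\tilde s_g \sqrt{1/n_A + 1/n_B})$ is referred to a $t$
distribution on $d_0 + d_g$ df, and the prior $(d_0, s_0^2)$ is estimated
from the ensemble of sample variances via the method-of-moments F-fit
(delegated to `limma::squeezeVar`; the test suite cross-checks the whole
pipeline against `limma::eBayes`). `params = list(d0 = 0, ...)` recovers the
ordinary pooled t (`stat = "plain"`), and `d0 = Inf` pins all variances at
$s_0^2$ — both limits are tested. P-values are BH-adjusted and the DE rule
is strict on both thresholds: adjusted p **<** 0.05 and |log2 FC| **>** 1
(defaults; both are parameters). Features with fewer than two usable
samples in a group are excluded and reported — a conservative treatment of
missingness. Multiple probes per gene are collapsed to the probe with the
smallest raw p (ties: largest |t|, then smallest probe id).

## Network assembly

Interaction records carry an evidence class. A (microRNA, gene) pair enters
the reference network iff it has at least one *low-throughput* experimental
record, or is predicted by at least `min_predicted_support` (default 2)
distinct prediction databases. High-throughput-only support never qualifies
a pair — it is retained as annotation only — and an experimental pair is not
penalized by disagreeing predictions. MicroRNA names are normalized to
canonical mature names through an alias table before integration (aliases
collapsing onto one canonical pair are deliberately kept as duplicate
records until integration, where evidence counting needs the multiplicity);
gene symbols are upper-cased at ingest. The condition-specific network is
the induced subgraph on the differentially expressed microRNAs and genes,
with edge-less nodes removed.

## Evaluation

Per-candidate discrimination is summarized by the AUC of the microRNA's
expression against the group labels, computed by the Mann–Whitney identity
with ties counting one half; the ROC curve is the tie-grouped threshold
sweep whose trapezoidal area equals that AUC exactly. A down-regulated
marker separates groups with *low* values, so each candidate's score is
oriented by the sign of its discovery-set log2 fold change (the flip is
recorded) — the validation labels are never consulted for orientation.
Prediction precision is the fraction of candidates present in a curated
list of previously reported biomarkers; on the shipped worked example
(`inst/extdata/mpca_step2_scores.tsv`) the UTP step takes seven survivors
to five candidates and precision from 2/7 (28.6%) to 2/5 (40%).

## The synthetic-data generator

`simulate_network()` emulates the structure the scoring stage cares about:
a sparse bipartite network with heavy-tailed microRNA out-degree (truncated
power law, exponent 2, lower cutoff solved so the mean matches
`mean_outdegree`), a controllable fraction of in-degree-1 genes, and a TF
label on a gene subset. Defaults mirror a curated human corpus of roughly
49k pairs over ~600 microRNAs and ~9.5k genes: mean out-degree 79,
single-line fraction 0.25, TF fraction 0.10 (about the TF share of the
human genome). The out-degree law is truncated above at a third of the gene
set — even the hubs of curated corpora target only a minority of genes, and
an untruncated law at this density produces microRNAs targeting nearly the
whole gene universe. Degree sequences are realized by stub matching with
swap-based collision repair, which preserves both degree margins exactly,
so the realized single-line fraction tracks the request (the suite checks
±2% at ≥1,000 genes).

Planted "vulnerable" microRNAs are drawn from the upper degree quartile
(excluding extreme hubs) and *rewired*, never given extra edges, so their
degree totals stay comparable to the background: co-regulator edges are
moved off ~70% of their targets (making those single-line), and TF labels
are swapped so ~35% of their targets — including at least one unique
target — are TFs. These strengths are the generator's fixed definition of a
planted signal. `simulate_expression()` draws group A i.i.d.
Normal($\mu_0$, $\sigma^2$) on the log2 scale ($\mu_0 = 7$, $\sigma = 0.5$
by default, a typical array-like spread) and shifts group B by each planted
feature's effect size. Both generators are bit-reproducible per seed.

What passing tests on these data do *not* show: real corpora have
database-specific biases, correlated targeting (families of microRNAs
sharing seed sequences), and expression data have probe artifacts,
batch effects and heavier-tailed noise. The generator makes no attempt at
platform noise models.

## Numerical choices and degenerate inputs

* Exact signed-rank null: computed by generating-function convolution over
  doubled (tie-averaged) ranks — identical to full sign enumeration, in
  polynomial time; the suite verifies it against literal $2^n$ enumeration.
* All-zero difference vectors raise a distinct condition
  (`mirvuln_all_zero`), as does precision on an empty candidate set
  (`mirvuln_empty_candidates`).
* A microRNA whose score ties the entire population gets p = 1 (no evidence
  of elevation); `alpha = 0` therefore selects nothing.
* Empty projections (DE sets disjoint from the reference) return an empty
  network with a warning rather than an error.
* BH adjustment, the two-sample KS test, and t tail probabilities are
  delegated to `stats`; their outputs are property-tested against direct
  computations.

## Problem sizes used by the test suite

The oracle suites run on networks of 5–50 microRNAs against brute-force
scans, signed-rank enumeration up to $2^{12}$, and 100-replicate studies of
the full filter at 600 microRNAs × 9,000 genes; calibration uses 10,000
null features and 200-sample null markers. These sizes were chosen to make
every statistical claim in this vignette a computed, not asserted, result.

## Known limitations

Genes are weighted only by the binary TF flag — no finer functional
annotation enters the scores. The signed-rank selection rule's scale
sensitivity (above) is the main methodological caveat; the percentile rule
is the recommended alternative on networks much larger than ~100 microRNAs.
Single markers only: no panels, no cross-validation, no survival modelling.
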