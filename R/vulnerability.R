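# Network-vulnerability scoring of microRNAs on a bipartite regulatory
# network. A gene with in-degree 1 is a single-line regulation: its loss
# cannot be compensated by another regulator, so microRNAs holding many such
# edges — especially onto transcription-factor genes — sit at vulnerable
# points of the system. Three measurements per microRNA:
#   NSR  number of targets whose only regulator is this microRNA
#   TFP  fraction of targets that are TF genes
#   UTP  fraction of the in-degree-1 (unique) targets that are TF genes
# Candidates are microRNAs with significantly high NSR (step 1), significantly
# high TFP (step 2) and UTP > 0 (step 3).

#' Number of single-line regulations per microRNA
#'
#' For every microRNA in the network, the count of its target genes whose
#' in-degree in the network is exactly 1 (i.e. genes regulated by that
#' microRNA alone).
#'
#' @param net a [regulatory_network()].
#' @return named integer vector over all network microRNAs (zeros included).
#' @export
compute_nsr <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  e <- net$edges
  indeg <- table(e$gene)
  uniq <- e$gene %in% names(indeg)[indeg == 1L]
  out <- stats::setNames(integer(length(net$mirnas)), net$mirnas)
  if (any(uniq)) {
    cnt <- table(e$mirna[uniq])
    out[names(cnt)] <- as.integer(cnt)
  }
  out
}

#' Transcription-factor target percentage per microRNA
#'
#' Fraction of a microRNA's targets that are transcription-factor genes.
#'
#' @param net a [regulatory_network()].
#' @param tf_set character vector of TF gene symbols.
#' @return named numeric vector in `[0, 1]` over all network microRNAs (every
#'   microRNA in a constructed network has at least one target).
#' @export
compute_tfp <- function(net, tf_set) {
  stopifnot(inherits(net, "regulatory_network"))
  e <- net$edges
  is_tf <- e$gene %in% tf_set
  n_t <- tapply(rep(1L, nrow(e)), e$mirna, sum)
  n_tf <- tapply(as.integer(is_tf), e$mirna, sum)
  out <- as.numeric(n_tf[net$mirnas] / n_t[net$mirnas])
  stats::setNames(out, net$mirnas)
}

#' Unique-regulated TF gene percentage per microRNA
#'
#' Fraction of a microRNA's unique (in-degree-1) targets that are TF genes;
#' defined as 0 when the microRNA has no unique target (NSR = 0), so the
#' candidate rule `UTP > 0` cleanly excludes such microRNAs.
#'
#' @inheritParams compute_tfp
#' @return named numeric vector in `[0, 1]` over all network microRNAs.
#' @export
compute_utp <- function(net, tf_set) {
  stopifnot(inherits(net, "regulatory_network"))
  e <- net$edges
  indeg <- table(e$gene)
  uniq <- e$gene %in% names(indeg)[indeg == 1L]
  nsr <- stats::setNames(numeric(length(net$mirnas)), net$mirnas)
  ntf <- nsr
  if (any(uniq)) {
    cnt <- tapply(rep(1L, sum(uniq)), e$mirna[uniq], sum)
    nsr[names(cnt)] <- cnt
    tf_uniq <- uniq & e$gene %in% tf_set
    if (any(tf_uniq)) {
      cnt_tf <- tapply(rep(1L, sum(tf_uniq)), e$mirna[tf_uniq], sum)
      ntf[names(cnt_tf)] <- cnt_tf
    }
  }
  ifelse(nsr == 0, 0, ntf / nsr)
}

#' One-sided Wilcoxon signed-rank test
#'
#' Tests H1: "the median difference is > 0" on a vector of differences. Exact
#' zeros are removed first (Wilcoxon's original treatment). For `n <= 25`
#' non-zero differences the exact null distribution of the positive-rank sum
#' is used (computed over all 2^n sign assignments with tie-averaged ranks);
#' beyond that, a normal approximation with tie-corrected variance and a 0.5
#' continuity correction.
#'
#' @param diffs numeric vector of differences.
#' @return the one-sided p-value.
#' @export
wilcoxon_signed_rank_one_sided <- function(diffs) {
  stopifnot(is.numeric(diffs), length(diffs) > 0)
  d <- diffs[diffs != 0]
  if (!length(d))
    stop(structure(class = c("mirvuln_all_zero", "error", "condition"),
                   list(message = "all differences are zero: test undefined",
                        call = sys.call(-1))))
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null: P(W+ >= W) under random signs. Tie-averaged ranks are
    # multiples of 1/2, so doubling makes them integers and the distribution
    # of 2*W+ is a {1 + x^(2r)} generating-function convolution.
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    counts <- numeric(tot + 1L)   # counts[w + 1] = #assignments with 2W+ = w
    counts[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(tot + 1L - rr)])
      counts <- counts + shifted
    }
    W2 <- as.integer(round(2 * W))
    p <- sum(counts[(W2 + 1L):(tot + 1L)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- pnorm((W - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  min(max(p, 0), 1)
}

#' Per-microRNA "significantly high score" p-values
#'
#' For each microRNA `i`, a one-sided Wilcoxon signed-rank test on the
#' differences `score_i - score_j` over all other microRNAs `j` whose score
#' differs from `score_i` (equal scores contribute zero differences, which the
#' test drops anyway). A small p-value means the score sits significantly
#' above the network's score population. A microRNA whose score equals every
#' other score gets p = 1 (no evidence of elevation).
#'
#' @param scores named numeric vector of per-microRNA scores.
#' @return named numeric vector of one-sided p-values.
#' @export
signed_rank_high_pvalues <- function(scores) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  p <- vapply(seq_along(scores), function(i) {
    d <- scores[i] - scores[-i]
    d <- d[d != 0]
    if (!length(d)) return(1)
    wilcoxon_signed_rank_one_sided(d)
  }, numeric(1))
  stats::setNames(p, names(scores))
}

#' MicroRNAs with significantly high scores
#'
#' Two selection rules are available. `"signed_rank"` (default) runs, per
#' microRNA, the one-sided Wilcoxon signed-rank test of
#' [signed_rank_high_pvalues()] and keeps `p < alpha`. Because the
#' differences against all other microRNAs are treated as one sample, this
#' rule gains power rapidly with network size; on large networks it admits
#' any score moderately above the population bulk. The `"percentile"`
#' alternative keeps the scores strictly above the empirical
#' `1 - alpha` quantile of the population — a scale-stable notion of
#' "significantly high" that selects at most a fraction `alpha` of
#' microRNAs regardless of network size.
#'
#' @param scores named numeric vector (>= 3 microRNAs).
#' @param alpha significance level / tail fraction (default 0.05); selection
#'   is strict, so `alpha = 0` selects nothing.
#' @param method `"signed_rank"` (default) or `"percentile"`.
#' @return character vector of microRNA names with significantly high scores.
#' @export
significant_high <- function(scores, alpha = 0.05,
                             method = c("signed_rank", "percentile")) {
  method <- match.arg(method)
  if (length(scores) < 3L) stop("need at least 3 scores")
  if (method == "signed_rank") {
    p <- signed_rank_high_pvalues(scores)
    names(p)[p < alpha]
  } else {
    cut <- stats::quantile(scores, 1 - alpha, names = FALSE, type = 7)
    names(scores)[scores > cut]
  }
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided `D = sup |ECDF_a - ECDF_b|` with the asymptotic p-value; used to
#' compare score distributions (e.g. reported-biomarker NSR/TFP vs the whole
#' network). Wrapper around `stats::ks.test`.
#'
#' @param a,b non-empty numeric samples.
#' @return list with elements `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided",
                                 exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = unname(kt$p.value))
}

#' Vulnerability score table for a network
#'
#' Computes per microRNA the target count, NSR, TFP and UTP, plus the
#' one-sided signed-rank p-values of NSR and TFP against the network's score
#' population.
#'
#' @inheritParams compute_tfp
#' @return data.frame with columns
#'   `mirna, n_targets, nsr, tfp, utp, p_nsr, p_tfp`, sorted by microRNA name.
#' @export
score_network <- function(net, tf_set) {
  stopifnot(inherits(net, "regulatory_network"))
  if (!nrow(net$edges)) stop("empty network")
  nsr <- compute_nsr(net)
  tfp <- compute_tfp(net, tf_set)
  utp <- compute_utp(net, tf_set)
  n_t <- table(net$edges$mirna)[net$mirnas]
  p_nsr <- if (length(nsr) >= 3L) signed_rank_high_pvalues(nsr) else
    stats::setNames(rep(NA_real_, length(nsr)), names(nsr))
  p_tfp <- if (length(tfp) >= 3L) signed_rank_high_pvalues(tfp) else
    stats::setNames(rep(NA_real_, length(tfp)), names(tfp))
  data.frame(
    mirna = net$mirnas,
    n_targets = as.integer(n_t),
    nsr = as.integer(nsr[net$mirnas]),
    tfp = unname(tfp[net$mirnas]),
    utp = unname(utp[net$mirnas]),
    p_nsr = unname(p_nsr[net$mirnas]),
    p_tfp = unname(p_tfp[net$mirnas]),
    stringsAsFactors = FALSE
  )
}

#' UTP > 0 candidate filter
#'
#' The final filtration step: of the microRNAs surviving the TFP step, keep
#' those with at least one transcription-factor gene among their unique
#' targets (UTP strictly positive).
#'
#' @param scores data.frame with columns `mirna` and `utp` (e.g. the step-2
#'   survivors of [score_network()]).
#' @return character vector of candidate microRNA names.
#' @export
utp_filter <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("mirna", "utp") %in% names(scores)))
  scores$mirna[scores$utp > 0]
}

#' Three-step vulnerability filter
#'
#' Step 1 keeps microRNAs with significantly high NSR; step 2 keeps, among
#' those, the microRNAs whose TFP is significantly high (significance always
#' judged against the full network score population); step 3 keeps the step-2
#' survivors with UTP > 0. The full trace is returned.
#'
#' @inheritParams compute_tfp
#' @inheritParams significant_high
#' @param alpha significance level for both selection steps (default 0.05).
#' @return object of class `candidate_set`: list with `step1`, `step2`,
#'   `candidates` (character vectors, nested), `alpha`, `method` and the full
#'   `scores` table.
#' @export
microrna_bd_filter <- function(net, tf_set, alpha = 0.05,
                               method = c("signed_rank", "percentile")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "regulatory_network"))
  if (!nrow(net$edges)) stop("empty network")
  sc <- score_network(net, tf_set)
  if (method == "signed_rank") {
    step1 <- sc$mirna[!is.na(sc$p_nsr) & sc$p_nsr < alpha]
    step2 <- intersect(step1, sc$mirna[!is.na(sc$p_tfp) & sc$p_tfp < alpha])
  } else {
    nsr <- stats::setNames(as.numeric(sc$nsr), sc$mirna)
    tfp <- stats::setNames(sc$tfp, sc$mirna)
    step1 <- significant_high(nsr, alpha, method = "percentile")
    step2 <- intersect(step1,
                       significant_high(tfp, alpha, method = "percentile"))
  }
  candidates <- intersect(step2, sc$mirna[sc$utp > 0])
  structure(
    list(step1 = step1, step2 = step2, candidates = candidates,
         alpha = alpha, method = method, scores = sc),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(paste0(
    "candidate_set (alpha = %g)\n",
    "  step 1 (high NSR):        %d microRNA(s)\n",
    "  step 2 (+ high TFP):      %d microRNA(s)\n",
    "  step 3 (+ UTP > 0):       %d candidate(s)\n"),
    x$alpha, length(x$step1), length(x$step2), length(x$candidates)))
  if (length(x$candidates))
    cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}

#' Candidate trace table
#'
#' @param cs a `candidate_set` from [microrna_bd_filter()].
#' @return data.frame with columns
#'   `mirna, passed_step1, passed_step2, is_candidate`.
#' @export
candidate_trace <- function(cs) {
  stopifnot(inherits(cs, "candidate_set"))
  m <- cs$scores$mirna
  data.frame(
    mirna = m,
    passed_step1 = m %in% cs$step1,
    passed_step2 = m %in% cs$step2,
    is_candidate = m %in% cs$candidates,
    stringsAsFactors = FALSE
  )
}
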