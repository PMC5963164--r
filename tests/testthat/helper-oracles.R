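# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive (loops, full enumeration) so they share no code path
# with the implementation they check.

fig2_network <- function() {
  # one uniquely regulated non-TF gene (G1), one co-regulated TF gene (G5),
  # one uniquely regulated TF gene (G10)
  regulatory_network(data.frame(
    mirna = c("M1", "M2", "M3", "M4"),
    gene = c("G1", "G5", "G5", "G10"),
    stringsAsFactors = FALSE))
}

# Erdos-Renyi-ish bipartite network, structurally independent of
# simulate_network()
random_bipartite <- function(n_mirna, n_gene, n_edges, seed) {
  set.seed(seed)
  all_pairs <- expand.grid(mirna = paste0("m", seq_len(n_mirna)),
                           gene = paste0("g", seq_len(n_gene)),
                           stringsAsFactors = FALSE)
  picked <- all_pairs[sample.int(nrow(all_pairs),
                                 min(n_edges, nrow(all_pairs))), ]
  regulatory_network(picked)
}

brute_nsr <- function(net) {
  e <- net$edges
  out <- stats::setNames(integer(length(net$mirnas)), net$mirnas)
  for (m in net$mirnas) {
    tgt <- e$gene[e$mirna == m]
    n <- 0L
    for (g in tgt) if (sum(e$gene == g) == 1L) n <- n + 1L
    out[m] <- n
  }
  out
}

brute_tfp <- function(net, tf_set) {
  e <- net$edges
  out <- stats::setNames(numeric(length(net$mirnas)), net$mirnas)
  for (m in net$mirnas) {
    tgt <- e$gene[e$mirna == m]
    out[m] <- sum(tgt %in% tf_set) / length(tgt)
  }
  out
}

brute_utp <- function(net, tf_set) {
  e <- net$edges
  out <- stats::setNames(numeric(length(net$mirnas)), net$mirnas)
  for (m in net$mirnas) {
    tgt <- e$gene[e$mirna == m]
    uniq <- tgt[vapply(tgt, function(g) sum(e$gene == g) == 1L, logical(1))]
    out[m] <- if (length(uniq)) sum(uniq %in% tf_set) / length(uniq) else 0
  }
  out
}

# exact one-sided signed-rank p by enumerating all 2^n sign assignments
brute_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 14)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    if (sum(r[signs]) >= w_obs - 1e-9) count <- count + 1L
  }
  count / 2^n
}

# AUC by counting over all positive-negative pairs (ties count 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# direct BH step-up computation: sort ascending, take running minima of
# n*p_(k)/k from the top down, map back
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  s <- p[o]
  adj_sorted <- numeric(n)
  running <- 1
  for (k in n:1) {
    running <- min(running, n * s[k] / k)
    adj_sorted[k] <- running
  }
  out <- numeric(n)
  out[o] <- adj_sorted
  out
}

# two-sample KS D by sweeping the pooled support
brute_ks_d <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(vapply(xs, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

tmp_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

toy_expression <- function(seed = 1, n_feat = 6, nA = 4, nB = 4) {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * (nA + nB), 8, 1), n_feat, nA + nB,
              dimnames = list(paste0("f", seq_len(n_feat)),
                              paste0("s", seq_len(nA + nB))))
  expression_matrix(m, rep(c("PPCa", "MPCa"), c(nA, nB)))
}
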