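# Generators for networks and expression data with known ground truth, so
# every pipeline stage is testable without external downloads. The network
# generator mimics the sparse hub structure of curated microRNA target
# corpora: heavy-tailed (truncated power-law) microRNA out-degree, a
# controllable fraction of in-degree-1 ("single-line") genes, and a TF label
# on a subset of genes. Planted microRNAs are rewired — never given extra
# edges — so their degree totals stay comparable to the background.

# Smallest degree of a truncated power-law on {kmin..kmax} whose mean best
# matches `target_mean`; the mean is monotone increasing in kmin.
powerlaw_kmin <- function(target_mean, kmax, exponent) {
  pl_mean <- function(kmin) {
    k <- kmin:kmax
    w <- k^(-exponent)
    sum(k * w) / sum(w)
  }
  if (target_mean >= kmax) stop("mean_outdegree must be < n_gene")
  lo <- 1L; hi <- kmax - 1L
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (pl_mean(mid) <= target_mean) lo <- mid else hi <- mid - 1L
  }
  # lo is the largest kmin not overshooting; pick the closer of lo, lo+1
  if (lo < kmax - 1L &&
      abs(pl_mean(lo + 1L) - target_mean) < abs(pl_mean(lo) - target_mean))
    lo <- lo + 1L
  lo
}

#' Simulate a bipartite regulatory network with planted vulnerable microRNAs
#'
#' MicroRNA out-degrees follow a truncated power law (exponent
#' `outdegree_exponent`, lower cutoff solved so the mean matches
#' `mean_outdegree`). A fraction `singleline_fraction` of genes receives
#' in-degree exactly 1; the remaining edge stubs are spread over genes with
#' in-degree at least 2. `tf_fraction` of the network genes are labelled as
#' transcription factors.
#'
#' Planted microRNAs are drawn from the upper degree quartile (excluding the
#' extreme hubs) and rewired so that about 70% of their targets become
#' single-line regulations; their targets are then enriched to a TF share of
#' about 35% overall and among unique targets (guaranteeing at least one TF
#' unique target). Rewiring moves co-regulator edges to other multi-regulated
#' genes, so every microRNA keeps its drawn out-degree and the total edge
#' count is unchanged.
#'
#' @param n_mirna,n_gene node counts (positive integers).
#' @param mean_outdegree target mean microRNA out-degree (default 79,
#'   matching the density of curated human microRNA-target corpora).
#' @param singleline_fraction fraction of genes with in-degree 1
#'   (default 0.25).
#' @param tf_fraction fraction of network genes labelled TF (default 0.10,
#'   roughly the share of TF genes in the human genome).
#' @param n_planted number of planted vulnerable microRNAs (default 0).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param outdegree_exponent power-law exponent (default 2).
#' @param max_outdegree upper truncation of the out-degree law; default one
#'   third of `n_gene` (even the largest hubs of curated corpora target only
#'   a minority of the gene universe).
#' @return list with elements `network` (a [regulatory_network()]), `tf_set`
#'   (character vector) and `truth` (class `synthetic_truth`: list with
#'   `planted_mirnas`, `tf_fraction`, `de_features`, `seed`).
#' @export
simulate_network <- function(n_mirna, n_gene, mean_outdegree = 79,
                             singleline_fraction = 0.25, tf_fraction = 0.10,
                             n_planted = 0L, seed = 1L,
                             outdegree_exponent = 2,
                             max_outdegree = NULL) {
  stopifnot(n_mirna >= 1, n_gene >= 2, mean_outdegree >= 1,
            singleline_fraction >= 0, singleline_fraction <= 1,
            tf_fraction >= 0, tf_fraction <= 1, n_planted >= 0)
  if (n_planted > n_mirna) stop("n_planted > n_mirna is infeasible")
  set.seed(as.integer(seed))

  mirna_ids <- sprintf("miR-sim-%03d", seq_len(n_mirna))
  gene_ids <- sprintf("G%05d", seq_len(n_gene))

  kmax <- max_outdegree %||% max(2L, n_gene %/% 3L)
  if (kmax > n_gene) stop("max_outdegree must be <= n_gene")
  if (kmax <= mean_outdegree) stop("max_outdegree must exceed mean_outdegree")
  kmin <- powerlaw_kmin(mean_outdegree, kmax, outdegree_exponent)
  kk <- kmin:kmax
  deg <- sample(kk, n_mirna, replace = TRUE, prob = kk^(-outdegree_exponent))
  E <- sum(deg)

  n1 <- round(singleline_fraction * n_gene)
  if (E < n1) stop("infeasible: fewer edges than requested single-line genes")
  R <- E - n1
  m_max <- n_gene - n1
  single_genes <- gene_ids[seq_len(n1)]
  if (R >= 2 * m_max) {
    extra <- as.vector(rmultinom(1, R - 2L * m_max,
                                 prob = seq_len(m_max)^-1))
    indeg_multi <- 2L + extra
    multi_genes <- gene_ids[n1 + seq_len(m_max)]
  } else {
    m <- R %/% 2L
    if (m == 0L && R > 0L) m <- 1L
    indeg_multi <- if (m > 0L) rep(2L, m) else integer(0)
    if (m > 0L) indeg_multi[1L] <- indeg_multi[1L] + (R - 2L * m)
    multi_genes <- gene_ids[n1 + seq_len(m)]
  }
  mirna_stub_idx <- sample(rep(seq_len(n_mirna), deg))
  gene_stub_idx <- sample(c(match(single_genes, gene_ids),
                            rep(match(multi_genes, gene_ids), indeg_multi)))
  gene_stub_idx <- repair_collisions(mirna_stub_idx, gene_stub_idx, n_gene)
  edges <- data.frame(mirna = mirna_ids[mirna_stub_idx],
                      gene = gene_ids[gene_stub_idx],
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$mirna, edges$gene, sep = "\r")), ]
  rownames(edges) <- NULL

  planted <- character(0)
  if (n_planted > 0L) {
    realized_deg <- table(edges$mirna)
    q <- stats::quantile(as.numeric(realized_deg), c(0.75, 0.97))
    eligible <- names(realized_deg)[realized_deg >= q[1] & realized_deg <= q[2]]
    if (length(eligible) < n_planted)
      eligible <- names(sort(realized_deg, decreasing = TRUE))[
        seq_len(max(n_planted, ceiling(n_mirna / 4)))]
    planted <- sample(eligible, n_planted)
    edges <- plant_vulnerable(edges, planted, unique_share = 0.7)
  }

  genes_net <- unique(edges$gene)
  n_tf <- round(tf_fraction * length(genes_net))
  tf_set <- sample(genes_net, n_tf)
  if (n_planted > 0L)
    tf_set <- enrich_planted_tf(edges, planted, tf_set, tf_share = 0.35)

  net <- regulatory_network(edges)
  truth <- structure(
    list(planted_mirnas = planted, tf_fraction = tf_fraction,
         de_features = NULL, seed = as.integer(seed)),
    class = "synthetic_truth")
  list(network = net, tf_set = tf_set, truth = truth)
}

# Resolve repeated (mirna, gene) stub pairings by swapping gene endpoints
# between edge pairs; both degree sequences are preserved exactly, so the
# realized single-line fraction stays at the requested value (a plain drop
# of collided pairs would convert multi-regulated genes into spurious
# single-line ones under heavy-tailed out-degrees). Swaps are accepted only
# when neither resulting pair already exists; any collisions that survive
# the passes are left for the downstream dedup (vanishingly rare for
# feasible degree sequences).
repair_collisions <- function(mirna_idx, gene_idx, n_gene, max_pass = 100L) {
  n <- length(gene_idx)
  enc <- function(m, g) (m - 1) * n_gene + g     # integer pair key
  for (pass in seq_len(max_pass)) {
    key <- enc(mirna_idx, gene_idx)
    dup <- which(duplicated(key))
    if (!length(dup)) break
    partner <- sample.int(n, length(dup), replace = TRUE)
    proposed1 <- enc(mirna_idx[dup], gene_idx[partner])
    proposed2 <- enc(mirna_idx[partner], gene_idx[dup])
    valid <- dup != partner & !(proposed1 %in% key) & !(proposed2 %in% key)
    d <- dup[valid]; p <- partner[valid]
    touched <- logical(n)
    for (k in seq_along(d)) {        # scalar swaps keep the stub multiset
      i <- d[k]; j <- p[k]
      if (touched[i] || touched[j]) next
      tmp <- gene_idx[i]; gene_idx[i] <- gene_idx[j]; gene_idx[j] <- tmp
      touched[i] <- TRUE; touched[j] <- TRUE
    }
  }
  gene_idx
}

# Rewire co-regulator edges away from a share of each planted microRNA's
# targets so those targets become in-degree-1. Destination genes always keep
# in-degree >= 2 and are never targets of a planted microRNA, so other
# planted profiles are untouched and no new single-line gene appears outside
# the planted target sets.
plant_vulnerable <- function(edges, planted, unique_share = 0.7) {
  gene_levels <- unique(edges$gene)
  mirna_levels <- unique(edges$mirna)
  n_gene <- length(gene_levels)
  g_idx <- match(edges$gene, gene_levels)
  m_idx <- match(edges$mirna, mirna_levels)
  indeg <- tabulate(g_idx, n_gene)
  planted_i <- match(planted, mirna_levels)
  is_planted_tgt <- logical(n_gene)
  is_planted_tgt[g_idx[m_idx %in% planted_i]] <- TRUE
  # hash of existing (mirna, gene) pairs for duplicate avoidance
  pair_key <- function(m, g) as.character((m - 1) * n_gene + g)
  pair_env <- new.env(hash = TRUE, size = nrow(edges) * 2L)
  for (k in pair_key(m_idx, g_idx)) assign(k, TRUE, envir = pair_env)
  dest_pool <- which(indeg >= 2L & !is_planted_tgt)
  rows_by_gene <- split(seq_along(g_idx), g_idx)

  for (mi in planted_i) {
    tgt <- g_idx[m_idx == mi]
    want <- ceiling(unique_share * length(tgt))
    n_unique <- sum(indeg[tgt] == 1L)
    # genes we may free up: multi-regulated targets of this microRNA not
    # shared with another planted microRNA
    shared <- unique(g_idx[m_idx %in% setdiff(planted_i, mi)])
    candidates <- sample(setdiff(tgt[indeg[tgt] >= 2L], shared))
    for (g in candidates) {
      if (n_unique >= want) break
      # rows_by_gene stays valid: rewiring destinations are never planted
      # targets, and each planted target gene is processed at most once
      rows <- rows_by_gene[[as.character(g)]]
      move_rows <- rows[m_idx[rows] != mi]
      for (rw in move_rows) {
        mprime <- m_idx[rw]
        dest <- NA_integer_
        for (try in seq_len(50L)) {
          cand <- dest_pool[sample.int(length(dest_pool), 1L)]
          if (indeg[cand] >= 2L &&
              !exists(pair_key(mprime, cand), envir = pair_env,
                      inherits = FALSE)) {
            dest <- cand
            break
          }
        }
        if (is.na(dest)) next
        rm(list = pair_key(mprime, g), envir = pair_env)
        assign(pair_key(mprime, dest), TRUE, envir = pair_env)
        g_idx[rw] <- dest
        indeg[g] <- indeg[g] - 1L
        indeg[dest] <- indeg[dest] + 1L
      }
      if (indeg[g] == 1L) n_unique <- n_unique + 1L
    }
  }
  edges$gene <- gene_levels[g_idx]
  edges
}

# Swap TF labels so each planted microRNA reaches ~`tf_share` TF genes among
# all of its targets and among its unique targets (>= 1 TF unique target
# guaranteed). The TF set size is preserved by dropping TFs not targeted by
# any planted microRNA.
enrich_planted_tf <- function(edges, planted, tf_set, tf_share = 0.35) {
  indeg <- table(edges$gene)
  added <- character(0)
  for (m in planted) {
    tgt <- edges$gene[edges$mirna == m]
    u <- tgt[indeg[tgt] == 1L]
    nonu <- setdiff(tgt, u)
    want_u <- if (length(u)) max(1L, ceiling(tf_share * length(u))) else 0L
    need_u <- want_u - sum(u %in% tf_set)
    if (need_u > 0) {
      conv <- sample(setdiff(u, tf_set), min(need_u, length(setdiff(u, tf_set))))
      tf_set <- c(tf_set, conv); added <- c(added, conv)
    }
    want_all <- ceiling(tf_share * length(tgt))
    need_all <- want_all - sum(tgt %in% tf_set)
    if (need_all > 0) {
      pool <- setdiff(nonu, tf_set)
      conv <- sample(pool, min(need_all, length(pool)))
      tf_set <- c(tf_set, conv); added <- c(added, conv)
    }
  }
  planted_targets <- unique(edges$gene[edges$mirna %in% planted])
  removable <- setdiff(tf_set, c(planted_targets, added))
  n_drop <- min(length(added), length(removable))
  if (n_drop > 0) tf_set <- setdiff(tf_set, sample(removable, n_drop))
  tf_set
}

#' Simulate two-group log2-scale expression with planted effects
#'
#' Group A values are i.i.d. Normal(`mu0`, `sigma^2`); group B values are
#' shifted by the feature's effect size (in log2 units, 0 for non-DE
#' features). Deterministic per seed.
#'
#' @param n_features number of features; ids are `f0001, f0002, ...` unless
#'   `feature_ids` is given.
#' @param n_A,n_B samples per group (group A = reference).
#' @param de_features named numeric vector of log2 effect sizes; names must
#'   be feature ids (a positive effect means up in group B).
#' @param sigma residual standard deviation on the log2 scale (default 0.5,
#'   a typical within-group spread for array data).
#' @param seed integer seed.
#' @param mu0 baseline log2 abundance (default 7).
#' @param feature_ids optional character vector of feature ids.
#' @return an [expression_matrix()] with attribute `truth` (a
#'   `synthetic_truth` carrying `de_features` and `seed`).
#' @export
simulate_expression <- function(n_features, n_A, n_B,
                                de_features = numeric(0), sigma = 0.5,
                                seed = 1L, mu0 = 7, feature_ids = NULL) {
  stopifnot(n_features >= 1, n_A >= 2, n_B >= 2)
  if (sigma <= 0) stop("sigma must be > 0")
  set.seed(as.integer(seed))
  if (is.null(feature_ids))
    feature_ids <- sprintf("f%04d", seq_len(n_features))
  stopifnot(length(feature_ids) == n_features)
  if (length(de_features)) {
    stopifnot(!is.null(names(de_features)))
    bad <- setdiff(names(de_features), feature_ids)
    if (length(bad)) stop("unknown DE feature id(s): ",
                          paste(bad, collapse = ", "))
  }
  n <- n_A + n_B
  vals <- matrix(rnorm(n_features * n, mean = mu0, sd = sigma),
                 nrow = n_features, ncol = n,
                 dimnames = list(feature_ids,
                                 c(sprintf("A%03d", seq_len(n_A)),
                                   sprintf("B%03d", seq_len(n_B)))))
  if (length(de_features)) {
    idx <- match(names(de_features), feature_ids)
    vals[idx, n_A + seq_len(n_B)] <-
      vals[idx, n_A + seq_len(n_B)] + de_features
  }
  em <- expression_matrix(vals, factor(rep(c("group_A", "group_B"),
                                           c(n_A, n_B)),
                                       levels = c("group_A", "group_B")))
  attr(em, "truth") <- structure(
    list(planted_mirnas = character(0), tf_fraction = NA_real_,
         de_features = de_features, seed = as.integer(seed)),
    class = "synthetic_truth")
  em
}
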