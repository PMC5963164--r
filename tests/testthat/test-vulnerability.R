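test_that("NSR counts uniquely regulated targets", {
  net <- fig2_network()
  expect_equal(compute_nsr(net), c(M1 = 1L, M2 = 0L, M3 = 0L, M4 = 1L))
})

test_that("NSR/TFP/UTP match brute-force scans on random networks", {
  set.seed(101)
  for (rep in 1:25) {
    net <- random_bipartite(n_mirna = sample(5:20, 1),
                            n_gene = sample(20:60, 1),
                            n_edges = sample(30:120, 1),
                            seed = 1000 + rep)
    tf <- sample(net$genes, ceiling(length(net$genes) / 5))
    expect_equal(compute_nsr(net), brute_nsr(net))
    expect_equal(compute_tfp(net, tf), brute_tfp(net, tf))
    expect_equal(compute_utp(net, tf), brute_utp(net, tf))
    # conservation: total NSR equals the number of in-degree-1 genes
    indeg <- table(net$edges$gene)
    expect_equal(sum(compute_nsr(net)), sum(indeg == 1L))
  }
})

test_that("larger random network matches the brute-force oracle", {
  net <- random_bipartite(50, 200, 600, seed = 77)
  tf <- sample(net$genes, 40)
  expect_equal(compute_nsr(net), brute_nsr(net))
  expect_equal(compute_tfp(net, tf), brute_tfp(net, tf))
  expect_equal(compute_utp(net, tf), brute_utp(net, tf))
})

test_that("UTP follows its stated conventions", {
  net <- fig2_network()
  # M4 uniquely regulates only the TF gene G10
  expect_equal(compute_utp(net, "G10")[["M4"]], 1.0)
  # NSR = 0 gives UTP = 0 by convention (M2, M3 share G5)
  expect_equal(compute_utp(net, c("G5", "G10"))[["M2"]], 0)
  # NSR 5 with exactly 1 TF unique target gives 0.2
  net2 <- regulatory_network(data.frame(
    mirna = "mA", gene = paste0("u", 1:5)))
  expect_equal(compute_utp(net2, "u3")[["mA"]], 0.2)
})

test_that("score products are integers over their denominators", {
  net <- random_bipartite(15, 50, 120, seed = 5150)
  tf <- sample(net$genes, 10)
  sc <- score_network(net, tf)
  expect_true(all(abs(sc$tfp * sc$n_targets -
                        round(sc$tfp * sc$n_targets)) < 1e-9))
  expect_true(all(abs(sc$utp * sc$nsr - round(sc$utp * sc$nsr)) < 1e-9))
  expect_true(all(sc$nsr <= sc$n_targets))
})

test_that("NSR monotonicity under edge edits", {
  set.seed(202)
  for (rep in 1:10) {
    net <- random_bipartite(8, 25, 50, seed = 300 + rep)
    nsr <- compute_nsr(net)
    # adding a regulator to an in-degree-1 gene never increases any NSR
    indeg <- table(net$edges$gene)
    g1 <- names(indeg)[indeg == 1L]
    if (length(g1)) {
      g <- g1[1]
      owner <- net$edges$mirna[net$edges$gene == g]
      other <- setdiff(net$mirnas, owner)[1]
      if (!is.na(other)) {
        net2 <- regulatory_network(rbind(net$edges,
          data.frame(mirna = other, gene = g, n_experimental_lt = 0L,
                     predicted_dbs = "")))
        nsr2 <- compute_nsr(net2)
        expect_true(all(nsr2[names(nsr)] <= nsr))
      }
    }
    # deleting a co-regulator edge never decreases the remaining NSRs
    g2 <- names(indeg)[indeg == 2L]
    if (length(g2)) {
      drop_row <- which(net$edges$gene == g2[1])[1]
      net3 <- regulatory_network(net$edges[-drop_row, ])
      nsr3 <- compute_nsr(net3)
      expect_true(all(nsr3[names(nsr3)] >= nsr[names(nsr3)]))
    }
  }
})

test_that("exact signed-rank p equals full sign enumeration", {
  expect_equal(wilcoxon_signed_rank_one_sided(c(0.3, 1, 2, 0.5, 4)), 1 / 32)
  set.seed(404)
  for (rep in 1:15) {
    n <- sample(3:12, 1)
    d <- round(rnorm(n), sample(0:1, 1))  # rounding induces ties/zeros
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxon_signed_rank_one_sided(d), brute_signed_rank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank handles symmetry, zeros and degenerate input", {
  # symmetric pairs: no support for a positive shift
  expect_gte(wilcoxon_signed_rank_one_sided(c(2, -2, 1, -1)), 0.5)
  # exact zeros dropped before testing
  expect_equal(wilcoxon_signed_rank_one_sided(c(0, 0, 1, 2, 3, 4, 5)), 1 / 32)
  expect_error(wilcoxon_signed_rank_one_sided(c(0, 0, 0)),
               class = "mirvuln_all_zero")
})

test_that("signed-rank approximation agrees with wilcox.test beyond n = 25", {
  set.seed(505)
  for (rep in 1:5) {
    d <- rnorm(40, 0.3)
    expect_equal(wilcoxon_signed_rank_one_sided(d),
                 wilcox.test(d, alternative = "greater", exact = FALSE,
                             correct = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("significant_high flags outliers and respects invariances", {
  scores <- c(A = 40, stats::setNames(rep(c(0, 1, 2), 10), paste0("m", 1:30)))
  expect_true("A" %in% significant_high(scores))
  # the exact p for A derives from enumeration over the non-tied diffs
  dA <- scores["A"] - scores[-1]
  expect_lt(brute_signed_rank_p(dA[dA != 0][1:12]), 0.05)
  expect_equal(significant_high(c(a = 1, b = 1, c = 1)), character(0))
  expect_equal(significant_high(scores, alpha = 0), character(0))
  expect_error(significant_high(c(a = 1, b = 2)), "at least 3")
  # invariant to ordering and to adding a constant
  perm <- sample(length(scores))
  expect_setequal(significant_high(scores[perm]), significant_high(scores))
  expect_setequal(significant_high(scores + 7), significant_high(scores))
})

test_that("percentile rule keeps only the upper tail", {
  scores <- stats::setNames(1:100, paste0("m", 1:100))
  hi <- significant_high(scores, alpha = 0.05, method = "percentile")
  expect_true(all(scores[hi] > stats::quantile(scores, 0.95)))
  expect_lte(length(hi), 5)
})

test_that("KS statistic matches the brute-force ECDF sweep", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  set.seed(606)
  for (rep in 1:10) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), 0.5)
    expect_equal(ks_two_sample(a, b)$statistic, brute_ks_d(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the three-step filter nests and traces correctly", {
  sim <- simulate_network(80, 600, mean_outdegree = 10,
                          singleline_fraction = 0.3, n_planted = 2,
                          seed = 2024)
  cs <- microrna_bd_filter(sim$network, sim$tf_set)
  expect_true(all(cs$candidates %in% cs$step2))
  expect_true(all(cs$step2 %in% cs$step1))
  expect_true(all(cs$step1 %in% sim$network$mirnas))
  expect_true(all(cs$scores$utp[match(cs$candidates, cs$scores$mirna)] > 0))
  tr <- candidate_trace(cs)
  expect_equal(sum(tr$is_candidate), length(cs$candidates))
  expect_true(all(tr$is_candidate <= tr$passed_step2))
  expect_true(all(tr$passed_step2 <= tr$passed_step1))
  expect_error(microrna_bd_filter(regulatory_network(
    data.frame(mirna = character(), gene = character())), "TF"), "empty")
})

test_that("a uniform-degree network yields no vulnerability signal", {
  # every gene regulated by exactly two microRNAs: NSR and UTP all zero
  edges <- expand.grid(mirna = paste0("m", 1:6), gene = paste0("g", 1:8),
                       stringsAsFactors = FALSE)
  edges <- edges[rep(c(TRUE, FALSE), length.out = nrow(edges)), ]
  keep <- unlist(lapply(split(seq_len(nrow(edges)), edges$gene),
                        function(i) i[1:2]))
  net <- regulatory_network(edges[keep, ])
  cs <- microrna_bd_filter(net, sample(net$genes, 2))
  expect_length(cs$candidates, 0)
  expect_equal(sum(compute_nsr(net)), 0L)
})

test_that("planted vulnerable microRNAs are recovered by the filter", {
  sim <- simulate_network(600, 9000, n_planted = 3, seed = 7001)
  cs <- microrna_bd_filter(sim$network, sim$tf_set)
  expect_true(all(sim$truth$planted_mirnas %in% cs$candidates))
})

test_that("the UTP > 0 step reproduces the seven-to-five worked example", {
  scores <- read_result_table(system.file("extdata", "mpca_step2_scores.tsv",
                                          package = "mirvuln"))
  expect_equal(nrow(scores), 7L)
  cand <- utp_filter(scores)
  expect_setequal(cand, c("miR-204-5p", "miR-101-3p", "miR-145-5p",
                          "miR-198", "miR-152"))
  expect_false(any(c("miR-130a-3p", "miR-363-3p") %in% cand))
})
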