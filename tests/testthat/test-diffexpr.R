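make_em <- function(vals_by_group, feature_ids = NULL) {
  # vals_by_group: list(A = matrix, B = matrix) with features in rows
  m <- cbind(vals_by_group$A, vals_by_group$B)
  nA <- ncol(vals_by_group$A); nB <- ncol(vals_by_group$B)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(m)))
  dimnames(m) <- list(feature_ids, paste0("s", seq_len(nA + nB)))
  expression_matrix(m, rep(c("A", "B"), c(nA, nB)))
}

test_that("log2 fold change is the B-minus-A mean difference", {
  em <- make_em(list(A = rbind(c(2, 2)), B = rbind(c(3, 3))))
  expect_equal(log2_fold_change(em, "f1"), 1.0)
  em0 <- make_em(list(A = rbind(c(5, 6)), B = rbind(c(5, 6))))
  expect_equal(log2_fold_change(em0, "f1"), 0.0)
  set.seed(42)
  A <- matrix(rnorm(50), 10); B <- matrix(rnorm(50), 10)
  em2 <- make_em(list(A = A, B = B))
  expect_equal(unname(log2_fold_change(em2)),
               rowMeans(B) - rowMeans(A))
  expect_error(log2_fold_change(em2, "nope"), "unknown feature")
})

test_that("d0 = 0 reduces the moderated t to the ordinary pooled t", {
  set.seed(5)
  em <- make_em(list(A = matrix(rnorm(40, 8), 8), B = matrix(rnorm(40, 8), 8)))
  res <- moderated_t_test(em, params = list(d0 = 0, s0_sq = 1))
  # independently coded pooled two-sample t
  for (i in seq_len(8)) {
    a <- em$values[i, 1:5]; b <- em$values[i, 6:10]
    sp2 <- ((5 - 1) * var(a) + (5 - 1) * var(b)) / 8
    t_ref <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / 5 + 1 / 5))
    expect_equal(res$t_stat[i], unname(t_ref), tolerance = 1e-10)
    expect_equal(res$p_raw[i], 2 * pt(-abs(t_ref), df = 8), tolerance = 1e-10)
  }
})

test_that("d0 = Inf pins every posterior variance at s0_sq", {
  set.seed(6)
  em <- make_em(list(A = matrix(rnorm(30, 8), 6), B = matrix(rnorm(30, 8), 6)))
  res <- moderated_t_test(em, params = list(d0 = Inf, s0_sq = 0.25))
  lfc <- log2_fold_change(em)
  expect_equal(res$t_stat, unname(lfc / sqrt(0.25 * (1 / 5 + 1 / 5))),
               tolerance = 1e-12)
})

test_that("estimated moderated t agrees with the limma eBayes pipeline", {
  set.seed(8)
  nA <- 6; nB <- 6
  em <- make_em(list(A = matrix(rnorm(300 * nA, 8, 0.7), 300),
                     B = matrix(rnorm(300 * nB, 8, 0.7), 300)))
  res <- moderated_t_test(em)
  design <- cbind(1, rep(c(0, 1), c(nA, nB)))
  fit <- limma::eBayes(limma::lmFit(em$values, design))
  expect_equal(res$t_stat, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p_raw, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(res$log2_fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-8)
})

test_that("null simulation keeps the raw-p rejection rate near nominal", {
  em <- simulate_expression(2000, 10, 10, sigma = 0.6, seed = 303)
  res <- moderated_t_test(em)
  frac <- mean(res$p_raw < 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("features with too few usable samples are excluded", {
  em <- make_em(list(A = matrix(rnorm(12, 8), 3), B = matrix(rnorm(12, 8), 3)))
  em$values[2, 1:3] <- NA   # one usable A sample left for f2
  expect_message(res <- moderated_t_test(em, params = list(d0 = 0, s0_sq = 1)),
                 "excluding 1 feature")
  expect_setequal(res$feature_id, c("f1", "f3"))
})

test_that("BH adjustment matches the direct step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))                      # BH only increases
    expect_true(all(diff(adj[order(p)]) >= -1e-12)) # monotone in sorted order
    # re-sorting invariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm])[order(perm)], adj)
  }
})

test_that("probe collapsing keeps the most significant probe per gene", {
  res <- data.frame(
    feature_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    log2_fc = c(1, 2, 0.5, 1, 1, 3),
    t_stat = c(2.5, 4.0, 1.0, 3.1, -2.0, 5),
    p_raw = c(0.2, 0.01, 0.3, 0.05, 0.05, 0.001),
    p_adj = NA_real_, is_de = NA)
  p2g <- c(p1 = "GENEA", p2 = "GENEA", p3 = "GENEB",
           p4 = "GENEC", p5 = "GENEC", p6 = "UNUSED_SINGLE")
  out <- collapse_probes(res, p2g)
  expect_equal(out$probe_id[out$feature_id == "GENEA"], "p2")  # min p_raw
  expect_equal(out$probe_id[out$feature_id == "GENEB"], "p3")  # single probe
  expect_equal(out$probe_id[out$feature_id == "GENEC"], "p4")  # |t| tie-break
  # single-probe record passes through unchanged (apart from the id columns)
  expect_equal(out$p_raw[out$feature_id == "GENEB"], 0.3)
  # unmapped probes dropped with a message
  res2 <- rbind(res, data.frame(feature_id = "p7", log2_fc = 0, t_stat = 0,
                                p_raw = 0.5, p_adj = NA_real_, is_de = NA))
  expect_message(out2 <- collapse_probes(res2, p2g), "1 unmapped")
  expect_setequal(out2$feature_id, out$feature_id)
  # p_raw tie with equal |t|: lexicographically smallest probe id wins
  res3 <- res
  res3$p_raw[4:5] <- 0.05; res3$t_stat[4:5] <- c(2, -2)
  out3 <- collapse_probes(res3, p2g)
  expect_equal(out3$probe_id[out3$feature_id == "GENEC"], "p4")
})

test_that("the DE cut-off is strict on both thresholds", {
  res <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    log2_fc = c(-1.5, 0.5, 2.0, -2.0896),
    p_adj = c(0.04, 0.04, 0.05, 3.43e-08))
  expect_setequal(filter_de(res), c("a", "d"))
  expect_false("b" %in% filter_de(res))      # |lfc| too small
  expect_false("c" %in% filter_de(res))      # p_adj == alpha excluded
  expect_error(filter_de(data.frame(feature_id = "a", log2_fc = 1,
                                    p_adj = NA_real_)), "p_adj")
})

test_that("filter_de is order-invariant and label-swap symmetric", {
  set.seed(21)
  em <- simulate_expression(200, 6, 6, de_features = c(f0001 = 3, f0002 = -3),
                            sigma = 0.5, seed = 99)
  de <- run_de(em)
  perm <- sample(nrow(de))
  expect_setequal(filter_de(de[perm, ]), filter_de(de))
  # swapping group labels flips log2_fc but keeps the DE set
  em_sw <- expression_matrix(em$values,
                             factor(em$groups,
                                    levels = rev(levels(em$groups))))
  de_sw <- run_de(em_sw)
  expect_equal(de_sw$log2_fc, -de$log2_fc, tolerance = 1e-12)
  expect_setequal(filter_de(de_sw), filter_de(de))
  expect_setequal(filter_de(de), c("f0001", "f0002"))
})
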