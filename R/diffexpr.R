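# Two-group differential expression with an empirical-Bayes moderated t.
# Feature-wise sample variances are shrunk toward a common prior
# s2_post = (d0*s0^2 + d*s2) / (d0 + d); the prior (d0, s0^2) is either given
# or estimated from the ensemble of sample variances (method of moments on
# the scaled-F model, via limma::squeezeVar). d0 = 0 recovers the ordinary
# pooled two-sample t; d0 = Inf pins every variance at s0^2.

#' Log2 fold changes between the two groups
#'
#' Mean of group B minus mean of group A, per feature, on the (already log2)
#' scale of the matrix. Positive values mean up-regulated in group B.
#' Missing values are ignored per group.
#'
#' @param em an [expression_matrix()].
#' @param feature optional single feature id; when given, returns a scalar.
#' @return named numeric vector of fold changes (or a scalar for one feature).
#' @export
log2_fold_change <- function(em, feature = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  gm <- group_masks(em)
  mA <- rowMeans(em$values[, gm$A, drop = FALSE], na.rm = TRUE)
  mB <- rowMeans(em$values[, gm$B, drop = FALSE], na.rm = TRUE)
  lfc <- mB - mA
  if (!is.null(feature)) {
    if (!feature %in% rownames(em$values)) stop("unknown feature: ", feature)
    return(unname(lfc[feature]))
  }
  lfc
}

#' Moderated two-sample t-test
#'
#' Per feature: pooled sample variance `s2` on `d = nA + nB - 2` residual
#' degrees of freedom, posterior variance
#' `s2_post = (d0*s0_sq + d*s2)/(d0 + d)`, moderated statistic
#' `t = log2FC / sqrt(s2_post * (1/nA + 1/nB))`, and a two-sided p-value from
#' a t distribution on `d0 + d` degrees of freedom.
#'
#' Features are tested on their non-missing samples; features with fewer than
#' two usable samples in either group are excluded with a message. The
#' adjusted p-value column is left `NA` — apply [bh_adjust()] (or use
#' [run_de()]) afterwards.
#'
#' @param em an [expression_matrix()].
#' @param params either the string `"estimate"` (fit `d0` and `s0_sq` from the
#'   ensemble of sample variances) or a list with elements `d0` (prior
#'   degrees of freedom, `>= 0`, may be `Inf`) and `s0_sq` (prior variance,
#'   `> 0`).
#' @return data.frame (class `de_result`) with columns
#'   `feature_id, log2_fc, t_stat, p_raw, p_adj, is_de`; attributes `d0` and
#'   `s0_sq` record the prior used.
#' @export
moderated_t_test <- function(em, params = "estimate") {
  stopifnot(inherits(em, "expr_matrix"))
  gm <- group_masks(em)
  A <- em$values[, gm$A, drop = FALSE]
  B <- em$values[, gm$B, drop = FALSE]
  nA <- rowSums(!is.na(A))
  nB <- rowSums(!is.na(B))
  usable <- nA >= 2L & nB >= 2L
  if (!all(usable))
    message("moderated_t_test: excluding ", sum(!usable),
            " feature(s) with < 2 usable samples in a group")
  if (!any(usable)) stop("no feature has >= 2 samples in both groups")
  A <- A[usable, , drop = FALSE]; B <- B[usable, , drop = FALSE]
  nA <- nA[usable]; nB <- nB[usable]

  mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)
  ssA <- rowSums((A - mA)^2, na.rm = TRUE)
  ssB <- rowSums((B - mB)^2, na.rm = TRUE)
  d <- nA + nB - 2
  s2 <- (ssA + ssB) / d
  lfc <- mB - mA

  if (identical(params, "estimate")) {
    if (all(s2 == 0)) stop("all sample variances are zero: degenerate input")
    sq <- limma::squeezeVar(s2, df = d)
    d0 <- sq$df.prior
    s0_sq <- sq$var.prior
    s2_post <- sq$var.post
  } else {
    if (!is.list(params) || is.null(params$d0) || is.null(params$s0_sq))
      stop("`params` must be \"estimate\" or list(d0 =, s0_sq =)")
    d0 <- params$d0; s0_sq <- params$s0_sq
    if (d0 < 0) stop("d0 must be >= 0")
    if (s0_sq <= 0) stop("s0_sq must be > 0")
    s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
               else (d0 * s0_sq + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  t_stat <- lfc / se
  df_total <- d0 + d
  p_raw <- 2 * pt(-abs(t_stat), df = df_total)
  out <- data.frame(
    feature_id = rownames(A),
    log2_fc = unname(lfc),
    t_stat = unname(t_stat),
    p_raw = unname(p_raw),
    p_adj = NA_real_,
    is_de = NA,
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment, capped at 1, order-preserving with the input
#' index. Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p_raw numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_raw) {
  if (anyNA(p_raw) || any(p_raw < 0 | p_raw > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_raw, method = "BH")
}

#' Collapse probe-level results to gene level
#'
#' A gene measured by several probes is represented by the probe with the most
#' significant variation: smallest `p_raw`, ties broken by largest `|t_stat|`,
#' then by lexicographically smallest probe id. Probes without a gene mapping
#' are dropped (and counted in a message).
#'
#' @param results probe-level data.frame from [moderated_t_test()].
#' @param probe2gene named character vector: `names()` are probe ids, values
#'   gene symbols.
#' @return gene-level data.frame; `feature_id` becomes the gene symbol, and a
#'   `probe_id` column records the representative probe. Rows sorted by gene.
#' @export
collapse_probes <- function(results, probe2gene) {
  stopifnot(is.data.frame(results), is.character(probe2gene),
            !is.null(names(probe2gene)))
  gene <- unname(probe2gene[results$feature_id])
  unmapped <- is.na(gene)
  if (any(unmapped))
    message("collapse_probes: dropping ", sum(unmapped),
            " unmapped probe(s)")
  res <- results[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  if (!nrow(res)) stop("no probe maps to a gene")
  ord <- order(gene, res$p_raw, -abs(res$t_stat), res$feature_id)
  res <- res[ord, , drop = FALSE]
  gene <- gene[ord]
  first <- !duplicated(gene)
  out <- res[first, , drop = FALSE]
  out$probe_id <- out$feature_id
  out$feature_id <- gene[first]
  rownames(out) <- NULL
  out
}

#' Apply the differential-expression cut-off
#'
#' A feature is differentially expressed iff `p_adj < alpha` AND
#' `|log2_fc| > lfc_cut` — both inequalities strict.
#'
#' @param results data.frame with populated `p_adj` and `log2_fc` columns.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc_cut absolute log2 fold-change threshold (default 1).
#' @return character vector of DE feature ids.
#' @export
filter_de <- function(results, alpha = 0.05, lfc_cut = 1.0) {
  stopifnot(is.data.frame(results))
  if (anyNA(results$p_adj))
    stop("p_adj is not populated; run bh_adjust() first")
  results$feature_id[results$p_adj < alpha & abs(results$log2_fc) > lfc_cut]
}

#' Full differential-expression stage
#'
#' Convenience wrapper: moderated (or plain pooled) t-test, BH adjustment,
#' and the DE flag.
#'
#' @inheritParams moderated_t_test
#' @inheritParams filter_de
#' @param stat `"moderated"` (empirical-Bayes shrinkage, default) or
#'   `"plain"` (ordinary pooled t, i.e. `d0 = 0`).
#' @return data.frame with all columns of [moderated_t_test()] populated,
#'   including `p_adj` and `is_de`.
#' @export
run_de <- function(em, alpha = 0.05, lfc_cut = 1.0,
                   stat = c("moderated", "plain"), params = "estimate") {
  stat <- match.arg(stat)
  if (stat == "plain") {
    gm <- group_masks(em)
    # d0 = 0 makes s0_sq irrelevant; any positive value works
    params <- list(d0 = 0, s0_sq = 1)
  }
  res <- moderated_t_test(em, params = params)
  res$p_adj <- bh_adjust(res$p_raw)
  res$is_de <- res$p_adj < alpha & abs(res$log2_fc) > lfc_cut
  attr(res, "alpha") <- alpha
  attr(res, "lfc_cut") <- lfc_cut
  res
}
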