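# Single-marker evaluation: per-microRNA ROC/AUC for separating the two
# sample groups, and prediction precision against previously reported
# biomarkers.

#' ROC curve and AUC for one marker
#'
#' AUC is computed by the Mann-Whitney identity `U / (n_pos * n_neg)` with
#' ties contributing 1/2. The curve is a threshold sweep over the unique score
#' values (ties grouped) from the highest threshold down, so it starts at
#' (0, 0) and ends at (1, 1); its trapezoidal area equals the rank-based AUC.
#'
#' Down-regulated markers separate the groups with low scores; passing that
#' marker's (negative) fold change as `orient_by` negates the scores first so
#' the reported AUC reflects the marker's discriminative direction, and the
#' flip is recorded.
#'
#' @param scores per-sample numeric marker values (e.g. one microRNA's
#'   expression).
#' @param labels per-sample class labels, coercible to logical; `TRUE` is the
#'   positive class (e.g. metastatic).
#' @param orient_by `"none"` (default) or a single numeric; a negative value
#'   (e.g. the marker's discovery-set log2 fold change) flips the score sign
#'   before computing the curve.
#' @param name optional marker name carried into the result.
#' @return object of class `roc_result`: list with `name`, `auc`, `curve`
#'   (data.frame `fpr, tpr`) and `oriented` (whether the sign was flipped).
#' @export
roc_auc <- function(scores, labels, orient_by = "none", name = NULL) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  lab <- as.logical(labels)
  if (anyNA(lab)) stop("labels must be coercible to logical")
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  oriented <- FALSE
  if (is.numeric(orient_by)) {
    if (orient_by < 0) { scores <- -scores; oriented <- TRUE }
  } else if (!identical(orient_by, "none")) {
    stop("`orient_by` must be \"none\" or a single numeric")
  }
  r <- rank(scores)
  auc <- (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- lab[ord]
  grp_end <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(!l)[grp_end]
  curve <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(name = name, auc = auc, curve = curve, oriented = oriented),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result%s: AUC = %.4f%s\n",
              if (is.null(x$name)) "" else paste0(" [", x$name, "]"),
              x$auc, if (x$oriented) " (score sign flipped)" else ""))
  invisible(x)
}

#' Prediction precision against reported biomarkers
#'
#' The fraction of predicted candidates that appear in a curated list of
#' previously reported biomarkers.
#'
#' @param candidates non-empty character vector of predicted microRNAs.
#' @param reported character vector of reported biomarker microRNAs.
#' @return precision in `[0, 1]`.
#' @export
prediction_precision <- function(candidates, reported) {
  candidates <- unique(candidates)
  if (!length(candidates))
    stop(structure(class = c("mirvuln_empty_candidates", "error", "condition"),
                   list(message = "precision undefined for an empty candidate set",
                        call = sys.call(-1))))
  length(intersect(candidates, reported)) / length(candidates)
}

#' Evaluate a candidate set on an expression matrix
#'
#' Per candidate microRNA present in the matrix: oriented AUC for separating
#' group B from group A (orientation taken from the sign of the microRNA's
#' log2 fold change in `de_table`), the flip flag, and membership in the
#' reported-biomarker list.
#'
#' @param em an [expression_matrix()]; group B is the positive class.
#' @param candidates character vector of candidate microRNAs.
#' @param de_table data.frame with `feature_id` and `log2_fc` (used only for
#'   orientation; candidates absent from it are oriented by their own
#'   fold change in `em`).
#' @param reported character vector of reported biomarkers.
#' @return data.frame `mirna, auc_oriented, flipped, in_reported`, with the
#'   overall precision attached as attribute `precision`.
#' @export
evaluate_candidates <- function(em, candidates, de_table = NULL,
                                reported = character()) {
  stopifnot(inherits(em, "expr_matrix"))
  present <- intersect(candidates, rownames(em$values))
  if (!length(present)) stop("no candidate is present in the matrix")
  missing <- setdiff(candidates, present)
  if (length(missing))
    message("evaluate_candidates: ", length(missing),
            " candidate(s) absent from the matrix: ",
            paste(missing, collapse = ", "))
  gm <- group_masks(em)
  lfc_all <- log2_fold_change(em)
  rows <- lapply(present, function(m) {
    lfc <- if (!is.null(de_table) && m %in% de_table$feature_id)
      de_table$log2_fc[match(m, de_table$feature_id)] else lfc_all[[m]]
    rr <- roc_auc(em$values[m, ], gm$B, orient_by = lfc, name = m)
    data.frame(mirna = m, auc_oriented = rr$auc, flipped = rr$oriented,
               in_reported = m %in% reported, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "precision") <- prediction_precision(candidates, reported)
  out
}
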