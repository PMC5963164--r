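#' Two-group expression matrix
#'
#' Container for a log2-scale features x samples matrix together with a
#' two-level sample grouping. Group A is the reference condition (e.g. primary
#' tumour) and group B the contrast condition (e.g. metastatic tumour); fold
#' changes are reported as B minus A.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Values are assumed to be on
#'   log2 scale already. `NA` marks missing measurements; infinite values are
#'   rejected.
#' @param groups factor (or vector coercible to one) of length `ncol(values)`,
#'   with exactly two levels. The first level is taken as group A.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `groups`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, c("A", "A", "B", "B"))
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values`")
  if (any(is.infinite(values)))
    stop("`values` contains non-finite entries")
  if (length(groups) != ncol(values))
    stop("`groups` length (", length(groups), ") != number of samples (",
         ncol(values), ")")
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L)
    stop("`groups` must have exactly two levels, got ", nlevels(groups))
  if (anyNA(groups)) stop("every sample needs a group label")
  if (any(table(groups) == 0L)) stop("both groups must be non-empty")
  names(groups) <- colnames(values)
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("expr_matrix: %d features x %d samples (%s: %d, %s: %d)\n",
              nrow(x$values), ncol(x$values),
              levels(x$groups)[1], tab[1], levels(x$groups)[2], tab[2]))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

group_masks <- function(em) {
  lev <- levels(em$groups)
  list(A = em$groups == lev[1], B = em$groups == lev[2], levels = lev)
}
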