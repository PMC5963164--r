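#' Bipartite microRNA-mRNA regulatory network
#'
#' The central container of the package: a set of directed microRNA -> gene
#' regulatory edges with evidence provenance. Vulnerability scores (NSR, TFP,
#' UTP) are computed on this object.
#'
#' @param edges data.frame with columns `mirna`, `gene` and optionally
#'   `n_experimental_lt` (count of low-throughput experimental records
#'   supporting the pair) and `predicted_dbs` (semicolon-joined prediction
#'   databases). Duplicate (mirna, gene) pairs are an error; collapse them
#'   with [integrate_reference()] first.
#' @return object of class `regulatory_network`: list with `edges` (the
#'   data.frame), `mirnas` and `genes` (sorted character vectors of node
#'   names). Zero-edge networks are allowed (both node sets empty).
#' @export
regulatory_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("mirna", "gene") %in% names(edges)))
  edges$mirna <- as.character(edges$mirna)
  edges$gene <- as.character(edges$gene)
  if (nrow(edges)) {
    if (any(!nzchar(edges$mirna)) || any(!nzchar(edges$gene)))
      stop("edge with empty endpoint name")
    if (anyDuplicated(paste(edges$mirna, edges$gene, sep = "\r")))
      stop("duplicate (mirna, gene) pairs; run integrate_reference() first")
  }
  if (is.null(edges$n_experimental_lt))
    edges$n_experimental_lt <- rep(0L, nrow(edges))
  if (is.null(edges$predicted_dbs))
    edges$predicted_dbs <- rep("", nrow(edges))
  edges <- edges[, c("mirna", "gene", "n_experimental_lt", "predicted_dbs")]
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         mirnas = sort(unique(edges$mirna)),
         genes = sort(unique(edges$gene))),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d edges, %d microRNAs, %d genes\n",
              nrow(x$edges), length(x$mirnas), length(x$genes)))
  invisible(x)
}

#' Normalize microRNA names against an alias table
#'
#' Replaces every record's microRNA name by its canonical mature name
#' (miRBase Release-21 style). Records whose name has no canonical mapping are
#' dropped; the number dropped is reported via a message and attached as
#' attribute `n_unmapped`. Duplicate records produced by the collapse of two
#' aliases onto one canonical name are retained — deduplication happens during
#' [integrate_reference()], where evidence counting needs the multiplicity.
#'
#' @param edges edge records as returned by [read_edge_table()].
#' @param aliases alias mapping from [read_alias_table()] / [alias_table()].
#' @return edge records with canonical `mirna` names, in input order.
#' @export
normalize_names <- function(edges, aliases) {
  aliases <- alias_table(aliases)
  canon <- unname(aliases[edges$mirna])
  unmapped <- is.na(canon)
  if (any(unmapped))
    message("normalize_names: dropping ", sum(unmapped),
            " record(s) with unmappable microRNA name(s): ",
            paste(unique(edges$mirna[unmapped]), collapse = ", "))
  out <- edges[!unmapped, , drop = FALSE]
  out$mirna <- canon[!unmapped]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

#' Integrate evidence-tagged records into a reference network
#'
#' A (mirna, gene) pair enters the reference network iff it is supported by at
#' least one low-throughput experimental record (reporter assay, qPCR, ...) OR
#' predicted by at least `min_predicted_support` distinct prediction
#' databases. High-throughput experimental records never qualify a pair on
#' their own (they carry a higher false-positive rate) and are kept only as
#' annotation via the per-pair evidence summary.
#'
#' @param edges name-normalized edge records.
#' @param min_predicted_support minimum number of distinct prediction
#'   databases required for a purely predicted pair (default 2, i.e. the
#'   "at least two of three databases" agreement rule).
#' @return a [regulatory_network()]; one row per qualifying pair, sorted by
#'   (mirna, gene) so the result is invariant to input record order.
#' @export
integrate_reference <- function(edges, min_predicted_support = 2L) {
  stopifnot(is.data.frame(edges))
  if (min_predicted_support < 1L) stop("min_predicted_support must be >= 1")
  bad_evid <- setdiff(unique(edges$evidence), EVIDENCE_LEVELS)
  if (length(bad_evid))
    stop("unknown evidence label(s): ", paste(bad_evid, collapse = ", "))
  if (!nrow(edges)) return(regulatory_network(
    data.frame(mirna = character(), gene = character())))
  key <- paste(edges$mirna, edges$gene, sep = "\r")
  f <- factor(key, levels = unique(key))
  idx <- split(seq_len(nrow(edges)), f)
  rows <- lapply(idx, function(i) {
    ev <- edges$evidence[i]
    pred_dbs <- sort(unique(edges$source_db[i][ev == "predicted"]))
    data.frame(
      mirna = edges$mirna[i[1]],
      gene = edges$gene[i[1]],
      n_experimental_lt = sum(ev == "experimental_low_throughput"),
      n_predicted_dbs = length(pred_dbs),
      predicted_dbs = paste(pred_dbs, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  pairs <- do.call(rbind, rows)
  keep <- pairs$n_experimental_lt >= 1L |
    pairs$n_predicted_dbs >= min_predicted_support
  pairs <- pairs[keep, c("mirna", "gene", "n_experimental_lt",
                         "predicted_dbs"), drop = FALSE]
  pairs <- pairs[order(pairs$mirna, pairs$gene), , drop = FALSE]
  net <- regulatory_network(pairs)
  message(sprintf(
    "integrate_reference: %d pairs among %d microRNAs and %d genes",
    nrow(net$edges), length(net$mirnas), length(net$genes)))
  net
}

#' Project a reference network onto differential feature sets
#'
#' Extracts the condition-specific network: the induced bipartite subgraph on
#' the differentially expressed microRNAs and genes. Nodes left without edges
#' disappear (the node sets are derived from the surviving edges).
#'
#' @param ref reference [regulatory_network()].
#' @param de_mirnas character vector of DE microRNA names.
#' @param de_genes character vector of DE gene symbols.
#' @return the projected [regulatory_network()]; empty (with a warning) when
#'   the DE sets do not intersect the reference on one side.
#' @export
project_condition_network <- function(ref, de_mirnas, de_genes) {
  stopifnot(inherits(ref, "regulatory_network"))
  keep <- ref$edges$mirna %in% de_mirnas & ref$edges$gene %in% de_genes
  out <- regulatory_network(ref$edges[keep, , drop = FALSE])
  if (!nrow(out$edges))
    warning("projection is empty: DE sets do not overlap the reference network")
  out
}
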