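# Canonical external formats are TSV with a header line. A `dialect` mapping
# lets exports from heterogeneous interaction databases be ingested without
# prior renaming.

#' Read a microRNA-mRNA edge table
#'
#' Reads evidence-tagged interaction records. The canonical file is TSV with
#' columns `mirna, gene, source_db, evidence`; the `dialect` argument maps
#' canonical column names to the names actually used in the file.
#'
#' Gene symbols are upper-cased on ingest (symbol case is inconsistent across
#' source databases); microRNA names are kept case-sensitive per miRBase
#' convention. Rows with an empty `mirna` or `gene` field are dropped with a
#' row-numbered warning. Duplicate rows are retained at this layer: evidence
#' counting during network integration needs them.
#'
#' @param path path to a TSV file with a header line.
#' @param dialect named character vector mapping canonical names
#'   (`mirna`, `gene`, `source_db`, `evidence`) to file column names.
#'   Defaults to the identity mapping.
#' @return data.frame with columns `mirna, gene, source_db, evidence`
#'   (class `edge_records`), rows in file order.
#' @seealso [write_edge_table()], [integrate_reference()]
#' @export
read_edge_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("edge table not found: ", path)
  canon <- c("mirna", "gene", "source_db", "evidence")
  map <- stats::setNames(canon, canon)
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || !all(names(dialect) %in% canon))
      stop("`dialect` must be named with a subset of: ",
           paste(canon, collapse = ", "))
    map[names(dialect)] <- dialect
  }
  raw <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols))
    stop("cannot resolve column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df <- data.frame(
    mirna     = trimws(raw[[map["mirna"]]]),
    gene      = toupper(trimws(raw[[map["gene"]]])),
    source_db = trimws(raw[[map["source_db"]]]),
    evidence  = trimws(raw[[map["evidence"]]]),
    stringsAsFactors = FALSE
  )
  bad_evid <- setdiff(unique(df$evidence), EVIDENCE_LEVELS)
  if (length(bad_evid))
    stop("unknown evidence label(s): ", paste(bad_evid, collapse = ", "),
         " (expected one of: ", paste(EVIDENCE_LEVELS, collapse = ", "), ")")
  incomplete <- !nzchar(df$mirna) | !nzchar(df$gene)
  if (any(incomplete)) {
    warning("dropping ", sum(incomplete),
            " row(s) with empty mirna/gene field: rows ",
            paste(which(incomplete), collapse = ", "))
    df <- df[!incomplete, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("edge_records", "data.frame")
  df
}

#' Write a microRNA-mRNA edge table
#' @param edges data.frame with columns `mirna, gene, source_db, evidence`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  stopifnot(all(c("mirna", "gene", "source_db", "evidence") %in% names(edges)))
  write.table(edges[, c("mirna", "gene", "source_db", "evidence")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor gene list
#'
#' Plain text, one gene symbol per line; blank lines and lines starting with
#' `#` are ignored. Symbols are upper-cased and deduplicated.
#'
#' @param path path to the list file.
#' @return character vector of unique, upper-cased symbols.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stop("TF list not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- unique(toupper(lines))
  if (!length(out)) warning("TF list ", path, " is empty")
  out
}

#' Read a microRNA alias table
#'
#' TSV with columns `alias, canonical` mapping legacy or database-specific
#' microRNA names to canonical mature names (miRBase Release-21 style, e.g.
#' `miR-204-5p`). Canonical names are made fixed points of the mapping:
#' identity entries are added for every canonical name that does not already
#' appear as an alias. An alias mapping to two different canonicals is an
#' error.
#'
#' @param path path to the TSV file.
#' @return named character vector: `names()` are aliases, values canonical
#'   names.
#' @export
read_alias_table <- function(path) {
  if (!file.exists(path)) stop("alias table not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE)
  if (!all(c("alias", "canonical") %in% names(raw)))
    stop("alias table must have columns `alias` and `canonical`")
  alias_table(stats::setNames(trimws(raw$canonical), trimws(raw$alias)))
}

#' Validate and complete an alias mapping
#'
#' @param mapping named character vector alias -> canonical.
#' @return the validated mapping with identity entries added for canonicals.
#' @export
alias_table <- function(mapping) {
  if (!is.character(mapping) || is.null(names(mapping)))
    stop("`mapping` must be a named character vector")
  dup <- duplicated(names(mapping))
  if (any(dup)) {
    conflicting <- vapply(unique(names(mapping)[dup]), function(a) {
      length(unique(mapping[names(mapping) == a])) > 1L
    }, logical(1))
    if (any(conflicting))
      stop("alias maps to multiple canonical names: ",
           paste(names(conflicting)[conflicting], collapse = ", "))
    mapping <- mapping[!dup]
  }
  need_id <- setdiff(unique(mapping), names(mapping))
  mapping <- c(mapping, stats::setNames(need_id, need_id))
  # canonical names must be fixed points
  canon <- unique(mapping)
  not_fixed <- canon[mapping[canon] != canon]
  if (length(not_fixed))
    stop("canonical name is not a fixed point of the mapping: ",
         paste(not_fixed, collapse = ", "))
  mapping
}

#' Read a two-group expression matrix
#'
#' The matrix file is TSV: first column feature ids, remaining columns one per
#' sample. The group file is TSV with columns `sample_id, group` (two distinct
#' group labels; the first label encountered in the file is taken as group A).
#' Samples present in the matrix but lacking a group label are dropped with a
#' warning.
#'
#' @param matrix_path path to the expression TSV.
#' @param groups_path path to the sample-group TSV.
#' @return an [expression_matrix()] object.
#' @export
read_expression <- function(matrix_path, groups_path) {
  if (!file.exists(matrix_path)) stop("expression matrix not found: ", matrix_path)
  if (!file.exists(groups_path)) stop("group file not found: ", groups_path)
  raw <- read.delim(matrix_path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE)
  if (ncol(raw) < 2L) stop("expression matrix needs >= 1 sample column")
  feats <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cell(s) in expression matrix")
  rownames(vals) <- feats
  g <- read.delim(groups_path, sep = "\t", header = TRUE, quote = "",
                  colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(g)))
    stop("group file must have columns `sample_id` and `group`")
  lab <- stats::setNames(g$group, g$sample_id)
  unlabeled <- setdiff(colnames(vals), names(lab))
  if (length(unlabeled)) {
    warning("dropping ", length(unlabeled), " sample(s) without group label: ",
            paste(unlabeled, collapse = ", "))
    vals <- vals[, setdiff(colnames(vals), unlabeled), drop = FALSE]
  }
  keep <- colnames(vals)
  expression_matrix(vals, factor(lab[keep], levels = unique(g$group)))
}

#' Write a two-group expression matrix
#' @param em an [expression_matrix()] object.
#' @param matrix_path,groups_path output TSV paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(em, matrix_path, groups_path) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(feature_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- data.frame(sample_id = colnames(em$values),
                  group = as.character(em$groups))
  write.table(g, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Read / write an integrated regulatory network
#'
#' Network files are TSV with columns `mirna, gene, n_experimental_lt,
#' predicted_dbs` where `predicted_dbs` is a semicolon-joined list of
#' prediction databases supporting the pair (empty when none).
#'
#' @param path TSV path.
#' @return [regulatory_network()] object.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE,
                    colClasses = c("character", "character", "integer",
                                   "character"))
  if (!all(c("mirna", "gene") %in% names(raw)))
    stop("network file must have columns `mirna` and `gene`")
  if (is.null(raw$n_experimental_lt)) raw$n_experimental_lt <- 0L
  if (is.null(raw$predicted_dbs)) raw$predicted_dbs <- ""
  raw$predicted_dbs[is.na(raw$predicted_dbs)] <- ""
  regulatory_network(raw)
}

#' @rdname read_network
#' @param net a [regulatory_network()] object.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write result tables
#'
#' Differential-expression tables carry columns
#' `feature_id, log2_fc, t_stat, p_raw, p_adj, is_de`; vulnerability score
#' tables carry `mirna, n_targets, nsr, tfp, utp, p_nsr, p_tfp`; candidate
#' trace tables carry `mirna, passed_step1, passed_step2, is_candidate`.
#'
#' @param x result data.frame.
#' @param path TSV path.
#' @return for writers, `path` invisibly; for readers, the data.frame.
#' @export
write_result_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop("result table not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, quote = "", check.names = FALSE)
}
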