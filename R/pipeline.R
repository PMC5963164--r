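# End-to-end orchestration: differential expression on the microRNA and mRNA
# matrices, projection of the reference network, vulnerability scoring, the
# three-step filter, and single-marker evaluation. Each stage writes its TSV
# artifact; a rerun with `resume = TRUE` reloads existing artifacts instead
# of recomputing them.

#' Assemble a pipeline run configuration
#'
#' @param edges character vector of edge-table paths.
#' @param aliases optional alias-table path (NULL to skip normalization).
#' @param tf TF-list path.
#' @param mirna_matrix,mirna_groups microRNA expression matrix / group files.
#' @param mrna_matrix,mrna_groups mRNA expression matrix / group files.
#' @param reported optional path to a reported-biomarker list (one name per
#'   line, `#` comments).
#' @param outdir output directory (created if needed).
#' @param alpha significance level for DE and the filter steps (default 0.05).
#' @param lfc_cut absolute log2 fold-change DE threshold (default 1).
#' @param min_predicted_support prediction-database agreement rule (default 2).
#' @param stat `"moderated"` or `"plain"` t-statistic.
#' @param seed optional integer seed recorded in the manifest.
#' @return a validated `run_config` list.
#' @export
run_config <- function(edges, tf, mirna_matrix, mirna_groups,
                       mrna_matrix, mrna_groups, outdir,
                       aliases = NULL, reported = NULL,
                       alpha = 0.05, lfc_cut = 1.0,
                       min_predicted_support = 2L,
                       stat = c("moderated", "plain"), seed = NULL) {
  stat <- match.arg(stat)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (lfc_cut < 0) stop("lfc_cut must be >= 0")
  cfg <- list(edges = edges, aliases = aliases, tf = tf,
              mirna_matrix = mirna_matrix, mirna_groups = mirna_groups,
              mrna_matrix = mrna_matrix, mrna_groups = mrna_groups,
              reported = reported, outdir = outdir, alpha = alpha,
              lfc_cut = lfc_cut,
              min_predicted_support = as.integer(min_predicted_support),
              stat = stat, seed = seed)
  paths <- c(cfg$edges, cfg$aliases, cfg$tf, cfg$mirna_matrix,
             cfg$mirna_groups, cfg$mrna_matrix, cfg$mrna_groups, cfg$reported)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a flat key = value file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Multiple edge tables are separated by `;` in the `edges` value. Keys match
#' the arguments of [run_config()].
#'
#' @param path config file path.
#' @param overrides named list of values taking precedence over the file
#'   (every config key has a command-line override in the `netvuln` script).
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  cfg <- as.list(stats::setNames(vals, keys))
  cfg[names(overrides)] <- overrides
  num <- intersect(names(cfg), c("alpha", "lfc_cut"))
  cfg[num] <- lapply(cfg[num], as.numeric)
  int <- intersect(names(cfg), c("min_predicted_support", "seed"))
  cfg[int] <- lapply(cfg[int], as.integer)
  if (!is.null(cfg$edges) && is.character(cfg$edges))
    cfg$edges <- trimws(strsplit(cfg$edges, ";", fixed = TRUE)[[1]])
  do.call(run_config, cfg)
}

# Run one pipeline stage with a stage-labelled error message, or reload its
# artifact when resuming.
run_stage <- function(name, outputs, resume, compute, reload) {
  if (resume && all(file.exists(outputs))) {
    message("pipeline: reusing existing output of stage '", name, "'")
    return(reload())
  }
  tryCatch(compute(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

read_reported_list <- function(path) {
  if (is.null(path)) return(character(0))
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]   # miRNA names keep case
}

#' Run the full biomarker-discovery pipeline
#'
#' Stage order: differential expression on the microRNA and mRNA matrices;
#' reference-network assembly (name normalization + evidence integration) and
#' projection onto the DE sets; vulnerability scoring; the three-step filter;
#' candidate evaluation (oriented AUC and precision). Writes `de_mirna.tsv`,
#' `de_mrna.tsv`, `network.tsv`, `scores.tsv`, `candidates.tsv`, `eval.tsv`
#' and `manifest.txt` into `config$outdir`. Any stage error halts the run
#' with a stage-labelled message; artifacts of completed stages are retained.
#'
#' @param config a `run_config` from [run_config()] / [read_run_config()].
#' @param resume reload artifacts of stages whose output files already exist
#'   instead of recomputing them (default FALSE).
#' @return invisibly, a list with the stage results (`de_mirna`, `de_mrna`,
#'   `network`, `scores`, `candidates` trace, `candidate_mirnas`, `eval`,
#'   `precision`).
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  de_mirna <- run_stage("diffexpr-mirna", out("de_mirna.tsv"), resume,
    compute = function() {
      em <- read_expression(config$mirna_matrix, config$mirna_groups)
      de <- run_de(em, alpha = config$alpha, lfc_cut = config$lfc_cut,
                   stat = config$stat)
      write_result_table(de, out("de_mirna.tsv"))
      de
    },
    reload = function() read_result_table(out("de_mirna.tsv")))

  de_mrna <- run_stage("diffexpr-mrna", out("de_mrna.tsv"), resume,
    compute = function() {
      em <- read_expression(config$mrna_matrix, config$mrna_groups)
      de <- run_de(em, alpha = config$alpha, lfc_cut = config$lfc_cut,
                   stat = config$stat)
      write_result_table(de, out("de_mrna.tsv"))
      de
    },
    reload = function() read_result_table(out("de_mrna.tsv")))

  network <- run_stage("network", out("network.tsv"), resume,
    compute = function() {
      recs <- do.call(rbind, lapply(config$edges, read_edge_table))
      if (!is.null(config$aliases))
        recs <- normalize_names(recs, read_alias_table(config$aliases))
      ref <- integrate_reference(recs, config$min_predicted_support)
      de_mirnas <- de_mirna$feature_id[de_mirna$is_de]
      de_genes <- toupper(de_mrna$feature_id[de_mrna$is_de])
      net <- project_condition_network(ref, de_mirnas, de_genes)
      write_network(net, out("network.tsv"))
      net
    },
    reload = function() read_network(out("network.tsv")))

  cand_set <- run_stage("score", c(out("scores.tsv"), out("candidates.tsv")),
    resume = FALSE,
    compute = function() {
      tf_set <- read_tf_list(config$tf)
      cs <- microrna_bd_filter(network, tf_set, alpha = config$alpha)
      write_result_table(cs$scores, out("scores.tsv"))
      write_result_table(candidate_trace(cs), out("candidates.tsv"))
      cs
    },
    reload = function() NULL)

  eval_tab <- run_stage("evaluate", out("eval.tsv"), resume = FALSE,
    compute = function() {
      reported <- read_reported_list(config$reported)
      em <- read_expression(config$mirna_matrix, config$mirna_groups)
      if (length(cand_set$candidates)) {
        ev <- evaluate_candidates(em, cand_set$candidates,
                                  de_table = de_mirna, reported = reported)
      } else {
        ev <- data.frame(mirna = character(), auc_oriented = numeric(),
                         flipped = logical(), in_reported = logical())
        attr(ev, "precision") <- NA_real_
      }
      write_result_table(ev, out("eval.tsv"))
      ev
    },
    reload = function() NULL)

  inputs <- c(config$edges, config$aliases, config$tf, config$mirna_matrix,
              config$mirna_groups, config$mrna_matrix, config$mrna_groups,
              config$reported)
  manifest <- c(
    sprintf("mirvuln_version = %s", as.character(packageVersion("mirvuln"))),
    sprintf("r_version = %s", R.version.string),
    sprintf("timestamp = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed = %s", config$seed %||% "unset"),
    sprintf("alpha = %g", config$alpha),
    sprintf("lfc_cut = %g", config$lfc_cut),
    sprintf("min_predicted_support = %d", config$min_predicted_support),
    sprintf("stat = %s", config$stat),
    sprintf("input %s md5 = %s", inputs, md5sum(inputs))
  )
  writeLines(manifest, out("manifest.txt"))

  invisible(list(
    de_mirna = de_mirna, de_mrna = de_mrna, network = network,
    scores = cand_set$scores, candidates = candidate_trace(cand_set),
    candidate_mirnas = cand_set$candidates, eval = eval_tab,
    precision = attr(eval_tab, "precision")
  ))
}
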