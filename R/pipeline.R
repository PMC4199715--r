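#' Assemble and validate a pipeline configuration
#'
#' Collects every tunable pipeline parameter, each defaulting to the
#' package's reference value (hub penalty `alpha = 15`, group-size penalty
#' `beta = 20`, DE threshold 0.05, clustering cut `d = 0.5`, kernel
#' `gamma = 1` with 5 iterations). Inputs may be given as file paths or as
#' already-constructed objects; `known` and `candidates` may be character
#' vectors or paths to one-symbol-per-line files.
#'
#' @param ppi a `ppi_network` or path to an edge-list file.
#' @param expr an `expr_data` or path to an expression TSV.
#' @param labels path to the sample-label TSV (required when `expr` is a
#'   path).
#' @param known known disease genes (vector or path); optional, enables
#'   evaluation.
#' @param candidates candidate genes (vector or path); default: all
#'   network nodes.
#' @param d clustering distance threshold in `[0, 1]`. Default 0.5.
#' @param gamma,n_iter diffusion-kernel parameters.
#' @param alpha,beta penalization parameters.
#' @param de_alpha DE significance threshold (corrected p). Default 0.05.
#' @param penalty `"cap"` or `"exp"` (see [grouprank_params()]).
#' @param distance_mode `"signed"` or `"abs"` (see
#'   [correlation_distance()]).
#' @param linkage hierarchical-clustering linkage. Default `"average"`.
#' @param linear expression values are linear-scale (see [log2_ratio()]).
#' @param drop_singletons discard singleton groups.
#' @param seed seed recorded for seeded downstream steps.
#' @return A `grouprank_config` list.
#' @export
grouprank_config <- function(ppi, expr, labels = NULL, known = NULL,
                             candidates = NULL, d = 0.5, gamma = 1,
                             n_iter = 5, alpha = 15, beta = 20,
                             de_alpha = 0.05, penalty = "cap",
                             distance_mode = "signed", linkage = "average",
                             linear = FALSE, drop_singletons = FALSE,
                             seed = NULL) {
  if (!is.numeric(d) || d < 0 || d > 1) stop("d must be in [0, 1]")
  if (!is.numeric(de_alpha) || de_alpha <= 0 || de_alpha > 1) {
    stop("de_alpha must be in (0, 1]")
  }
  structure(list(ppi = ppi, expr = expr, labels = labels, known = known,
                 candidates = candidates, d = d, gamma = gamma,
                 n_iter = n_iter, alpha = alpha, beta = beta,
                 de_alpha = de_alpha, penalty = penalty,
                 distance_mode = distance_mode, linkage = linkage,
                 linear = linear, drop_singletons = drop_singletons,
                 seed = seed),
            class = "grouprank_config")
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key value`), `#` comments allowed.
#' Values are coerced to numeric or logical where possible. Keys mirror the
#' arguments of [grouprank_config()] one to one; arguments passed directly
#' to this function override the file.
#'
#' @param path configuration file path.
#' @param ... overrides forwarded to [grouprank_config()].
#' @return A `grouprank_config`.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=?\\s*(.*)$",
                                  lines))
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3L])
    v <- gsub('^"|"$', "", v)
    if (grepl("^-?[0-9.eE+]+$", v) && !is.na(suppressWarnings(as.numeric(v)))) {
      as.numeric(v)
    } else if (toupper(v) %in% c("TRUE", "FALSE")) {
      as.logical(toupper(v))
    } else v
  })
  names(vals) <- vapply(kv, `[`, character(1L), 2L)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  allowed <- names(formals(grouprank_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(grouprank_config, vals)
}

read_gene_list <- function(x) {
  if (is.null(x) || !is.character(x)) return(x)
  if (length(x) == 1L && file.exists(x)) {
    lines <- trimws(readLines(x))
    lines[nzchar(lines) & !grepl("^#", lines)]
  } else x
}

#' Run the full prioritization pipeline
#'
#' Executes the stages in order — load, differential expression,
#' co-expression grouping, diffusion kernel, group scoring/ranking, and
#' (when known genes are supplied) evaluation — logging counts at each
#' stage. DE genes absent from the network are excluded before grouping
#' (the kernel is defined only on network nodes) and reported. Stage
#' failures abort with the stage name and a remediation hint.
#'
#' @param config a `grouprank_config`.
#' @param quiet suppress stage log messages.
#' @return A `grouprank_result` list: `network`, `expression`, `de`,
#'   `de_genes_off_network`,
#'   `groups`, `kernel`, `ranking` (a `ranking_result`), `evaluation`
#'   (list with `mrr`, `rank_ratios`, `excluded_known`, `roc` when known
#'   genes were given), `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stage <- function(name, hint, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (", hint, ")", call. = FALSE)
    })
  }
  say <- function(...) if (!quiet) message(sprintf(...))

  net <- stage("load_network", "check the --ppi edge-list path", {
    if (inherits(config$ppi, "ppi_network")) config$ppi
    else load_ppi(config$ppi, quiet = quiet)
  })
  expr <- stage("load_expression", "check the --expr/--labels paths", {
    if (inherits(config$expr, "expr_data")) config$expr
    else {
      if (is.null(config$labels)) stop("labels path is required")
      load_expression(config$expr, config$labels, quiet = quiet)
    }
  })
  say("pipeline: %d network nodes, %d genes x %d samples",
      length(net$nodes), nrow(expr$values), ncol(expr$values))

  de <- stage("differential_expression", "check class labels and sample counts",
              de_test(expr, alpha = config$de_alpha, linear = config$linear))
  de_genes <- de$gene[de$de]
  off_net <- setdiff(de_genes, net$nodes)
  de_in <- sort(intersect(de_genes, net$nodes))
  say("pipeline: %d DE genes at corrected p < %g (%d off-network excluded)",
      length(de_genes), config$de_alpha, length(off_net))

  groups <- stage("gene_grouping", "check d and the expression values", {
    if (length(de_in) >= 2L) {
      dist_mat <- correlation_distance(expr, de_in,
                                       mode = config$distance_mode)
      cluster_groups(dist_mat, config$d, de, linkage = config$linkage,
                     drop_singletons = config$drop_singletons)
    } else if (length(de_in) == 1L) {
      structure(list(gene_group(de_in, de, id = "G1")),
                class = "gene_groups", d = config$d,
                linkage = config$linkage)
    } else {
      structure(list(), class = "gene_groups", d = config$d,
                linkage = config$linkage)
    }
  })
  say("pipeline: %d group(s) at d = %g", length(groups), config$d)

  kernel <- stage("diffusion_kernel", "check gamma and n_iter",
                  diffusion_kernel(transition_matrix(net),
                                   gamma = config$gamma,
                                   n_iter = config$n_iter))

  params <- grouprank_params(alpha = config$alpha, beta = config$beta,
                             gamma = config$gamma, n_iter = config$n_iter,
                             penalty = config$penalty)
  candidates <- read_gene_list(config$candidates) %||% net$nodes
  ranking <- stage("ranking", "check the candidate list",
                   rank_candidates(candidates, groups, kernel, de, net,
                                   params))
  say("pipeline: ranked %d candidate(s); %d off-network",
      ranking$n_candidates, length(ranking$unranked))

  evaluation <- NULL
  known <- read_gene_list(config$known)
  if (!is.null(known) && length(known)) {
    evaluation <- stage("evaluation", "check the known-gene list", {
      mrr <- mean_rank_ratio(ranking, known)
      list(mrr = as.numeric(mrr),
           rank_ratios = attr(mrr, "rank_ratios"),
           excluded_known = attr(mrr, "excluded"),
           roc = roc_auc(ranking, known))
    })
    say("pipeline: MRR = %.4f, AUC = %.4f over %d known gene(s)",
        evaluation$mrr, evaluation$roc$auc, length(evaluation$rank_ratios))
  }

  structure(list(network = net, expression = expr, de = de,
                 de_genes_off_network = off_net,
                 groups = groups, kernel = kernel, ranking = ranking,
                 evaluation = evaluation, config = config),
            class = "grouprank_result")
}

#' @export
print.grouprank_result <- function(x, ...) {
  cat(sprintf("grouprank result: %d groups at d = %g, %d candidates ranked\n",
              length(x$groups), x$config$d, x$ranking$n_candidates))
  if (!is.null(x$evaluation)) {
    cat(sprintf("  MRR = %.4f, AUC = %.4f\n", x$evaluation$mrr,
                x$evaluation$roc$auc))
  }
  invisible(x)
}

#' Write a ranking table to TSV
#'
#' Columns: gene, score, rank, rank_ratio, top_group, top_contrib. A
#' schema-versioned header comment makes the format self-identifying;
#' writing is deterministic for identical rankings.
#'
#' @param ranking a `ranking_result`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# grouprank ranking schema v1", con)
  write.table(ranking$ranking, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a threshold-sweep curve to TSV
#'
#' @param sweep a `sweep_result`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sweep <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# grouprank sweep schema v1",
               sprintf("# d_opt\t%g", sweep$d_opt),
               sprintf("# mrr_opt\t%.15g", sweep$mrr_opt)), con)
  write.table(sweep$curve, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
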