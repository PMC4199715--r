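#' Pairwise correlation distance between genes
#'
#' Computes Pearson correlation `r` between gene expression profiles over
#' all samples and maps it to a distance in `[0, 1]`. The default (signed)
#' mapping is `d = (1 - r) / 2`, so perfectly correlated genes are at
#' distance 0 and perfectly anti-correlated genes at distance 1; the
#' alternative `"abs"` mode uses `d = 1 - |r|`, which treats strong
#' anti-correlation as proximity. Genes with zero expression variance have
#' an undefined correlation and are placed at maximal distance (1) from
#' every partner, with a warning.
#'
#' @param expr an `expr_data` object.
#' @param genes genes to include (default: all genes in `expr`). At least
#'   two genes and three samples are required.
#' @param mode `"signed"` (default) or `"abs"`.
#' @return Symmetric distance matrix with zero diagonal, entries in `[0, 1]`.
#' @export
correlation_distance <- function(expr, genes = NULL, mode = c("signed", "abs")) {
  mode <- match.arg(mode)
  genes <- genes %||% rownames(expr$values)
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing)) stop("genes absent from expression matrix: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  if (length(genes) < 2L) stop("need at least two genes")
  X <- expr$values[genes, , drop = FALSE]
  if (ncol(X) < 3L) stop("need at least three samples per gene")
  zero_var <- apply(X, 1L, sd) == 0
  r <- suppressWarnings(cor(t(X)))
  d <- if (mode == "signed") (1 - r) / 2 else 1 - abs(r)
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance gene(s); assigned maximal distance")
    d[zero_var, ] <- 1
    d[, zero_var] <- 1
  }
  d[is.na(d)] <- 1
  d <- pmin(pmax(d, 0), 1)  # clip float dust outside [0, 1]
  diag(d) <- 0
  d[lower.tri(d)] <- t(d)[lower.tri(d)]  # enforce exact symmetry
  d
}

#' Construct a co-expressed gene group
#'
#' @param members character vector of gene symbols (non-empty).
#' @param de a `de_result` providing the per-gene log2 ratios from which the
#'   group expression level `e` is computed.
#' @param id optional group identifier.
#' @return A `gene_group`: `id`, `members`, `n` (group size), `e`
#'   (geometric mean of member |log2 ratio|), `sign` (majority direction of
#'   regulation, recorded as metadata).
#' @export
gene_group <- function(members, de, id = NA_character_) {
  if (length(members) == 0L) stop("empty group")
  lfc <- de$log2_ratio[match(members, de$gene)]
  if (anyNA(lfc)) stop("group member(s) without a log2 ratio: ",
                       paste(members[is.na(lfc)], collapse = ", "))
  structure(list(id = id, members = members, n = length(members),
                 e = geo_mean_floored(abs(lfc)),
                 sign = sign(sum(sign(lfc)))),
            class = "gene_group")
}

#' @export
print.gene_group <- function(x, ...) {
  cat(sprintf("gene group %s: n = %d, e = %.4g [%s]\n", x$id, x$n, x$e,
              paste(utils::head(x$members, 6L), collapse = ", ")))
  invisible(x)
}

#' Partition DE genes into co-expressed groups by hierarchical clustering
#'
#' Clusters genes agglomeratively (average linkage by default) on a
#' correlation distance matrix and cuts the tree at height `d`: gene pairs
#' whose cluster distance exceeds `d` end up in different groups. At
#' `d = 0` every gene is its own group (when all pairwise distances are
#' positive); larger `d` merges groups monotonically. Genes are put into a
#' fixed lexicographic order before clustering so the partition does not
#' depend on input order.
#'
#' @param dist_mat symmetric distance matrix from [correlation_distance()].
#' @param d cut height (distance threshold) in `[0, 1]`.
#' @param de a `de_result`; each cluster's expression level `e` is the
#'   geometric mean of its members' absolute log2 ratios.
#' @param linkage agglomeration method for [stats::hclust()].
#' @param drop_singletons discard groups of size 1 (default keeps them; the
#'   group-size penalty handles them naturally).
#' @return A `gene_groups` list of [gene_group()] objects; attributes `d`
#'   and `linkage` record the cut.
#' @export
cluster_groups <- function(dist_mat, d, de, linkage = "average",
                           drop_singletons = FALSE) {
  if (!is.numeric(d) || length(d) != 1L || d < 0 || d > 1) {
    stop("d must be a single value in [0, 1]")
  }
  genes <- rownames(dist_mat)
  if (is.null(genes)) stop("distance matrix must have gene row names")
  ord <- order(genes)  # canonical order: result invariant to input order
  genes <- genes[ord]
  if (length(genes) == 1L) {
    cl <- setNames(1L, genes)
  } else {
    hc <- hclust(as.dist(dist_mat[ord, ord, drop = FALSE]), method = linkage)
    cl <- cutree(hc, h = d)
  }
  ids <- sort(unique(cl))
  groups <- lapply(seq_along(ids), function(i) {
    gene_group(genes[cl == ids[i]], de, id = sprintf("G%d", i))
  })
  if (drop_singletons) {
    groups <- Filter(function(g) g$n > 1L, groups)
  }
  structure(groups, class = "gene_groups", d = d, linkage = linkage)
}

#' @export
print.gene_groups <- function(x, ...) {
  sizes <- vapply(x, `[[`, numeric(1L), "n")
  cat(sprintf("%d gene group(s) at d = %g (sizes: %s)\n", length(x),
              attr(x, "d"),
              paste(utils::head(sort(sizes, decreasing = TRUE), 10L),
                    collapse = ", ")))
  invisible(x)
}

#' Tabulate gene groups
#'
#' @param groups a `gene_groups` list.
#' @return Data frame with one row per group: `id`, `n`, `e`, `members`
#'   (comma-separated).
#' @export
groups_table <- function(groups) {
  data.frame(
    id = vapply(groups, `[[`, character(1L), "id"),
    n = vapply(groups, `[[`, numeric(1L), "n"),
    e = vapply(groups, `[[`, numeric(1L), "e"),
    members = vapply(groups, function(g) paste(g$members, collapse = ","),
                     character(1L)),
    stringsAsFactors = FALSE)
}
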