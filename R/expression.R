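#' Construct an expression data set
#'
#' @param values genes x samples numeric matrix with gene symbols as row
#'   names and sample IDs as column names. Values are assumed to be on the
#'   log2 scale unless stated otherwise downstream.
#' @param labels character vector of sample classes, `"case"` or
#'   `"control"`, named by sample ID (or in column order of `values`).
#' @return An `expr_data` object (`values`, `labels`).
#' @export
expr_data <- function(values, labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("values must have gene symbols as row names")
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols; collapse first")
  if (is.null(names(labels))) {
    if (length(labels) != ncol(values)) stop("labels length must match sample count")
    names(labels) <- colnames(values)
  }
  labels <- labels[colnames(values)]
  if (anyNA(labels)) stop("labels missing for samples: ",
                          paste(colnames(values)[is.na(labels)], collapse = ", "))
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "),
                        " (expected 'case' / 'control')")
  counts <- table(factor(labels, levels = c("case", "control")))
  if (any(counts < 2L)) stop("need at least 2 samples per class (have ",
                             counts[["case"]], " case, ",
                             counts[["control"]], " control)")
  structure(list(values = values, labels = labels), class = "expr_data")
}

#' Load an expression matrix and its case/control sample labels
#'
#' The matrix file is a TSV with a gene-symbol first column and sample IDs
#' in the header; the labels file is a two-column TSV mapping each sample
#' ID to `case` or `control` (a header line is tolerated). Duplicate gene
#' rows are collapsed by their mean, keeping symbols unique for network
#' matching. The matrix is restricted to (and ordered by) its own samples;
#' every matrix sample must appear in the labels file.
#'
#' @param matrix_path path to the expression TSV.
#' @param labels_path path to the sample-label TSV.
#' @param quiet suppress the load summary message.
#' @return An `expr_data` object.
#' @export
load_expression <- function(matrix_path, labels_path, quiet = FALSE) {
  tab <- read.delim(matrix_path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("expression matrix needs a gene column plus >=2 samples")
  genes <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  ndup <- sum(duplicated(genes))
  if (ndup > 0L) {
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(vals) <- genes

  lab <- read.delim(labels_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(lab) < 2L) stop("labels file must have two columns: sample, class")
  # tolerate a header line
  if (nrow(lab) > 0L && !(lab[1L, 2L] %in% c("case", "control")) &&
      !(lab[1L, 1L] %in% colnames(vals))) {
    lab <- lab[-1L, , drop = FALSE]
  }
  labels <- setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
  missing <- setdiff(colnames(vals), names(labels))
  if (length(missing)) {
    stop("samples missing from labels file: ", paste(missing, collapse = ", "))
  }
  out <- expr_data(vals, labels[colnames(vals)])
  if (!quiet) {
    message(sprintf(
      "loaded expression: %d genes x %d samples (%d case / %d control; %d duplicate gene rows collapsed)",
      nrow(vals), ncol(vals), sum(out$labels == "case"),
      sum(out$labels == "control"), ndup))
  }
  out
}

#' @export
print.expr_data <- function(x, ...) {
  cat(sprintf("expression data: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' Per-gene log2 case/control expression ratio
#'
#' With log2-scale data (the default assumption) the ratio is the
#' difference of class means; with `linear = TRUE` it is
#' `log2(mean(case) / mean(control))` on the raw scale.
#'
#' @param expr an `expr_data` object.
#' @param linear treat values as linear-scale intensities.
#' @return Named numeric vector of per-gene log2 ratios (case over control).
#' @export
log2_ratio <- function(expr, linear = FALSE) {
  case <- expr$values[, expr$labels == "case", drop = FALSE]
  ctrl <- expr$values[, expr$labels == "control", drop = FALSE]
  mc <- rowMeans(case)
  m0 <- rowMeans(ctrl)
  if (linear) {
    if (any(mc <= 0) || any(m0 <= 0)) {
      stop("linear mode requires positive class means for every gene")
    }
    log2(mc / m0)
  } else {
    mc - m0
  }
}

#' Differential-expression test (Student t with Bonferroni correction)
#'
#' Runs a two-sample, two-sided Student t-test per gene (pooled variance by
#' default; `var_equal = FALSE` switches to Welch), corrects the p-values by
#' Bonferroni over the number of genes tested, and flags genes with
#' corrected p strictly below `alpha` as differentially expressed. Genes
#' with zero variance in both classes have no defined t statistic and are
#' assigned p = 1 (never DE), with a warning.
#'
#' @param expr an `expr_data` object with >=2 samples per class.
#' @param alpha significance threshold on the corrected p-value. Default 0.05.
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @param linear passed to [log2_ratio()].
#' @return A `de_result` data frame: `gene`, `t`, `p_value`, `p_adj`
#'   (Bonferroni), `log2_ratio`, `de` (logical flag).
#' @export
de_test <- function(expr, alpha = 0.05, var_equal = TRUE, linear = FALSE) {
  case <- expr$values[, expr$labels == "case", drop = FALSE]
  ctrl <- expr$values[, expr$labels == "control", drop = FALSE]
  nx <- ncol(case)
  ny <- ncol(ctrl)
  mx <- rowMeans(case)
  my <- rowMeans(ctrl)
  vx <- apply(case, 1L, stats::var)
  vy <- apply(ctrl, 1L, stats::var)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, length(se))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mx - my) / se
  p <- 2 * pt(-abs(tstat), df)
  degen <- !is.finite(tstat)  # zero pooled variance
  if (any(degen)) {
    warning(sum(degen), " gene(s) with zero variance in both classes; ",
            "t undefined, p set to 1")
    tstat[degen] <- NA_real_
    p[degen] <- 1
  }
  p_adj <- p.adjust(p, method = "bonferroni")
  res <- data.frame(gene = rownames(expr$values),
                    t = unname(tstat),
                    p_value = unname(p),
                    p_adj = unname(p_adj),
                    log2_ratio = unname(log2_ratio(expr, linear = linear)),
                    de = unname(p_adj < alpha),
                    stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  attr(res, "alpha") <- alpha
  res
}
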