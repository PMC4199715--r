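#' Construct a PPI network object from an edge list
#'
#' Internal constructor shared by [load_ppi()] and [make_network()].
#' Expects edges already deduplicated (as unordered pairs) and free of
#' self-loops.
#'
#' @param edges two-column character matrix of gene-symbol pairs.
#' @param nodes optional node order; defaults to first appearance in `edges`.
#' @return A `ppi_network` object: `nodes` (ordered symbols), `edges`
#'   (two-column matrix), `adjacency` (sparse symmetric 0/1 matrix with zero
#'   diagonal) and `degree` (named numeric, the row sums of the adjacency).
#' @keywords internal
new_ppi_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  if (is.null(nodes)) nodes <- unique(as.vector(t(edges)))
  if (nrow(edges) == 0L || length(nodes) == 0L) stop("empty network")
  n <- length(nodes)
  i <- match(edges[, 1L], nodes)
  j <- match(edges[, 2L], nodes)
  if (anyNA(i) || anyNA(j)) stop("edge references a symbol missing from nodes")
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n), dimnames = list(nodes, nodes))
  A@x[A@x > 0] <- 1  # guard against accidental double counting
  deg <- setNames(Matrix::rowSums(A), nodes)
  structure(list(nodes = nodes, edges = unname(edges),
                 adjacency = A, degree = deg),
            class = "ppi_network")
}

#' Load a protein-protein interaction network from an edge-list file
#'
#' Reads a flat two-column edge list (HINT-style: one interaction per line,
#' whitespace- or tab-separated gene symbols; extra columns ignored).
#' Comment lines starting with `#` are skipped and a single header line is
#' dropped when either of its first two tokens matches `header_keywords`
#' (case-insensitive). Duplicate edges — `(a,b)` and `(b,a)` count as the
#' same interaction — and self-loops are removed. Node order is first
#' appearance in the retained edges.
#'
#' @param path path to the edge-list file.
#' @param header_keywords tokens that mark a header line.
#' @param quiet suppress the load summary message.
#' @return A `ppi_network` object (see [new_ppi_network()] for fields).
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("A B", "B C", "C A"), tf)
#' net <- load_ppi(tf, quiet = TRUE)
#' net$degree
load_ppi <- function(path,
                     header_keywords = c("gene", "gene_a", "gene_b", "genea",
                                         "geneb", "protein", "node", "source",
                                         "target", "from", "to", "symbol",
                                         "id_a", "id_b"),
                     quiet = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty network: no edges found in '", path, "'")
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) {
    stop("malformed edge line ", lineno[bad[1L]], " in '", path,
         "': expected at least two columns")
  }
  a <- vapply(toks, `[[`, character(1L), 1L)
  b <- vapply(toks, `[[`, character(1L), 2L)
  if (any(tolower(c(a[1L], b[1L])) %in% tolower(header_keywords))) {
    a <- a[-1L]
    b <- b[-1L]
  }
  loops <- a == b
  a2 <- a[!loops]
  b2 <- b[!loops]
  if (length(a2) == 0L) stop("empty network: no valid edges in '", path, "'")
  key <- paste(pmin(a2, b2), pmax(a2, b2), sep = "\r")
  dup <- duplicated(key)
  net <- new_ppi_network(cbind(a2[!dup], b2[!dup]))
  if (!quiet) {
    message(sprintf(
      "loaded PPI network: %d nodes, %d edges (%d duplicate edges and %d self-loops dropped)",
      length(net$nodes), nrow(net$edges), sum(dup), sum(loops)))
  }
  net
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d nodes, %d edges, mean degree %.2f\n",
              length(x$nodes), nrow(x$edges), mean(x$degree)))
  invisible(x)
}
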