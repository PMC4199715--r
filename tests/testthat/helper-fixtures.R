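# Shared in-code fixtures for the test suite.

# Tiny network from an explicit edge list (character pairs).
toy_net <- function(...) {
  pairs <- list(...)
  new_ppi_network(do.call(rbind, pairs))
}

# Write an edge list to a temp file and return its path.
edge_file <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# Small expression set: genes x samples matrix with n_case/n_control labels.
toy_expr <- function(values, n_case, n_control) {
  colnames(values) <- c(sprintf("c%02d", seq_len(n_case)),
                        sprintf("n%02d", seq_len(n_control)))
  expr_data(values, setNames(rep(c("case", "control"),
                                 c(n_case, n_control)), colnames(values)))
}

# Random expression matrix under the global null (no DE, no structure).
null_expr <- function(n_genes, n_case = 10L, n_control = 10L,
                      gene_names = sprintf("g%03d", seq_len(n_genes))) {
  m <- matrix(rnorm(n_genes * (n_case + n_control)), nrow = n_genes,
              dimnames = list(gene_names, NULL))
  toy_expr(m, n_case, n_control)
}

# Naive repeated-multiplication oracle for the diffusion kernel:
# (I + (gamma/N)(W - I))^N by plain left-to-right products.
naive_kernel <- function(W, gamma, n_iter) {
  W <- as.matrix(W)
  n <- nrow(W)
  M <- diag(n) + (gamma / n_iter) * (W - diag(n))
  S <- diag(n)
  for (i in seq_len(n_iter)) S <- S %*% M
  dimnames(S) <- dimnames(W)
  S
}

# Brute-force all-pairs AUC oracle with half-credit for ties.
allpairs_auc <- function(scores, is_pos) {
  ps <- scores[is_pos]
  ns <- scores[!is_pos]
  tot <- 0
  for (p in ps) tot <- tot + sum(p > ns) + 0.5 * sum(p == ns)
  tot / (length(ps) * length(ns))
}

# Expression matrix with two planted correlated blocks (no class effect
# needed): block genes share a latent factor at correlation ~rho.
block_expr <- function(block_sizes, rho, n_samples = 50L, sd = 1) {
  genes <- sprintf("b%d_%02d", rep(seq_along(block_sizes), block_sizes),
                   unlist(lapply(block_sizes, seq_len)))
  X <- matrix(NA_real_, length(genes), n_samples,
              dimnames = list(genes, sprintf("s%02d", seq_len(n_samples))))
  row <- 1L
  for (b in seq_along(block_sizes)) {
    z <- rnorm(n_samples)
    for (i in seq_len(block_sizes[b])) {
      X[row, ] <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n_samples)
      row <- row + 1L
    }
  }
  X * sd
}
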