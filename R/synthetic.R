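#' Generate a synthetic PPI-like network
#'
#' Random undirected graph with heavy-tailed degrees, standing in for a
#' curated PPI network. The default preferential-attachment model gives a
#' connected scale-free-ish graph; the configuration model draws a
#' power-law degree sequence and keeps the largest connected component if
#' the result is disconnected (logged). Deterministic for a fixed seed.
#'
#' @param n_nodes number of genes (>= 10).
#' @param model `"pa"` (preferential attachment, default) or
#'   `"configuration"`.
#' @param seed RNG seed.
#' @param m edges added per step under preferential attachment; the mean
#'   degree is about `2 * m`. Default 3, giving a mean degree near that of
#'   curated human PPI networks (about 7).
#' @param exponent degree-distribution exponent for the configuration
#'   model. Default 2.5.
#' @return A `ppi_network` with nodes named `g001`, `g002`, ...
#' @export
make_network <- function(n_nodes, model = c("pa", "configuration"),
                         seed = NULL, m = 3, exponent = 2.5) {
  model <- match.arg(model)
  if (n_nodes < 10L) stop("n_nodes must be >= 10")
  g <- with_seed(seed, {
    if (model == "pa") {
      igraph::sample_pa(n_nodes, power = 1, m = m, directed = FALSE)
    } else {
      ks <- 2:min(n_nodes - 1L, 100L)
      deg <- sample(ks, n_nodes, replace = TRUE, prob = ks^(-exponent))
      if (sum(deg) %% 2L == 1L) deg[1L] <- deg[1L] + 1L
      igraph::simplify(igraph::sample_degseq(deg, method = "configuration"))
    }
  })
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    g <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize)))
    message("configuration model disconnected; kept largest component (",
            igraph::vcount(g), " of ", n_nodes, " nodes)")
  }
  width <- nchar(as.character(n_nodes))
  igraph::V(g)$name <- sprintf(paste0("g%0", width, "d"),
                               seq_len(igraph::vcount(g)))
  new_ppi_network(igraph::as_edgelist(g), nodes = igraph::V(g)$name)
}

#' Plant disease genes with adjacent co-expressed modules
#'
#' Picks `n_disease_genes` mid-degree nodes (degree above the network
#' median but at most `degree_cap`, so the planted genes are neither
#' periphery nor heavily penalized hubs) and assigns each a module of
#' `module_size` genes sampled from its `hop_radius`-neighborhood,
#' excluding the disease gene itself. The disease gene therefore need not
#' be differentially expressed: the recoverable signal is purely its
#' network proximity to a coordinately DE module. Modules are disjoint
#' across disease genes when `disjoint = TRUE`.
#'
#' @param net a `ppi_network`.
#' @param n_disease_genes number of planted disease genes. Default 3.
#' @param module_size genes per planted module. Default 8.
#' @param hop_radius neighborhood radius for module membership. Default 1
#'   (direct neighbors).
#' @param degree_cap upper degree bound for eligible disease genes.
#'   Default 15, matching the default hub-penalty cap so planted genes are
#'   unpenalized.
#' @param disjoint forbid sharing module members across disease genes.
#' @param seed RNG seed.
#' @return A `planted_truth` list: `disease_genes`, `modules` (named list
#'   of member vectors), `module_signs` (direction of regulation, ±1),
#'   `hop_radius`.
#' @export
plant_modules <- function(net, n_disease_genes = 3L, module_size = 8L,
                          hop_radius = 1L, degree_cap = 15,
                          disjoint = TRUE, seed = NULL) {
  deg <- net$degree
  med <- median(deg)
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  missing_nodes <- setdiff(net$nodes, igraph::V(g)$name)
  if (length(missing_nodes)) g <- igraph::add_vertices(g, length(missing_nodes),
                                                       name = missing_nodes)
  nb_all <- igraph::ego(g, order = hop_radius, nodes = net$nodes,
                        mindist = 1L)
  names(nb_all) <- net$nodes
  eligible <- net$nodes[deg > med & deg <= degree_cap &
                          lengths(nb_all) >= module_size]
  if (length(eligible) < n_disease_genes) {
    stop("only ", length(eligible), " eligible mid-degree node(s) with a ",
         "large enough neighborhood; try a smaller module_size or a larger ",
         "hop_radius")
  }
  with_seed(seed, {
    order_try <- sample(eligible)
    disease <- character(0L)
    modules <- list()
    used <- character(0L)
    for (v in order_try) {
      if (length(disease) == n_disease_genes) break
      if (v %in% used) next  # already a member of a planted module
      avoid <- if (disjoint) used else character(0L)
      nb <- setdiff(igraph::V(g)$name[nb_all[[v]]], c(disease, avoid, v))
      if (length(nb) < module_size) next
      members <- sample(nb, module_size)
      disease <- c(disease, v)
      modules[[v]] <- members
      if (disjoint) used <- c(used, members)
    }
    if (length(disease) < n_disease_genes) {
      stop("could not place ", n_disease_genes, " disjoint modules; ",
           "try a smaller module_size or n_disease_genes")
    }
    signs <- sample(c(-1, 1), n_disease_genes, replace = TRUE)
    structure(list(disease_genes = disease, modules = modules,
                   module_signs = setNames(signs, disease),
                   hop_radius = hop_radius),
              class = "planted_truth")
  })
}

#' Simulate an expression matrix with planted co-expressed DE modules
#'
#' Background genes are independent Gaussians with the same mean in both
#' classes. Each planted module shares a per-sample latent factor so that
#' the within-module pairwise Pearson correlation is approximately `rho`
#' (equicorrelation), and its members receive a class-mean shift of
#' `effect * noise_sd` in cases, signed per module. Values emulate
#' log2-scale intensities around `baseline`. Planted disease genes get
#' background expression by default — the ranking signal is their network
#' adjacency to the module, not their own expression — unless
#' `de_disease_genes = TRUE`.
#'
#' @param net a `ppi_network`; one expression row is generated per node.
#' @param truth a `planted_truth` from [plant_modules()].
#' @param n_case,n_control samples per class (>= 3 each). Defaults 10.
#' @param effect class-mean shift of module genes, in units of `noise_sd`.
#'   Default 2.
#' @param rho target within-module pairwise correlation, in `[0, 1)`.
#'   Default 0.85. (Correlation over all samples also picks up the shared
#'   class shift; the target is recovered exactly within classes.)
#' @param noise_sd per-gene expression SD. Default 1.
#' @param baseline mean log2 intensity. Default 7.
#' @param de_disease_genes give the disease genes themselves the module
#'   class shift.
#' @param seed RNG seed.
#' @return An `expr_data` with samples `c01..` (cases) and `n01..`
#'   (controls).
#' @export
simulate_expression <- function(net, truth, n_case = 10L, n_control = 10L,
                                effect = 2, rho = 0.85, noise_sd = 1,
                                baseline = 7, de_disease_genes = FALSE,
                                seed = NULL) {
  if (n_case < 3L || n_control < 3L) stop("need >= 3 samples per class")
  if (!is.numeric(rho) || rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  genes <- net$nodes
  ns <- n_case + n_control
  is_case <- c(rep(1, n_case), rep(0, n_control))
  samples <- c(sprintf("c%02d", seq_len(n_case)),
               sprintf("n%02d", seq_len(n_control)))
  with_seed(seed, {
    X <- matrix(rnorm(length(genes) * ns, mean = baseline, sd = noise_sd),
                nrow = length(genes), ncol = ns,
                dimnames = list(genes, samples))
    for (v in names(truth$modules)) {
      members <- truth$modules[[v]]
      sgn <- truth$module_signs[[v]]
      z <- rnorm(ns)
      shift <- effect * noise_sd * sgn * is_case
      for (gmem in members) {
        X[gmem, ] <- baseline +
          noise_sd * (sqrt(rho) * z + sqrt(1 - rho) * rnorm(ns)) + shift
      }
      if (de_disease_genes) X[v, ] <- X[v, ] + shift
    }
    expr_data(X, setNames(ifelse(is_case == 1, "case", "control"), samples))
  })
}

#' Generate a complete synthetic benchmark instance
#'
#' Bundles [make_network()], [plant_modules()] and [simulate_expression()]
#' under one master seed (fanned out to independent per-stage seeds). The
#' defaults define the reference benchmark condition used throughout the
#' package's tests: a 200-node preferential-attachment network, 3 planted
#' disease genes with disjoint direct-neighbor modules of 8 genes,
#' class-mean shift 2 SD, within-module correlation 0.85, and 10 + 10
#' samples.
#'
#' @inheritParams make_network
#' @inheritParams plant_modules
#' @inheritParams simulate_expression
#' @param seed master seed.
#' @return A `synthetic_instance` list: `network`, `expression`, `truth`
#'   (with `effect` and `rho` recorded), `seed`.
#' @export
make_instance <- function(n_nodes = 200L, n_disease_genes = 3L,
                          module_size = 8L, hop_radius = 1L,
                          n_case = 10L, n_control = 10L,
                          effect = 2, rho = 0.85, noise_sd = 1,
                          model = "pa", m = 3, de_disease_genes = FALSE,
                          seed = NULL) {
  seeds <- child_seeds(seed, 3L)
  net <- make_network(n_nodes, model = model, seed = seeds[[1L]], m = m)
  truth <- plant_modules(net, n_disease_genes = n_disease_genes,
                         module_size = module_size, hop_radius = hop_radius,
                         seed = seeds[[2L]])
  expr <- simulate_expression(net, truth, n_case = n_case,
                              n_control = n_control, effect = effect,
                              rho = rho, noise_sd = noise_sd,
                              de_disease_genes = de_disease_genes,
                              seed = seeds[[3L]])
  truth$effect <- effect
  truth$rho <- rho
  structure(list(network = net, expression = expr, truth = truth,
                 seed = seed),
            class = "synthetic_instance")
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf(
    "synthetic instance: %d-node network, %d disease gene(s), module size %d, effect %g, rho %g\n",
    length(x$network$nodes), length(x$truth$disease_genes),
    length(x$truth$modules[[1L]]), x$truth$effect, x$truth$rho))
  invisible(x)
}

#' Write a synthetic instance to disk in pipeline input formats
#'
#' Writes `edges.tsv` (two-column edge list), `expr.tsv` (expression
#' matrix TSV), `labels.tsv` (sample to class map) and `truth.json` —
#' exactly the formats [load_ppi()] and [load_expression()] read.
#'
#' @param instance a `synthetic_instance`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_instance <- function(instance, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("edges.tsv", "expr.tsv", "labels.tsv",
                            "truth.json"))
  write.table(instance$network$edges, paths[1L], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expr_tab <- data.frame(gene = rownames(instance$expression$values),
                         instance$expression$values, check.names = FALSE,
                         stringsAsFactors = FALSE)
  write.table(expr_tab, paths[2L], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  write.table(data.frame(sample = names(instance$expression$labels),
                         class = unname(instance$expression$labels)),
              paths[3L], sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing truth.json requires the jsonlite package")
  }
  jsonlite::write_json(
    list(disease_genes = instance$truth$disease_genes,
         modules = instance$truth$modules,
         module_signs = as.list(instance$truth$module_signs),
         effect = instance$truth$effect, rho = instance$truth$rho,
         hop_radius = instance$truth$hop_radius, seed = instance$seed),
    paths[4L], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
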