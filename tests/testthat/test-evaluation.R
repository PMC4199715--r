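# Build a ranking_result directly from a score vector over named genes.
ranking_from_scores <- function(scores) {
  rk <- rank(-scores, ties.method = "average")
  nc <- length(scores)
  df <- data.frame(gene = names(scores), score = unname(scores),
                   rank = unname(rk), rank_ratio = unname(rk) / nc,
                   stringsAsFactors = FALSE)
  df <- df[order(df$rank, df$gene), ]
  rownames(df) <- NULL
  structure(list(ranking = df, contributions = NULL, groups = list(),
                 unranked = character(0), n_candidates = nc),
            class = "ranking_result")
}

test_that("rank ratios follow the average-rank convention", {
  sc <- setNames(seq(100, 1), sprintf("g%03d", 1:100))
  rk <- ranking_from_scores(sc)
  expect_equal(rank_ratio(rk, "g001"), 0.01)
  expect_equal(rank_ratio(rk, "g100"), 1.0)

  sc10 <- setNames(c(10, 9, 8, 8, 6, 5, 4, 3, 2, 1), paste0("t", 1:10))
  rk10 <- ranking_from_scores(sc10)
  expect_equal(rank_ratio(rk10, "t3"), 0.35)  # tie at positions 3-4
  expect_equal(rank_ratio(rk10, "t4"), 0.35)
  expect_error(rank_ratio(rk10, "absent"), "not ranked")
})

test_that("MRR averages the rank ratios of rankable known genes", {
  sc <- setNames(seq(10, 1), paste0("t", 1:10))
  rk <- ranking_from_scores(sc)
  m <- mean_rank_ratio(rk, c("t1", "t3"))
  expect_equal(as.numeric(m), 0.2)
  m2 <- mean_rank_ratio(rk, c("t1", "t3", "nope"))
  expect_equal(as.numeric(m2), 0.2)
  expect_equal(attr(m2, "excluded"), "nope")
  expect_error(mean_rank_ratio(rk, "nope"), "none of the known genes")

  last <- mean_rank_ratio(rk, "t10")
  expect_equal(as.numeric(last), 1.0)
})

test_that("AUC hits its closed-form extremes and tie symmetry", {
  sc <- setNames(seq(10, 1), paste0("t", 1:10))
  rk <- ranking_from_scores(sc)
  expect_equal(roc_auc(rk, c("t1", "t2"))$auc, 1.0)
  expect_equal(roc_auc(rk, c("t9", "t10"))$auc, 0.0)

  # single positive sitting at the exact middle of 2k+1 candidates
  sc2 <- setNames(seq(9, 1), paste0("u", 1:9))
  expect_equal(roc_auc(ranking_from_scores(sc2), "u5")$auc, 0.5)

  # fully tied scores: midranks give exactly 0.5
  tied <- ranking_from_scores(setNames(rep(1, 20), paste0("v", 1:20)))
  expect_equal(roc_auc(tied, paste0("v", 1:5))$auc, 0.5)
  expect_error(roc_auc(rk, character(0)), "no positives")
  expect_error(roc_auc(rk, paste0("t", 1:10)), "no negatives")
})

test_that("midrank AUC equals the brute-force all-pairs oracle, ties included", {
  set.seed(51)
  for (i in 1:15) {
    n <- sample(20:200, 1)
    scores <- setNames(sample(round(rnorm(n), 1)), sprintf("c%03d", 1:n))
    pos <- sample(names(scores), sample(2:8, 1))
    rk <- ranking_from_scores(scores)
    expect_equal(roc_auc(rk, pos)$auc,
                 allpairs_auc(scores, names(scores) %in% pos))
  }
})

test_that("ROC curve is a valid monotone staircase from (0,0) to (1,1)", {
  set.seed(52)
  scores <- setNames(round(rnorm(50), 1), sprintf("c%02d", 1:50))
  roc <- roc_auc(ranking_from_scores(scores), sample(names(scores), 10))
  expect_equal(roc$curve$fpr[1], 0)
  expect_equal(roc$curve$tpr[1], 0)
  expect_equal(roc$curve$fpr[nrow(roc$curve)], 1)
  expect_equal(roc$curve$tpr[nrow(roc$curve)], 1)
  expect_true(all(diff(roc$curve$fpr) >= 0))
  expect_true(all(diff(roc$curve$tpr) >= 0))
})

test_that("the threshold sweep covers the grid and degenerates to the baseline at d = 0", {
  inst <- make_instance(n_nodes = 120, seed = 13)
  de <- de_test(inst$expression)
  kern <- diffusion_kernel(transition_matrix(inst$network))
  sw <- threshold_sweep(inst$network, inst$expression,
                        inst$truth$disease_genes, kernel = kern, de = de)
  expect_equal(nrow(sw$curve), 101L)
  expect_equal(sw$curve$d, seq(0, 1, by = 0.01))
  expect_true(sw$d_opt %in% sw$curve$d)
  expect_equal(sw$mrr_opt, min(sw$curve$mrr))
  # smallest-d tie rule
  expect_equal(sw$d_opt, sw$curve$d[which.min(sw$curve$mrr)])

  sr <- single_rank(inst$network$nodes, de, kern, inst$network)
  expect_equal(sw$curve$mrr[1],
               as.numeric(mean_rank_ratio(sr, inst$truth$disease_genes)))
})

test_that("random-group null is seeded, reproducible, and uses the add-one p", {
  inst <- make_instance(n_nodes = 120, seed = 19)
  res <- run_pipeline(grouprank_config(ppi = inst$network,
                                       expr = inst$expression), quiet = TRUE)
  nl1 <- random_group_null(res$groups, res$kernel, res$de, res$network,
                           inst$truth$disease_genes, n_resamples = 50,
                           seed = 77)
  nl2 <- random_group_null(res$groups, res$kernel, res$de, res$network,
                           inst$truth$disease_genes, n_resamples = 50,
                           seed = 77)
  expect_identical(nl1$null_mrr, nl2$null_mrr)
  expect_identical(nl1$p_value, nl2$p_value)
  b <- sum(nl1$null_mrr <= nl1$observed_mrr)
  expect_equal(nl1$p_value, (b + 1) / 51)
  expect_gt(nl1$p_value, 0)
  expect_error(random_group_null(list(), res$kernel, res$de, res$network,
                                 inst$truth$disease_genes),
               "at least one")
})

test_that("paired Wilcoxon comparison handles extremes per the exact distribution", {
  x <- seq(0.1, 0.9, length.out = 20)
  expect_warning(res <- compare_methods(x, x), "zero")
  expect_equal(res$p_value, 1)

  set.seed(53)
  y <- x + runif(20, 0.01, 0.1)  # B worse than A in every pair
  cmp <- compare_methods(x, y)
  expect_equal(cmp$p_value, 2 * 2^-20, tolerance = 1e-10)
  expect_error(compare_methods(1:3, 2:4), "at least 5")

  # type-I behavior under exchangeable pairs: p roughly uniform
  set.seed(54)
  rej <- mean(replicate(400, {
    a <- rnorm(12)
    b <- rnorm(12)
    compare_methods(a, b)$p_value < 0.05
  }))
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})
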