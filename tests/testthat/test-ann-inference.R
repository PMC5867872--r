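fast_cfg <- function(...) ann_config(n_reshuffles = 10, max_epochs = 200, ...)

test_that("config and phenotype encoding are validated", {
  expect_error(ann_config(split = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(ann_config(n_reshuffles = 0), "n_reshuffles")
  des <- make_design("L1", c("sufficient", "low"), "T1", 3)
  ph <- phenotype_vector(des)
  expect_equal(unname(ph[des$treatment == "low"]), rep(0, 3))
  expect_equal(unname(ph[des$treatment == "sufficient"]), rep(1, 3))
  des$treatment[1] <- "drought"
  expect_error(phenotype_vector(des), "without encoding")
})

test_that("a perfect phenotype predictor ranks first and ranking is gene-order invariant", {
  des <- make_design(c("L1", "L2"), c("sufficient", "low"), "T1", 6)
  ph <- phenotype_vector(des)
  set.seed(1)
  expr <- matrix(rnorm(20 * nrow(des)), 20, nrow(des),
                 dimnames = list(sprintf("noise%02d", 1:20), des$sample))
  expr <- rbind(expr, oracle_gene = as.numeric(ph) * 2 + 5)
  for (s in 1:3) {
    r <- rank_genes_stage1(expr, ph, fast_cfg(seed = s))
    expect_equal(r$gene[1], "oracle_gene")
    expect_lt(r$mean_mse[1], min(r$mean_mse[-1]))
  }

  r1 <- rank_genes_stage1(expr, ph, fast_cfg(seed = 4))
  perm <- sample(nrow(expr))
  r2 <- rank_genes_stage1(expr[perm, ], ph, fast_cfg(seed = 4))
  expect_identical(r1[order(r1$gene), c("gene", "mean_mse", "sd_mse")],
                   r2[order(r2$gene), c("gene", "mean_mse", "sd_mse")])
  # ranks are a permutation of 1..n sorted by mean MSE
  expect_identical(r1$rank, seq_len(nrow(expr)))
  expect_false(is.unsorted(r1$mean_mse))
})

test_that("stage 1 recovers planted informative genes and agrees with a |t| ranking oracle", {
  st <- sim_study(n_genes = 100, n_informative = 10, replicates = 10,
                  log2fc_range = c(2, 3), noise_sd = 0.5, seed = 41,
                  n_regulators = 2, targets = 2,
                  strength_range = c(0.2, 0.3))
  ph <- phenotype_vector(st$design)[colnames(st$expr)]
  r <- rank_genes_stage1(st$expr, ph, fast_cfg(seed = 2))
  planted <- st$truth$informative$gene
  expect_gte(sum(planted %in% r$gene[1:20]), 8)

  de <- differential_expression(st$expr, st$design)
  t_top10 <- de$gene[order(-abs(de$t_statistic))][1:10]
  expect_gte(length(intersect(t_top10, r$gene[1:10])), 7)
})

test_that("stage 2 enumerates k(k-1) candidate edges and is deterministic", {
  des <- make_design("L1", c("sufficient", "low"), "T1", 8)
  set.seed(3)
  for (k in c(2, 5, 10)) {
    expr <- matrix(rnorm(k * nrow(des)), k, nrow(des),
                   dimnames = list(sprintf("g%02d", 1:k), des$sample))
    ed <- infer_interactions_stage2(expr, ann_config(seed = 1),
                                    strata = des$treatment)
    expect_equal(nrow(ed), k * (k - 1))
    expect_true(all(ed$source != ed$target))
    # every target model integrates exactly k-1 per-input terms
    expect_true(all(table(ed$target) == k - 1))
  }
  expr <- matrix(rnorm(4 * nrow(des)), 4, nrow(des),
                 dimnames = list(sprintf("g%02d", 1:4), des$sample))
  e1 <- infer_interactions_stage2(expr, ann_config(seed = 9))
  e2 <- infer_interactions_stage2(expr, ann_config(seed = 9))
  expect_identical(e1, e2)
  expect_error(infer_interactions_stage2(expr[1, , drop = FALSE],
                                         ann_config(seed = 1)), "at least 2")
})

test_that("stage 2 recovers the sign of strong planted interactions", {
  neg_ok <- 0
  for (s in 1:10) {
    tr <- generate_truth_network(20, 1, 1, repressor_fraction = 1, seed = s,
                                 n_informative = 1,
                                 strength_range = c(0.9, 0.9))
    des <- make_design(c("L1", "L2"), c("sufficient", "low"), "T1", 10)
    expr <- simulate_expression(tr, des, noise_sd = 0.1, seed = s + 200)
    ed <- infer_interactions_stage2(expr, ann_config(top_k = 20, seed = s),
                                    strata = des$treatment)
    e <- tr$edges[1, ]
    w <- ed$weight[ed$source == e$source & ed$target == e$target]
    neg_ok <- neg_ok + (w < 0)
  }
  expect_gte(neg_ok, 9)
})

test_that("Z-scores standardize the candidate set and truncation keeps the strongest edges", {
  two <- data.frame(source = c("a", "b"), target = c("b", "a"),
                    weight = c(1, -1), stringsAsFactors = FALSE)
  expect_equal(zscore_edges(two)$z_score, c(1, -1))

  const <- data.frame(source = c("a", "b", "c"), target = c("b", "c", "a"),
                      weight = rep(2, 3), stringsAsFactors = FALSE)
  expect_true(all(zscore_edges(const)$z_score == 0))

  set.seed(5)
  big <- data.frame(source = "s", target = sprintf("t%04d", 1:9900),
                    weight = rnorm(9900), stringsAsFactors = FALSE)
  z <- zscore_edges(big)$z_score
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-12)

  # truncation: kept |z| dominates dropped |z|; ties broken lexicographically
  ed <- zscore_edges(data.frame(
    source = sample(sprintf("g%02d", 1:30), 400, TRUE),
    target = sample(sprintf("g%02d", 1:30), 400, TRUE),
    weight = rnorm(400), stringsAsFactors = FALSE))
  ed <- ed[ed$source != ed$target, ]
  net <- truncate_top_edges(ed, 50)
  expect_equal(nrow(net$edges), 50)
  kept_keys <- paste(net$edges$from, net$edges$to)
  dropped <- ed[!paste(ed$source, ed$target) %in% kept_keys, ]
  expect_gte(min(abs(net$edges$score)), max(abs(dropped$z_score)))

  all_net <- truncate_top_edges(ed, nrow(ed) + 10)
  expect_equal(nrow(all_net$edges), nrow(ed))

  tie <- zscore_edges(data.frame(source = c("b", "a", "c"),
                                 target = c("x", "x", "x"),
                                 weight = c(1, -1, 1),
                                 stringsAsFactors = FALSE))
  tie$z_score <- abs(tie$z_score)  # force exact ties in |z|
  t1 <- truncate_top_edges(tie, 2)
  expect_setequal(t1$edges$from, c("a", "b"))
})

test_that("the fitted ann_grn object exposes ranking, network and methods", {
  st <- sim_study(n_genes = 30, n_informative = 4, replicates = 6, seed = 51)
  ph <- phenotype_vector(st$design)[colnames(st$expr)]
  fit <- ann_grn(st$expr, ph, fast_cfg(top_k = 12, edge_k = 40, seed = 3))
  expect_s3_class(fit, "ann_grn")
  expect_equal(nrow(fit$edges), 12 * 11)
  expect_lte(nrow(fit$network$edges), 40)
  expect_true(all(fit$top_genes %in% rownames(st$expr)))
  expect_output(print(fit), "stage 2: 132 candidate edges")
  expect_output(summary(fit), "Top-ranked genes")
  expect_s3_class(coef(fit), "data.frame")
  expect_equal(nrow(coef(fit, all = TRUE)), 132)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("TF-restricted runs equal the full run when the list covers all genes", {
  st <- sim_study(n_genes = 25, n_informative = 4, replicates = 6, seed = 61)
  ph <- phenotype_vector(st$design)[colnames(st$expr)]
  cfg <- fast_cfg(top_k = 10, edge_k = 30, seed = 7)
  full <- ann_grn(st$expr, ph, cfg)
  tf_all <- run_tf_subset(st$expr, rownames(st$expr), ph, cfg)
  expect_identical(full$ranking, tf_all$ranking)
  expect_identical(full$network$edges, tf_all$network$edges)

  expect_warning(
    sub <- run_tf_subset(st$expr, c(rownames(st$expr)[1:12], "NOT_A_GENE"),
                         ph, cfg),
    "ignored")
  expect_equal(nrow(sub$ranking), 12)
  expect_error(run_tf_subset(st$expr, c("nope1", "nope2"), ph, cfg),
               "no TF id")
})
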