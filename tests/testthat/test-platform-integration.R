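test_that("unique-probe filter keeps exactly the single-hit records, order-stable", {
  empty <- data.frame(probe = character(), gene = character(),
                      n_hits = integer(), stringsAsFactors = FALSE)
  expect_equal(nrow(filter_unique_probes(empty)), 0)

  m <- data.frame(probe = c("p1", "p2", "p3"), gene = c("gA", "gB", "gA"),
                  n_hits = c(1L, 2L, 1L), stringsAsFactors = FALSE)
  expect_equal(filter_unique_probes(m)$probe, c("p1", "p3"))

  set.seed(4)
  big <- data.frame(probe = sprintf("p%03d", 1:200),
                    gene = sample(sprintf("g%02d", 1:50), 200, replace = TRUE),
                    n_hits = 1L, stringsAsFactors = FALSE)
  big$n_hits[sample(200, 37)] <- 2L
  kept <- filter_unique_probes(big)
  expect_equal(nrow(kept), 163)
  expect_identical(kept$probe, big$probe[big$n_hits == 1])  # brute-force scan
})

test_that("probe collapse matches the per-gene mean and max-variance oracles", {
  samples <- sprintf("s%02d", 1:6)
  one <- matrix(rnorm(18), 3, 6,
                dimnames = list(c("p1", "p2", "p3"), samples))
  map1 <- data.frame(probe = c("p1", "p2", "p3"), gene = c("gA", "gB", "gC"),
                     n_hits = 1L, stringsAsFactors = FALSE)
  out1 <- collapse_probes_to_genes(one, map1, "mean")
  expect_equal(unname(out1[order(map1$gene), ]), unname(one))

  two <- matrix(c(rep(4, 6), rep(6, 6)), 2, 6, byrow = TRUE,
                dimnames = list(c("p1", "p2"), samples))
  map2 <- data.frame(probe = c("p1", "p2"), gene = "gA", n_hits = 1L,
                     stringsAsFactors = FALSE)
  expect_true(all(collapse_probes_to_genes(two, map2, "mean")["gA", ] == 5))

  set.seed(8)
  genes <- rep(sprintf("g%02d", 1:50), times = sample(1:3, 50, replace = TRUE))
  probes <- sprintf("p%03d", seq_along(genes))
  m <- matrix(rnorm(length(probes) * 8, sd = runif(length(probes), 0.1, 2)),
              length(probes), 8, dimnames = list(probes, sprintf("s%d", 1:8)))
  map <- data.frame(probe = probes, gene = genes, n_hits = 1L,
                    stringsAsFactors = FALSE)
  mv <- collapse_probes_to_genes(m, map, "max-variance-probe")
  v <- apply(m, 1, var)
  for (g in rownames(mv)) {   # exhaustive max check
    expect_equal(var(mv[g, ]), max(v[map$probe[map$gene == g]]))
  }

  expect_warning(
    res <- collapse_probes_to_genes(one, data.frame(probe = "zz", gene = "gX",
                                                    n_hits = 1L)),
    "empty")
  expect_equal(nrow(res), 0)
})

test_that("differential expression matches the Welch t-test oracle and calls planted genes", {
  des <- make_design("L1", c("sufficient", "low"), "T1", 10)
  tr <- null_truth(40, seed = 5)
  tr$informative <- data.frame(gene = "G0003", log2fc = -3,
                               stringsAsFactors = FALSE)
  expr <- simulate_expression(tr, des, noise_sd = 0.2, seed = 6)
  de <- differential_expression(expr, des)

  # planted gene called down with very small p
  row <- de[de$gene == "G0003", ]
  expect_equal(row$status, "down")
  expect_lt(row$p_value, 0.001)
  expect_lt(row$linear_FC, -4)

  # Welch oracle on every gene
  low <- des$sample[des$treatment == "low"]
  suf <- des$sample[des$treatment == "sufficient"]
  for (g in rownames(expr)[1:15]) {
    tt <- t.test(expr[g, low], expr[g, suf])
    i <- match(g, de$gene)
    expect_equal(de$t_statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-10)
  }

  # identical groups: zero fold change, ns, p = 1
  half <- expr[, low]
  copied <- cbind(half, half)
  colnames(copied) <- des$sample
  de0 <- differential_expression(copied, des)
  expect_true(all(de0$log2FC == 0))
  expect_true(all(de0$status == "ns"))
  expect_true(all(de0$p_value == 1))

  expect_error(differential_expression(expr[, 1:3], des[1:3, ]), "at least 2")
})

test_that("DE calls are symmetric in the contrast and monotone in the thresholds", {
  st <- sim_study(n_genes = 50, seed = 21, replicates = 4)
  a <- differential_expression(st$expr, st$design, c("low", "sufficient"))
  b <- differential_expression(st$expr, st$design, c("sufficient", "low"))
  expect_equal(a$log2FC, -b$log2FC)
  expect_equal(abs(a$t_statistic), abs(b$t_statistic))
  expect_equal(a$p_value, b$p_value)

  loose <- differential_expression(st$expr, st$design, fc_thresh = 1.5,
                                   alpha = 0.1)
  strict <- differential_expression(st$expr, st$design, fc_thresh = 2,
                                    alpha = 0.01)
  de_loose <- loose$gene[loose$status != "ns"]
  de_strict <- strict$gene[strict$status != "ns"]
  expect_true(all(de_strict %in% de_loose))

  bh <- differential_expression(st$expr, st$design, adjust = "BH")
  expect_true(all(bh$p_value >= a$p_value - 1e-12))
})

test_that("null simulations stay within the nominal false-call budget", {
  flagged <- vapply(1:5, function(s) {
    tr <- null_truth(1000, seed = s)
    des <- make_design("L1", c("sufficient", "low"), "T1", 3)
    expr <- simulate_expression(tr, des, noise_sd = 0.5, seed = s + 50)
    de <- differential_expression(expr, des)
    mean(de$status != "ns")
  }, numeric(1))
  expect_true(all(flagged <= 0.06))
})

test_that("within-study integration keeps genes DE in every genotype", {
  st <- sim_study(seed = 31)
  de <- differential_expression(st$expr, st$design)
  single <- integrate_within_study(list(L1 = de))
  expect_setequal(single$gene, de$gene[de$status != "ns"])

  # down in 3 of 4 genotypes but ns in the 4th -> excluded
  mk <- function(status_g5) {
    data.frame(gene = c("g1", "g5"), mean_ref = 0, mean_alt = 0,
               log2FC = c(-2, -2), linear_FC = c(-4, -4), t_statistic = 0,
               p_value = 0.01, status = c("down", status_g5),
               stringsAsFactors = FALSE)
  }
  tabs <- list(a = mk("down"), b = mk("down"), c = mk("down"), d = mk("ns"))
  res <- integrate_within_study(tabs)
  expect_equal(res$gene, "g1")
  expect_equal(res$direction, "down")

  # mixed directions retained and flagged
  tabs2 <- list(a = mk("down"), b = mk("up"))
  res2 <- integrate_within_study(tabs2)
  expect_equal(res2$direction[res2$gene == "g5"], "mixed")
})

test_that("planted concordant genes survive multi-genotype integration", {
  hits <- vapply(1:10, function(s) {
    tr <- null_truth(220, seed = s)
    planted <- sprintf("G%04d", 1:20)
    tr$informative <- data.frame(gene = planted, log2fc = -2.5,
                                 stringsAsFactors = FALSE)
    des <- make_design(c("L1", "L2", "L3", "L4"), c("sufficient", "low"),
                       "T1", 4)
    expr <- simulate_expression(tr, des, noise_sd = 0.3, seed = s + 70)
    tabs <- lapply(split(des, des$genotype), function(d) {
      differential_expression(expr[, d$sample], d)
    })
    res <- integrate_within_study(tabs)
    setequal(res$gene, planted)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("cross-study classes partition the common set and match a brute-force classifier", {
  empty_a <- data.frame(gene = c("x1", "x2"), direction = "down",
                        directions = "down", stringsAsFactors = FALSE)
  empty_b <- data.frame(gene = c("y1"), direction = "down",
                        directions = "down", stringsAsFactors = FALSE)
  expect_equal(unname(integrate_across_studies(empty_a, empty_b)$counts["n_common"]), 0)

  set.seed(17)
  for (trial in 1:100) {
    na <- sample(3:25, 1)
    nb <- sample(3:25, 1)
    ga <- sample(sprintf("g%02d", 1:25), na)
    gb <- sample(sprintf("g%02d", 1:25), nb)
    a <- data.frame(gene = ga,
                    direction = sample(c("down", "up", "mixed"), na, TRUE),
                    stringsAsFactors = FALSE)
    b <- data.frame(gene = gb,
                    direction = sample(c("down", "up", "mixed"), nb, TRUE),
                    stringsAsFactors = FALSE)
    res <- integrate_across_studies(a, b)
    cnt <- res$counts
    expect_identical(unname(cnt["n_down"] + cnt["n_up"] + cnt["n_conflicted"]),
                     unname(cnt["n_common"]))
    # oracle equivalence per gene
    for (i in seq_len(nrow(res$table))) {
      expect_identical(res$table$class[i],
                       oracle_classify(res$table$direction_a[i],
                                       res$table$direction_b[i]))
    }
  }
})

test_that("category tabulation conserves counts and matches a group-by oracle", {
  expect_equal(nrow(tabulate_categories(character(), c(g1 = "A"))), 0)

  genes <- sprintf("g%02d", 1:10)
  cmap <- setNames(sample(c("A", "B", "C"), 7, TRUE), genes[1:7])
  tab <- tabulate_categories(genes, cmap)
  expect_equal(sum(tab$count), 10)
  expect_equal(tab$count[tab$category == "unannotated"], 3)

  set.seed(23)
  g500 <- sample(sprintf("g%03d", 1:300), 500, replace = TRUE)
  m500 <- setNames(sample(LETTERS[1:11], 250, TRUE), sprintf("g%03d", 1:250))
  tab2 <- tabulate_categories(g500, m500)
  lab <- ifelse(is.na(m500[g500]), "unannotated", m500[g500])
  oracle <- table(lab)
  expect_equal(setNames(tab2$count, tab2$category),
               setNames(as.integer(oracle), names(oracle)))
})
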