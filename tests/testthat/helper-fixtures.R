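# Shared fixture builders: small simulated studies with planted structure.

# one study: planted truth + design + gene-level expression matrix
sim_study <- function(n_genes = 60, n_regulators = 3, targets = 4,
                      repressor_fraction = 0.3, n_informative = 5,
                      log2fc_range = c(2, 3), strength_range = c(0.8, 0.95),
                      genotypes = c("L1", "L2"),
                      treatments = c("sufficient", "low"),
                      timepoints = "T1", replicates = 5,
                      noise_sd = 0.5, seed = 1, ...) {
  truth <- generate_truth_network(n_genes, n_regulators, targets,
                                  repressor_fraction, seed = seed,
                                  n_informative = n_informative,
                                  log2fc_range = log2fc_range,
                                  strength_range = strength_range, ...)
  design <- make_design(genotypes, treatments, timepoints, replicates)
  expr <- simulate_expression(truth, design, noise_sd = noise_sd,
                              seed = seed + 1000)
  list(truth = truth, design = design, expr = expr)
}

# truth with no informative genes and no edges (pure-noise null model)
null_truth <- function(n_genes, seed = 1) {
  tr <- generate_truth_network(n_genes, 1, 1, 0, seed = seed,
                               n_informative = 1)
  tr$edges <- tr$edges[0, , drop = FALSE]
  tr$informative <- tr$informative[0, , drop = FALSE]
  tr
}

# random undirected gene_network on n nodes with edge probability p
random_network <- function(n, p = 0.25, seed = 1, signed = FALSE) {
  set.seed(seed)
  ids <- sprintf("n%02d", 1:n)
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      score = runif(sum(keep), -1, 1),
                      stringsAsFactors = FALSE)
  if (signed) edges$sign <- ifelse(edges$score >= 0, 1L, -1L)
  gene_network(edges, nodes = data.frame(id = ids, stringsAsFactors = FALSE))
}
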