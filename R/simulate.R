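## Synthetic-data generator: planted regulatory truth, two pseudo-platforms,
## design tables. Everything is a pure function of its arguments + seed.

#' Generate a planted ground-truth regulatory model
#'
#' Draws a set of regulators, a signed regulator-to-target edge list, and a set
#' of phenotype-informative genes carrying non-zero planted log2 fold changes
#' under low nitrogen. This is the object downstream recovery tests compare
#' against.
#'
#' @param n_genes size of the gene universe (ids `G0001`, `G0002`, ...)
#' @param n_regulators number of regulator genes (must be `< n_genes`)
#' @param targets_per_regulator distinct targets drawn per regulator
#'   (self-edges excluded; duplicates resampled). Must be `< n_genes - 1`.
#' @param repressor_fraction probability an edge carries sign -1
#' @param seed integer seed; identical seed gives an identical model
#' @param n_informative number of phenotype-informative genes (default 5% of
#'   the universe)
#' @param log2fc_range magnitude range of planted log2 fold changes
#' @param down_fraction fraction of informative genes that are down-regulated
#'   under low N (the remainder are up-regulated)
#' @param strength_range range of edge coupling strengths, within (0, 1]
#' @param regulators_informative if `TRUE` (default) regulators are drawn into
#'   the informative set first: the planted network drives the nitrogen
#'   response, so its regulators carry treatment-linked variance that
#'   propagates to their targets
#' @return an object of class `truth_model`: list with `genes`, `regulators`,
#'   `edges` (data frame `source`, `target`, `sign`, `strength`),
#'   `informative` (data frame `gene`, `log2fc`) and `seed`
#' @export
generate_truth_network <- function(n_genes, n_regulators, targets_per_regulator,
                                   repressor_fraction, seed,
                                   n_informative = max(1L, round(0.05 * n_genes)),
                                   log2fc_range = c(1, 3),
                                   down_fraction = 0.8,
                                   strength_range = c(0.5, 1),
                                   regulators_informative = TRUE) {
  .assert(n_regulators < n_genes, "n_regulators must be smaller than n_genes")
  .assert(targets_per_regulator >= 1, "targets_per_regulator must be >= 1")
  .assert(targets_per_regulator < n_genes - 1,
          "targets_per_regulator >= n_genes - 1: impossible edge count")
  .assert(repressor_fraction >= 0 && repressor_fraction <= 1,
          "repressor_fraction must lie in [0, 1]")
  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed(stream_seed(seed, "truth"), {
    regulators <- sort(sample(genes, n_regulators))
    edges <- do.call(rbind, lapply(regulators, function(r) {
      pool <- setdiff(genes, r)
      data.frame(source = r,
                 target = sample(pool, targets_per_regulator),
                 stringsAsFactors = FALSE)
    }))
    n_edges <- nrow(edges)
    edges$sign <- ifelse(runif(n_edges) < repressor_fraction, -1, 1)
    edges$strength <- runif(n_edges, strength_range[1], strength_range[2])
    n_informative <- min(n_informative, n_genes)
    inf_genes <- if (regulators_informative) {
      pool <- c(sample(regulators), sample(setdiff(genes, regulators)))
      sort(pool[seq_len(n_informative)])
    } else {
      sort(sample(genes, n_informative))
    }
    mag <- runif(n_informative, log2fc_range[1], log2fc_range[2])
    dir <- ifelse(runif(n_informative) < down_fraction, -1, 1)
    informative <- data.frame(gene = inf_genes, log2fc = mag * dir,
                              stringsAsFactors = FALSE)
  })
  structure(list(genes = genes, regulators = regulators, edges = edges,
                 informative = informative, seed = as.integer(seed)),
            class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat(sprintf("truth_model: %d genes, %d regulators, %d signed edges, %d informative genes (seed %d)\n",
              length(x$genes), length(x$regulators), nrow(x$edges),
              nrow(x$informative), x$seed))
  invisible(x)
}

#' Build a full-factorial sample design table
#'
#' @param genotypes character vector of line labels
#' @param treatments subset of `c("sufficient", "low", "recovery")`
#' @param timepoints character vector of time-point labels
#' @param replicates biological replicates per cell
#' @return data frame with columns `sample`, `genotype`, `treatment`, `time`,
#'   `replicate`; sample ids are unique
#' @export
make_design <- function(genotypes, treatments = c("sufficient", "low"),
                        timepoints = "T1", replicates = 3) {
  .assert(all(treatments %in% c("sufficient", "low", "recovery")),
          "treatments must be among sufficient/low/recovery")
  g <- expand.grid(replicate = seq_len(replicates), time = timepoints,
                   treatment = treatments, genotype = genotypes,
                   stringsAsFactors = FALSE)
  g <- g[, c("genotype", "treatment", "time", "replicate")]
  g$sample <- sprintf("%s_%s_%s_r%d", g$genotype, g$treatment, g$time,
                      g$replicate)
  g[, c("sample", "genotype", "treatment", "time", "replicate")]
}

#' Simulate a log2-scale expression matrix from a planted truth model
#'
#' Each gene's baseline is `base_mean`. Informative genes shift by their
#' planted log2 fold change in low-N samples (and by `recovery_fraction` of it
#' in recovery samples). Each regulator-to-target edge then adds
#' `sign * strength * (regulator value - regulator mean)` to the target, using
#' the regulator's pre-coupling signal, which induces the planted
#' co-expression. Finally i.i.d. Gaussian noise with sd `noise_sd` is added on
#' the log2 scale.
#'
#' @param truth a `truth_model`
#' @param design a design data frame from [make_design()]
#' @param base_mean baseline log2 expression (default 8, typical microarray)
#' @param noise_sd Gaussian noise sd on the log2 scale (> 0)
#' @param seed integer seed
#' @param recovery_fraction fraction of the low-N effect expressed in recovery
#'   samples (default 0.5, an intermediate profile)
#' @return numeric matrix genes x samples (row names gene ids, column names
#'   sample ids)
#' @export
simulate_expression <- function(truth, design, base_mean = 8, noise_sd = 0.5,
                                seed = truth$seed, recovery_fraction = 0.5) {
  .assert(noise_sd > 0, "noise_sd must be > 0")
  .assert(nrow(design) > 0, "design must be non-empty")
  bad <- setdiff(unique(design$treatment), c("sufficient", "low", "recovery"))
  .assert(length(bad) == 0,
          paste0("unknown treatment label(s): ", paste(bad, collapse = ", ")))
  genes <- truth$genes
  n_g <- length(genes)
  n_s <- nrow(design)
  eff <- setNames(numeric(n_g), genes)
  if (nrow(truth$informative)) {
    eff[truth$informative$gene] <- truth$informative$log2fc
  }
  tw <- c(sufficient = 0, low = 1, recovery = recovery_fraction)
  w <- tw[design$treatment]
  mu <- base_mean + outer(eff, w)      # genes x samples mean surface
  signal <- mu
  noise <- with_seed(stream_seed(seed, "expr"), {
    matrix(rnorm(n_g * n_s, 0, noise_sd), n_g, n_s)
  })
  vals <- signal + noise
  if (nrow(truth$edges)) {
    base_vals <- vals                  # pre-coupling regulator signal
    for (k in seq_len(nrow(truth$edges))) {
      e <- truth$edges[k, ]
      r <- base_vals[e$source, ]
      vals[e$target, ] <- vals[e$target, ] + e$sign * e$strength * (r - mean(r))
    }
  }
  dimnames(vals) <- list(genes, design$sample)
  vals
}

#' Fabricate probe maps for two pseudo-platforms over a shared gene universe
#'
#' Each platform independently covers a `1 - dropout_rate` fraction of the
#' universe; covered genes get `probes_per_gene_*` probes; an `ambiguity_rate`
#' fraction of probes is flagged multi-hit (`n_hits` 2-5). Probe ids are
#' disjoint between platforms (`A_`/`B_` prefixes).
#'
#' @param gene_universe character vector of gene ids
#' @param probes_per_gene_a,probes_per_gene_b probes per covered gene
#' @param ambiguity_rate fraction of probes flagged multi-hit, in [0, 1)
#' @param dropout_rate per-platform fraction of genes not covered, in [0, 1)
#' @param seed integer seed
#' @return list of two data frames (`platform_a`, `platform_b`) with columns
#'   `probe`, `gene`, `n_hits`
#' @export
generate_platforms <- function(gene_universe, probes_per_gene_a = 2,
                               probes_per_gene_b = 1, ambiguity_rate = 0.1,
                               dropout_rate = 0.1, seed = 1) {
  .assert(length(gene_universe) > 0, "gene universe must be non-empty")
  .assert(ambiguity_rate >= 0 && ambiguity_rate < 1,
          "ambiguity_rate must lie in [0, 1)")
  .assert(dropout_rate >= 0 && dropout_rate < 1,
          "dropout_rate must lie in [0, 1)")
  one_platform <- function(prefix, ppg, sub_seed) {
    with_seed(sub_seed, {
      keep <- gene_universe[runif(length(gene_universe)) >= dropout_rate]
      genes <- rep(keep, each = ppg)
      probes <- sprintf("%s_%06d", prefix, seq_along(genes))
      multi <- runif(length(probes)) < ambiguity_rate
      n_hits <- ifelse(multi, sample(2:5, length(probes), replace = TRUE), 1L)
      data.frame(probe = probes, gene = genes, n_hits = as.integer(n_hits),
                 stringsAsFactors = FALSE)
    })
  }
  list(platform_a = one_platform("A", probes_per_gene_a,
                                 stream_seed(seed, "platform", "A")),
       platform_b = one_platform("B", probes_per_gene_b,
                                 stream_seed(seed, "platform", "B")))
}

#' Probe-level measurements from a gene-level expression matrix
#'
#' Probe measurement = value of its mapped gene + independent Gaussian probe
#' noise, so collapsing probes by the mean is consistent with the gene signal.
#'
#' @param expr gene x sample log2 matrix
#' @param probe_map data frame `probe`, `gene`, `n_hits`
#' @param probe_noise_sd probe-level noise sd (default 0.1)
#' @param seed integer seed
#' @return probe x sample matrix restricted to probes whose gene is in `expr`
#' @export
probe_expression <- function(expr, probe_map, probe_noise_sd = 0.1, seed = 1) {
  pm <- probe_map[probe_map$gene %in% rownames(expr), , drop = FALSE]
  .assert(nrow(pm) > 0, "no probe maps to a gene present in `expr`")
  vals <- expr[pm$gene, , drop = FALSE]
  noise <- with_seed(stream_seed(seed, "probe_noise"), {
    matrix(rnorm(nrow(pm) * ncol(expr), 0, probe_noise_sd), nrow(pm), ncol(expr))
  })
  vals <- vals + noise
  rownames(vals) <- pm$probe
  vals
}

#' Write a truth model to JSON
#' @param truth a `truth_model`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(seed = truth$seed, regulators = truth$regulators,
         edges = truth$edges, informative = truth$informative),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a truth model back from JSON
#' @param path JSON path written by [write_truth_json()]
#' @return a `truth_model` (gene universe reconstructed from the stored parts)
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- sort(unique(c(x$regulators, x$edges$source, x$edges$target,
                         x$informative$gene)))
  structure(list(genes = genes, regulators = x$regulators,
                 edges = as.data.frame(x$edges),
                 informative = as.data.frame(x$informative),
                 seed = as.integer(x$seed)),
            class = "truth_model")
}
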