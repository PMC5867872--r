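## End-to-end orchestration: simulate -> collapse -> DE -> integrate ->
## ANN rank/network -> co-expression/CLR -> seed subnetwork -> metrics ->
## overlay -> export, driven by one config and one master seed.

#' Default pipeline configuration
#'
#' Returns the nested configuration list understood by [run_pipeline()], with a
#' built-in synthetic study pair: study A (four lines, three N treatments,
#' three replicates) and study B (two lines, two N treatments, two time points,
#' two replicates), probing a shared gene universe through two fabricated
#' platforms. Every entry can be overridden before the run; a YAML file with
#' the same structure can be passed to [run_pipeline()] directly.
#'
#' @param out_dir output directory for all stage files
#' @param seed master seed; all stage and per-gene streams derive from it
#' @return a nested list of class `pipeline_config`
#' @export
default_pipeline_config <- function(out_dir, seed = 1) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(
      n_genes = 200, n_regulators = 5, targets_per_regulator = 6,
      repressor_fraction = 0.3, n_informative = 12, noise_sd = 0.5,
      base_mean = 8, probe_noise_sd = 0.1, ambiguity_rate = 0.1,
      dropout_rate = 0.1, probes_per_gene_a = 2, probes_per_gene_b = 1,
      study_a = list(genotypes = c("L1", "L2", "L3", "L4"),
                     treatments = c("sufficient", "low", "recovery"),
                     timepoints = "T1", replicates = 3),
      study_b = list(genotypes = c("A188", "B73"),
                     treatments = c("sufficient", "low"),
                     timepoints = c("T1", "T2"), replicates = 2)
    ),
    paths = list(interaction_table = NULL, homology_map = NULL,
                 tf_list = NULL, seeds = NULL),
    thresholds = list(fc_thresh = 2, alpha = 0.05, corr_cutoff = 0.8,
                      corr_cutoff_de = 0.85, clr_cutoff = 3.6),
    ann = list(top_k = 30, edge_k = 100, n_reshuffles = 20),
    coexpr_max_genes = 80,
    subnet_hops = 1
  ), class = "pipeline_config")
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, skipping optional stages whose inputs are
#' absent (e.g. no interaction table means no known-network overlay), writes
#' every result as TSV under `config$out_dir`, and returns a manifest recording
#' each stage's inputs, outputs and parameters. Re-running with the same config
#' and seed reproduces byte-identical outputs.
#'
#' @param config a `pipeline_config` list (see [default_pipeline_config()]) or
#'   the path of a YAML file with the same structure
#' @return data frame manifest (stage, status, inputs, outputs, parameters),
#'   invisibly; also written to `manifest.tsv`
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  out <- cfg$out_dir
  .assert(!is.null(out), "config must name an out_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1L
  manifest <- list()
  note <- function(stage, status, inputs, outputs, params) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, status = status,
      inputs = paste(inputs, collapse = ","),
      outputs = paste(basename(outputs), collapse = ","),
      parameters = params, stringsAsFactors = FALSE)
    message(sprintf("[%s] %s (%s)", stage, status, params))
  }
  p <- function(f) file.path(out, f)

  ## --- simulate -------------------------------------------------------
  sm <- cfg$simulate
  .assert(!is.null(sm), "config must contain a `simulate` block")
  truth <- generate_truth_network(
    sm$n_genes, sm$n_regulators, sm$targets_per_regulator,
    sm$repressor_fraction, seed = stream_seed(seed, "sim"),
    n_informative = sm$n_informative)
  design_a <- do.call(make_design, sm$study_a)
  design_b <- do.call(make_design, sm$study_b)
  design_b$sample <- paste0("B_", design_b$sample)
  expr_a <- simulate_expression(truth, design_a, base_mean = sm$base_mean,
                                noise_sd = sm$noise_sd,
                                seed = stream_seed(seed, "expr_a"))
  expr_b <- simulate_expression(truth, design_b, base_mean = sm$base_mean,
                                noise_sd = sm$noise_sd,
                                seed = stream_seed(seed, "expr_b"))
  plats <- generate_platforms(truth$genes, sm$probes_per_gene_a,
                              sm$probes_per_gene_b, sm$ambiguity_rate,
                              sm$dropout_rate, seed = stream_seed(seed, "plat"))
  probes_a <- probe_expression(expr_a, plats$platform_a, sm$probe_noise_sd,
                               seed = stream_seed(seed, "pnoise_a"))
  probes_b <- probe_expression(expr_b, plats$platform_b, sm$probe_noise_sd,
                               seed = stream_seed(seed, "pnoise_b"))
  write_truth_json(truth, p("truth.json"))
  write_table_tsv(design_a, p("design_a.tsv"))
  write_table_tsv(design_b, p("design_b.tsv"))
  write_table_tsv(plats$platform_a, p("probe_map_a.tsv"))
  write_table_tsv(plats$platform_b, p("probe_map_b.tsv"))
  write_expression_tsv(probes_a, p("expr_probes_a.tsv"))
  write_expression_tsv(probes_b, p("expr_probes_b.tsv"))
  note("simulate", "done", "config",
       c("truth.json", "design_a.tsv", "design_b.tsv", "probe_map_a.tsv",
         "probe_map_b.tsv", "expr_probes_a.tsv", "expr_probes_b.tsv"),
       sprintf("n_genes=%d n_edges=%d n_informative=%d", sm$n_genes,
               nrow(truth$edges), nrow(truth$informative)))

  ## --- probe collapse -------------------------------------------------
  map_a <- filter_unique_probes(plats$platform_a)
  map_b <- filter_unique_probes(plats$platform_b)
  genes_a <- collapse_probes_to_genes(probes_a, map_a, method = "mean")
  genes_b <- collapse_probes_to_genes(probes_b, map_b, method = "mean")
  write_expression_tsv(genes_a, p("expr_genes_a.tsv"))
  write_expression_tsv(genes_b, p("expr_genes_b.tsv"))
  note("collapse", "done",
       c("expr_probes_a.tsv", "expr_probes_b.tsv"),
       c("expr_genes_a.tsv", "expr_genes_b.tsv"),
       sprintf("genes_a=%d genes_b=%d", nrow(genes_a), nrow(genes_b)))

  ## --- differential expression per genotype ---------------------------
  th <- cfg$thresholds
  de_one_study <- function(genes_m, design, tag) {
    tabs <- list()
    for (g in unique(design$genotype)) {
      sub <- design[design$genotype == g, , drop = FALSE]
      de <- differential_expression(genes_m[, sub$sample, drop = FALSE], sub,
                                    fc_thresh = th$fc_thresh, alpha = th$alpha)
      f <- sprintf("de_%s_%s.tsv", tag, g)
      write_table_tsv(de, p(f))
      note(paste0("de_", tag, "_", g), "done",
           sprintf("expr_genes_%s.tsv", tag), f,
           sprintf("fc_thresh=%g alpha=%g n_de=%d", th$fc_thresh, th$alpha,
                   sum(de$status != "ns")))
      tabs[[g]] <- de
    }
    tabs
  }
  de_a <- de_one_study(genes_a, design_a, "a")
  de_b <- de_one_study(genes_b, design_b, "b")

  ## --- integration ----------------------------------------------------
  within_a <- integrate_within_study(de_a)
  within_b <- integrate_within_study(de_b)
  across <- integrate_across_studies(within_a, within_b)
  write_table_tsv(within_a, p("integration_within_a.tsv"))
  write_table_tsv(within_b, p("integration_within_b.tsv"))
  write_table_tsv(across$table, p("integration_across.tsv"))
  note("integrate", "done",
       "de tables",
       c("integration_within_a.tsv", "integration_within_b.tsv",
         "integration_across.tsv"),
       sprintf("n_common=%d n_down=%d n_up=%d n_conflicted=%d",
               across$counts["n_common"], across$counts["n_down"],
               across$counts["n_up"], across$counts["n_conflicted"]))

  ## --- two-stage ANN on study A gene matrix ---------------------------
  acfg <- ann_config(top_k = min(cfg$ann$top_k, nrow(genes_a)),
                     edge_k = cfg$ann$edge_k,
                     n_reshuffles = cfg$ann$n_reshuffles,
                     seed = stream_seed(seed, "ann"))
  pheno <- phenotype_vector(design_a)[colnames(genes_a)]
  fit <- ann_grn(genes_a, pheno, acfg)
  write_table_tsv(fit$ranking, p("ann_ranking.tsv"))
  write_table_tsv(fit$edges, p("ann_edges.tsv"))
  export_network(fit$network, p("ann_network.tsv"), "edge-tsv")
  export_network(fit$network, p("ann_network.sif"), "sif")
  note("ann", "done", "expr_genes_a.tsv",
       c("ann_ranking.tsv", "ann_edges.tsv", "ann_network.tsv",
         "ann_network.sif"),
       sprintf("top_k=%d edge_k=%d candidates=%d", acfg$top_k, acfg$edge_k,
               nrow(fit$edges)))

  ## --- co-expression + CLR on the DE gene set -------------------------
  de_genes <- across$table$gene
  if (length(de_genes) < 10) {
    v <- apply(genes_a, 1, var)
    de_genes <- names(sort(v, decreasing = TRUE))[
      seq_len(min(cfg$coexpr_max_genes, nrow(genes_a)))]
  }
  de_genes <- head(de_genes, cfg$coexpr_max_genes)
  sub_m <- genes_a[intersect(de_genes, rownames(genes_a)), , drop = FALSE]
  corr_net <- correlation_network(sub_m, cutoff = th$corr_cutoff_de)
  clr_net <- clr_network(sub_m, cutoff = th$clr_cutoff)
  export_network(corr_net, p("coexpr_network.tsv"), "edge-tsv")
  export_network(clr_net, p("clr_network.tsv"), "edge-tsv")
  note("coexpression", "done", "expr_genes_a.tsv",
       c("coexpr_network.tsv", "clr_network.tsv"),
       sprintf("genes=%d corr_edges=%d clr_edges=%d (corr>%g, clr>%g)",
               nrow(sub_m), nrow(corr_net$edges), nrow(clr_net$edges),
               th$corr_cutoff_de, th$clr_cutoff))

  ## --- seed subnetwork -------------------------------------------------
  seeds <- if (!is.null(cfg$paths$seeds)) {
    readLines(cfg$paths$seeds)
  } else {
    down <- across$table$gene[across$table$class == "concordant_down"]
    if (!length(down)) down <- rownames(sub_m)[1]
    head(down, 10)
  }
  seeds_in <- intersect(seeds, rownames(sub_m))
  if (length(seeds_in)) seeds <- seeds_in else seeds <- rownames(sub_m)[1]
  subnet <- extract_seed_subnetwork(clr_net, seeds, hops = cfg$subnet_hops)
  export_network(subnet, p("seed_subnetwork.tsv"), "edge-tsv")
  note("subnetwork", "done", "clr_network.tsv", "seed_subnetwork.tsv",
       sprintf("seeds=%d hops=%d nodes=%d links=%d", length(seeds),
               cfg$subnet_hops, nrow(subnet$nodes), nrow(subnet$edges)))

  ## --- graph metrics / hubs -------------------------------------------
  metrics <- graph_metrics(clr_net)
  hubs <- rank_hubs(metrics, "degree", top_n = 20)
  write_table_tsv(metrics, p("node_metrics.tsv"))
  writeLines(hubs, p("hub_genes.txt"))
  note("metrics", "done", "clr_network.tsv",
       c("node_metrics.tsv", "hub_genes.txt"),
       sprintf("nodes=%d max_degree=%d", nrow(metrics),
               if (nrow(metrics)) max(metrics$degree) else 0L))

  ## --- known-interaction overlay (optional) ---------------------------
  if (!is.null(cfg$paths$interaction_table) &&
      !is.null(cfg$paths$homology_map)) {
    tab <- read_interaction_table(cfg$paths$interaction_table)
    hmap <- read_table_tsv(cfg$paths$homology_map)
    overlay <- overlay_known_interactions(tab, across$table$gene, hmap)
    export_network(overlay, p("overlay_network.tsv"), "edge-tsv")
    note("overlay", "done",
         c(cfg$paths$interaction_table, cfg$paths$homology_map),
         "overlay_network.tsv",
         sprintf("edges=%d", nrow(overlay$edges)))
  } else {
    note("overlay", "skipped", "", "", "no interaction table / homology map")
  }

  ## --- export ----------------------------------------------------------
  export_network(fit$network, p("ann_network.graphml"), "graphml")
  note("export", "done", "ann_network.tsv", "ann_network.graphml", "graphml")

  man <- do.call(rbind, manifest)
  man$seed <- seed
  write_table_tsv(man, p("manifest.tsv"))
  invisible(man)
}
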