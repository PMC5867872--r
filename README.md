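# nitronet

Inference of nitrogen-response gene regulatory networks from
multi-platform expression data.

## The problem

Nitrogen use efficiency (NUE) in crops is controlled by a transcriptional
network that responds to nitrogen availability. Identifying its regulators
from microarray experiments is hard for two reasons: different chip
platforms lack common probe identifiers, and single-gene differential
expression says nothing about which genes *drive* the response. `nitronet`
implements a complete desk-scale pipeline for this problem, aimed at
computational biologists working with cross-platform plant expression data:

1. **Cross-platform integration** — probes with unique genome hits are
   mapped to gene identifiers, collapsed to gene-level profiles, tested per
   genotype for differential expression between low and sufficient N
   (Welch *t*-test, |FC| ≥ 2, *p* ≤ 0.05), and integrated across genotypes
   and platforms into concordant-down / concordant-up / conflicted classes.
2. **Two-stage ANN network inference** — the package's core estimator
   (`ann_grn()`). Stage 1 trains, for every gene *g*, single-input
   feed-forward networks (1 input → 2 sigmoidal hidden units → linear
   output) to predict the sample phenotype *y* ∈ [0, 1] over 50 random
   train/test/validation reshuffles with early stopping, and ranks genes by
   mean held-out MSE. Stage 2 trains one network per top-ranked target
   *t* with the other *k* − 1 top genes as inputs; the signed influence of
   input *i* on *t* is

   w(i→t) = Σ_h W1[i,h] · w2[h],

   giving k(k−1) directed candidate edges (9 900 for k = 100). Weights are
   standardized to Z-scores over the candidate set and the strongest |Z|
   edges (top 200 by default) form the network; sign(w) distinguishes
   activation from repression.
3. **Co-expression and CLR networks** — Spearman co-expression (|ρ| > 0.8)
   and Context Likelihood of Relatedness on a histogram plug-in mutual
   information matrix: z_i = max(0, (MI_ij − μ_i)/σ_i) against each gene's
   background row, CLR(i,j) = √(z_i² + z_j²), with edges at CLR > 3.6, plus
   breadth-first seed-gene subnetwork extraction.
4. **Graph-theoretic hub analysis** — degree, Brandes betweenness and
   closeness; hub ranking; overlay of known interactions (BioGRID-style
   tables) through a many-to-many homology map; SIF/GraphML/TSV export.
5. **A planted-truth simulator** — every stage is validated against
   synthetic data in which the informative genes, the signed regulator →
   target edges and the platform structure are known
   (`generate_truth_network()`, `simulate_expression()`,
   `generate_platforms()`).

## Worked example

```r
library(nitronet)

truth  <- generate_truth_network(n_genes = 120, n_regulators = 4,
                                 targets_per_regulator = 4,
                                 repressor_fraction = 0.4, seed = 42,
                                 n_informative = 8)
design <- make_design(c("L1", "L2"), c("sufficient", "low"), "T1",
                      replicates = 10)
expr   <- simulate_expression(truth, design, noise_sd = 0.4, seed = 43)

de <- differential_expression(expr, design, fc_thresh = 2, alpha = 0.05)
head(de[de$status != "ns", c("gene", "log2FC", "linear_FC", "p_value", "status")], 4)
#>     gene    log2FC linear_FC      p_value status
#> 2  G0002  1.642680  3.122453 4.295834e-12     up
#> 6  G0006 -1.386995 -2.615334 1.972550e-11   down
#> 15 G0015 -1.932835 -3.818048 8.957131e-14   down
#> 21 G0021 -2.091230 -4.261113 6.360116e-14   down
```

`log2FC` is the difference of log2 group means (low − sufficient);
`linear_FC` is the signed linear fold change sign(log2FC)·2^|log2FC|, so
−3.8 means a 3.8-fold drop under low N. Fitting the two-stage ANN:

```r
fit <- ann_grn(expr, phenotype_vector(design)[colnames(expr)],
               ann_config(top_k = 25, edge_k = 60, n_reshuffles = 20, seed = 44))
fit
#> Two-stage ANN gene regulatory network
#>   stage 1: 120 genes ranked (20 reshuffles each)
#>   stage 2: 600 candidate edges among top 25 genes
#>   network: 60 edges retained by |Z| (7 activating, 53 repressing)

summary(fit, n = 4)
#> Top-ranked genes (stage 1, mean held-out MSE):
#>    gene   mean_mse      sd_mse rank
#> 1 G0104 0.00901868 0.007641622    1
#> 2 G0098 0.01096357 0.006498027    2
#> ...
#> Strongest inferred interactions (stage 2, |Z|):
#>     from    to     score     weight sign
#> 16 G0030 G0075  5.493620  1.8986797    1
#> 39 G0066 G0075  3.980813  1.4166571    1
```

A low `mean_mse` means the gene's profile alone predicts the N treatment
well; the edge `score` is the weight's Z-score over all 600 candidates, and
`sign = -1` marks inferred repression. CLR and hub analysis on the
top-ranked genes:

```r
net <- clr_network(expr[fit$top_genes, ], cutoff = 3.6)
hubs <- rank_hubs(graph_metrics(net), "degree")
```

The whole pipeline (simulate → collapse → DE → integrate → ANN → CLR →
subnetwork → metrics → export) runs from one config with one seed and
writes a provenance manifest:

```r
man <- run_pipeline(default_pipeline_config("out_dir", seed = 1))
```

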