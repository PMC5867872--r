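## Two-stage neural-network gene ranking and signed interaction inference.
##
## Stage 1 trains, for every gene, a battery of single-input feed-forward
## networks (1 input -> `hidden_units` sigmoidal units -> 1 linear output) to
## predict the sample phenotype, over `n_reshuffles` random train/test/validation
## splits with early stopping, and ranks genes by mean held-out test MSE.
## Stage 2 trains, for every gene among the top-ranked `top_k`, one network with
## the other top_k - 1 genes as inputs; the signed influence of input i on
## target t is the sum over hidden units of W1[i,h] * w2[h]. The resulting
## top_k * (top_k - 1) candidate edges are standardized to Z-scores and the
## strongest |Z| edges retained.

#' Configuration for the two-stage ANN inference
#'
#' @param hidden_units sigmoidal hidden units (default 2)
#' @param learning_rate back-propagation step size (default 0.1; stage 2 scales
#'   it by 1/sqrt(n inputs) so multi-input updates stay stable)
#' @param momentum momentum coefficient (default 0.9)
#' @param max_epochs cap on training epochs (default 500)
#' @param patience early stopping: epochs without validation improvement
#'   (default 20)
#' @param split train/test/validation fractions, summing to 1 (default 60/20/20)
#' @param n_reshuffles random re-splits per gene in stage 1 (default 50)
#' @param top_k genes carried into stage 2 (default 100)
#' @param edge_k candidate edges retained after Z-score truncation (default 200)
#' @param stage2_restarts independent trainings averaged per stage-2 target
#'   (default 3; averaging stabilises the influence signs)
#' @param pairwise if `TRUE`, stage 2 trains one single-input model per ordered
#'   gene pair instead of one multi-input model per target
#' @param seed master seed; per-gene streams are derived from it so results are
#'   invariant to gene order
#' @return a list of class `ann_config`
#' @export
ann_config <- function(hidden_units = 2, learning_rate = 0.1, momentum = 0.9,
                       max_epochs = 500, patience = 20,
                       split = c(train = 0.6, test = 0.2, validation = 0.2),
                       n_reshuffles = 50, top_k = 100, edge_k = 200,
                       stage2_restarts = 3, pairwise = FALSE, seed = 1) {
  .assert(abs(sum(split) - 1) < 1e-8, "split fractions must sum to 1")
  .assert(hidden_units >= 1, "need at least one hidden unit")
  .assert(n_reshuffles >= 1, "n_reshuffles must be >= 1")
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), split = split,
                 n_reshuffles = as.integer(n_reshuffles),
                 top_k = as.integer(top_k), edge_k = as.integer(edge_k),
                 stage2_restarts = as.integer(stage2_restarts),
                 pairwise = isTRUE(pairwise), seed = as.integer(seed)),
            class = "ann_config")
}

#' Encode the treatment factor as a numeric phenotype
#'
#' @param design design data frame with `sample` and `treatment`
#' @param encoding named numeric vector mapping treatment to target value; the
#'   default places recovery midway between sufficient and low N
#' @return numeric vector named by sample id, values in \[0, 1\]
#' @export
phenotype_vector <- function(design,
                             encoding = c(sufficient = 1, low = 0, recovery = 0.5)) {
  bad <- setdiff(unique(design$treatment), names(encoding))
  .assert(length(bad) == 0,
          paste0("treatment(s) without encoding: ", paste(bad, collapse = ", ")))
  setNames(unname(encoding[design$treatment]), design$sample)
}

## row-wise standardization to zero mean / unit variance; constant rows -> 0
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  s[s == 0] <- 1
  (m - mu) / s
}

## Random train/test/validation split, stratified so that no subset loses an
## entire stratum when avoidable; consumes the current RNG stream.
stratified_split <- function(strata, fracs) {
  n <- length(strata)
  assign_vec <- integer(n)
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    cuts <- diff(round(cumsum(c(0, fracs)) * length(idx)))
    assign_vec[idx] <- rep.int(seq_along(fracs), cuts)
  }
  parts <- lapply(1:3, function(k) which(assign_vec == k))
  # guarantee every subset non-empty by stealing from the largest
  for (k in 1:3) {
    if (!length(parts[[k]])) {
      big <- which.max(lengths(parts))
      parts[[k]] <- parts[[big]][1]
      parts[[big]] <- parts[[big]][-1]
    }
  }
  names(parts) <- c("train", "test", "validation")
  parts
}

## number of weights for a p-input, H-hidden network
n_weights <- function(p, H) p * H + 2L * H + 1L

## draw initial weights on the current stream; input weights scaled by sqrt(p)
init_weights <- function(p, H) {
  w <- runif(n_weights(p, H), -0.5, 0.5)
  w[seq_len(p * H)] <- w[seq_len(p * H)] / sqrt(p)
  w
}

#' Stage 1: rank genes by single-input phenotype-prediction error
#'
#' @param expr gene x sample log2 matrix (rows standardized internally)
#' @param phenotype numeric phenotype per sample, aligned to `expr` columns
#'   (see [phenotype_vector()])
#' @param cfg an [ann_config()]
#' @return data frame of class `gene_ranking` with columns `gene`, `mean_mse`,
#'   `sd_mse`, `rank` (1 = best; ties broken by gene id), sorted by rank
#' @export
rank_genes_stage1 <- function(expr, phenotype, cfg = ann_config()) {
  n <- ncol(expr)
  .assert(n >= 10, "stage 1 needs at least 10 samples")
  .assert(length(phenotype) == n, "phenotype must align to expression columns")
  strata <- as.character(phenotype)
  xs <- standardize_rows(expr)
  H <- cfg$hidden_units
  genes <- rownames(expr)
  res <- vapply(genes, function(g) {
    X <- matrix(xs[g, ], ncol = 1)
    with_seed(stream_seed(cfg$seed, "stage1", g), {
      mses <- vapply(seq_len(cfg$n_reshuffles), function(r) {
        sp <- stratified_split(strata, cfg$split)
        w0 <- init_weights(1L, H)
        fit <- mlp_train_cpp(X, phenotype, sp$train, sp$validation, w0, H,
                             cfg$learning_rate, cfg$momentum, cfg$max_epochs,
                             cfg$patience)
        pred <- mlp_predict_cpp(X, fit$weights, H)
        mean((pred[sp$test] - phenotype[sp$test])^2)
      }, numeric(1))
      c(mean(mses), sd(mses))
    })
  }, numeric(2))
  out <- data.frame(gene = genes, mean_mse = res[1, ], sd_mse = res[2, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$mean_mse, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("gene_ranking", "data.frame")
  out
}

## train one stage-2 model and return the per-input signed influence vector
stage2_influence <- function(X, y, strata, cfg) {
  p <- ncol(X)
  H <- cfg$hidden_units
  lr <- cfg$learning_rate / sqrt(p)
  infl <- matrix(0, cfg$stage2_restarts, p)
  for (r in seq_len(cfg$stage2_restarts)) {
    sp <- stratified_split(strata, cfg$split)
    w0 <- init_weights(p, H)
    fit <- mlp_train_cpp(X, y, sp$train, sp$validation, w0, H, lr,
                         cfg$momentum, cfg$max_epochs, cfg$patience)
    w <- fit$weights
    W1 <- matrix(w[seq_len(p * H)], p, H)
    w2 <- w[(p * H + H + 1):(p * H + 2 * H)]
    infl[r, ] <- as.vector(W1 %*% w2)
  }
  colMeans(infl)
}

#' Stage 2: infer signed candidate interactions among the top-ranked genes
#'
#' One network per target gene, with the remaining genes as inputs; the signed
#' influence of input i on target t is the hidden-layer weight-product sum.
#' With `cfg$pairwise = TRUE` each ordered pair instead gets its own
#' single-input model. Enumerates all `top_k * (top_k - 1)` directed candidate
#' edges.
#'
#' @param expr_top expression matrix restricted to the stage-1 top genes
#'   (exactly `cfg$top_k` rows when used within [ann_grn()])
#' @param cfg an [ann_config()]
#' @param strata optional character vector per sample used to stratify splits
#'   (e.g. the treatment); unstratified when `NULL`
#' @return data frame with columns `source`, `target`, `weight`
#' @export
infer_interactions_stage2 <- function(expr_top, cfg = ann_config(),
                                      strata = NULL) {
  k <- nrow(expr_top)
  .assert(k >= 2, "stage 2 needs at least 2 genes")
  genes <- rownames(expr_top)
  xs <- standardize_rows(expr_top)
  if (is.null(strata)) strata <- rep("all", ncol(expr_top))
  edges <- vector("list", k)
  for (t_i in seq_len(k)) {
    tgt <- genes[t_i]
    inputs <- genes[-t_i]
    y <- xs[t_i, ]
    infl <- with_seed(stream_seed(cfg$seed, "stage2", tgt), {
      if (cfg$pairwise) {
        vapply(inputs, function(src) {
          X <- matrix(xs[src, ], ncol = 1)
          stage2_influence(X, y, strata, cfg)
        }, numeric(1))
      } else {
        X <- t(xs[-t_i, , drop = FALSE])
        stage2_influence(X, y, strata, cfg)
      }
    })
    edges[[t_i]] <- data.frame(source = inputs, target = tgt,
                               weight = as.numeric(infl),
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

#' Standardize candidate edge weights to Z-scores
#'
#' Z = (weight - mean) / sd over the full candidate set, with the population
#' (divide-by-n) sd; a degenerate sd of 0 maps every Z to 0. Adds `z_score`
#' and `sign` columns.
#'
#' @param edges data frame with a `weight` column
#' @return `edges` with `z_score` and `sign` added
#' @export
zscore_edges <- function(edges) {
  .assert(nrow(edges) >= 2, "need at least 2 edges to standardize")
  w <- edges$weight
  mu <- mean(w)
  s <- sqrt(mean((w - mu)^2))
  edges$z_score <- if (s > 0) (w - mu) / s else rep(0, length(w))
  edges$sign <- ifelse(edges$weight >= 0, 1L, -1L)
  edges
}

#' Keep the strongest candidate edges by |Z|
#'
#' @param edges data frame with `z_score` (see [zscore_edges()])
#' @param edge_k number of edges retained (default 200); ties in |Z| broken by
#'   (source, target) lexicographic order
#' @return the retained edges as a directed `gene_network` (scores = z)
#' @export
truncate_top_edges <- function(edges, edge_k = 200) {
  .assert(edge_k >= 1, "edge_k must be >= 1")
  ord <- order(-abs(edges$z_score), edges$source, edges$target)
  kept <- edges[head(ord, edge_k), , drop = FALSE]
  gene_network(data.frame(from = kept$source, to = kept$target,
                          score = kept$z_score, weight = kept$weight,
                          sign = kept$sign, stringsAsFactors = FALSE),
               directed = TRUE)
}

#' Fit the two-stage ANN gene regulatory network
#'
#' The package's central estimator: stage-1 ranking of every gene by
#' cross-validated single-input phenotype-prediction MSE, stage-2 signed
#' interaction inference among the `top_k` best-ranked genes, Z-score
#' standardization of the candidate edges and truncation to the strongest
#' `edge_k`.
#'
#' @param expr gene x sample log2 expression matrix
#' @param phenotype numeric phenotype per sample (see [phenotype_vector()])
#' @param config an [ann_config()]
#' @param strata optional per-sample stratification labels for the random
#'   splits (defaults to the distinct phenotype values)
#' @return an object of class `ann_grn`: list with `ranking` (stage-1
#'   `gene_ranking`), `top_genes`, `edges` (all candidates with weights and
#'   Z-scores), `network` (directed `gene_network` of the retained edges) and
#'   `config`
#' @seealso [rank_genes_stage1()], [infer_interactions_stage2()],
#'   [run_tf_subset()]
#' @export
ann_grn <- function(expr, phenotype, config = ann_config(), strata = NULL) {
  .assert(config$top_k <= nrow(expr), "top_k exceeds the number of genes")
  if (is.null(strata)) strata <- as.character(phenotype)
  ranking <- rank_genes_stage1(expr, phenotype, config)
  top_genes <- ranking$gene[seq_len(config$top_k)]
  edges <- infer_interactions_stage2(expr[top_genes, , drop = FALSE], config,
                                     strata = strata)
  edges <- zscore_edges(edges)
  edge_k <- min(config$edge_k, nrow(edges))
  net <- truncate_top_edges(edges, edge_k)
  structure(list(ranking = ranking, top_genes = top_genes, edges = edges,
                 network = net, config = config, call = match.call()),
            class = "ann_grn")
}

#' @export
print.ann_grn <- function(x, ...) {
  cat("Two-stage ANN gene regulatory network\n")
  cat(sprintf("  stage 1: %d genes ranked (%d reshuffles each)\n",
              nrow(x$ranking), x$config$n_reshuffles))
  cat(sprintf("  stage 2: %d candidate edges among top %d genes\n",
              nrow(x$edges), x$config$top_k))
  cat(sprintf("  network: %d edges retained by |Z| (%d activating, %d repressing)\n",
              nrow(x$network$edges), sum(x$network$edges$sign > 0),
              sum(x$network$edges$sign < 0)))
  invisible(x)
}

#' @export
summary.ann_grn <- function(object, n = 10, ...) {
  cat("Top-ranked genes (stage 1, mean held-out MSE):\n")
  print(head(object$ranking, n))
  cat("\nStrongest inferred interactions (stage 2, |Z|):\n")
  ed <- object$network$edges
  print(head(ed[order(-abs(ed$score)), ], n))
  invisible(object)
}

#' @export
coef.ann_grn <- function(object, all = FALSE, ...) {
  if (all) object$edges else object$network$edges
}

#' @export
plot.ann_grn <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  hist(x$edges$z_score, breaks = 40, main = "Candidate edge Z-scores",
       xlab = "Z", col = "grey80", border = "white")
  plot(x$ranking$rank, x$ranking$mean_mse, pch = 20, cex = 0.5,
       xlab = "rank", ylab = "mean test MSE", main = "Stage-1 gene ranking")
  invisible(x)
}

#' Run the two-stage inference on a transcription-factor subset
#'
#' Restricts the expression matrix to the supplied TF list (unknown ids are
#' dropped with a warning) and runs stage 1 + stage 2 on that subset, with
#' `top_k` capped at the subset size.
#'
#' @param expr gene x sample log2 matrix
#' @param tf_list character vector of TF gene ids
#' @param phenotype numeric phenotype per sample
#' @param cfg an [ann_config()]
#' @return an `ann_grn` object fitted on the TF subset
#' @export
run_tf_subset <- function(expr, tf_list, phenotype, cfg = ann_config()) {
  known <- intersect(tf_list, rownames(expr))
  .assert(length(known) > 0, "no TF id matches the expression rows")
  missing <- setdiff(tf_list, rownames(expr))
  if (length(missing)) {
    warning(sprintf("%d TF id(s) not in the expression matrix; ignored: %s",
                    length(missing),
                    paste(head(missing, 5), collapse = ", ")))
  }
  cfg$top_k <- min(cfg$top_k, length(known))
  ann_grn(expr[known, , drop = FALSE], phenotype, cfg)
}
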