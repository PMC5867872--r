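## Probe -> gene collapse, per-genotype differential expression, and
## cross-genotype / cross-platform integration into concordance classes.

#' Retain only probes with a unique genome hit
#'
#' @param raw_map data frame with columns `probe`, `gene`, `n_hits`
#' @return the subset with `n_hits == 1`, original order preserved
#' @export
filter_unique_probes <- function(raw_map) {
  out <- raw_map[raw_map$n_hits == 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse a probe-level matrix to gene level
#'
#' @param expr probe x sample log2 matrix
#' @param map unique-filtered probe map (`probe`, `gene`, `n_hits` all 1)
#' @param method `"mean"` (arithmetic mean of a gene's probes, default) or
#'   `"max-variance-probe"` (the single most variable probe represents the gene)
#' @return gene x sample matrix; probes absent from the map are dropped
#' @export
collapse_probes_to_genes <- function(expr, map,
                                     method = c("mean", "max-variance-probe")) {
  method <- match.arg(method)
  .assert(all(map$n_hits == 1), "map must be unique-filtered (all n_hits == 1)")
  map <- map[map$probe %in% rownames(expr), , drop = FALSE]
  if (nrow(map) == 0) {
    warning("no probe of `expr` is present in `map`; empty result")
    return(expr[integer(0), , drop = FALSE])
  }
  sub <- expr[map$probe, , drop = FALSE]
  if (method == "mean") {
    out <- rowsum(sub, group = map$gene, reorder = TRUE)
    out <- out / as.vector(table(map$gene)[rownames(out)])
  } else {
    v <- apply(sub, 1, var)
    pick <- vapply(split(seq_len(nrow(map)), map$gene), function(idx) {
      idx[which.max(v[idx])]
    }, integer(1))
    out <- sub[pick, , drop = FALSE]
    rownames(out) <- names(pick)
    out <- out[order(rownames(out)), , drop = FALSE]
  }
  out
}

#' Per-gene differential expression (Welch t-test + fold-change filter)
#'
#' For each gene, a Welch two-sample t-test of log2 values between the
#' alternative and reference treatment groups. `log2FC = mean(alt) - mean(ref)`
#' and the signed linear fold change is `sign(log2FC) * 2^|log2FC|`. A gene is
#' `down` iff `log2FC <= -log2(fc_thresh)` and `p <= alpha`, `up` symmetric,
#' otherwise `ns`. Group variances are floored at 1e-8 so zero-variance genes
#' keep a finite t (equal-mean, zero-variance genes get p = 1).
#'
#' @param expr gene x sample log2 matrix
#' @param design design data frame matching the columns of `expr`
#' @param contrast length-2 character vector `c(alt, ref)` of treatment labels
#'   (default low vs sufficient)
#' @param fc_thresh linear fold-change threshold (default 2, i.e. |log2FC| >= 1)
#' @param alpha p-value threshold (inclusive, default 0.05)
#' @param adjust `"none"` (default; raw p) or `"BH"` for Benjamini-Hochberg
#' @return data frame of class `de_table` with columns `gene`, `mean_ref`,
#'   `mean_alt`, `log2FC`, `linear_FC`, `t_statistic`, `p_value`, `status`
#' @export
differential_expression <- function(expr, design,
                                    contrast = c("low", "sufficient"),
                                    fc_thresh = 2, alpha = 0.05,
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  design <- design[match(colnames(expr), design$sample), , drop = FALSE]
  .assert(!anyNA(design$sample), "every expression column needs a design row")
  alt_idx <- which(design$treatment == contrast[1])
  ref_idx <- which(design$treatment == contrast[2])
  .assert(length(alt_idx) >= 2 && length(ref_idx) >= 2,
          "each contrast group needs at least 2 samples")
  xa <- expr[, alt_idx, drop = FALSE]
  xr <- expr[, ref_idx, drop = FALSE]
  na <- ncol(xa); nr <- ncol(xr)
  ma <- rowMeans(xa); mr <- rowMeans(xr)
  va <- pmax(apply(xa, 1, var), 1e-8)
  vr <- pmax(apply(xr, 1, var), 1e-8)
  se2 <- va / na + vr / nr
  tstat <- (ma - mr) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vr / nr)^2 / (nr - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  if (adjust == "BH") p <- p.adjust(p, method = "BH")
  l2fc <- ma - mr
  lin <- ifelse(l2fc < 0, -1, 1) * 2^abs(l2fc)
  thr <- log2(fc_thresh)
  status <- rep("ns", length(l2fc))
  status[l2fc <= -thr & p <= alpha] <- "down"
  status[l2fc >= thr & p <= alpha] <- "up"
  out <- data.frame(gene = rownames(expr), mean_ref = mr, mean_alt = ma,
                    log2FC = l2fc, linear_FC = lin, t_statistic = tstat,
                    p_value = p, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Integrate DE calls across the genotypes of one study
#'
#' A gene is retained iff it is differentially expressed (non-`ns`) in every
#' genotype's table. Its per-genotype directions are recorded; a retained gene
#' whose directions disagree is flagged `mixed`.
#'
#' @param tables named list of `de_table`s, one per genotype
#' @return data frame with columns `gene`, `direction`
#'   (`down`/`up`/`mixed`) and `directions` (comma-separated per-genotype calls)
#' @export
integrate_within_study <- function(tables) {
  .assert(length(tables) >= 1, "need at least one DE table")
  de_sets <- lapply(tables, function(t) t$gene[t$status != "ns"])
  common <- Reduce(intersect, de_sets)
  if (!length(common)) {
    return(data.frame(gene = character(), direction = character(),
                      directions = character(), stringsAsFactors = FALSE))
  }
  dir_mat <- vapply(tables, function(t) {
    setNames(t$status, t$gene)[common]
  }, character(length(common)))
  dir_mat <- matrix(dir_mat, nrow = length(common))
  direction <- apply(dir_mat, 1, function(d) {
    if (all(d == "down")) "down" else if (all(d == "up")) "up" else "mixed"
  })
  out <- data.frame(gene = common, direction = direction,
                    directions = apply(dir_mat, 1, paste, collapse = ","),
                    stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}

#' Integrate two studies' direction summaries into concordance classes
#'
#' On the intersection of the two gene sets, a gene is `concordant_down` iff
#' every direction in both studies is down, `concordant_up` symmetric, and
#' `conflicted` otherwise (including within-study mixed calls). The three
#' classes partition the common set.
#'
#' @param a,b outputs of [integrate_within_study()]
#' @return object of class `integration_result`: list with `table` (gene,
#'   direction_a, direction_b, class) and `counts` (n_common, n_down, n_up,
#'   n_conflicted)
#' @export
integrate_across_studies <- function(a, b) {
  common <- sort(intersect(a$gene, b$gene))
  da <- setNames(a$direction, a$gene)[common]
  db <- setNames(b$direction, b$gene)[common]
  cls <- ifelse(da == "down" & db == "down", "concordant_down",
         ifelse(da == "up" & db == "up", "concordant_up", "conflicted"))
  tab <- data.frame(gene = common, direction_a = unname(da),
                    direction_b = unname(db), class = unname(cls),
                    stringsAsFactors = FALSE)
  counts <- c(n_common = length(common),
              n_down = sum(cls == "concordant_down"),
              n_up = sum(cls == "concordant_up"),
              n_conflicted = sum(cls == "conflicted"))
  structure(list(table = tab, counts = counts), class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("integration_result: %d common genes (%d down, %d up, %d conflicted)\n",
              x$counts["n_common"], x$counts["n_down"], x$counts["n_up"],
              x$counts["n_conflicted"]))
  invisible(x)
}

#' Tabulate genes by functional category
#'
#' @param genes character vector of gene ids
#' @param category_map named character vector (gene -> category) or a data
#'   frame with columns `gene`, `category`
#' @return data frame `category`, `count`; genes missing from the map are
#'   counted under `unannotated`
#' @export
tabulate_categories <- function(genes, category_map) {
  if (is.data.frame(category_map)) {
    category_map <- setNames(category_map$category, category_map$gene)
  }
  if (!length(genes)) {
    return(data.frame(category = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  cats <- category_map[genes]
  cats[is.na(cats)] <- "unannotated"
  tt <- table(cats)
  data.frame(category = names(tt), count = as.integer(tt),
             stringsAsFactors = FALSE, row.names = NULL)
}
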