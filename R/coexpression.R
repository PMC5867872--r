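## Correlation and CLR mutual-information networks, seed-gene subnetworks.

#' Build a correlation co-expression network
#'
#' Undirected edge (i, j) iff |rho_ij| > cutoff; the edge sign is the sign of
#' the correlation. Genes with zero variance have undefined correlation and
#' produce no edges.
#'
#' @param expr gene x sample matrix
#' @param method correlation method (default `"spearman"`)
#' @param cutoff absolute-correlation threshold, strict (default 0.8)
#' @return an undirected `gene_network` with edge `score` = rho
#' @export
correlation_network <- function(expr, method = c("spearman", "pearson"),
                                cutoff = 0.8) {
  method <- match.arg(method)
  .assert(ncol(expr) >= 3, "need at least 3 samples")
  cc <- suppressWarnings(cor(t(expr), method = method))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  idx <- which(abs(cc) > cutoff & upper.tri(cc), arr.ind = TRUE)
  edges <- data.frame(from = rownames(cc)[idx[, 1]],
                      to = colnames(cc)[idx[, 2]],
                      score = cc[idx],
                      sign = ifelse(cc[idx] >= 0, 1L, -1L),
                      stringsAsFactors = FALSE)
  gene_network(edges, nodes = data.frame(id = rownames(expr),
                                         stringsAsFactors = FALSE),
               directed = FALSE)
}

## per-gene equal-width bin codes in 1..n_bins; constant genes land in bin 1
bin_rows <- function(expr, n_bins) {
  t(apply(expr, 1, function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(1L, length(x)))
    b <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
    pmin(b, n_bins)
  }))
}

default_bins <- function(n_samples) max(3L, min(10L, ceiling(sqrt(n_samples))))

#' Plug-in mutual information matrix
#'
#' Pairwise mutual information in nats from a 2-D equal-width histogram with
#' `n_bins` bins per axis. The diagonal holds each gene's MI with itself (its
#' plug-in entropy, which bounds every off-diagonal entry of the row).
#'
#' @param expr gene x sample matrix
#' @param n_bins bins per axis; default `ceiling(sqrt(n_samples))` clipped to
#'   \[3, 10\]
#' @return symmetric gene x gene matrix of MI values (nats)
#' @export
mutual_information_matrix <- function(expr, n_bins = NULL) {
  n <- ncol(expr)
  if (is.null(n_bins)) n_bins <- default_bins(n)
  .assert(n_bins >= 2, "n_bins must be >= 2")
  .assert(n >= n_bins, "need at least n_bins samples")
  B <- bin_rows(expr, n_bins)
  g <- nrow(expr)
  marg <- lapply(seq_len(g), function(i) tabulate(B[i, ], n_bins) / n)
  hx <- vapply(marg, function(p) -sum(p[p > 0] * log(p[p > 0])), numeric(1))
  mi <- matrix(0, g, g, dimnames = list(rownames(expr), rownames(expr)))
  for (i in seq_len(g)) {
    mi[i, i] <- hx[i]
    if (i == g) next
    for (j in (i + 1):g) {
      joint <- tabulate((B[i, ] - 1L) * n_bins + B[j, ], n_bins * n_bins) / n
      pij <- joint[joint > 0]
      hxy <- -sum(pij * log(pij))
      v <- hx[i] + hx[j] - hxy
      mi[i, j] <- v
      mi[j, i] <- v
    }
  }
  mi
}

#' Context likelihood of relatedness (CLR) scores
#'
#' Each MI value is standardized against the background MI distribution of both
#' of its genes: `z_i(i,j) = max(0, (MI_ij - mu_i) / sd_i)` over row i with the
#' diagonal excluded, and `CLR(i,j) = sqrt(z_i^2 + z_j^2)`. Rows with zero
#' background sd contribute z = 0.
#'
#' @param mi symmetric non-negative MI matrix (see
#'   [mutual_information_matrix()])
#' @return symmetric matrix of CLR scores (diagonal 0)
#' @export
clr_scores <- function(mi) {
  g <- nrow(mi)
  off <- mi
  diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sdv <- apply(off, 1, sd, na.rm = TRUE)
  sdv[is.na(sdv)] <- 0
  z <- (mi - mu) / ifelse(sdv > 0, sdv, Inf)
  z[z < 0] <- 0
  clr <- sqrt(z^2 + t(z)^2)
  diag(clr) <- 0
  dimnames(clr) <- dimnames(mi)
  clr
}

#' CLR mutual-information network
#'
#' @param expr gene x sample matrix
#' @param cutoff CLR score threshold, strict (default 3.6)
#' @param n_bins passed to [mutual_information_matrix()]
#' @return an undirected `gene_network` with edge `score` = CLR
#' @export
clr_network <- function(expr, cutoff = 3.6, n_bins = NULL) {
  clr <- clr_scores(mutual_information_matrix(expr, n_bins))
  idx <- which(clr > cutoff & upper.tri(clr), arr.ind = TRUE)
  edges <- data.frame(from = rownames(clr)[idx[, 1]],
                      to = colnames(clr)[idx[, 2]],
                      score = clr[idx], stringsAsFactors = FALSE)
  gene_network(edges, nodes = data.frame(id = rownames(expr),
                                         stringsAsFactors = FALSE),
               directed = FALSE)
}

#' Extract the subnetwork around seed genes
#'
#' Induced subgraph on the breadth-first ball of radius `hops` around the seed
#' set. Seeds absent from the network are kept as isolated nodes flagged
#' `missing`.
#'
#' @param net a `gene_network`
#' @param seeds character vector of seed gene ids (non-empty)
#' @param hops neighborhood radius (0 = seeds only)
#' @return a `gene_network`; node attributes `is_seed` and `missing`
#' @export
extract_seed_subnetwork <- function(net, seeds, hops = 1) {
  .assert(length(seeds) > 0, "seed list must be non-empty")
  .assert(hops >= 0, "hops must be >= 0")
  present <- intersect(seeds, net$nodes$id)
  absent <- setdiff(seeds, net$nodes$id)
  keep <- character()
  if (length(present)) {
    g <- as_igraph(net)
    ball <- igraph::ego(g, order = hops, nodes = present,
                        mode = if (net$directed) "all" else "all")
    keep <- unique(unlist(lapply(ball, function(v) igraph::V(g)$name[v])))
  }
  nodes <- net$nodes[net$nodes$id %in% keep, , drop = FALSE]
  if (length(absent)) {
    add <- as.data.frame(lapply(nodes, function(col) rep(NA, length(absent))),
                         stringsAsFactors = FALSE)
    names(add) <- names(nodes)
    add$id <- absent
    nodes <- rbind(nodes, add)
  }
  nodes$is_seed <- nodes$id %in% seeds
  nodes$missing <- nodes$id %in% absent
  edges <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, ,
                     drop = FALSE]
  gene_network(edges, nodes, directed = net$directed)
}
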