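## Network container, graph metrics, known-interaction overlay, export.

#' Construct a gene network
#'
#' Lightweight container used by every inference stage. Undirected edges are
#' stored canonically (endpoint pair sorted lexicographically) and de-duplicated;
#' self-loops are dropped. Node attributes beyond `id` are free-form columns.
#'
#' @param edges data frame with columns `from`, `to` and optionally `score`,
#'   `sign` (+1/-1) and others
#' @param nodes data frame with an `id` column, or `NULL` to derive nodes from
#'   the edge endpoints
#' @param directed logical; directed edges are kept as given
#' @return an object of class `gene_network` with elements `nodes`, `edges`,
#'   `directed`
#' @export
gene_network <- function(edges = NULL, nodes = NULL, directed = FALSE) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (!directed && nrow(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ,
                   drop = FALSE]
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(nodes)) {
    nodes <- data.frame(id = sort(unique(c(edges$from, edges$to))),
                        stringsAsFactors = FALSE)
  } else {
    nodes$id <- as.character(nodes$id)
    extra <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
    if (length(extra)) {
      add <- nodes[rep(NA_integer_, length(extra)), , drop = FALSE]
      add$id <- extra
      nodes <- rbind(nodes, add)
    }
    nodes <- nodes[order(nodes$id), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, directed = directed),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d %s edges\n",
              nrow(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  if (nrow(x$edges)) {
    cat("first edges:\n")
    print(head(x$edges, 5L))
  }
  invisible(x)
}

#' Convert a gene network to an igraph graph
#' @param net a `gene_network`
#' @return an igraph graph with all node/edge attributes carried over
#' @export
as_igraph <- function(net) {
  .assert(inherits(net, "gene_network"), "`net` must be a gene_network")
  igraph::graph_from_data_frame(net$edges, directed = net$directed,
                                vertices = net$nodes)
}

#' Node centrality metrics
#'
#' Degree, unnormalized shortest-path betweenness (fractional credit among tied
#' geodesics) and closeness on the undirected simple graph. Closeness of an
#' isolated node is defined as 0; in a disconnected graph closeness is computed
#' over each node's reachable set.
#'
#' @param net a `gene_network`
#' @return data frame with columns `id`, `degree`, `betweenness`, `closeness`
#' @export
graph_metrics <- function(net) {
  g <- as_igraph(net)
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  cls <- suppressWarnings(igraph::closeness(g, mode = "all"))
  cls[!is.finite(cls)] <- 0
  cls[deg == 0] <- 0
  data.frame(id = igraph::V(g)$name, degree = as.numeric(deg),
             betweenness = as.numeric(btw), closeness = as.numeric(cls),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank hub genes by a centrality metric
#'
#' @param metrics data frame from [graph_metrics()]
#' @param key one of `"degree"`, `"betweenness"`, `"closeness"`
#' @param top_n optional truncation of the ranked list
#' @return character vector of node ids, descending by `key`, ties broken by
#'   lexicographic node id
#' @export
rank_hubs <- function(metrics, key = c("degree", "betweenness", "closeness"),
                      top_n = NULL) {
  key <- match.arg(key)
  ord <- order(-metrics[[key]], metrics$id)
  ids <- metrics$id[ord]
  if (!is.null(top_n)) ids <- head(ids, top_n)
  ids
}

#' Read a known-interaction table
#'
#' Accepts either a minimal 3-column TSV (`a`, `b`, `evidence`; header optional
#' names ignored) or an official BioGRID TAB 2.0 export, from which the
#' "Official Symbol Interactor A/B" columns are selected by name. Duplicate
#' records are collapsed.
#'
#' @param path TSV file path
#' @return data frame with columns `a`, `b`, `evidence`
#' @export
read_interaction_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   quote = "", comment.char = "", stringsAsFactors = FALSE)
  cn <- names(df)
  sym_a <- grep("Official Symbol Interactor A", cn, fixed = TRUE)
  sym_b <- grep("Official Symbol Interactor B", cn, fixed = TRUE)
  if (length(sym_a) == 1 && length(sym_b) == 1) {
    ev <- if ("Experimental System" %in% cn) df[["Experimental System"]] else "biogrid"
    out <- data.frame(a = df[[sym_a]], b = df[[sym_b]], evidence = ev,
                      stringsAsFactors = FALSE)
  } else {
    .assert(ncol(df) >= 2, "interaction table needs at least two columns")
    out <- data.frame(a = as.character(df[[1]]), b = as.character(df[[2]]),
                      evidence = if (ncol(df) >= 3) as.character(df[[3]]) else "known",
                      stringsAsFactors = FALSE)
  }
  out <- out[nzchar(out$a) & nzchar(out$b), , drop = FALSE]
  out[!duplicated(out[c("a", "b", "evidence")]), , drop = FALSE]
}

#' Overlay query genes on a known-interaction table via a homology map
#'
#' Query gene ids are translated through a many-to-many homology map (one query
#' gene may contribute several homologs); every interaction record with at
#' least one endpoint in the translated set is retained, testing both endpoint
#' columns symmetrically. Node attributes record the back-mapping from homolog
#' to query gene(s) and, if supplied, each query gene's DE status.
#'
#' @param table data frame of known interactions (`a`, `b`, `evidence`), e.g.
#'   from [read_interaction_table()]
#' @param query_genes character vector of query gene ids
#' @param map homology map data frame with columns `source`, `homolog`
#' @param de_status optional named vector: DE status per query gene
#' @return an undirected `gene_network`; empty (with a warning) if no query
#'   gene translates
#' @export
overlay_known_interactions <- function(table, query_genes, map,
                                       de_status = NULL) {
  map <- map[!duplicated(map[c("source", "homolog")]), , drop = FALSE]
  hit <- map[map$source %in% query_genes, , drop = FALSE]
  translated <- unique(hit$homolog)
  if (!length(translated)) {
    warning("no query gene has a homolog in the map; empty overlay")
    return(gene_network())
  }
  keep <- table$a %in% translated | table$b %in% translated
  edges <- table[keep, , drop = FALSE]
  if (!nrow(edges)) {
    warning("translated genes touch no interaction record; empty overlay")
    return(gene_network())
  }
  edges <- data.frame(from = edges$a, to = edges$b, evidence = edges$evidence,
                      stringsAsFactors = FALSE)
  ids <- sort(unique(c(edges$from, edges$to)))
  back <- vapply(ids, function(h) {
    paste(sort(unique(hit$source[hit$homolog == h])), collapse = ",")
  }, FUN.VALUE = "")
  nodes <- data.frame(id = ids, query_gene = unname(back),
                      is_query_homolog = ids %in% translated,
                      stringsAsFactors = FALSE)
  if (!is.null(de_status)) {
    st <- vapply(nodes$query_gene, function(q) {
      qs <- strsplit(q, ",", fixed = TRUE)[[1]]
      qs <- qs[qs %in% names(de_status)]
      if (length(qs)) paste(unique(de_status[qs]), collapse = ",") else ""
    }, "")
    nodes$de_status <- unname(st)
  }
  gene_network(edges, nodes, directed = FALSE)
}

#' Export a network to SIF, GraphML or edge TSV
#'
#' SIF lines are `source<TAB>relation<TAB>target` with relation `pos`/`neg`
#' from the edge sign (or `assoc` when unsigned). GraphML export (via igraph)
#' carries node and edge attributes. `edge-tsv` writes the edge table with a
#' header and round-trips through [read_network_tsv()].
#'
#' @param net a `gene_network`
#' @param path output file path
#' @param format one of `"sif"`, `"graphml"`, `"edge-tsv"`
#' @return `path`, invisibly
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "edge-tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    rel <- if ("sign" %in% names(net$edges)) {
      ifelse(net$edges$sign >= 0, "pos", "neg")
    } else {
      rep("assoc", nrow(net$edges))
    }
    lines <- if (nrow(net$edges)) {
      paste(net$edges$from, rel, net$edges$to, sep = "\t")
    } else {
      character()
    }
    writeLines(lines, path)
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    write_table_tsv(net$edges, path)
  }
  invisible(path)
}

#' Read an edge TSV written by [export_network()] back into a network
#' @param path edge TSV path
#' @param directed logical, as originally exported
#' @return a `gene_network`
#' @export
read_network_tsv <- function(path, directed = FALSE) {
  df <- read_table_tsv(path)
  gene_network(df, directed = directed)
}
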