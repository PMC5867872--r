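# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# plug-in MI (nats) via an explicit joint table and the p*log(p/(px*py)) sum
oracle_bin <- function(x, n_bins) {
  if (min(x) == max(x)) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
                 include.lowest = TRUE))
}

oracle_mi <- function(x, y, n_bins) {
  bx <- factor(oracle_bin(x, n_bins), levels = 1:n_bins)
  by <- factor(oracle_bin(y, n_bins), levels = 1:n_bins)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  s <- 0
  for (i in 1:n_bins) {
    for (j in 1:n_bins) {
      if (joint[i, j] > 0) {
        s <- s + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
      }
    }
  }
  as.numeric(s)
}

# two-loop CLR: row-wise clamped z combined Euclidean-wise
oracle_clr <- function(mi) {
  g <- nrow(mi)
  out <- matrix(0, g, g, dimnames = dimnames(mi))
  row_stats <- lapply(1:g, function(i) {
    v <- mi[i, -i]
    list(mu = mean(v), s = stats::sd(v))
  })
  for (i in 1:g) {
    for (j in 1:g) {
      if (i == j) next
      zi <- if (row_stats[[i]]$s > 0 && !is.na(row_stats[[i]]$s)) {
        max(0, (mi[i, j] - row_stats[[i]]$mu) / row_stats[[i]]$s)
      } else 0
      zj <- if (row_stats[[j]]$s > 0 && !is.na(row_stats[[j]]$s)) {
        max(0, (mi[j, i] - row_stats[[j]]$mu) / row_stats[[j]]$s)
      } else 0
      out[i, j] <- sqrt(zi^2 + zj^2)
    }
  }
  out
}

# all-pairs shortest-path betweenness by explicit BFS path counting
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  nb <- lapply(1:n, function(i) which(adj[i, ] > 0))
  bfs <- function(s) {
    d <- rep(Inf, n); sig <- rep(0, n)
    d[s] <- 0; sig[s] <- 1; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in nb[[v]]) {
        if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
        if (d[w] == d[v] + 1) sig[w] <- sig[w] + sig[v]
      }
    }
    list(d = d, sig = sig)
  }
  sp <- lapply(1:n, bfs)
  btw <- rep(0, n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(sp[[s]]$d[t])) next
      for (v in 1:n) {
        if (v != s && v != t &&
            sp[[s]]$d[v] + sp[[t]]$d[v] == sp[[s]]$d[t]) {
          btw[v] <- btw[v] + sp[[s]]$sig[v] * sp[[t]]$sig[v] / sp[[s]]$sig[t]
        }
      }
    }
  }
  btw
}

# BFS ball of radius `hops` around seeds, on an undirected edge list
oracle_bfs_ball <- function(edges, seeds, hops) {
  frontier <- seeds
  seen <- seeds
  for (h in seq_len(hops)) {
    nxt <- unique(c(edges$to[edges$from %in% frontier],
                    edges$from[edges$to %in% frontier]))
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
    if (!length(frontier)) break
  }
  sort(seen)
}

# per-gene concordance classifier over two direction summaries
oracle_classify <- function(da, db) {
  if (da == "down" && db == "down") "concordant_down"
  else if (da == "up" && db == "up") "concordant_up"
  else "conflicted"
}
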