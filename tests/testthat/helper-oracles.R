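# Brute-force oracles, independent of the package internals and of igraph:
# plain-R BFS, exhaustive shortest-path enumeration, pairwise AUROC
# counting, and precision-recall step walking. Deliberately slow and simple.

# Adjacency list (named list of character vectors) from a LinkGraph, via the
# public surface only.
oracle_adj <- function(g) {
  sapply(nodeNames(g), function(v) neighborSet(g, v), simplify = FALSE)
}

oracle_bfs_dist <- function(adj, s) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- character()
    for (x in frontier) {
      for (y in adj[[x]]) {
        if (is.infinite(dist[y])) {
          dist[y] <- dist[x] + 1
          nxt <- c(nxt, y)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# All shortest s-t paths, as a list of node vectors, by backward recursion
# over the BFS distance labels.
oracle_shortest_paths <- function(adj, dist_s, t) {
  if (is.infinite(dist_s[t])) return(list())
  walk <- function(x) {
    if (dist_s[x] == 0) return(list(x))
    preds <- adj[[x]][vapply(adj[[x]], function(y)
      dist_s[y] == dist_s[x] - 1, logical(1))]
    out <- list()
    for (p in preds)
      for (tail in walk(p)) out[[length(out) + 1L]] <- c(tail, x)
    out
  }
  walk(t)
}

# Unnormalized betweenness by literal path enumeration over unordered pairs.
oracle_betweenness <- function(g) {
  adj <- oracle_adj(g)
  nodes <- names(adj)
  b <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    dist_s <- oracle_bfs_dist(adj, nodes[i])
    for (j in seq_along(nodes)) {
      if (j <= i) next
      paths <- oracle_shortest_paths(adj, dist_s, nodes[j])
      if (length(paths) == 0L) next
      for (p in paths) {
        interior <- p[-c(1L, length(p))]
        b[interior] <- b[interior] + 1 / length(paths)
      }
    }
  }
  b
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

oracle_aupr <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(-scores, method = "radix")
  lab <- labels[ord]
  tp <- 0; precs <- numeric()
  for (r in seq_along(lab)) {
    if (lab[r]) {
      tp <- tp + 1
      precs <- c(precs, tp / r)
    }
  }
  mean(precs)
}

oracle_common_neighbors <- function(g, u, v) {
  adj <- oracle_adj(g)
  Filter(function(x) (x %in% adj[[u]]) && (x %in% adj[[v]]), names(adj))
}

# Small seeded random graph for property loops.
random_graph <- function(seed, n_max = 12L) {
  set.seed(seed)
  n <- sample(4:n_max, 1L)
  p <- runif(1, 0.2, 0.7)
  erdosRenyi(n, p, seed = seed * 7L + 1L)
}

toy <- toyGraph()
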