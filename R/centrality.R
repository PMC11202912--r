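.newCentrality <- function(kind, scores, convention = list()) {
  new("CentralityVector", kind = kind, scores = scores,
      convention = convention)
}

#' @rdname CentralityVector-class
#' @export
setMethod("centralityKind", "CentralityVector", function(x) x@kind)

#' @rdname CentralityVector-class
#' @export
setMethod("centralityScores", "CentralityVector", function(x) x@scores)

#' @rdname CentralityVector-class
#' @export
setMethod("convention", "CentralityVector", function(x) x@convention)

setMethod("show", "CentralityVector", function(object) {
  cat(sprintf("CentralityVector (%s) over %d nodes; mean %.6g\n",
              object@kind, length(object@scores), mean(object@scores)))
})

#' Degree centrality
#'
#' Degree divided by a denominator convention. The textbook normalization is
#' `N - 1`; the worked-example values this package reproduces (0.375 for a
#' degree-3 node of an 8-node graph, 0.625 for degree 5, graph average
#' 0.375) use `N`, which is therefore the default. SAC scores are provably
#' identical under either convention: scaling every score also scales the
#' graph average, leaving the threshold test unchanged.
#'
#' @param g a [LinkGraph-class].
#' @param denominator `"N"` (default) or `"N-1"`.
#' @return a [CentralityVector-class] of kind `"degree"`.
#' @examples
#' centralityScores(degreeCentrality(toyGraph()))[["4"]]  # 0.625
#' @export
degreeCentrality <- function(g, denominator = c("N", "N-1")) {
  denominator <- match.arg(denominator)
  n <- numNodes(g)
  if (denominator == "N-1" && n < 2L)
    stop("denominator N-1 requires at least two nodes", call. = FALSE)
  den <- if (denominator == "N") n else n - 1L
  .newCentrality("degree", lengths(g@adj) / den,
                 list(denominator = denominator))
}

#' Local clustering coefficient
#'
#' 2 K_v / (d_v (d_v - 1)) where K_v is the triangle count through v; nodes
#' of degree 0 or 1 (where the ratio is 0/0) score 0.
#'
#' @param g a [LinkGraph-class].
#' @return a [CentralityVector-class] of kind `"clustering"`.
#' @export
clusteringCoefficient <- function(g) {
  deg <- lengths(g@adj)
  k <- triangleCounts(g)
  cc <- ifelse(deg < 2L, 0, 2 * k / (deg * pmax(deg - 1L, 1L)))
  .newCentrality("clustering", stats::setNames(as.numeric(cc), g@nodes),
                 list(low_degree = "zero"))
}

#' Closeness centrality
#'
#' On a connected graph, (N - 1) divided by the sum of hop distances from v
#' to every other node. On disconnected graphs the reachable-set variant is
#' used: (R_v - 1) / sum(distances to reachable nodes), scaled by
#' (R_v - 1)/(N - 1), which reduces exactly to the connected-graph formula
#' when the graph is connected; isolated nodes score 0.
#'
#' @param g a [LinkGraph-class].
#' @return a [CentralityVector-class] of kind `"closeness"`.
#' @export
closenessCentrality <- function(g) {
  n <- numNodes(g)
  D <- igraph::distances(.asIgraph(g))
  scores <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0L) return(0)
    (r / sum(d[reach])) * (r / (n - 1L))
  }, numeric(1))
  .newCentrality("closeness", stats::setNames(scores, g@nodes),
                 list(variant = "reachable-scaled"))
}

#' Betweenness centrality
#'
#' For each node v, the sum over unordered pairs (s, t), s != v != t, of the
#' fraction of shortest s-t paths passing through v (Brandes accumulation).
#' When `normalized` (the default) the sum is divided by
#' (N - 1)(N - 2) / 2. SAC thresholding is scale-invariant, so the choice
#' only affects reported values, never SAC scores.
#'
#' @param g a [LinkGraph-class].
#' @param normalized divide by the number of pairs not involving v.
#' @return a [CentralityVector-class] of kind `"betweenness"`.
#' @export
betweennessCentrality <- function(g, normalized = TRUE) {
  raw <- igraph::betweenness(.asIgraph(g), directed = FALSE)
  n <- numNodes(g)
  scores <- if (normalized && n > 2L) raw / ((n - 1) * (n - 2) / 2) else raw
  .newCentrality("betweenness",
                 stats::setNames(as.numeric(scores), g@nodes),
                 list(normalized = normalized))
}

#' Eigenvector centrality
#'
#' Scores proportional to the principal eigenvector of the adjacency matrix,
#' non-negative and normalized to unit Euclidean norm. Computed by power
#' iteration on A + I (the unit spectral shift leaves the eigenvectors
#' unchanged while making the leading eigenvalue strictly dominant, so
#' bipartite graphs, whose adjacency spectrum is symmetric, also converge).
#'
#' @param g a [LinkGraph-class], non-empty.
#' @param tol L1 convergence tolerance on the iterate difference.
#' @param maxIter maximum number of iterations.
#' @return a [CentralityVector-class] of kind `"eigenvector"`.
#' @export
eigenvectorCentrality <- function(g, tol = 1e-6, maxIter = 1000L) {
  n <- numNodes(g)
  if (n == 0L) stop("empty graph", call. = FALSE)
  A <- igraph::as_adjacency_matrix(.asIgraph(g), sparse = TRUE)
  x <- rep(1 / sqrt(n), n)
  for (iter in seq_len(maxIter)) {
    y <- as.numeric(A %*% x) + x            # (A + I) x
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) break                     # edgeless graph: uniform vector
    y <- y / nrm
    if (sum(abs(y - x)) < tol) {
      x <- y
      return(.newCentrality("eigenvector", stats::setNames(x, g@nodes),
                            list(norm = "L2", tol = tol, iterations = iter)))
    }
    x <- y
  }
  if (numEdges(g) == 0L)
    return(.newCentrality("eigenvector", stats::setNames(x, g@nodes),
                          list(norm = "L2", tol = tol, iterations = 0L)))
  resid <- sum(abs(as.numeric(A %*% x) + x - x * (sum(x * (as.numeric(A %*% x) + x)))))
  stop(sprintf(
    "power iteration did not converge in %d iterations (L1 residual %.3g)",
    maxIter, resid), call. = FALSE)
}

#' Graph-average centrality
#'
#' The arithmetic mean of a centrality vector over all nodes of the graph,
#' A_C(G): the SAC threshold.
#'
#' @param cv a non-empty [CentralityVector-class].
#' @return an [AverageCentrality-class].
#' @examples
#' averageCentrality(degreeCentrality(toyGraph()))  # 0.375
#' @export
averageCentrality <- function(cv) {
  if (length(cv@scores) == 0L) stop("empty centrality vector", call. = FALSE)
  new("AverageCentrality", kind = cv@kind, value = mean(cv@scores))
}

setMethod("show", "AverageCentrality", function(object) {
  cat(sprintf("AverageCentrality (%s): %.6g\n", object@kind, object@value))
})
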