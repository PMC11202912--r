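# Measure identifiers accepted throughout: five classical local indices,
# two recent centrality-based indices, four SAC instantiations.
.measureIds <- c("cn", "jc", "pa", "ra", "aa", "ccpa", "knlp",
                 "sac_d", "sac_b", "sac_c", "sac_cc")

.sacKinds <- c(sac_d = "degree", sac_b = "betweenness",
               sac_c = "closeness", sac_cc = "clustering")

.checkScorable <- function(g, u, v, allowAdjacent) {
  .checkNode(g, u); .checkNode(g, v)
  if (u == v) stop("cannot score a node against itself", call. = FALSE)
  if (!allowAdjacent && v %in% g@adj[[u]])
    stop(sprintf("pair (%s, %s) is adjacent; similarity indices are defined for non-adjacent pairs (use allowAdjacent = TRUE to override)",
                 u, v), call. = FALSE)
  invisible(NULL)
}

#' Common-neighbor score
#'
#' The number of nodes adjacent to both members of a non-adjacent pair: the
#' simplest local similarity index for link prediction.
#'
#' @param g a [LinkGraph-class].
#' @param u,v node labels of a non-adjacent pair.
#' @param allowAdjacent score adjacent pairs instead of raising an error.
#' @return a single numeric score.
#' @examples
#' scoreCN(toyGraph(), "1", "2")  # 2 (common neighbors 4 and 7)
#' @export
scoreCN <- function(g, u, v, allowAdjacent = FALSE) {
  .checkScorable(g, u, v, allowAdjacent)
  length(commonNeighbors(g, u, v))
}

#' Jaccard coefficient
#'
#' Common-neighbor count normalized by the size of the neighborhood union.
#' Two nodes whose neighborhoods are both empty score 0 by convention.
#'
#' @inheritParams scoreCN
#' @return a single numeric score in [0, 1].
#' @export
scoreJC <- function(g, u, v, allowAdjacent = FALSE) {
  .checkScorable(g, u, v, allowAdjacent)
  uni <- union(g@adj[[u]], g@adj[[v]])
  if (length(uni) == 0L) return(0)
  length(intersect(g@adj[[u]], g@adj[[v]])) / length(uni)
}

#' Preferential-attachment score
#'
#' The product of the two degrees: link propensity proportional to each
#' endpoint's connectivity, ignoring shared neighbors.
#'
#' @inheritParams scoreCN
#' @return a single numeric score.
#' @export
scorePA <- function(g, u, v, allowAdjacent = FALSE) {
  .checkScorable(g, u, v, allowAdjacent)
  length(g@adj[[u]]) * length(g@adj[[v]])
}

#' Resource-allocation score
#'
#' Sum over common neighbors r of 1/d_r: resources sent from one endpoint to
#' the other through shared nodes, penalizing high-degree intermediaries.
#'
#' @inheritParams scoreCN
#' @return a single numeric score.
#' @export
scoreRA <- function(g, u, v, allowAdjacent = FALSE) {
  .checkScorable(g, u, v, allowAdjacent)
  cn <- commonNeighbors(g, u, v)
  if (length(cn) == 0L) return(0)
  sum(1 / lengths(g@adj[cn]))
}

#' Adamic-Adar score
#'
#' Sum over common neighbors r of 1/ln(d_r) (natural logarithm: the base
#' that reproduces the worked-example values, e.g. 2/ln 3 = 1.82 for a pair
#' whose two common neighbors have degree 3). Any common neighbor of a
#' simple-graph pair has degree at least 2, so the logarithm is positive.
#'
#' @inheritParams scoreCN
#' @return a single numeric score.
#' @export
scoreAA <- function(g, u, v, allowAdjacent = FALSE) {
  .checkScorable(g, u, v, allowAdjacent)
  cn <- commonNeighbors(g, u, v)
  if (length(cn) == 0L) return(0)
  sum(1 / log(lengths(g@adj[cn])))
}

#' CCPA score (common neighbor and centrality-based parameterized algorithm)
#'
#' alpha * CN(u, v) + (1 - alpha) * N / D(u, v), blending the
#' common-neighbor count with a closeness-like term driven by the
#' shortest-path length D. When the pair is disconnected the second term is
#' 0 (the D -> Inf limit).
#'
#' @inheritParams scoreCN
#' @param alpha trade-off parameter in [0, 1]; 1 reduces to the
#'   common-neighbor score. Default 0.8, the value consistent with the
#'   worked example.
#' @return a single numeric score.
#' @export
scoreCCPA <- function(g, u, v, alpha = 0.8, allowAdjacent = FALSE) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  .checkScorable(g, u, v, allowAdjacent)
  d <- shortestPathLength(g, u, v)
  second <- if (is.finite(d)) numNodes(g) / d else 0
  alpha * length(commonNeighbors(g, u, v)) + (1 - alpha) * second
}

#' KNLP score (keyword-network link prediction)
#'
#' (CS_u + CS_v) / (CC_u + CC_v + epsilon), where CS is eigenvector
#' centrality (unit L2 norm) and CC the local clustering coefficient;
#' epsilon guards the division when both clustering coefficients are 0.
#'
#' @inheritParams scoreCN
#' @param cs eigenvector [CentralityVector-class] on `g`; computed if `NULL`.
#' @param cc clustering [CentralityVector-class] on `g`; computed if `NULL`.
#' @param epsilon small positive constant, default 1e-6.
#' @return a single numeric score.
#' @export
scoreKNLP <- function(g, u, v, cs = NULL, cc = NULL, epsilon = 1e-6,
                      allowAdjacent = FALSE) {
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  .checkScorable(g, u, v, allowAdjacent)
  if (is.null(cs)) cs <- eigenvectorCentrality(g)
  if (is.null(cc)) cc <- clusteringCoefficient(g)
  if (cs@kind != "eigenvector" || cc@kind != "clustering")
    stop("cs must be an eigenvector and cc a clustering CentralityVector",
         call. = FALSE)
  s <- cs@scores; c2 <- cc@scores
  (s[[u]] + s[[v]]) / (c2[[u]] + c2[[v]] + epsilon)
}

#' Build a SAC scoring context
#'
#' Computes a centrality vector on the graph together with its graph
#' average, the pairing that SAC scoring thresholds against.
#'
#' @param g a [LinkGraph-class].
#' @param kind centrality kind: `"degree"`, `"betweenness"`, `"closeness"`
#'   or `"clustering"`.
#' @param denominator degree-centrality convention (see
#'   [degreeCentrality()]); SAC output does not depend on it.
#' @param normalized betweenness normalization flag; SAC output does not
#'   depend on it.
#' @return a [SACContext-class].
#' @export
sacContext <- function(g, kind = c("degree", "betweenness", "closeness",
                                   "clustering"),
                       denominator = "N", normalized = TRUE) {
  kind <- match.arg(kind)
  cv <- switch(kind,
               degree = degreeCentrality(g, denominator),
               betweenness = betweennessCentrality(g, normalized),
               closeness = closenessCentrality(g),
               clustering = clusteringCoefficient(g))
  new("SACContext", centrality = cv, average = averageCentrality(cv))
}

setMethod("show", "SACContext", function(object) {
  cat(sprintf("SACContext (%s); A_C(G) = %.6g over %d nodes\n",
              object@centrality@kind, object@average@value,
              length(object@centrality@scores)))
})

#' SAC score: common neighbors with above-average centrality
#'
#' The number of common neighbors x of a non-adjacent pair whose centrality
#' satisfies C(x) >= A_C(G), the graph-average centrality. The comparison is
#' inclusive, so nodes sitting exactly at the average count. SAC is bounded
#' above by the plain common-neighbor score and is invariant to any common
#' rescaling of the centrality (both sides of the threshold test scale
#' together).
#'
#' @inheritParams scoreCN
#' @param ctx a [SACContext-class] built on `g` (see [sacContext()]).
#' @return a single numeric score (a non-negative integer count).
#' @examples
#' g <- toyGraph()
#' scoreSAC(g, "1", "2", sacContext(g, "degree"))  # 1
#' scoreSAC(g, "4", "7", sacContext(g, "degree"))  # 2: both sit at the mean
#' @export
scoreSAC <- function(g, u, v, ctx, allowAdjacent = FALSE) {
  if (!is(ctx, "SACContext")) stop("ctx must be a SACContext", call. = FALSE)
  .checkScorable(g, u, v, allowAdjacent)
  cn <- commonNeighbors(g, u, v)
  if (length(cn) == 0L) return(0L)
  sum(ctx@centrality@scores[cn] >= ctx@average@value)
}

# Vectorized scorer over many pairs via sparse matrix algebra; used by
# rankPairs() and the evaluation harness. Agrees with the per-pair score*
# functions (asserted in the test suite).
.scorePairsBulk <- function(g, measure, pairs, alpha = 0.8, epsilon = 1e-6,
                            denominator = "N") {
  n <- numNodes(g)
  if (nrow(pairs) == 0L) return(numeric())
  ig <- .asIgraph(g)
  A <- igraph::as_adjacency_matrix(ig, sparse = TRUE)
  iu <- match(pairs$u, g@nodes); iv <- match(pairs$v, g@nodes)
  deg <- lengths(g@adj)
  cnAt <- function() {
    A2 <- A %*% A
    as.numeric(A2[cbind(iu, iv)])
  }
  weighted <- function(w) {
    M <- A %*% Matrix::Diagonal(x = w) %*% A
    as.numeric(M[cbind(iu, iv)])
  }
  switch(measure,
    cn = cnAt(),
    pa = as.numeric(deg[iu] * deg[iv]),
    jc = {
      cn <- cnAt()
      uni <- deg[iu] + deg[iv] - cn
      ifelse(uni == 0, 0, cn / uni)
    },
    ra = weighted(ifelse(deg >= 1L, 1 / pmax(deg, 1L), 0)),
    aa = weighted(ifelse(deg >= 2L, 1 / log(pmax(deg, 2L)), 0)),
    ccpa = {
      uu <- unique(pairs$u)
      D <- igraph::distances(ig, v = uu, to = unique(pairs$v))
      d <- D[cbind(match(pairs$u, uu), match(pairs$v, colnames(D)))]
      alpha * cnAt() + (1 - alpha) * ifelse(is.finite(d), n / d, 0)
    },
    knlp = {
      cs <- centralityScores(eigenvectorCentrality(g))
      cc <- centralityScores(clusteringCoefficient(g))
      (cs[iu] + cs[iv]) / (cc[iu] + cc[iv] + epsilon)
    },
    {
      kind <- .sacKinds[[measure]]
      ctx <- sacContext(g, kind, denominator = denominator)
      ind <- as.numeric(ctx@centrality@scores >= ctx@average@value)
      weighted(ind)
    })
}

#' Score and rank candidate node pairs
#'
#' Scores a set of node pairs (by default every non-adjacent pair of the
#' graph) under one similarity measure and returns them sorted by
#' descending score, ties broken by canonical pair order so rankings are
#' reproducible across platforms. Centrality contexts are computed once per
#' call, not per pair.
#'
#' @param g a [LinkGraph-class].
#' @param measure one of `"cn"`, `"jc"`, `"pa"`, `"ra"`, `"aa"`, `"ccpa"`,
#'   `"knlp"`, `"sac_d"`, `"sac_b"`, `"sac_c"`, `"sac_cc"`.
#' @param pairs optional data.frame/matrix with columns `u`, `v`; defaults
#'   to [nonAdjacentPairs()] of `g`.
#' @param alpha CCPA trade-off parameter.
#' @param epsilon KNLP guard constant.
#' @param denominator degree-centrality convention for `sac_d`.
#' @param allowAdjacent permit adjacent pairs in a user-supplied `pairs`.
#' @return data.frame with columns `u`, `v`, `score`, sorted by descending
#'   score then canonical pair order.
#' @examples
#' head(rankPairs(toyGraph(), "sac_d"), 3)
#' @export
rankPairs <- function(g, measure, pairs = NULL, alpha = 0.8,
                      epsilon = 1e-6, denominator = "N",
                      allowAdjacent = FALSE) {
  if (!(measure %in% .measureIds))
    stop(sprintf("unknown measure '%s'; valid measures: %s", measure,
                 paste(.measureIds, collapse = ", ")), call. = FALSE)
  if (is.null(pairs)) {
    pairs <- nonAdjacentPairs(g)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs)[1:2] <- c("u", "v")
    pairs$u <- as.character(pairs$u); pairs$v <- as.character(pairs$v)
    if (nrow(pairs) > 0L) {
      for (x in unique(c(pairs$u, pairs$v))) .checkNode(g, x)
      cm <- .canonPairMatrix(pairs$u, pairs$v)
      pairs$u <- cm[, 1L]; pairs$v <- cm[, 2L]
      if (!allowAdjacent) {
        adjHit <- mapply(function(a, b) b %in% g@adj[[a]], pairs$u, pairs$v)
        if (any(adjHit))
          stop(sprintf("%d supplied pair(s) are adjacent; use allowAdjacent = TRUE to score them",
                       sum(adjHit)), call. = FALSE)
      }
      rank <- stats::setNames(seq_along(g@nodes), g@nodes)
      pairs <- pairs[order(rank[pairs$u], rank[pairs$v]), , drop = FALSE]
    }
  }
  if (nrow(pairs) == 0L)
    return(data.frame(u = character(), v = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  score <- .scorePairsBulk(g, measure, pairs, alpha = alpha,
                           epsilon = epsilon, denominator = denominator)
  ord <- order(-score, method = "radix")  # stable: ties keep canonical order
  out <- data.frame(u = pairs$u[ord], v = pairs$v[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a scored-pair ranking as TSV
#'
#' Header `u	v	score`; rows sorted by descending score then canonical
#' pair order (the order [rankPairs()] returns).
#'
#' @param ranking data.frame from [rankPairs()].
#' @param path file path or connection.
#' @return invisibly, the path.
#' @export
writeScores <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
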