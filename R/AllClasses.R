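#' @import methods
NULL

#' Undirected simple graph for link prediction
#'
#' An undirected, unweighted simple graph stored as an adjacency list over
#' opaque character node labels. Validity enforces symmetry of the adjacency
#' relation, absence of self-loops and of multi-edges, and consistency of the
#' cached edge count with the handshake identity m = sum(degrees)/2.
#'
#' Construct with [linkGraph()] or [readEdgeList()]; interrogate with
#' [nodeNames()], [numNodes()], [numEdges()], [edgeMatrix()] and
#' [neighborSet()].
#'
#' @slot nodes character vector of node labels in canonical order
#'   (numeric-aware when every label is an unsigned integer, else C-locale
#'   lexicographic).
#' @slot adj named list mapping each node label to the character vector of
#'   its neighbors, each sorted in canonical order.
#'
#' @seealso [linkGraph()], [readEdgeList()], [toyGraph()]
#' @export
setClass("LinkGraph", representation(nodes = "character", adj = "list"))

setValidity("LinkGraph", function(object) {
  msgs <- character()
  nodes <- object@nodes
  adj <- object@adj
  if (anyDuplicated(nodes)) msgs <- c(msgs, "duplicate node labels")
  if (!identical(sort(names(adj)), sort(nodes)))
    msgs <- c(msgs, "adjacency names do not match node set")
  for (v in nodes) {
    nb <- adj[[v]]
    if (anyDuplicated(nb)) msgs <- c(msgs, sprintf("multi-edge at node %s", v))
    if (v %in% nb) msgs <- c(msgs, sprintf("self-loop at node %s", v))
    if (!all(nb %in% nodes)) msgs <- c(msgs, sprintf("unknown neighbor of %s", v))
  }
  if (length(msgs) == 0L) {
    # symmetry: u in adj[v] <=> v in adj[u]
    for (v in nodes) {
      for (u in adj[[v]]) {
        if (!(v %in% adj[[u]])) {
          msgs <- c(msgs, sprintf("asymmetric adjacency %s-%s", v, u))
          break
        }
      }
    }
  }
  if (sum(lengths(adj)) %% 2L != 0L)
    msgs <- c(msgs, "odd degree sum; adjacency not symmetric")
  if (length(msgs)) msgs else TRUE
})

#' Per-node centrality scores
#'
#' A vector of real-valued node scores of one centrality kind, together with
#' the normalization conventions used to compute it. Every node of the source
#' graph carries exactly one score.
#'
#' @slot kind one of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"clustering"`, `"eigenvector"`.
#' @slot scores named numeric vector, one entry per node.
#' @slot convention named list recording normalization choices (e.g. the
#'   degree denominator, whether betweenness is normalized, the closeness
#'   variant, the eigenvector norm).
#'
#' @seealso [degreeCentrality()], [betweennessCentrality()],
#'   [closenessCentrality()], [clusteringCoefficient()],
#'   [eigenvectorCentrality()], [averageCentrality()]
#' @export
setClass("CentralityVector",
         representation(kind = "character", scores = "numeric",
                        convention = "list"))

.centrality_kinds <- c("degree", "betweenness", "closeness", "clustering",
                       "eigenvector")

setValidity("CentralityVector", function(object) {
  msgs <- character()
  if (length(object@kind) != 1L || !(object@kind %in% .centrality_kinds))
    msgs <- c(msgs, sprintf("kind must be one of: %s",
                            paste(.centrality_kinds, collapse = ", ")))
  if (is.null(names(object@scores)) || anyDuplicated(names(object@scores)))
    msgs <- c(msgs, "scores must be uniquely named by node")
  if (any(!is.finite(object@scores)))
    msgs <- c(msgs, "scores must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Graph-average centrality
#'
#' The arithmetic mean of a [CentralityVector-class]'s scores over all nodes,
#' A_C(G), tagged with its centrality kind. This is the threshold against
#' which SAC tests each common neighbor.
#'
#' @slot kind centrality kind, as in [CentralityVector-class].
#' @slot value the mean score.
#' @seealso [averageCentrality()], [sacContext()]
#' @export
setClass("AverageCentrality",
         representation(kind = "character", value = "numeric"))

#' Centrality context for SAC scoring
#'
#' Pairs a [CentralityVector-class] with its graph average of the same kind.
#' Validity checks the kinds match and that the stored average equals the
#' mean of the scores to within 1e-12.
#'
#' @slot centrality a [CentralityVector-class].
#' @slot average an [AverageCentrality-class] of the same kind.
#' @seealso [sacContext()], [scoreSAC()]
#' @export
setClass("SACContext",
         representation(centrality = "CentralityVector",
                        average = "AverageCentrality"))

setValidity("SACContext", function(object) {
  msgs <- character()
  if (!identical(object@centrality@kind, object@average@kind))
    msgs <- c(msgs, "centrality and average kinds differ")
  if (abs(object@average@value - mean(object@centrality@scores)) > 1e-12)
    msgs <- c(msgs, "stored average does not equal the mean of the scores")
  if (length(msgs)) msgs else TRUE
})

#' Train/test edge holdout
#'
#' The result of removing a random fraction of edges from a graph: the
#' training graph, the held-out test edges (canonicalized pairs), and the
#' seed and fraction that produced the split.
#'
#' @slot train a [LinkGraph-class] with the test edges removed.
#' @slot testEdges two-column character matrix of held-out edges, one row
#'   per edge, each row in canonical pair order.
#' @slot seed integer seed used for the draw.
#' @slot fraction fraction of edges held out.
#' @seealso [splitEdges()], [labelCandidates()]
#' @export
setClass("EdgeSplit",
         representation(train = "LinkGraph", testEdges = "matrix",
                        seed = "integer", fraction = "numeric"))

setValidity("EdgeSplit", function(object) {
  msgs <- character()
  te <- object@testEdges
  if (ncol(te) != 2L) msgs <- c(msgs, "testEdges must have two columns")
  if (nrow(te) >= 1L) {
    trainKeys <- .pairKeys(edgeMatrix(object@train))
    testKeys <- .pairKeys(te)
    if (anyDuplicated(testKeys)) msgs <- c(msgs, "duplicate test edges")
    if (any(testKeys %in% trainKeys))
      msgs <- c(msgs, "test edges overlap training edges")
  }
  if (object@fraction <= 0 || object@fraction >= 1)
    msgs <- c(msgs, "fraction must lie in (0,1)")
  if (length(msgs)) msgs else TRUE
})
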