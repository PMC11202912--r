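# Canonical label order: numeric-aware when every label parses as an
# unsigned integer (the worked-example graph uses 1-based integer labels),
# otherwise C-locale lexicographic. Guarantees deterministic iteration
# across platforms.
.labelOrder <- function(labels) {
  if (length(labels) == 0L) return(integer())
  if (all(grepl("^[0-9]+$", labels))) {
    order(as.numeric(labels), labels, method = "radix")
  } else {
    order(labels, method = "radix")
  }
}

.sortLabels <- function(labels) labels[.labelOrder(labels)]

# Canonicalize pair columns: row-wise (u, v) with u before v in label order.
.canonPairMatrix <- function(u, v) {
  ord <- .labelOrder(unique(c(u, v)))
  rank <- stats::setNames(seq_along(ord), unique(c(u, v))[ord])
  swap <- rank[u] > rank[v]
  cbind(u = ifelse(swap, v, u), v = ifelse(swap, u, v))
}

.pairKeys <- function(mat) {
  if (nrow(mat) == 0L) return(character())
  m <- .canonPairMatrix(mat[, 1L], mat[, 2L])
  paste(m[, 1L], m[, 2L], sep = "\r")
}

.checkNode <- function(g, v) {
  if (!(v %in% g@nodes))
    stop(sprintf("unknown node '%s'", v), call. = FALSE)
  invisible(v)
}

#' Construct a LinkGraph from an edge table
#'
#' @param edges two-column matrix or data.frame of edges; coerced to
#'   character. Interpreted as undirected.
#' @param nodes optional character vector of node labels; isolated nodes may
#'   be declared here. Defaults to the labels occurring in `edges`.
#' @param deduplicate drop duplicate edges (either orientation) instead of
#'   raising an error.
#' @param dropSelfLoops drop self-loops instead of raising an error.
#' @return a [LinkGraph-class].
#' @examples
#' g <- linkGraph(cbind(c("a", "b"), c("b", "c")))
#' numEdges(g)
#' @export
linkGraph <- function(edges, nodes = NULL, deduplicate = TRUE,
                      dropSelfLoops = TRUE) {
  edges <- as.matrix(edges)
  if (nrow(edges) > 0L && ncol(edges) < 2L)
    stop("edges must have two columns")
  u <- as.character(edges[, 1L])
  v <- as.character(edges[, 2L])
  loops <- u == v
  if (any(loops)) {
    if (!dropSelfLoops)
      stop(sprintf("%d self-loop(s) present", sum(loops)), call. = FALSE)
    if (sum(loops) > 0L)
      message(sprintf("dropped %d self-loop(s)", sum(loops)))
    u <- u[!loops]; v <- v[!loops]
  }
  if (length(u)) {
    mat <- .canonPairMatrix(u, v)
    keys <- paste(mat[, 1L], mat[, 2L], sep = "\r")
    dup <- duplicated(keys)
    if (any(dup)) {
      if (!deduplicate)
        stop(sprintf("%d duplicate edge(s) present", sum(dup)), call. = FALSE)
      message(sprintf("dropped %d duplicate edge(s)", sum(dup)))
      mat <- mat[!dup, , drop = FALSE]
    }
    u <- mat[, 1L]; v <- mat[, 2L]
  }
  allNodes <- .sortLabels(unique(c(u, v, as.character(nodes))))
  adj <- lapply(stats::setNames(allNodes, allNodes), function(x) character())
  if (length(u)) {
    half <- split(c(v, u), factor(c(u, v), levels = allNodes))
    filled <- names(half)[lengths(half) > 0L]
    adj[filled] <- lapply(half[filled], .sortLabels)
  }
  new("LinkGraph", nodes = allNodes, adj = adj)
}

#' Read an undirected edge list
#'
#' One edge per line, two whitespace- or comma-separated node tokens
#' (auto-detected); `#` starts a comment; blank lines are ignored. Tokens
#' beyond the second are ignored with a warning. Duplicate edges and
#' self-loops are dropped with a message when the corresponding flags are
#' set (public edge lists are messy), and raise errors in strict mode.
#'
#' @param source a file path, connection, or character vector of lines.
#' @param commentChar comment delimiter, default `"#"`.
#' @param deduplicate,dropSelfLoops tolerate duplicates / self-loops
#'   (default) or raise.
#' @return a [LinkGraph-class].
#' @examples
#' g <- readEdgeList(c("1 4", "1 7", "4 1"))
#' numEdges(g)  # the repeated 1-4 edge collapses
#' @export
readEdgeList <- function(source, commentChar = "#", deduplicate = TRUE,
                         dropSelfLoops = TRUE) {
  lines <- if (is.character(source)) {
    if (length(source) == 1L && file.exists(source)) readLines(source)
    else if (length(source) == 1L && grepl("\n", source, fixed = TRUE))
      strsplit(source, "\n", fixed = TRUE)[[1L]]
    else source
  } else {
    readLines(source)
  }
  stripped <- sub(paste0("\\", commentChar, ".*$"), "", lines)
  keep <- which(nzchar(trimws(stripped)))
  if (length(keep) == 0L) stop("empty edge-list input", call. = FALSE)
  body <- trimws(stripped[keep])
  delim <- if (any(grepl(",", body, fixed = TRUE))) "[,[:space:]]+" else "[[:space:]]+"
  toks <- strsplit(body, delim)
  ntok <- lengths(toks)
  if (any(ntok < 2L)) {
    bad <- keep[which(ntok < 2L)[1L]]
    stop(sprintf("malformed edge-list line %d: fewer than two tokens", bad),
         call. = FALSE)
  }
  if (any(ntok > 2L))
    warning(sprintf("%d line(s) had extra tokens; ignored beyond the second",
                    sum(ntok > 2L)), call. = FALSE)
  edges <- cbind(vapply(toks, `[`, character(1), 1L),
                 vapply(toks, `[`, character(1), 2L))
  linkGraph(edges, deduplicate = deduplicate, dropSelfLoops = dropSelfLoops)
}

#' Write a graph as an edge list
#'
#' Writes one edge per line, two space-separated tokens, canonical order.
#' Re-reading the file reproduces the adjacency structure exactly.
#'
#' @param g a [LinkGraph-class].
#' @param path file path or connection.
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(g, path) {
  em <- edgeMatrix(g)
  writeLines(paste(em[, 1L], em[, 2L]), path)
  invisible(path)
}

#' @rdname LinkGraph-class
#' @export
setMethod("nodeNames", "LinkGraph", function(x) x@nodes)

#' @rdname LinkGraph-class
#' @export
setMethod("numNodes", "LinkGraph", function(x) length(x@nodes))

#' @rdname LinkGraph-class
#' @export
setMethod("numEdges", "LinkGraph", function(x) sum(lengths(x@adj)) %/% 2L)

#' @rdname LinkGraph-class
#' @export
setMethod("edgeMatrix", "LinkGraph", function(x) {
  us <- character(); vs <- character()
  rank <- stats::setNames(seq_along(x@nodes), x@nodes)
  for (v in x@nodes) {
    nb <- x@adj[[v]]
    nb <- nb[rank[nb] > rank[v]]
    us <- c(us, rep(v, length(nb))); vs <- c(vs, nb)
  }
  cbind(u = us, v = vs)
})

#' @rdname LinkGraph-class
#' @export
setMethod("neighborSet", "LinkGraph", function(x, v) {
  .checkNode(x, v)
  x@adj[[v]]
})

setMethod("show", "LinkGraph", function(object) {
  cat(sprintf("LinkGraph with %d nodes and %d edges\n",
              numNodes(object), numEdges(object)))
})

# igraph view of a LinkGraph; vertex order follows canonical node order.
.asIgraph <- function(g) {
  ig <- igraph::make_empty_graph(n = numNodes(g), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g@nodes)
  em <- edgeMatrix(g)
  if (nrow(em) > 0L) ig <- igraph::add_edges(ig, t(em))
  ig
}

#' Common neighbors of a node pair
#'
#' @param g a [LinkGraph-class].
#' @param u,v node labels.
#' @return character vector of nodes adjacent to both `u` and `v`, in
#'   canonical order.
#' @examples
#' commonNeighbors(toyGraph(), "1", "2")  # "4" "7"
#' @export
commonNeighbors <- function(g, u, v) {
  .checkNode(g, u); .checkNode(g, v)
  .sortLabels(intersect(g@adj[[u]], g@adj[[v]]))
}

#' Shortest-path (hop) distance between two nodes
#'
#' BFS hop distance; `Inf` when the nodes lie in different components.
#'
#' @inheritParams commonNeighbors
#' @return non-negative number, possibly `Inf`.
#' @export
shortestPathLength <- function(g, u, v) {
  .checkNode(g, u); .checkNode(g, v)
  as.numeric(igraph::distances(.asIgraph(g), v = u, to = v))
}

#' All non-adjacent node pairs
#'
#' Every unordered pair of distinct, non-adjacent nodes, each exactly once,
#' in canonical deterministic order. These are the candidate pairs a link
#' predictor scores.
#'
#' @param g a [LinkGraph-class].
#' @return data.frame with character columns `u`, `v`.
#' @export
nonAdjacentPairs <- function(g) {
  nodes <- g@nodes
  n <- length(nodes)
  us <- vector("list", max(n - 1L, 0L))
  vs <- vector("list", max(n - 1L, 0L))
  for (i in seq_len(max(n - 1L, 0L))) {
    later <- nodes[(i + 1L):n]
    cand <- setdiff(later, g@adj[[nodes[i]]])
    us[[i]] <- rep(nodes[i], length(cand))
    vs[[i]] <- cand  # 'later' preserves canonical order; setdiff keeps it
  }
  data.frame(u = unlist(us, use.names = FALSE),
             v = unlist(vs, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Per-node triangle counts
#'
#' K_v: the number of edges among the neighbors of v, i.e. triangles through
#' v. Always between 0 and d_v (d_v - 1) / 2.
#'
#' @param g a [LinkGraph-class].
#' @return named integer vector over all nodes.
#' @export
triangleCounts <- function(g) {
  out <- stats::setNames(integer(numNodes(g)), g@nodes)
  for (v in g@nodes) {
    nb <- g@adj[[v]]
    k <- 0L
    if (length(nb) >= 2L) {
      for (i in seq_len(length(nb) - 1L))
        k <- k + sum(nb[(i + 1L):length(nb)] %in% g@adj[[nb[i]]])
    }
    out[v] <- k
  }
  out
}

#' Basic graph statistics
#'
#' Node and edge counts, maximum and average degree, diameter, and average
#' clustering coefficient (mean over all nodes, degree-0/1 nodes
#' contributing 0). On a disconnected graph the diameter is reported on the
#' largest connected component, with a message.
#'
#' @param g a [LinkGraph-class].
#' @return named list with elements `nodes`, `edges`, `max_degree`,
#'   `avg_degree`, `diameter`, `avg_clustering`.
#' @export
graphSummary <- function(g) {
  if (numNodes(g) == 0L) stop("empty graph", call. = FALSE)
  deg <- lengths(g@adj)
  ig <- .asIgraph(g)
  comps <- igraph::components(ig)
  if (comps$no > 1L) {
    message(sprintf(
      "graph has %d components; diameter reported on the largest (%d nodes)",
      comps$no, max(comps$csize)))
    ig <- igraph::induced_subgraph(ig, which(comps$membership ==
                                             which.max(comps$csize)))
  }
  list(nodes = numNodes(g),
       edges = numEdges(g),
       max_degree = max(deg),
       avg_degree = mean(deg),
       diameter = igraph::diameter(ig, unconnected = FALSE),
       avg_clustering = mean(centralityScores(clusteringCoefficient(g))))
}
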