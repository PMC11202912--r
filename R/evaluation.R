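# Run fn under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
.withSeed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Hold out a random fraction of edges
#'
#' Uniformly samples `floor(fraction * m)` edges (at least one) without
#' replacement under the given seed, removes them from the graph, and
#' returns the training graph together with the held-out test edges. The
#' node set is preserved, so edge removal may disconnect the training graph
#' (a message is emitted when it does). The split is deterministic for a
#' fixed (graph, fraction, seed).
#'
#' @param g a [LinkGraph-class] with at least two edges.
#' @param fraction fraction of edges to hold out, in (0, 1); the protocol
#'   default is 0.2.
#' @param seed integer seed.
#' @return an [EdgeSplit-class].
#' @export
splitEdges <- function(g, fraction = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  m <- numEdges(g)
  if (m < 2L) stop("need at least two edges to split", call. = FALSE)
  em <- edgeMatrix(g)  # canonical order: sampling indices is reproducible
  nTest <- max(1L, as.integer(floor(fraction * m)))
  idx <- .withSeed(seed, function() sample.int(m, nTest))
  test <- em[idx, , drop = FALSE]
  train <- linkGraph(em[-idx, , drop = FALSE], nodes = nodeNames(g))
  split <- new("EdgeSplit", train = train, testEdges = test,
               seed = as.integer(seed), fraction = fraction)
  if (igraph::components(.asIgraph(train))$no >
      igraph::components(.asIgraph(g))$no)
    message("edge holdout disconnected the training graph")
  split
}

#' @rdname EdgeSplit-class
#' @export
setMethod("trainGraph", "EdgeSplit", function(x) x@train)

#' @rdname EdgeSplit-class
#' @export
setMethod("testEdges", "EdgeSplit", function(x) x@testEdges)

setMethod("show", "EdgeSplit", function(object) {
  cat(sprintf(
    "EdgeSplit: %d training edges, %d test edges (fraction %.2f, seed %d)\n",
    numEdges(object@train), nrow(object@testEdges), object@fraction,
    object@seed))
})

#' Candidate pairs with positive/negative labels
#'
#' The candidate set is every pair non-adjacent in the training graph; a
#' candidate is labeled positive exactly when it is a held-out test edge,
#' negative otherwise. The count identity n_pos + n_neg =
#' choose(N, 2) - m_train holds by construction.
#'
#' @param split an [EdgeSplit-class].
#' @return data.frame with columns `u`, `v`, `label` (logical; TRUE =
#'   held-out edge).
#' @export
labelCandidates <- function(split) {
  cand <- nonAdjacentPairs(split@train)
  if (nrow(cand) == 0L)
    stop("training graph is complete; no candidate pairs to predict",
         call. = FALSE)
  cand$label <- .pairKeys(as.matrix(cand[, c("u", "v")])) %in%
    .pairKeys(split@testEdges)
  cand
}

#' Area under the ROC curve
#'
#' Rank-statistic form: the probability that a random positive outscores a
#' random negative, counting ties as one half (midranks; the Mann-Whitney
#' statistic divided by n_pos * n_neg). Equals the trapezoidal area under
#' the empirical ROC curve.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) labels, TRUE = positive.
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("AUROC needs at least one positive and one negative", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Entries are sorted by descending score, ties kept in their input order
#' (pass candidates in canonical pair order for reproducibility); the score
#' is the mean over positives of the precision at each positive's rank.
#'
#' @inheritParams aurocScore
#' @return AUPR in (0, 1].
#' @export
auprScore <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels)
  if (nPos == 0L) stop("AUPR needs at least one positive", call. = FALSE)
  ord <- order(-scores, method = "radix")  # stable under ties
  lab <- labels[ord]
  hits <- cumsum(lab)
  mean((hits / seq_along(lab))[lab])
}

#' Ranking metrics restricted to the top-k candidates
#'
#' Keeps the k highest-scoring entries (ties at the boundary resolved by the
#' deterministic input order, i.e. canonical pair order) and computes AUROC
#' and AUPR on that subset. Subsets containing a single class yield `NA`
#' metrics with an explanatory flag rather than an error, which is
#' inevitable at small k.
#'
#' @param candidates data.frame with columns `u`, `v`, `score`, `label`, in
#'   canonical pair order.
#' @param k positive integer; values above the candidate count are clamped
#'   with a warning. `Inf` (or the candidate count) gives the unrestricted
#'   metrics.
#' @return one-row data.frame: `k`, `auroc`, `aupr`, `n_pos`, `n_neg`,
#'   `flag` (`NA` or an explanation of a null metric).
#' @export
topkMetrics <- function(candidates, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a positive integer", call. = FALSE)
  n <- nrow(candidates)
  if (k > n) {
    if (is.finite(k))
      warning(sprintf("k = %d exceeds the %d candidates; clamped", k, n),
              call. = FALSE)
    k <- n
  }
  ord <- order(-candidates$score, method = "radix")
  top <- candidates[ord[seq_len(k)], , drop = FALSE]
  nPos <- sum(top$label); nNeg <- k - nPos
  flag <- NA_character_
  auroc <- aupr <- NA_real_
  if (nPos == 0L) {
    flag <- "no positives in top-k subset"
  } else if (nNeg == 0L) {
    flag <- "no negatives in top-k subset"
    aupr <- 1
  } else {
    auroc <- aurocScore(top$score, top$label)
    aupr <- auprScore(top$score, top$label)
  }
  data.frame(k = k, auroc = auroc, aupr = aupr, n_pos = nPos, n_neg = nNeg,
             flag = flag, stringsAsFactors = FALSE)
}

#' Run the edge-holdout evaluation protocol
#'
#' Splits the graph once per seed (so all measures are compared on the same
#' split), scores every candidate pair of the training graph under each
#' measure, and reports AUROC/AUPR unrestricted (`k = "all"`) and on each
#' requested top-k subset.
#'
#' @param g a [LinkGraph-class].
#' @param measures character vector of measure ids (see [rankPairs()]).
#' @param fraction holdout fraction, default 0.2.
#' @param seed integer seed for the split.
#' @param kGrid integer vector of top-k sizes (may be empty).
#' @param alpha,epsilon,denominator passed to the scorers.
#' @return data.frame, one row per (measure, k) including `k = "all"`, with
#'   columns `measure`, `k`, `auroc`, `aupr`, `n_pos`, `n_neg`, `flag`,
#'   `seed`, `fraction`. JSON-serializable.
#' @export
runExperiment <- function(g, measures, fraction = 0.2, seed = 1L,
                          kGrid = integer(), alpha = 0.8, epsilon = 1e-6,
                          denominator = "N") {
  if (length(measures) == 0L) stop("no measures supplied", call. = FALSE)
  bad <- setdiff(measures, .measureIds)
  if (length(bad))
    stop(sprintf("unknown measure(s): %s; valid measures: %s",
                 paste(bad, collapse = ", "),
                 paste(.measureIds, collapse = ", ")), call. = FALSE)
  split <- splitEdges(g, fraction, seed)
  cand <- labelCandidates(split)
  out <- list()
  for (ms in measures) {
    scored <- cand
    scored$score <- tryCatch(
      .scorePairsBulk(split@train, ms, cand, alpha = alpha,
                      epsilon = epsilon, denominator = denominator),
      error = function(e) stop(sprintf("measure '%s': %s", ms,
                                       conditionMessage(e)), call. = FALSE))
    rows <- topkMetrics(scored, Inf)
    rows$k <- "all"
    for (k in kGrid) {
      r <- topkMetrics(scored, k)
      r$k <- as.character(k)
      rows <- rbind(rows, r)
    }
    rows <- cbind(measure = ms, rows, stringsAsFactors = FALSE)
    out[[ms]] <- rows
  }
  res <- do.call(rbind, out)
  res$seed <- as.integer(seed)
  res$fraction <- fraction
  rownames(res) <- NULL
  res
}
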