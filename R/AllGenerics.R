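#' @rdname LinkGraph-class
#' @param x,object a `LinkGraph` (or, for centrality accessors, a
#'   `CentralityVector`).
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname LinkGraph-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname LinkGraph-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname LinkGraph-class
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname LinkGraph-class
#' @param v a node label.
#' @export
setGeneric("neighborSet", function(x, v) standardGeneric("neighborSet"))

#' @rdname CentralityVector-class
#' @param x a `CentralityVector`.
#' @export
setGeneric("centralityKind", function(x) standardGeneric("centralityKind"))

#' @rdname CentralityVector-class
#' @export
setGeneric("centralityScores", function(x) standardGeneric("centralityScores"))

#' @rdname CentralityVector-class
#' @export
setGeneric("convention", function(x) standardGeneric("convention"))

#' @rdname EdgeSplit-class
#' @param x an `EdgeSplit`.
#' @export
setGeneric("trainGraph", function(x) standardGeneric("trainGraph"))

#' @rdname EdgeSplit-class
#' @export
setGeneric("testEdges", function(x) standardGeneric("testEdges"))
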