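#' Number of vertices in a graph
#' @param x a [CSRGraph-class]
#' @return integer scalar
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' Number of stored arcs in a graph
#'
#' For undirected graphs this counts stored arcs, i.e. twice the number of
#' input records minus the number of self-loops.
#' @param x a [CSRGraph-class]
#' @return integer scalar
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Is the graph directed?
#' @param x a [CSRGraph-class]
#' @return logical scalar
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))

#' External vertex labels
#' @param x a [CSRGraph-class]
#' @return character vector, one label per vertex
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' Per-vertex out-degree
#' @param x a [CSRGraph-class]
#' @return integer vector of stored out-degrees
#' @export
setGeneric("outDegree", function(x) standardGeneric("outDegree"))

#' Per-vertex in-degree
#' @param x a [CSRGraph-class]
#' @return integer vector of stored in-degrees
#' @export
setGeneric("inDegree", function(x) standardGeneric("inDegree"))

#' Distance matrix of a traversal result
#' @param x a [TraversalResult-class]
#' @return numeric matrix, one row per source; `Inf` marks unreachable
#'   vertices
#' @export
setGeneric("distMatrix", function(x) standardGeneric("distMatrix"))

#' Predecessor matrix of a traversal result
#' @param x a [TraversalResult-class]
#' @return integer matrix of predecessor ids (`NA` for sources and
#'   unreached vertices), or `NULL` when predecessors were not computed
#' @export
setGeneric("predMatrix", function(x) standardGeneric("predMatrix"))

#' Source vertices of a traversal result
#' @param x a [TraversalResult-class]
#' @return integer vector of source vertex ids, one per result row
#' @export
setGeneric("sourceVertices", function(x) standardGeneric("sourceVertices"))
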