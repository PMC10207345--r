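#' Build an adjacency graph from node labels and an edge list
#'
#' Constructs the undirected neighbourhood structure used by the ICAR/BYM2
#' spatial effect.  The edge list is symmetrized and deduplicated; node order
#' is the input order.  Isolated nodes (e.g. island countries with no declared
#' neighbour) are allowed and handled downstream by the BYM2 convention that
#' their structured component is zero.
#'
#' @param nodeIds character vector of unique node labels.
#' @param edges two-column matrix or data.frame of node labels (or a list of
#'   length-2 vectors), one row per edge.  May be empty.
#'
#' @return an [AdjacencyGraph-class].
#' @examples
#' g <- buildGraph(c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
#' nNodes(g); nEdges(g)
#' @export
buildGraph <- function(nodeIds, edges = NULL) {
  nodeIds <- as.character(nodeIds)
  if (!length(nodeIds)) stop("at least one node is required")
  if (anyDuplicated(nodeIds)) stop("node labels must be unique")
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0) ||
      (is.list(edges) && !length(edges))) {
    em <- matrix(integer(), 0L, 2L)
  } else {
    if (is.list(edges) && !is.data.frame(edges))
      edges <- do.call(rbind, lapply(edges, function(e) matrix(e, 1L)))
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
    i <- match(as.character(edges[, 1L]), nodeIds)
    j <- match(as.character(edges[, 2L]), nodeIds)
    if (anyNA(i) || anyNA(j)) {
      bad <- unique(c(edges[, 1L][is.na(i)], edges[, 2L][is.na(j)]))
      stop("unknown node label(s) in edges: ", paste(bad, collapse = ", "))
    }
    if (any(i == j))
      stop("self-loop at node '", nodeIds[i[which(i == j)[1L]]], "'")
    em <- cbind(pmin(i, j), pmax(i, j))
    em <- unique(em)
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
    storage.mode(em) <- "integer"
  }
  new("AdjacencyGraph", nodes = nodeIds, edges = em)
}

#' @describeIn buildGraph number of nodes.
#' @param graph an `AdjacencyGraph`.
#' @export
nNodes <- function(graph) length(graph@nodes)

#' @describeIn buildGraph number of undirected edges.
#' @export
nEdges <- function(graph) nrow(graph@edges)

#' @describeIn buildGraph node labels.
#' @export
graphNodes <- function(graph) graph@nodes

#' @describeIn buildGraph two-column integer matrix of edges (i < j).
#' @export
graphEdges <- function(graph) graph@edges

setMethod("show", "AdjacencyGraph", function(object) {
  cat("AdjacencyGraph:", nNodes(object), "nodes,", nEdges(object), "edges\n")
})

#' ICAR precision matrix of an adjacency graph
#'
#' Builds the intrinsic conditional autoregressive precision `Q = D - A`
#' (degree matrix minus adjacency), the connected-component labels, and the
#' per-component BYM2 scaling factor.  `Q` has zero row sums and rank
#' `n - (number of components)`; it is used with per-component sum-to-zero
#' constraints on the structured spatial effect.
#'
#' @param graph an [AdjacencyGraph-class].
#' @return an [IcarPrecision-class].
#' @examples
#' g <- buildGraph(c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
#' as.matrix(icarQ(icarPrecision(g)))
#' @export
icarPrecision <- function(graph) {
  stopifnot(is(graph, "AdjacencyGraph"))
  n <- nNodes(graph)
  e <- graph@edges
  if (nrow(e)) {
    deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = n)
    Q <- sparseMatrix(i = c(e[, 1L], e[, 2L], seq_len(n)),
                      j = c(e[, 2L], e[, 1L], seq_len(n)),
                      x = c(rep(-1, 2L * nrow(e)), deg),
                      dims = c(n, n), symmetric = FALSE)
  } else {
    Q <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                      dims = c(n, n))
  }
  Q <- forceSymmetric(Q)
  if (nrow(e)) {
    ig <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    comp <- as.integer(igraph::components(ig)$membership)
  } else {
    comp <- seq_len(n)
  }
  icar <- new("IcarPrecision", Q = Q, componentLabels = comp,
              scalingFactors = rep(1, max(comp)))
  icar@scalingFactors <- bym2ScalingFactor(icar)
  icar
}

#' @describeIn icarPrecision the sparse precision matrix.
#' @param icar an `IcarPrecision`.
#' @export
icarQ <- function(icar) icar@Q

#' @describeIn icarPrecision integer component label per node.
#' @export
componentLabels <- function(icar) icar@componentLabels

setMethod("show", "IcarPrecision", function(object) {
  cat("IcarPrecision:", nrow(object@Q), "nodes,",
      max(object@componentLabels), "component(s); scaling factor(s):",
      paste(signif(object@scalingFactors, 4), collapse = ", "), "\n")
})

#' BYM2 scaling factor per connected component
#'
#' The BYM2 parameterization requires the structured (ICAR) effect to be
#' scaled so that its generalized marginal variance is one; the scaling factor
#' of a component is `exp(mean(log(v_i)))` over the component's nodes, where
#' `v_i` are the diagonal entries of the sum-to-zero-constrained generalized
#' inverse of `Q` restricted to that component.  Singleton components get
#' factor 1 by convention (their structured contribution is zero).
#'
#' The generalized inverse is computed by dense eigendecomposition per
#' component; eigenvalues below `1e-10 * max(eigenvalue)` are treated as the
#' null space.
#'
#' @param icar an [IcarPrecision-class].
#' @return numeric vector, one positive factor per component.
#' @examples
#' g <- buildGraph(c("A", "B", "C"),
#'                 cbind(c("A", "A", "B"), c("B", "C", "C")))
#' bym2ScalingFactor(icarPrecision(g))  # complete graph on 3 nodes: 2/9
#' @export
bym2ScalingFactor <- function(icar) {
  stopifnot(is(icar, "IcarPrecision"))
  comp <- icar@componentLabels
  vapply(seq_len(max(comp)), function(k) {
    idx <- which(comp == k)
    if (length(idx) < 2L) return(1)
    Qk <- as.matrix(icar@Q[idx, idx, drop = FALSE])
    md <- constrainedGenInverseDiag(Qk)
    exp(mean(log(md)))
  }, numeric(1))
}

# diagonal of the sum-to-zero-constrained generalized inverse of a connected
# component's ICAR precision (null space = constant vector)
constrainedGenInverseDiag <- function(Qk) {
  eg <- eigen(Qk, symmetric = TRUE)
  tol <- 1e-10 * max(eg$values)
  keep <- eg$values > tol
  if (!any(keep)) stop("ICAR component is numerically singular beyond its null space")
  V <- eg$vectors[, keep, drop = FALSE]
  rowSums(sweep(V^2, 2L, eg$values[keep], "/"))
}

# scaled generalized inverse of the full ICAR precision: block-diagonal over
# components, each block pinv(Q_k) / kappa_k, zero for singletons.  This is the
# covariance of the standardized structured BYM2 component u.
scaledStructuredCovariance <- function(icar) {
  comp <- icar@componentLabels
  n <- nrow(icar@Q)
  G <- matrix(0, n, n)
  for (k in seq_len(max(comp))) {
    idx <- which(comp == k)
    if (length(idx) < 2L) next
    Qk <- as.matrix(icar@Q[idx, idx, drop = FALSE])
    eg <- eigen(Qk, symmetric = TRUE)
    tol <- 1e-10 * max(eg$values)
    keep <- eg$values > tol
    V <- eg$vectors[, keep, drop = FALSE]
    Gk <- V %*% (t(V) / eg$values[keep])
    G[idx, idx] <- Gk / icar@scalingFactors[k]
  }
  G
}

#' Read / write an edge-list file
#'
#' One edge per line as `node_id_1<TAB>node_id_2`; lines starting with `#` are
#' comments.  The node universe is supplied separately (typically the panel's
#' country set) so that isolated countries are representable.
#'
#' @param path file path.
#' @param nodeIds the full node universe.
#' @return [readEdgeList()] returns an [AdjacencyGraph-class];
#'   [writeEdgeList()] returns `path` invisibly.
#' @export
readEdgeList <- function(path, nodeIds) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(buildGraph(nodeIds))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed edge line: ", lines[which(lengths(parts) != 2L)[1L]])
  em <- do.call(rbind, parts)
  buildGraph(nodeIds, em)
}

#' @rdname readEdgeList
#' @param graph an [AdjacencyGraph-class] to write.
#' @export
writeEdgeList <- function(graph, path) {
  e <- graph@edges
  lines <- if (nrow(e)) paste(graph@nodes[e[, 1L]], graph@nodes[e[, 2L]],
                              sep = "\t") else character()
  writeLines(c("# edge list: node_id_1<TAB>node_id_2", lines), path)
  invisible(path)
}
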