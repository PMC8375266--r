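#' Construct a GeneNetwork
#'
#' Builds a weighted undirected gene interaction network from an edge table.
#' Duplicate undirected edges are collapsed (keeping the first weight),
#' self-loops are dropped, and edge endpoints are canonicalised so that
#' \code{gene1 < gene2}.
#'
#' @param edges data.frame (or matrix coercible to one) with at least two
#'   columns giving the two interacting genes; an optional third column is
#'   the interaction weight (defaults to 1, STRING-style confidence scores
#'   rescaled to \[0, 1\] are typical).
#' @param nodes optional character vector of gene ids; defaults to all genes
#'   seen in \code{edges}. Extra ids give isolated nodes.
#' @param seeds character vector of seed (known disease) genes.
#' @return a [GeneNetwork-class] object.
#' @examples
#' net <- geneNetwork(data.frame(a = c("G1", "G2"), b = c("G2", "G3")),
#'                    seeds = "G1")
#' numNodes(net)
#' @export
geneNetwork <- function(edges, nodes = NULL, seeds = character()) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2)
    stop("edges must have at least two columns (gene1, gene2)")
  g1 <- as.character(edges[[1]])
  g2 <- as.character(edges[[2]])
  w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(1, length(g1))
  keep <- g1 != g2
  g1 <- g1[keep]; g2 <- g2[keep]; w <- w[keep]
  a <- pmin(g1, g2); b <- pmax(g1, g2)
  dup <- duplicated(paste(a, b))
  ed <- data.frame(gene1 = a[!dup], gene2 = b[!dup], weight = w[!dup],
                   stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(ed$gene1, ed$gene2)))
  new("GeneNetwork", nodes = as.character(nodes), edges = ed,
      seeds = as.character(seeds))
}

#' @rdname geneNetwork
#' @param x a GeneNetwork.
#' @export
setMethod("numNodes", "GeneNetwork", function(x) length(x@nodes))

#' @rdname geneNetwork
#' @export
setMethod("numEdges", "GeneNetwork", function(x) nrow(x@edges))

#' @rdname geneNetwork
#' @export
setMethod("seedGenes", "GeneNetwork", function(x) x@seeds)

#' @rdname geneNetwork
#' @param ... unused.
#' @export
setMethod("asIgraph", "GeneNetwork", function(x, ...) {
  g <- igraph::graph_from_data_frame(x@edges, directed = FALSE,
                                     vertices = data.frame(name = x@nodes))
  igraph::E(g)$weight <- x@edges$weight
  g
})

#' Weighted adjacency matrix of a GeneNetwork
#'
#' @param net a GeneNetwork.
#' @return symmetric numeric matrix with zero diagonal, dimnames = gene ids.
#' @export
adjacencyMatrix <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  n <- length(net@nodes)
  A <- matrix(0, n, n, dimnames = list(net@nodes, net@nodes))
  if (nrow(net@edges)) {
    i <- match(net@edges$gene1, net@nodes)
    j <- match(net@edges$gene2, net@nodes)
    A[cbind(i, j)] <- net@edges$weight
    A[cbind(j, i)] <- net@edges$weight
  }
  A
}

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork with", length(object@nodes), "nodes,",
      nrow(object@edges), "edges,", length(object@seeds), "seed genes\n")
})

#' Restrict a network to its largest connected component
#'
#' @param net a GeneNetwork.
#' @return a GeneNetwork containing only the largest component (seeds
#'   outside it are dropped).
#' @export
largestComponent <- function(net) {
  g <- asIgraph(net)
  comp <- igraph::components(g)
  keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  ed <- net@edges[net@edges$gene1 %in% keep & net@edges$gene2 %in% keep, ,
                  drop = FALSE]
  geneNetwork(ed, nodes = intersect(net@nodes, keep),
              seeds = intersect(net@seeds, keep))
}
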