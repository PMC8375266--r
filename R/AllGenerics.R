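#' @rdname geneNetwork
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname geneNetwork
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname geneNetwork
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))

#' @rdname geneNetwork
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' @rdname GeneEmbedding-class
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname SmrResults-class
#' @export
setGeneric("smrTable", function(x) standardGeneric("smrTable"))

#' @rdname SmrResults-class
#' @export
setGeneric("significantGenes", function(x) standardGeneric("significantGenes"))
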