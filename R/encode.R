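# Network encoders: turn the gene interaction graph into per-gene feature
# vectors for the classifier.

#' Encode a gene network by random-walk adjacency reconstruction
#'
#' Learns one \code{cfg$dim}-dimensional vector per gene by minimizing the
#' adjacency-reconstruction objective
#' f(X) = sum_{i<j} (A_ij - x_i . x_j)^2
#' over the flattened embedding matrix with the random-walk optimizer
#' ([rwMinimize()]); A is the weighted adjacency (diagonal excluded).
#' Genes that interact are driven toward aligned vectors, so densely
#' interconnected disease modules end up clustered in feature space. The
#' objective is evaluated in the algebraically expanded form
#' (edge sum + Gram matrix), costing O(|E| d + |V| d^2) per evaluation
#' instead of O(|V|^2 d).
#'
#' The start point is drawn uniform(-0.1, 0.1) under \code{cfg$seed}, so
#' the encoding is deterministic for a fixed configuration.
#'
#' @param net a [GeneNetwork-class].
#' @param cfg an [rwConfig()]; \code{cfg$dim} must be smaller than the
#'   number of nodes (an embedding as wide as the graph is
#'   over-parameterized).
#' @return a [GeneEmbedding-class] with \code{objective} set to the final
#'   objective value.
#' @export
encodeNetwork <- function(net, cfg = rwConfig()) {
  stopifnot(is(net, "GeneNetwork"), inherits(cfg, "RwConfig"))
  n <- length(net@nodes)
  d <- cfg$dim
  if (d >= n)
    stop("configuration error: dim (", d, ") must be < number of nodes (",
         n, ")")
  i1 <- match(net@edges$gene1, net@nodes)
  i2 <- match(net@edges$gene2, net@nodes)
  w <- net@edges$weight
  constA <- 2 * sum(w^2)        # ||A||_F^2 (each edge appears twice)
  obj <- function(x) {
    X <- matrix(x, n, d)
    edgeDot <- if (length(i1))
      sum(w * rowSums(X[i1, , drop = FALSE] * X[i2, , drop = FALSE]))
    else 0
    G <- crossprod(X)
    rs <- rowSums(X^2)
    0.5 * (constA - 4 * edgeDot + sum(G^2) - sum(rs^2))
  }
  x0 <- withSeed(deriveSeed(cfg$seed, "rw-init"),
                 stats::runif(n * d, -0.1, 0.1))
  fit <- rwMinimize(obj, x0, cfg)
  feat <- matrix(fit$x, n, d,
                 dimnames = list(net@nodes, paste0("dim", seq_len(d))))
  new("GeneEmbedding", features = feat, objective = fit$f, encoder = "rw")
}

#' Encode a gene network by random walk with restart
#'
#' Baseline encoder: each gene's feature vector is its stationary
#' random-walk-with-restart affinity to every seed gene. The walker
#' follows the row-stochastic transition matrix P = D^-1 A and restarts
#' at the seed with probability \code{restartProb}; the stationary
#' distribution solves (I - (1 - a) P^T) p = a e_s exactly (dense linear
#' solve, no iteration error). Because P is row-stochastic, each seed's
#' affinity column sums to 1; with \code{restartProb = 1} the affinity is
#' the indicator of the seed itself.
#'
#' @param net a [GeneNetwork-class] with at least one seed gene.
#' @param restartProb restart probability in (0, 1].
#' @return a [GeneEmbedding-class] (one column per seed gene;
#'   \code{objective} is NA). Isolated nodes get zero affinity, with a
#'   warning.
#' @export
rwrEncode <- function(net, restartProb = 0.5) {
  stopifnot(is(net, "GeneNetwork"),
            restartProb > 0, restartProb <= 1)
  if (!length(net@seeds)) stop("rwrEncode needs at least one seed gene")
  A <- adjacencyMatrix(net)
  deg <- rowSums(A)
  if (any(deg == 0))
    warning(sum(deg == 0), " isolated node(s): affinity fixed at 0")
  P <- A / pmax(deg, 1)          # zero rows stay zero (isolated nodes)
  n <- nrow(A)
  M <- diag(n) - (1 - restartProb) * t(P)
  E <- matrix(0, n, length(net@seeds))
  E[cbind(match(net@seeds, net@nodes), seq_along(net@seeds))] <- 1
  feat <- restartProb * solve(M, E)
  dimnames(feat) <- list(net@nodes, net@seeds)
  new("GeneEmbedding", features = feat, objective = NA_real_,
      encoder = "rwr")
}

#' @rdname GeneEmbedding-class
#' @param x a GeneEmbedding.
#' @export
setMethod("featureMatrix", "GeneEmbedding", function(x) x@features)

setMethod("show", "GeneEmbedding", function(object) {
  cat("GeneEmbedding (", object@encoder, "): ",
      nrow(object@features), " genes x ", ncol(object@features),
      " dims", sep = "")
  if (!is.na(object@objective))
    cat(", final objective ", signif(object@objective, 4), sep = "")
  cat("\n")
})

#' Write an embedding as TSV (gene_id + one column per dimension)
#'
#' @param embedding a [GeneEmbedding-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEmbedding <- function(embedding, path) {
  stopifnot(is(embedding, "GeneEmbedding"))
  out <- data.frame(gene_id = rownames(embedding@features),
                    embedding@features, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
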