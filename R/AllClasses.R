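#' @import methods
NULL

#' GeneNetwork: a weighted undirected gene interaction graph with seed labels
#'
#' Container for a gene interaction network. Edges are stored as an
#' undirected edge table (each unordered pair appears once, with
#' \code{gene1 < gene2} lexicographically); seed genes are the positive
#' labels used downstream for classification and for random walk with
#' restart. All remaining genes are treated as unlabeled, not negative.
#'
#' @slot nodes character vector of gene identifiers.
#' @slot edges data.frame with columns \code{gene1}, \code{gene2},
#'   \code{weight} (non-negative).
#' @slot seeds character vector of seed gene identifiers; must be a subset
#'   of \code{nodes}.
#'
#' @seealso [geneNetwork()] for the user-facing constructor,
#'   [asIgraph()] for conversion.
#' @export
setClass("GeneNetwork",
  representation(nodes = "character", edges = "data.frame",
                 seeds = "character"))

setValidity("GeneNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  if (!all(c("gene1", "gene2", "weight") %in% names(ed)))
    msg <- c(msg, "edges must have columns gene1, gene2, weight")
  else {
    if (any(ed$gene1 == ed$gene2))
      msg <- c(msg, "self-loops are not allowed")
    if (any(ed$weight < 0))
      msg <- c(msg, "edge weights must be non-negative")
    if (!all(ed$gene1 %in% object@nodes) || !all(ed$gene2 %in% object@nodes))
      msg <- c(msg, "all edge endpoints must be listed in nodes")
    key <- paste(pmin(ed$gene1, ed$gene2), pmax(ed$gene1, ed$gene2))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate undirected edges")
  }
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node identifiers")
  if (!all(object@seeds %in% object@nodes))
    msg <- c(msg, "every seed gene must be a node")
  if (length(msg)) msg else TRUE
})

#' GeneEmbedding: per-gene feature vectors from a network encoder
#'
#' @slot features numeric matrix, one row per gene (rownames are gene ids),
#'   one column per embedding dimension.
#' @slot objective final value of the encoder objective (NA for encoders
#'   that do not minimize one, e.g. random walk with restart).
#' @slot encoder character, which encoder produced the features
#'   (\code{"rw"} or \code{"rwr"}).
#' @export
setClass("GeneEmbedding",
  representation(features = "matrix", objective = "numeric",
                 encoder = "character"))

setValidity("GeneEmbedding", function(object) {
  msg <- character()
  if (is.null(rownames(object@features)))
    msg <- c(msg, "features must have gene ids as rownames")
  if (!all(is.finite(object@features)))
    msg <- c(msg, "features must be finite")
  if (length(msg)) msg else TRUE
})

#' CvReport: stratified cross-validation metrics for a gene classifier
#'
#' @slot foldAuc numeric vector, AUC per fold (possibly averaged over
#'   negative resamplings).
#' @slot foldAupr numeric vector, AUPR per fold.
#' @slot meanAuc mean of foldAuc.
#' @slot meanAupr mean of foldAupr.
#' @slot roc data.frame of pooled out-of-fold ROC points (fpr, tpr).
#' @slot folds integer vector of fold assignments, named by gene id
#'   (from the first negative resampling when several are averaged).
#' @export
setClass("CvReport",
  representation(foldAuc = "numeric", foldAupr = "numeric",
                 meanAuc = "numeric", meanAupr = "numeric",
                 roc = "data.frame", folds = "integer"))

setValidity("CvReport", function(object) {
  ok <- all(object@foldAuc >= 0 & object@foldAuc <= 1) &&
        all(object@foldAupr >= 0 & object@foldAupr <= 1)
  if (!ok) "AUC and AUPR must lie in [0, 1]" else TRUE
})

#' SmrResults: per-gene summary-data Mendelian randomization results
#'
#' One row per gene that had a usable instrument: the top cis-eQTL SNP, the
#' Wald-ratio estimate of the expression-to-trait effect, its Delta-method
#' variance, the SMR test statistic and p-value, the multiplicity-adjusted
#' p-value and a significance flag.
#'
#' @slot results data.frame with columns gene, snp, b_xy, se_xy, t_smr,
#'   p_smr, p_adj, significant.
#' @slot nGenesTested number of genes entering the multiple-testing
#'   correction.
#' @slot correction "bonferroni" or "BH".
#' @slot alpha family-wise / FDR significance level.
#' @slot counts named integer vector of filtering-stage counts
#'   (SNPs read, shared, harmonized, instruments, significant genes).
#' @export
setClass("SmrResults",
  representation(results = "data.frame", nGenesTested = "integer",
                 correction = "character", alpha = "numeric",
                 counts = "integer"))

setValidity("SmrResults", function(object) {
  res <- object@results
  need <- c("gene", "snp", "b_xy", "se_xy", "t_smr", "p_smr", "p_adj",
            "significant")
  msg <- character()
  if (!all(need %in% names(res)))
    msg <- c(msg, paste("results must have columns:",
                        paste(need, collapse = ", ")))
  else if (nrow(res)) {
    if (any(res$t_smr < 0)) msg <- c(msg, "t_smr must be non-negative")
    if (any(res$p_smr <= 0 | res$p_smr > 1))
      msg <- c(msg, "p_smr must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})
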