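#' Wald-ratio (2SLS) estimate of the expression-to-trait effect
#'
#' With a SNP z as instrument, the effect of gene expression x on trait y is
#' estimated as the ratio of the SNP-trait effect to the SNP-expression
#' effect, b_xy = b_zy / b_zx. In the two-sample setting both effects come
#' from summary statistics of independent cohorts.
#'
#' @param betaZy numeric, SNP effect(s) on the trait.
#' @param betaZx numeric, SNP effect(s) on expression (must be non-zero).
#' @return numeric, betaZy / betaZx (vectorized).
#' @examples
#' waldRatio(0.2, 0.5)  # 0.4
#' @export
waldRatio <- function(betaZy, betaZx) {
  if (any(!is.finite(betaZx)) || any(betaZx == 0))
    stop("undefined instrument: betaZx must be finite and non-zero")
  betaZy / betaZx
}

#' Sampling variance of the 2SLS estimate in a single-sample design
#'
#' Closed-form variance of the instrumental-variable estimate when trait,
#' expression and genotype are measured in one cohort:
#' var(b_xy) = var(y) (1 - P2xy) / (n var(x) P2zy),
#' where P2xy is the proportion of trait variance explained by expression
#' and P2zy the proportion explained by the instrument. Exposed for
#' completeness; the pipeline's operative path is the two-sample
#' Delta-method variance ([varXyDelta()]).
#'
#' @param varY variance of the trait.
#' @param varX variance of the expression level.
#' @param n sample size.
#' @param p2xy fraction of var(y) explained by x, in \[0, 1).
#' @param p2zy fraction of var(y) explained by z, in (0, 1).
#' @return numeric variance.
#' @export
varXySingleSample <- function(varY, varX, n, p2xy, p2zy) {
  stopifnot(varY > 0, varX > 0, n > 0, p2xy >= 0, p2xy <= 1)
  if (any(p2zy <= 0))
    stop("infinite variance: p2zy must be positive")
  varY * (1 - p2xy) / (n * varX * p2zy)
}

#' Delta-method variance of the two-sample Wald ratio
#'
#' First-order Taylor approximation of var(b_zy / b_zx) with independent
#' numerator and denominator (two-sample design, zero covariance):
#' (b_zy^2 / b_zx^2) (se_zx^2 / b_zx^2 + se_zy^2 / b_zy^2), computed in the
#' algebraically expanded form
#' se_zy^2 / b_zx^2 + b_zy^2 se_zx^2 / b_zx^4 so that betaZy = 0 is safe.
#'
#' @param betaZx,seZx SNP-expression effect and its standard error.
#' @param betaZy,seZy SNP-trait effect and its standard error.
#' @return numeric variance (vectorized).
#' @export
varXyDelta <- function(betaZx, seZx, betaZy, seZy) {
  if (any(!is.finite(betaZx)) || any(betaZx == 0))
    stop("undefined instrument: betaZx must be finite and non-zero")
  seZy^2 / betaZx^2 + betaZy^2 * seZx^2 / betaZx^4
}

#' SMR test statistic and p-value
#'
#' Approximate chi-squared test of the two-sample Mendelian randomization
#' effect from the GWAS and eQTL z-statistics:
#' T = z_zy^2 z_zx^2 / (z_zy^2 + z_zx^2), referred to a chi-squared
#' distribution with one degree of freedom. T is symmetric in its
#' arguments and bounded by min(z_zy^2, z_zx^2): the test can never be more
#' significant than the weaker of the two associations.
#'
#' @param zZy numeric, GWAS z-statistic(s).
#' @param zZx numeric, eQTL z-statistic(s).
#' @return a list with numeric components \code{t} and \code{p} (upper-tail
#'   chi-squared, 1 df), vectorized over the inputs.
#' @examples
#' tSmr(3, 4)$t  # 144/25 = 5.76
#' @export
tSmr <- function(zZy, zZx) {
  if (any(zZy == 0 & zZx == 0))
    stop("undefined statistic: zZy and zZx are both zero")
  t <- zZy^2 * zZx^2 / (zZy^2 + zZx^2)
  # upper tail directly: no 1 - CDF cancellation for extreme statistics
  list(t = t, p = stats::pchisq(t, df = 1, lower.tail = FALSE))
}

#' Select the instrument SNP for one gene
#'
#' Standard SMR practice: the cis-SNP with the smallest eQTL p-value,
#' retained only if it passes the instrument significance threshold.
#' Ties on p are broken by the lexicographically smallest SNP id, making
#' selection deterministic.
#'
#' @param pairs data.frame of harmonized SNP-gene pairs
#'   (see [harmonizeEffects()]).
#' @param gene gene id to select an instrument for.
#' @param pEqtlMax instrument threshold on the eQTL p-value
#'   (default 5e-8, genome-wide significance).
#' @return single-row data.frame, or NULL when no SNP passes (a valid
#'   outcome, not an error).
#' @export
selectInstrument <- function(pairs, gene, pEqtlMax = 5e-8) {
  rows <- pairs[pairs$gene_id == gene & pairs$p_zx <= pEqtlMax, ,
                drop = FALSE]
  if (!nrow(rows)) return(NULL)
  rows <- rows[order(rows$p_zx, rows$snp_id), , drop = FALSE]
  rows[1, , drop = FALSE]
}

#' Run summary-data Mendelian randomization across genes
#'
#' Full SMR pass: harmonize GWAS and eQTL effect alleles, pick the top
#' cis-eQTL SNP per gene as instrument, compute the Wald ratio, its
#' Delta-method variance, the SMR chi-squared statistic and p-value, and
#' flag significance after multiple-testing correction over the genes
#' actually tested. The complete per-gene table is returned regardless of
#' significance.
#'
#' @param gwas data.frame of GWAS summary records (see [readGwas()]).
#' @param eqtl data.frame of eQTL summary records (see [readEqtl()]).
#' @param pEqtlMax instrument p-value threshold (default 5e-8).
#' @param correction multiple-testing procedure, "bonferroni" (default)
#'   or "BH".
#' @param alpha significance level after correction (default 0.05).
#' @param dropAmbiguous drop strand-ambiguous (A/T, C/G) SNPs during
#'   harmonization (default TRUE).
#' @param genePositions optional data.frame (gene_id, chrom, pos); when
#'   given and the GWAS records carry positions, SNP-gene pairs farther
#'   apart than \code{cisWindow} are dropped. When absent the eQTL file's
#'   (SNP, gene) pairing is trusted as already cis.
#' @param cisWindow cis distance in bp (default 1e6).
#' @return an [SmrResults-class] object.
#' @export
runSmr <- function(gwas, eqtl, pEqtlMax = 5e-8,
                   correction = c("bonferroni", "BH"), alpha = 0.05,
                   dropAmbiguous = TRUE, genePositions = NULL,
                   cisWindow = 1e6) {
  correction <- match.arg(correction)
  pairs <- harmonizeEffects(gwas, eqtl, dropAmbiguous = dropAmbiguous)
  if (!is.null(genePositions) && !all(is.na(gwas$pos))) {
    snpPos <- gwas$pos[match(pairs$snp_id, gwas$snp_id)]
    snpChr <- gwas$chrom[match(pairs$snp_id, gwas$snp_id)]
    gp <- match(pairs$gene_id, genePositions$gene_id)
    keep <- !is.na(gp) & !is.na(snpPos) &
      snpChr == genePositions$chrom[gp] &
      abs(snpPos - genePositions$pos[gp]) <= cisWindow
    att <- attributes(pairs)
    pairs <- pairs[keep, , drop = FALSE]
    attr(pairs, "nShared") <- att$nShared
    attr(pairs, "exclusions") <- c(att$exclusions,
                                   trans_window = sum(!keep))
  }
  counts <- c(snps_gwas = length(unique(gwas$snp_id)),
              snps_eqtl = length(unique(eqtl$snp_id)),
              snps_shared = attr(pairs, "nShared"),
              pairs_harmonized = nrow(pairs))
  if (!nrow(pairs)) {
    warning("no usable SNP-gene pairs after harmonization ",
            "(no shared SNPs, or all filtered); empty result")
    empty <- data.frame(gene = character(), snp = character(),
                        b_xy = numeric(), se_xy = numeric(),
                        t_smr = numeric(), p_smr = numeric(),
                        p_adj = numeric(), significant = logical())
    return(new("SmrResults", results = empty, nGenesTested = 0L,
               correction = correction, alpha = alpha,
               counts = as.integer(c(counts, genes_tested = 0L,
                                     genes_significant = 0L)) |>
                 stats::setNames(c(names(counts), "genes_tested",
                                   "genes_significant"))))
  }
  genes <- sort(unique(pairs$gene_id))
  sel <- lapply(genes, function(g) selectInstrument(pairs, g, pEqtlMax))
  names(sel) <- genes
  sel <- sel[!vapply(sel, is.null, logical(1))]
  if (length(sel)) {
    top <- do.call(rbind, sel)
    zZy <- top$beta_zy / top$se_zy
    zZx <- top$beta_zx / top$se_zx
    ts <- tSmr(zZy, zZx)
    bXy <- waldRatio(top$beta_zy, top$beta_zx)
    vXy <- varXyDelta(top$beta_zx, top$se_zx, top$beta_zy, top$se_zy)
    pAdj <- stats::p.adjust(ts$p, method = if (correction == "bonferroni")
      "bonferroni" else "BH")
    res <- data.frame(gene = top$gene_id, snp = top$snp_id, b_xy = bXy,
                      se_xy = sqrt(vXy), t_smr = ts$t, p_smr = ts$p,
                      p_adj = pAdj, significant = pAdj <= alpha,
                      row.names = NULL, stringsAsFactors = FALSE)
    res <- res[order(res$p_smr, res$gene), , drop = FALSE]
    rownames(res) <- NULL
  } else {
    res <- data.frame(gene = character(), snp = character(),
                      b_xy = numeric(), se_xy = numeric(),
                      t_smr = numeric(), p_smr = numeric(),
                      p_adj = numeric(), significant = logical())
  }
  counts <- c(counts, genes_tested = length(sel),
              genes_significant = sum(res$significant))
  new("SmrResults", results = res, nGenesTested = length(sel),
      correction = correction, alpha = alpha,
      counts = stats::setNames(as.integer(counts), names(counts)))
}

#' @rdname SmrResults-class
#' @param x an SmrResults object.
#' @export
setMethod("smrTable", "SmrResults", function(x) x@results)

#' @rdname SmrResults-class
#' @export
setMethod("significantGenes", "SmrResults",
          function(x) x@results$gene[x@results$significant])

setMethod("show", "SmrResults", function(object) {
  cat("SmrResults:", object@nGenesTested, "genes tested,",
      sum(object@results$significant), "significant (",
      object@correction, ", alpha =", object@alpha, ")\n")
  if (nrow(object@results))
    print(utils::head(object@results, 6))
})

#' Overlap between two prioritized gene sets
#'
#' @param smrSig character vector (e.g. SMR-significant genes).
#' @param svmPred character vector (e.g. SVM-predicted genes).
#' @return list with \code{intersection} (character) and \code{jaccard}
#'   (|intersection| / |union|; 0 when both sets are empty).
#' @examples
#' overlapGenes(c("A", "B", "C"), c("B", "C", "D"))
#' @export
overlapGenes <- function(smrSig, svmPred) {
  a <- unique(as.character(smrSig)); b <- unique(as.character(svmPred))
  int <- intersect(a, b)
  uni <- union(a, b)
  list(intersection = sort(int),
       jaccard = if (length(uni)) length(int) / length(uni) else 0)
}
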