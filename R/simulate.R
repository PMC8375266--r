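# Synthetic two-sample summary statistics and gene networks with known
# ground truth. Simulation is at the level of estimates + standard errors
# (no individual genotypes): the analysis only ever consumes summary data.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the study conditions exercised throughout the test
#' suite: 200 genes x 10 cis-SNPs for the summary-statistic arm, a
#' 240-gene scale-free network with a 60-gene planted disease module and
#' 34 seed genes for the network arm, two-sample GWAS/eQTL sizes of
#' 10,000, a causal expression-to-trait effect of 0.3, and one strong top
#' cis-eQTL per gene (|beta| = 0.3, |z| around 20 at n = 10,000, typical
#' of top blood cis-eQTLs).
#'
#' @param nGenes number of genes carrying cis-SNPs.
#' @param nSnpsPerGene cis-SNPs per gene.
#' @param nCausalGenes genes with a genuine expression-mediated effect.
#' @param bXyCausal true expression-to-trait effect for causal genes.
#' @param eqtlEffectSd SD of ordinary true cis-eQTL effects.
#' @param topEqtlEffect |effect| of the strongest cis-SNP per gene (the
#'   instrument); its sign is random.
#' @param nGwas,nEqtl sample sizes of the two independent cohorts.
#' @param mafRange range the per-SNP minor allele frequency is drawn from;
#'   must lie strictly inside (0, 0.5).
#' @param networkModel "barabasi_albert" (scale-free, default) or
#'   "erdos_renyi".
#' @param moduleSize number of genes in the planted disease module.
#' @param moduleEdgeProb edge probability inside the module.
#' @param nSeedGenes seed (known disease) genes sampled from the module.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return validated list of class "SimulationConfig".
#' @export
simulationConfig <- function(nGenes = 200, nSnpsPerGene = 10,
                             nCausalGenes = min(20, nGenes),
                             bXyCausal = 0.3,
                             eqtlEffectSd = 0.1, topEqtlEffect = 0.3,
                             nGwas = 10000, nEqtl = 10000,
                             mafRange = c(0.05, 0.45),
                             networkModel = c("barabasi_albert",
                                              "erdos_renyi"),
                             moduleSize = min(60, nGenes),
                             moduleEdgeProb = 0.3,
                             nSeedGenes = min(34, moduleSize),
                             seed = 1L) {
  networkModel <- match.arg(networkModel)
  stopifnot(nGenes >= 1, nSnpsPerGene >= 1,
            nCausalGenes >= 0, nCausalGenes <= nGenes,
            moduleSize <= nGenes, nSeedGenes <= moduleSize,
            moduleEdgeProb >= 0, moduleEdgeProb <= 1,
            nGwas > 1, nEqtl > 1, eqtlEffectSd > 0, topEqtlEffect >= 0,
            length(mafRange) == 2, mafRange[1] <= mafRange[2])
  if (mafRange[1] <= 0 || mafRange[2] >= 0.5)
    stop("degenerate mafRange: must lie strictly inside (0, 0.5)")
  structure(list(nGenes = nGenes, nSnpsPerGene = nSnpsPerGene,
                 nCausalGenes = nCausalGenes, bXyCausal = bXyCausal,
                 eqtlEffectSd = eqtlEffectSd,
                 topEqtlEffect = topEqtlEffect, nGwas = nGwas,
                 nEqtl = nEqtl, mafRange = mafRange,
                 networkModel = networkModel, moduleSize = moduleSize,
                 moduleEdgeProb = moduleEdgeProb,
                 nSeedGenes = nSeedGenes, seed = as.integer(seed)),
            class = "SimulationConfig")
}

.geneIds <- function(n) sprintf("G%04d", seq_len(n))

# Non-ambiguous allele pairs only, so simulated SNPs survive default
# harmonization; strand-ambiguous cases are constructed explicitly in tests.
.allelePairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                         "G", "A", "C", "A", "G", "T", "C", "T"),
                       ncol = 2, byrow = TRUE)

#' Simulate two-sample GWAS and eQTL summary statistics
#'
#' For each gene, \code{nSnpsPerGene} cis-SNPs receive true eQTL effects:
#' the first SNP per gene is the strong instrument (|beta_zx| =
#' \code{topEqtlEffect}, random sign), the rest are drawn
#' N(0, eqtlEffectSd^2). The true SNP-trait effect is
#' \code{b_xy * beta_zx} for causal genes and 0 otherwise: SNPs act on the
#' trait only through expression. Estimated effects add independent
#' Gaussian noise with the per-allele standard error
#' 1 / sqrt(2 maf (1 - maf) n) in each cohort (two-sample: GWAS and eQTL
#' noise independent). A fifth of eQTL records are stored with swapped
#' alleles and negated beta so that harmonization is exercised (and
#' inverted exactly) downstream.
#'
#' @param cfg a [simulationConfig()].
#' @param causalGenes optional character vector forcing which genes are
#'   causal (e.g. genes of a planted network module); default: sampled.
#' @return list with components \code{gwas}, \code{eqtl} (data.frames in
#'   the [readGwas()] / [readEqtl()] layouts) and \code{truth} (list:
#'   causalGenes, trueBxy named by gene, snpTruth data.frame with the true
#'   per-SNP effects, and the config).
#' @export
simulateSummaryStats <- function(cfg, causalGenes = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  withSeed(deriveSeed(cfg$seed, "sumstats"), {
    genes <- .geneIds(cfg$nGenes)
    if (is.null(causalGenes)) {
      causalGenes <- sort(sample(genes, cfg$nCausalGenes))
    } else {
      stopifnot(all(causalGenes %in% genes))
      causalGenes <- sort(unique(causalGenes))
    }
    nSnp <- cfg$nGenes * cfg$nSnpsPerGene
    geneOf <- rep(genes, each = cfg$nSnpsPerGene)
    snpIds <- sprintf("rs%06d", seq_len(nSnp))
    isTop <- rep(c(TRUE, rep(FALSE, cfg$nSnpsPerGene - 1L)), cfg$nGenes)

    maf <- stats::runif(nSnp, cfg$mafRange[1], cfg$mafRange[2])
    seZx <- 1 / sqrt(2 * maf * (1 - maf) * cfg$nEqtl)
    seZy <- 1 / sqrt(2 * maf * (1 - maf) * cfg$nGwas)

    trueBzx <- stats::rnorm(nSnp, 0, cfg$eqtlEffectSd)
    trueBzx[isTop] <- sample(c(-1, 1), sum(isTop), replace = TRUE) *
      cfg$topEqtlEffect
    trueBxy <- stats::setNames(ifelse(genes %in% causalGenes,
                                      cfg$bXyCausal, 0), genes)
    trueBzy <- trueBxy[geneOf] * trueBzx

    betaZx <- trueBzx + stats::rnorm(nSnp, 0, seZx)
    betaZy <- trueBzy + stats::rnorm(nSnp, 0, seZy)
    pZx <- 2 * stats::pnorm(-abs(betaZx / seZx))
    pZy <- 2 * stats::pnorm(-abs(betaZy / seZy))

    al <- .allelePairs[sample(nrow(.allelePairs), nSnp, replace = TRUE), ,
                       drop = FALSE]
    gwas <- data.frame(snp_id = snpIds, chrom = "1",
                       pos = match(geneOf, genes) * 1000000L +
                         (seq_len(nSnp) - 1L) %% cfg$nSnpsPerGene * 1000L,
                       effect_allele = al[, 1], other_allele = al[, 2],
                       eaf = maf, beta_zy = betaZy, se_zy = seZy,
                       p_zy = pmax(pZy, .Machine$double.xmin),
                       n = as.integer(cfg$nGwas),
                       stringsAsFactors = FALSE)
    # swap allele orientation for a fifth of eQTL records: harmonization
    # must flip these back without loss
    swap <- seq_len(nSnp) %% 5L == 0L
    eqtl <- data.frame(snp_id = snpIds, gene_id = geneOf,
                       effect_allele = ifelse(swap, al[, 2], al[, 1]),
                       other_allele = ifelse(swap, al[, 1], al[, 2]),
                       beta_zx = ifelse(swap, -betaZx, betaZx),
                       se_zx = seZx,
                       p_zx = pmax(pZx, .Machine$double.xmin),
                       stringsAsFactors = FALSE)
    truth <- list(causalGenes = causalGenes, trueBxy = trueBxy,
                  snpTruth = data.frame(snp_id = snpIds, gene_id = geneOf,
                                        maf = maf, true_b_zx = trueBzx,
                                        true_b_zy = trueBzy,
                                        is_top = isTop,
                                        stringsAsFactors = FALSE),
                  config = cfg)
    list(gwas = gwas, eqtl = eqtl, truth = truth)
  })
}

#' Simulate a gene network with a planted disease module
#'
#' Draws a base graph (scale-free Barabasi-Albert with 2 edges per new
#' node, or Erdos-Renyi matched to the same mean degree), then rewires a
#' random \code{moduleSize}-gene subset into a dense module by adding
#' edges between module genes independently with probability
#' \code{moduleEdgeProb}. Seed genes are sampled from the module; the
#' largest connected component is kept.
#'
#' @param cfg a [simulationConfig()].
#' @return list with components \code{network} (a [GeneNetwork-class])
#'   and \code{truth} (list: moduleGenes, seedGenes).
#' @export
simulateNetwork <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  withSeed(deriveSeed(cfg$seed, "network"), {
    n <- cfg$nGenes
    genes <- .geneIds(n)
    g <- if (cfg$networkModel == "barabasi_albert") {
      igraph::sample_pa(n, m = 2, directed = FALSE)
    } else {
      igraph::sample_gnp(n, p = min(1, 4 / (n - 1)))
    }
    baseDensity <- igraph::edge_density(g)
    if (cfg$moduleEdgeProb <= baseDensity)
      warning("moduleEdgeProb <= base graph density: planted module ",
              "carries no signal")
    moduleIdx <- sort(sample(n, cfg$moduleSize))
    if (cfg$moduleSize >= 2) {
      pairs <- utils::combn(moduleIdx, 2)
      add <- stats::runif(ncol(pairs)) < cfg$moduleEdgeProb
      if (any(add))
        g <- igraph::add_edges(g, as.vector(pairs[, add, drop = FALSE]))
      g <- igraph::simplify(g)
    }
    igraph::V(g)$name <- genes
    ed <- igraph::as_data_frame(g, what = "edges")
    moduleGenes <- genes[moduleIdx]
    seedGenes <- sort(sample(moduleGenes, cfg$nSeedGenes))
    net <- geneNetwork(ed[, c("from", "to")], nodes = genes,
                       seeds = seedGenes)
    net <- largestComponent(net)
    list(network = net,
         truth = list(moduleGenes = intersect(moduleGenes, net@nodes),
                      seedGenes = seedGenes))
  })
}
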