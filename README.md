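# netSMR

Disease-gene prioritization by fusing two independent lines of evidence:

1. **Network arm** — a gene interaction network is encoded into
   per-gene feature vectors (random-walk stochastic optimization of an
   adjacency-reconstruction objective, or random walk with restart),
   and a support vector machine trained on seed (known disease) genes
   versus sampled negatives ranks every remaining gene by
   cross-validated AUC/AUPR and calls novel candidates.
2. **Summary-statistic arm** — summary-data Mendelian randomization
   (SMR) integrates GWAS and cis-eQTL summary statistics to test, per
   gene, whether expression mediates a SNP–trait association.

Genes flagged by both arms carry orthogonal evidence; the package
reports their intersection. A synthetic-data generator with known
ground truth (planted network module, genes with genuine
expression-mediated effects) makes every stage testable end to end —
type-I error, power, parameter recovery, classifier performance —
without any external download.

## The statistics at the core

For a SNP *z*, gene expression *x* and trait *y*, with two-sample
summary estimates (b̂<sub>zy</sub>, se<sub>zy</sub>) from a GWAS and
(b̂<sub>zx</sub>, se<sub>zx</sub>) from an eQTL study:

- Wald ratio: **b̂<sub>xy</sub> = b̂<sub>zy</sub> / b̂<sub>zx</sub>**
- Delta-method variance (independent samples, zero covariance):
  **var(b̂<sub>xy</sub>) = se<sub>zy</sub>²/b<sub>zx</sub>² +
  b<sub>zy</sub>² se<sub>zx</sub>²/b<sub>zx</sub>⁴**
- Test statistic:
  **T<sub>SMR</sub> = z<sub>zy</sub>² z<sub>zx</sub>² /
  (z<sub>zy</sub>² + z<sub>zx</sub>²) ~ χ²₁**,
  with the top cis-eQTL SNP (p ≤ 5×10⁻⁸) as each gene's instrument and
  Bonferroni correction across tested genes.

The network encoder minimizes
**f(X) = Σ<sub>i&lt;j</sub> (A<sub>ij</sub> − x<sub>i</sub>·x<sub>j</sub>)²**
with a derivative-free random walk: uniform random directions,
normalized steps of length λ, strict-improvement acceptance, λ halved
after N consecutive failures, termination at λ < ε. See
`vignettes/methods.Rmd` for the full model, assumptions, parameter
defaults and limitations.

## Worked example

Simulate a 120-gene network with a 30-gene planted disease module and
matching two-sample summary statistics, then run both arms:

```r
library(netSMR)

cfg <- simulationConfig(nGenes = 120, nSnpsPerGene = 8, nCausalGenes = 12,
                        moduleSize = 30, nSeedGenes = 15, seed = 7)
ns  <- simulateNetwork(cfg)
ns$network
#> GeneNetwork with 120 nodes, 368 edges, 15 seed genes

sim <- simulateSummaryStats(cfg, causalGenes = ns$truth$moduleGenes[1:12])
smr <- runSmr(sim$gwas, sim$eqtl)
smr
#> SmrResults: 120 genes tested, 12 significant ( bonferroni , alpha = 0.05 )
#>    gene      snp      b_xy      se_xy    t_smr        p_smr        p_adj
#> 1 G0036 rs000281 0.3361621 0.04768957 49.68790 1.802545e-12 2.163054e-10
#> 2 G0017 rs000129 0.3792436 0.06639019 32.63088 1.114302e-08 1.337163e-06
#> ...

emb <- encodeNetwork(ns$network, rwConfig(dim = 8, lambda0 = 2,
                                          nTries = 40, maxEvals = 40000,
                                          seed = 7))
cv <- cvResampledNegatives(emb, ns$network, k = 5, seed = 7, nResamples = 3)
cv
#> CvReport: 15 fold metric(s)
#>   mean AUC  = 0.948
#>   mean AUPR = 0.95

negs <- sampleNegatives(ns$network, 15, seed = 7)
lf   <- labeledFeatures(emb, seedGenes(ns$network), negs)
pred <- predictNovel(trainSvm(lf), lf)
ov   <- overlapGenes(significantGenes(smr), pred$predictedPositive)
```

The 12 planted causal genes come back as the 12 SMR-significant genes
with effect estimates near the true b<sub>xy</sub> = 0.3; the SVM,
trained only on network structure, recovers the module (mean
cross-validated AUC 0.948) and calls 18 novel genes, 4 of which are
also SMR-significant. The same flow runs as one command —
`runPipeline(demoConfig())` — which writes every stage artifact
(`gwas.ma`, `eqtl.tsv`, `embedding.tsv`, `smr.tsv`, `predictions.tsv`,
`overlap.tsv`) plus a manifest with file hashes and per-stage counts;
`pipelineReport(manifest)` prints the filtering-funnel accounting.
Real data drop in through the same interfaces: `readGwas()` (COJO
`.ma` dialect or generic TSV), `readEqtl()`, `readGeneList()` and
`geneNetwork()` on a STRING-style edge list.

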