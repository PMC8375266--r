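---
title: "Methods: network-encoded SVM prioritization and summary-data Mendelian randomization"
author: "netSMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-encoded SVM prioritization and summary-data Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Genome-wide association studies locate trait-associated SNPs, but the
nearest gene is often not the causal one, and machine-learning gene
prioritizers rank candidates without saying anything about mechanism.
netSMR implements a fused design that attacks the problem from two
independent sides and intersects the answers:

1. **Network arm.** Known disease genes (*seed genes*) sit in densely
   interacting neighborhoods of the gene interaction network. Encoding
   the network into per-gene feature vectors and training a support
   vector machine on seeds versus sampled negatives ranks every other
   gene by how "seed-like" its network context is.
2. **Summary-statistic arm.** If a SNP's effect on a trait is mediated
   by the expression of a gene, the ratio of its GWAS effect to its
   cis-eQTL effect estimates the expression-to-trait effect. Summary-data
   Mendelian randomization (SMR) turns this into a per-gene chi-squared
   test using only published summary statistics.

Genes flagged by both arms carry two kinds of evidence — network context
and expression mediation — obtained from disjoint data.

# The SMR statistic

Let $\hat b_{zy}$, $se_{zy}$ be a SNP's estimated effect on the trait
(GWAS) and $\hat b_{zx}$, $se_{zx}$ its effect on a gene's expression
(eQTL), estimated in independent cohorts. The Wald ratio

$$\hat b_{xy} = \hat b_{zy} / \hat b_{zx}$$

estimates the effect of expression on the trait, free of non-genetic
confounding. Its sampling variance by the first-order Delta method, with
zero covariance between the two samples, is

$$\mathrm{var}(\hat b_{xy}) \approx
\frac{b_{zy}^2}{b_{zx}^2}\left(\frac{se_{zx}^2}{b_{zx}^2} +
\frac{se_{zy}^2}{b_{zy}^2}\right)
= \frac{se_{zy}^2}{b_{zx}^2} + \frac{b_{zy}^2\,se_{zx}^2}{b_{zx}^4},$$

implemented in the expanded right-hand form so that $b_{zy} = 0$ is
well-defined. With $z_{zy} = \hat b_{zy}/se_{zy}$ and
$z_{zx} = \hat b_{zx}/se_{zx}$ the test statistic is

$$T_{SMR} = \frac{z_{zy}^2\, z_{zx}^2}{z_{zy}^2 + z_{zx}^2}
\sim \chi^2_1 .$$

$T_{SMR}$ is symmetric in its arguments and bounded by
$\min(z_{zy}^2, z_{zx}^2)$: the evidence for mediation can never exceed
the weaker of the two marginal associations, and the test is calibrated
only when the instrument is strong. That is why instrument selection
(`selectInstrument`) keeps the top cis-SNP per gene only if its eQTL
p-value passes $5\times10^{-8}$. A single-sample variance formula
(`varXySingleSample`) is exposed for completeness; the operative path is
the two-sample form throughout, because the design the package targets
(public GWAS + public eQTL) is two-sample. The single-sample formula is
implemented exactly as its conventional printed form, with the variance
fraction of the instrument in the denominator; its notation mixes the
$x$-on-$y$ and $z$-on-$y$ variance fractions in ways the surrounding
literature does not fully pin down, and since it is not on the operative
path we deliberately did not reinterpret it.

Multiple testing is Bonferroni by default (the convention for SMR-style
transcriptome-wide scans), Benjamini–Hochberg by flag. No heterogeneity
(HEIDI-style) test is performed: significant genes may reflect linkage
between distinct causal variants rather than mediation — a documented
limitation of this pipeline.

## Allele harmonization

Two-sample ratios only make sense per shared effect allele. The
harmonizer intersects SNPs, aligns the GWAS effect to the eQTL effect
allele (flipping the sign where the allele pair is swapped), drops
incompatible pairs, and by default drops strand-ambiguous (A/T, C/G)
SNPs, which cannot be oriented without allele-frequency matching. Every
exclusion is counted by reason code; the pipeline report reconciles the
counts at each step.

# The random-walk optimizer and the network encoding

The optimizer is a derivative-free random walk. From the current point
$x$ it draws $u \sim \mathrm{Uniform}(-1,1)^n$, normalizes
$u' = u / \sqrt{\sum u_i^2}$, and evaluates $x_1 = x + \lambda u'$. A
strictly better candidate is accepted and resets the failure counter;
after $N$ consecutive failures the optimum is presumed inside the
current sphere, $\lambda$ is halved, and the walk ends once
$\lambda < \epsilon$. Two details are normative:

* **Strict acceptance** — ties are rejected, so a constant objective
  never moves and costs exactly
  $\lceil \log_2(\lambda_0/\epsilon)\rceil \cdot N$ evaluations.
* **Exact halving** — after $r$ failed rounds $\lambda = \lambda_0/2^r$,
  which both guarantees termination and makes the schedule testable to
  machine precision.

The encoder minimizes the adjacency-reconstruction objective

$$f(X) = \sum_{i<j} (A_{ij} - x_i \cdot x_j)^2$$

over the flattened $|V|\times d$ embedding. This is the package's own
choice of objective: it is the minimal objective under which "encoding
the network" is well-defined — genes that interact get aligned vectors,
dense modules become clusters in feature space. The objective is
evaluated in the expanded form
$\tfrac12\big(\lVert A\rVert_F^2 - 4\sum_{(i,j)\in E} w_{ij}\, x_i\cdot x_j
+ \lVert X^\top X\rVert_F^2 - \sum_i \lVert x_i\rVert^4\big)$,
which costs $O(|E|d + |V|d^2)$ per evaluation instead of $O(|V|^2 d)$
and lets a desk-scale machine afford $10^5$ evaluations in well under a
minute on a 240-node network.

Defaults: $d = 16$ (small enough for SVMs on tens of labeled genes),
$\lambda_0 = 1$, $\epsilon = 10^{-4}$, $N = 30$, budget $10^5$
evaluations, start point uniform$(-0.1, 0.1)$ under the configuration
seed. For embedding problems in thousands of dimensions the walk is run
with a longer initial step and more patience per round
($\lambda_0 = 2$, $N = 60$, budget $1.2\times10^5$): high-dimensional
random directions make individual improvements small, so premature
halving wastes the budget. These values were fixed once for the
planted-module experiment and are part of its stated conditions.

A random-walk-with-restart encoder (`rwrEncode`) ships as the
documented alternative: each gene's feature vector is its stationary
RWR affinity to every seed gene, solved exactly as a linear system. It
is the natural baseline when "random walk on a network" is read as
network propagation rather than stochastic optimization. Its feature
space has one caveat the package treats as a known limitation: seed
genes carry their own indicator-like affinity columns, so a classifier
trained on seeds versus negatives separates the *training* genes almost
perfectly while placing the entire unlabeled pool far from both classes.
Ranking is preserved (module genes still score highest), but the
absolute decision threshold of 0 can return zero predictions. The
adjacency-reconstruction encoder does not have this pathology because
labeled and unlabeled genes live in one feature space, and it is
therefore the default encoder everywhere.

# Classification

Features are Z-score normalized with the **population** standard
deviation, and the scaler is always fitted on the training rows only —
inside every cross-validation fold — then applied to held-out rows. A
guard test in the suite verifies that deliberately leaking the scaler
changes the fold metrics on a constructed example.

The classifier is a soft-margin SVM (RBF kernel, $C = 1$,
$\gamma = 1/d$) solved by libsvm's SMO-family dual solver; the contract
is the continuous decision function, not the solver internals, and the
decision sign is oriented so higher always means more disease-like.
Kernel and hyperparameters are conventional defaults; nothing in the
workflow depends on them beyond the reported metrics.

Because there are no certified non-disease genes, negatives are drawn
uniformly from the non-seed genes, the standard positive–unlabeled
compromise. A single draw makes 10-fold CV metrics high-variance, so the
evaluation averages over 10 independent negative draws (reported as the
mean over all resample-by-fold metrics); the final prediction model uses
one draw, matching the usual single-sample practice. Note what this
means for ceiling performance: some sampled "negatives" are genuine
module genes, so even a perfect module detector scores below AUC 1 in
expectation.

AUC is computed by trapezoidal integration of the tie-grouped ROC curve
and equals the Mann–Whitney U statistic divided by
$n_+ n_-$ — the suite asserts this equality against brute-force pair
counting on random instances. AUPR is the step-function
precision–recall integral. Baselines (random forest, naive Bayes,
single-hidden-layer backpropagation network, logistic regression) run on
identical folds with identical scaling and the identical metric code
path.

Novel genes are called at decision threshold 0 over the unlabeled pool;
seed genes are excluded from the pool by construction.

# The synthetic-data generator

The generator is the package's test bed and defines its study
conditions. It emulates, at desk scale, a two-sample design of the size
found in consortium GWAS and blood eQTL panels:

* 200 genes × 10 cis-SNPs (summary arm), GWAS and eQTL cohorts of
  10,000 each. Standard errors follow the per-allele approximation
  $se = 1/\sqrt{2\,p(1-p)\,n}$ with MAF uniform on (0.05, 0.45).
* Ordinary cis-eQTL effects are $N(0, 0.1^2)$; one SNP per gene is a
  strong instrument with $|\beta_{zx}| = 0.3$ (|z| ≈ 20 at $n = 10^4$,
  typical of top blood cis-eQTLs). Causal genes transmit
  $b_{xy} = 0.3$ to the trait through expression; null genes transmit
  nothing.
* GWAS and eQTL noise are independent (two-sample), and a fifth of the
  eQTL records are stored with swapped alleles and negated betas so the
  harmonizer is exercised on every run.
* The network arm plants a 60-gene module (within-module edge
  probability 0.3) in a 240-gene Barabási–Albert graph (m = 2) and
  samples 34 seed genes from the module — the scale of a known-locus
  gene set and its STRING neighborhood. In the full pipeline the causal
  genes of the summary arm are drawn from the module, so both arms chase
  the same ground truth.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: linkage disequilibrium between
cis-SNPs (instrument selection among correlated SNPs, and the
linkage-vs-pleiotropy ambiguity that HEIDI addresses), case/control
liability-scale effects, population stratification, winner's-curse bias
in discovery summary statistics, and biologically structured (rather
than random) negative genes.

Under these conditions the suite verifies: empirical type-I error of
the SMR test within [0.04, 0.06] at $\alpha = 0.05$ over 10,000 null
genes; null p-values uniform by Kolmogorov–Smirnov at 2,000 instrumented
genes; ≥ 80% power and unbiased $\hat b_{xy}$ (within 3 Monte-Carlo SEs)
for causal genes at $b_{xy} = 0.3$; and mean 10-fold CV AUC ≥ 0.85 on
the 240-node planted-module experiment. The AUC bar is a scaled analog
of performance on a real disease network of similar size, not a
reproduction of any published value.

# Numerical choices

* $\chi^2_1$ tails are computed as upper tails directly
  (`pchisq(..., lower.tail = FALSE)`), never as $1 - F(t)$, so p-values
  remain accurate to machine range; the far tail is cross-checked
  against the Mills-ratio series in the suite.
* Instrument ties on the eQTL p-value break by lexicographically
  smallest SNP id; all stochastic stages derive per-stage sub-seeds from
  one global seed, and reruns are byte-identical.
* The Wald ratio refuses $\hat b_{zx} = 0$; $T_{SMR}$ refuses the
  double-zero corner; degenerate MAF (0 or 0.5) is rejected at
  configuration time; constant feature columns are guarded to unit SD
  and flagged.
* Jaccard of two empty sets is defined as 0.
* RWR affinities are obtained by a dense linear solve, exact to
  round-off; isolated nodes get zero affinity with a warning.

# Problem sizes

The suite and the acceptance script use: $10^6$ Monte-Carlo replicates
for the Delta-variance check; 50 replicates × 200 genes for type-I
error; 5 replicates × 200 genes (20 causal each) for power; 2,000 genes
for the uniformity check; a 240-node network with $1.2\times10^5$
objective evaluations for the planted-module experiment; and a 120-gene
demo pipeline for determinism checks. These sizes were chosen so each
property is measured with comfortable Monte-Carlo margins while a full
run stays in the minutes range on one CPU.

# Known limitations

* No HEIDI/colocalization step: SMR significance conflates mediation
  with linkage of distinct causal variants.
* Single-SNP instruments only; multi-SNP SMR and trans-eQTLs are out of
  scope.
* The network objective is the package's own (the minimal adjacency
  reconstruction); other embedding objectives (skip-gram, Laplacian)
  are deliberately not implemented.
* Negative sampling assumes unlabeled ≈ negative; prevalence of true
  disease genes in the pool biases both training and the reported AUC
  downward.
* Strand-ambiguous SNPs are dropped rather than frequency-resolved.
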