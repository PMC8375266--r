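test_that("config validation rejects degenerate settings", {
  expect_error(simulationConfig(mafRange = c(0, 0.4)), "degenerate")
  expect_error(simulationConfig(mafRange = c(0.1, 0.5)), "degenerate")
  expect_error(simulationConfig(nCausalGenes = 50, nGenes = 20))
  expect_error(simulationConfig(moduleSize = 30, nGenes = 20))
})

test_that("null simulation gives standard-normal trait z-statistics", {
  cfg <- simulationConfig(nGenes = 150, nSnpsPerGene = 10,
                          nCausalGenes = 0, seed = 21)
  sim <- simulateSummaryStats(cfg)
  z <- sim$gwas$beta_zy / sim$gwas$se_zy
  expect_equal(mean(z), 0, tolerance = 0.06)       # ~3 MC SE at n=1500
  expect_equal(stats::var(z), 1, tolerance = 0.12)
  expect_true(all(sim$truth$trueBxy == 0))
})

test_that("fixed seed reproduces summary statistics byte for byte", {
  cfg <- simulationConfig(nGenes = 20, seed = 77)
  s1 <- simulateSummaryStats(cfg)
  s2 <- simulateSummaryStats(cfg)
  expect_identical(s1, s2)
  s3 <- simulateSummaryStats(simulationConfig(nGenes = 20, seed = 78))
  expect_false(identical(s1$gwas$beta_zy, s3$gwas$beta_zy))
})

test_that("regression through origin recovers the causal effect", {
  # oracle: OLS through the origin of estimated trait effects on
  # estimated eQTL effects across one causal gene's SNPs
  cfg <- simulationConfig(nGenes = 5, nSnpsPerGene = 400,
                          nCausalGenes = 5, bXyCausal = 0.3,
                          nGwas = 1e5, nEqtl = 1e5, seed = 4)
  sim <- simulateSummaryStats(cfg)
  h <- harmonizeEffects(sim$gwas, sim$eqtl)
  h <- h[h$gene_id == "G0001", ]
  fit <- stats::lm(h$beta_zy ~ 0 + h$beta_zx)
  expect_equal(unname(stats::coef(fit)), 0.3, tolerance = 0.05)
})

test_that("ground truth separates causal from null genes", {
  cfg <- simulationConfig(nGenes = 50, nCausalGenes = 10, seed = 2)
  sim <- simulateSummaryStats(cfg)
  expect_length(sim$truth$causalGenes, 10)
  expect_true(all(sim$truth$trueBxy[sim$truth$causalGenes] != 0))
  nullGenes <- setdiff(names(sim$truth$trueBxy), sim$truth$causalGenes)
  expect_true(all(sim$truth$trueBxy[nullGenes] == 0))
})

test_that("per-allele standard errors follow the 1/sqrt(2p(1-p)n) law", {
  cfg <- simulationConfig(nGenes = 10, seed = 5)
  sim <- simulateSummaryStats(cfg)
  maf <- sim$gwas$eaf
  expect_equal(sim$gwas$se_zy, 1 / sqrt(2 * maf * (1 - maf) * cfg$nGwas))
  expect_equal(sim$eqtl$se_zx, 1 / sqrt(2 * maf * (1 - maf) * cfg$nEqtl))
})

test_that("planted module forms a clique when edge probability is 1", {
  cfg <- simulationConfig(nGenes = 40, moduleSize = 5, nSeedGenes = 3,
                          moduleEdgeProb = 1, seed = 6)
  ns <- simulateNetwork(cfg)
  A <- adjacencyMatrix(ns$network)
  mod <- ns$truth$moduleGenes
  offdiag <- A[mod, mod][upper.tri(A[mod, mod])]
  expect_true(all(offdiag > 0))
})

test_that("network simulation is reproducible and module is denser", {
  cfg <- simulationConfig(nGenes = 120, moduleSize = 30, nSeedGenes = 10,
                          moduleEdgeProb = 0.4, seed = 13)
  n1 <- simulateNetwork(cfg)
  n2 <- simulateNetwork(cfg)
  expect_identical(n1$network@edges, n2$network@edges)
  expect_identical(n1$truth, n2$truth)
  A <- adjacencyMatrix(n1$network)
  deg <- rowSums(A > 0)
  expect_gt(mean(deg[n1$truth$moduleGenes]), mean(deg))
  expect_true(all(seedGenes(n1$network) %in% n1$truth$moduleGenes))
})

test_that("a module sparser than the base graph warns", {
  cfg <- simulationConfig(nGenes = 60, moduleSize = 10, nSeedGenes = 2,
                          moduleEdgeProb = 0.001, seed = 1)
  expect_warning(simulateNetwork(cfg), "no signal")
})
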