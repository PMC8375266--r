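test_that("Wald ratio arithmetic and symmetry", {
  expect_equal(waldRatio(0.2, 0.5), 0.4)
  expect_equal(waldRatio(0, 0.7), 0)
  expect_equal(waldRatio(-0.3, 0.6), -waldRatio(0.3, 0.6))
  expect_error(waldRatio(0.1, 0), "instrument")
})

test_that("single-sample variance follows the printed closed form", {
  expect_equal(varXySingleSample(1, 1, 100, 0, 0.1), 0.1)
  expect_equal(varXySingleSample(1, 1, 100, 1, 0.1), 0)
  v1 <- varXySingleSample(2, 1.5, 1000, 0.2, 0.05)
  expect_equal(varXySingleSample(2, 1.5, 500, 0.2, 0.05), 2 * v1)
  expect_error(varXySingleSample(1, 1, 100, 0, 0), "infinite")
})

test_that("Delta variance: expanded form handles betaZy = 0", {
  expect_equal(varXyDelta(1, 0, 0.3, 0.1), 0.01)
  expect_equal(varXyDelta(0.5, 0.02, 0, 0.1), 0.1^2 / 0.25)
  expect_error(varXyDelta(0, 0.1, 0.3, 0.1), "instrument")
  # equals the factored textbook form when betaZy != 0
  b <- c(0.4, -0.2); sb <- c(0.03, 0.05)
  g <- c(0.25, 0.15); sg <- c(0.04, 0.02)
  expect_equal(varXyDelta(b, sb, g, sg),
               (g^2 / b^2) * (sb^2 / b^2 + sg^2 / g^2))
})

test_that("Delta variance matches Monte-Carlo in the small-noise regime", {
  bzx <- 0.3; seZx <- 0.01; bzy <- 0.06; seZy <- 0.01
  mc <- withr::with_seed(101, {
    stats::var(stats::rnorm(2e5, bzy, seZy) /
                 stats::rnorm(2e5, bzx, seZx))
  })
  expect_equal(varXyDelta(bzx, seZx, bzy, seZy), mc, tolerance = 0.05)
})

test_that("SMR statistic: arithmetic, symmetry, bound and limits", {
  r <- tSmr(3, 4)
  expect_equal(r$t, 5.76)
  expect_equal(r$p, stats::pchisq(5.76, 1, lower.tail = FALSE))
  expect_equal(tSmr(2, 2)$t, 2)                   # z^2 / 2
  expect_equal(tSmr(4, 3)$t, tSmr(3, 4)$t)        # symmetric
  expect_equal(tSmr(3, 1e9)$t, 9, tolerance = 1e-6)  # perfect instrument
  expect_error(tSmr(0, 0), "zero")
  withr::with_seed(5, {
    z1 <- stats::rnorm(10000, 0, 3)
    z2 <- stats::rnorm(10000, 0, 3)
    ok <- !(z1 == 0 & z2 == 0)
    r <- tSmr(z1[ok], z2[ok])
    expect_true(all(r$t <= pmin(z1[ok]^2, z2[ok]^2) + 1e-12))
    expect_equal(r$t, tSmr(z2[ok], z1[ok])$t)
    # p can never beat the weaker of the two marginal associations
    pG <- stats::pchisq(z1[ok]^2, 1, lower.tail = FALSE)
    pE <- stats::pchisq(z2[ok]^2, 1, lower.tail = FALSE)
    expect_true(all(r$p >= pmax(pG, pE) - 1e-12))
  })
})

test_that("chi-squared tail agrees with the asymptotic series for t > 30", {
  # upper tail of chi2_1: P(T > t) = 2(1 - Phi(sqrt(t)));
  # Mills-ratio series: phi(x)/x * (1 - 1/x^2 + 3/x^4 - 15/x^6)
  for (t in c(36, 50, 80)) {
    x <- sqrt(t)
    series <- 2 * stats::dnorm(x) / x * (1 - 1 / x^2 + 3 / x^4 - 15 / x^6)
    expect_equal(tSmr(sqrt(t) * sqrt(2), sqrt(t) * sqrt(2))$p, series,
                 tolerance = 1e-3)
  }
})

test_that("internal consistency of Delta variance and z-form statistic", {
  # with |z| > 5 on both sides, t from bxy^2 / var_delta matches the
  # z-statistic form within 1%
  withr::with_seed(9, {
    bzx <- stats::runif(200, 0.2, 0.5) * sample(c(-1, 1), 200, TRUE)
    seZx <- abs(bzx) / stats::runif(200, 5.5, 30)
    bzy <- stats::runif(200, 0.05, 0.2) * sample(c(-1, 1), 200, TRUE)
    seZy <- abs(bzy) / stats::runif(200, 5.5, 30)
  })
  tDelta <- waldRatio(bzy, bzx)^2 / varXyDelta(bzx, seZx, bzy, seZy)
  tZ <- tSmr(bzy / seZy, bzx / seZx)$t
  expect_equal(tDelta, tZ, tolerance = 0.01)
})

test_that("instrument selection takes the smallest eQTL p, or nothing", {
  pairs <- data.frame(snp_id = c("rs2", "rs1", "rs3"),
                      gene_id = "G1",
                      beta_zy = 0.1, se_zy = 0.02, p_zy = 0.5, n = 100L,
                      beta_zx = 0.3, se_zx = 0.03,
                      p_zx = c(1e-9, 1e-12, 1e-3), flipped = FALSE)
  expect_equal(selectInstrument(pairs, "G1")$snp_id, "rs1")
  expect_null(selectInstrument(pairs, "G1", pEqtlMax = 1e-15))
  # tie on p: lexicographically smaller SNP id wins
  pairs$p_zx <- 1e-10
  expect_equal(selectInstrument(pairs, "G1")$snp_id, "rs1")
})

test_that("runSmr flags planted causal genes and spares null genes", {
  cfg <- simulationConfig(nGenes = 100, nSnpsPerGene = 8,
                          nCausalGenes = 10, seed = 23)
  sim <- simulateSummaryStats(cfg)
  res <- runSmr(sim$gwas, sim$eqtl)
  expect_s4_class(res, "SmrResults")
  tab <- smrTable(res)
  expect_equal(res@nGenesTested, 100)     # every gene has a strong top SNP
  sig <- significantGenes(res)
  # most causal genes recovered, few false positives
  expect_gte(length(intersect(sig, sim$truth$causalGenes)), 8)
  expect_lte(length(setdiff(sig, sim$truth$causalGenes)), 2)
  # estimated effects for causal genes are near the truth
  causalRows <- tab$gene %in% sim$truth$causalGenes
  expect_equal(mean(tab$b_xy[causalRows]), 0.3, tolerance = 0.05)
  # deterministic re-run
  expect_identical(smrTable(runSmr(sim$gwas, sim$eqtl)), tab)
})

test_that("zero overlapping SNPs yields an empty result with a warning", {
  cfg <- simulationConfig(nGenes = 10, seed = 2)
  sim <- simulateSummaryStats(cfg)
  gwas <- sim$gwas
  gwas$snp_id <- paste0("other", seq_len(nrow(gwas)))
  expect_warning(res <- runSmr(gwas, sim$eqtl), "no usable SNP-gene")
  expect_equal(nrow(smrTable(res)), 0)
  expect_equal(res@nGenesTested, 0L)
})

test_that("cis-window filtering drops distant SNP-gene pairs", {
  cfg <- simulationConfig(nGenes = 10, nSnpsPerGene = 3, seed = 8)
  sim <- simulateSummaryStats(cfg)
  genePos <- data.frame(gene_id = sprintf("G%04d", 1:10), chrom = "1",
                        pos = seq_len(10) * 1000000L)
  resAll <- runSmr(sim$gwas, sim$eqtl)
  resCis <- runSmr(sim$gwas, sim$eqtl, genePositions = genePos,
                   cisWindow = 1e6)
  expect_equal(smrTable(resCis), smrTable(resAll))  # all pairs are cis
  # genes moved far away make every pair trans: nothing is testable
  genePosFar <- transform(genePos, pos = pos + 50000000L)
  expect_warning(
    resFar <- runSmr(sim$gwas, sim$eqtl, genePositions = genePosFar,
                     cisWindow = 1e6),
    "pair")
  expect_equal(resFar@nGenesTested, 0L)
})

test_that("overlap and Jaccard agree with hand computation", {
  ov <- overlapGenes(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(ov$intersection, c("B", "C"))
  expect_equal(ov$jaccard, 0.5)
  expect_equal(overlapGenes(c("X", "Y"), c("X", "Y"))$jaccard, 1)
  expect_equal(overlapGenes("A", "B")$jaccard, 0)
  expect_equal(overlapGenes(character(), character())$jaccard, 0)
})

test_that("null p-values are uniform over 2,000 instrumented genes", {
  # one strong cis-SNP per gene, no causal effect anywhere: the SMR
  # p-values entering the pipeline must be Uniform(0, 1)
  cfg <- simulationConfig(nGenes = 2000, nSnpsPerGene = 1,
                          nCausalGenes = 0, seed = 55)
  sim <- simulateSummaryStats(cfg)
  p <- smrTable(runSmr(sim$gwas, sim$eqtl))$p_smr
  expect_length(p, 2000)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
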