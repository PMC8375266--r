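# build a LabeledFeatures object directly from a raw matrix
rawLabeled <- function(X, labels, pool = X[0, , drop = FALSE]) {
  structure(list(features = X, labels = labels,
                 geneIds = rownames(X), pool = pool),
            class = "LabeledFeatures")
}

test_that("negative sampling is uniform over non-seeds and reproducible", {
  net <- twoCliqueNetwork(k = 8, seeds = c("N01", "N02", "N03"))
  negs <- sampleNegatives(net, 5, seed = 1)
  expect_length(negs, 5)
  expect_length(intersect(negs, seedGenes(net)), 0)
  expect_identical(negs, sampleNegatives(net, 5, seed = 1))
  expect_false(identical(negs, sampleNegatives(net, 5, seed = 2)))
  # n = |unlabeled| returns all unlabeled genes
  expect_setequal(sampleNegatives(net, 13, seed = 1),
                  setdiff(net@nodes, seedGenes(net)))
  expect_error(sampleNegatives(net, 14, seed = 1), "cannot sample")
})

test_that("SVM separates a separable toy and memorizes XOR with RBF", {
  X <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  rownames(X) <- paste0("g", 1:4)
  lf <- rawLabeled(X, c(0, 0, 1, 1))
  m <- trainSvm(lf, kernel = "linear")
  sc <- decisionScores(m, X)
  expect_equal(as.integer(sc > 0), c(0, 0, 1, 1))

  xor <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  rownames(xor) <- paste0("g", 1:4)
  lfx <- rawLabeled(xor, c(1, 1, 0, 0))
  mx <- trainSvm(lfx, kernel = "radial", C = 100, gamma = 2)
  scx <- decisionScores(mx, xor)
  expect_equal(as.integer(scx > 0), c(1, 1, 0, 0))
})

test_that("single-class training data is rejected", {
  X <- matrix(stats::rnorm(10), 5, 2,
              dimnames = list(paste0("g", 1:5), NULL))
  expect_error(trainSvm(rawLabeled(X, rep(1, 5))), "both classes")
})

test_that("stratified CV keeps both classes in every fold", {
  withr::with_seed(1, {
    X <- matrix(stats::rnorm(40 * 4), 40, 4,
                dimnames = list(sprintf("g%02d", 1:40), NULL))
    X[1:20, ] <- X[1:20, ] + 2
  })
  lf <- rawLabeled(X, rep(1:0, each = 20))
  cv <- crossValidate(lf, k = 5, seed = 3)
  expect_length(cv@foldAuc, 5)
  tab <- table(cv@folds, lf$labels)
  expect_true(all(tab > 0))
  expect_gt(cv@meanAuc, 0.8)          # clear 2-SD mean shift
  expect_error(crossValidate(lf, k = 25, seed = 1), "stratification")
})

test_that("label permutation drives CV AUC to chance", {
  withr::with_seed(7, {
    X <- matrix(stats::rnorm(60 * 5), 60, 5,
                dimnames = list(sprintf("g%02d", 1:60), NULL))
    labels <- sample(rep(1:0, each = 30))   # labels independent of X
  })
  cv <- crossValidate(rawLabeled(X, labels), k = 6, seed = 2)
  expect_gt(cv@meanAuc, 0.25)
  expect_lt(cv@meanAuc, 0.75)         # ~0.5 within Monte-Carlo error
})

test_that("leaking the scaler across folds changes the metrics", {
  # guard test: per-fold refit must matter when the class means differ
  withr::with_seed(3, {
    X <- matrix(stats::rnorm(30 * 3), 30, 3,
                dimnames = list(sprintf("g%02d", 1:30), NULL))
    X[1:15, ] <- X[1:15, ] + 0.8
  })
  lf <- rawLabeled(X, rep(1:0, each = 15))
  honest <- crossValidate(lf, k = 3, seed = 4)
  # deliberately leaky variant: scaler fitted once on everything
  leakyAuc <- local({
    zs <- zscoreFitTransform(X)
    folds <- honest@folds
    aucs <- numeric(3)
    for (fd in 1:3) {
      tr <- folds != fd
      fit <- e1071::svm(zs$normalized[tr, ], factor(lf$labels[tr], 0:1),
                        kernel = "radial", cost = 1, gamma = 1 / 3,
                        scale = FALSE)
      dv <- attr(stats::predict(fit, zs$normalized[!tr, ],
                                decision.values = TRUE),
                 "decision.values")[, 1]
      dtr <- attr(stats::predict(fit, zs$normalized[tr, ],
                                 decision.values = TRUE),
                  "decision.values")[, 1]
      if (mean(dtr[lf$labels[tr] == 1]) < mean(dtr[lf$labels[tr] == 0]))
        dv <- -dv
      aucs[fd] <- rocAuc(dv, lf$labels[!tr])
    }
    aucs
  })
  expect_false(isTRUE(all.equal(honest@foldAuc, leakyAuc)))
})

test_that("prediction thresholds behave at the extremes", {
  net <- twoCliqueNetwork(k = 6, seeds = sprintf("N%02d", 1:4))
  emb <- rwrEncode(net, restartProb = 0.5)
  lf <- labeledFeatures(emb, seedGenes(net), c("N07", "N08", "N09", "N10"))
  m <- trainSvm(lf)
  expect_length(predictNovel(m, lf, threshold = Inf)$predictedPositive, 0)
  allPool <- predictNovel(m, lf, threshold = -Inf)$predictedPositive
  expect_setequal(allPool, rownames(lf$pool))
  # seeds can never be predicted novel
  expect_length(intersect(allPool, seedGenes(net)), 0)
})

test_that("planted-module predictions are enriched (hypergeometric)", {
  cfg <- simulationConfig(nGenes = 150, moduleSize = 40, nSeedGenes = 20,
                          moduleEdgeProb = 0.4, seed = 31)
  ns <- simulateNetwork(cfg)
  emb <- encodeNetwork(ns$network,
                       rwConfig(dim = 8, lambda0 = 2, nTries = 40,
                                maxEvals = 40000, seed = 31))
  negs <- sampleNegatives(ns$network, 20, seed = 5)
  lf <- labeledFeatures(emb, seedGenes(ns$network), negs)
  m <- trainSvm(lf)
  pred <- predictNovel(m, lf)
  hits <- length(intersect(pred$predictedPositive,
                           ns$truth$moduleGenes))
  poolModule <- length(intersect(rownames(lf$pool),
                                 ns$truth$moduleGenes))
  pHyper <- stats::phyper(hits - 1, poolModule,
                          nrow(lf$pool) - poolModule,
                          length(pred$predictedPositive),
                          lower.tail = FALSE)
  expect_lt(pHyper, 0.01)
})

test_that("baselines run on identical folds and all beat chance", {
  cfg <- simulationConfig(nGenes = 120, moduleSize = 30, nSeedGenes = 15,
                          moduleEdgeProb = 0.5, seed = 17)
  ns <- simulateNetwork(cfg)
  emb <- encodeNetwork(ns$network,
                       rwConfig(dim = 8, lambda0 = 2, nTries = 40,
                                maxEvals = 40000, seed = 17))
  negs <- sampleNegatives(ns$network, 15, seed = 2)
  lf <- labeledFeatures(emb, seedGenes(ns$network), negs)
  tab <- compareBaselines(lf, k = 5, seed = 6)
  expect_setequal(tab$algorithm, c("svm", "random_forest", "naive_bayes",
                                   "bp_ann", "logistic"))
  expect_true(all(tab$auc > 0.5))
  # deterministic: same seed, same table
  expect_equal(compareBaselines(lf, k = 5, seed = 6), tab)
})

test_that("duplicating a feature leaves scale-invariant learners alone", {
  withr::with_seed(19, {
    X <- matrix(stats::rnorm(40 * 2), 40, 2,
                dimnames = list(sprintf("g%02d", 1:40), NULL))
    X[1:20, ] <- X[1:20, ] + 1
  })
  lf1 <- rawLabeled(X, rep(1:0, each = 20))
  # same feature twice, one rescaled: after Z-scoring the columns are
  # identical, so fold-wise logistic scores (and metrics) cannot change
  X2 <- cbind(X, 10 * X[, 2])
  colnames(X2) <- NULL
  lf2 <- rawLabeled(X2, rep(1:0, each = 20))
  t1 <- compareBaselines(lf1, k = 4, seed = 9)
  t2 <- compareBaselines(lf2, k = 4, seed = 9)
  expect_equal(t2$auc[t2$algorithm == "logistic"],
               t1$auc[t1$algorithm == "logistic"], tolerance = 1e-6)
})
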