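# SVM classification of encoded gene features: Z-score normalization,
# negative sampling, stratified cross-validation and novel-gene prediction.

#' Z-score normalization fitted on a row subset
#'
#' Fits per-column mean and population standard deviation (divisor n, not
#' n - 1) on \code{fitRows} only and applies them to every row, so that no
#' information from held-out rows leaks into the scaler. Constant columns
#' get their SD guarded to 1 (flagged in the scaler) and map to zeros.
#'
#' @param features numeric matrix.
#' @param fitRows indices (or rownames) of the rows the scaler is fitted
#'   on; default all rows.
#' @return list with \code{normalized} (matrix covering all rows) and
#'   \code{scaler} (list: center, scale, guarded).
#' @export
zscoreFitTransform <- function(features, fitRows = seq_len(nrow(features))) {
  stopifnot(is.matrix(features), length(fitRows) >= 1)
  fit <- features[fitRows, , drop = FALSE]
  if (any(colSums(!is.na(fit)) == 0)) stop("all-NaN column in fit rows")
  mu <- colMeans(fit)
  sdev <- sqrt(colMeans(sweep(fit, 2, mu)^2))   # population SD
  guarded <- sdev == 0
  sdev[guarded] <- 1
  normalized <- sweep(sweep(features, 2, mu), 2, sdev, "/")
  list(normalized = normalized,
       scaler = list(center = mu, scale = sdev, guarded = guarded))
}

# apply a fitted scaler to new rows
.zscoreApply <- function(features, scaler) {
  sweep(sweep(features, 2, scaler$center), 2, scaler$scale, "/")
}

#' Sample negative genes from the unlabeled part of a network
#'
#' Disease-gene classification has no certified negatives; following
#' common practice, presumed negatives are drawn uniformly without
#' replacement from the non-seed genes.
#'
#' @param net a [GeneNetwork-class].
#' @param n number of negatives (conventionally the number of seeds).
#' @param seed RNG seed for reproducibility.
#' @return character vector of gene ids, disjoint from the seeds.
#' @export
sampleNegatives <- function(net, n, seed = 1L) {
  stopifnot(is(net, "GeneNetwork"))
  pool <- setdiff(net@nodes, net@seeds)
  if (n > length(pool))
    stop("cannot sample ", n, " negatives from ", length(pool),
         " unlabeled genes")
  withSeed(seed, sort(sample(pool, n)))
}

#' Assemble labeled features for classification
#'
#' @param embedding a [GeneEmbedding-class].
#' @param positives character vector of positive (seed) gene ids.
#' @param negatives character vector of presumed-negative gene ids.
#' @return list of class "LabeledFeatures": \code{features} (raw labeled
#'   matrix), \code{labels} (integer 0/1), \code{geneIds},
#'   \code{pool} (matrix of remaining unlabeled genes) — normalization is
#'   applied later, inside each model fit, to avoid leakage.
#' @export
labeledFeatures <- function(embedding, positives, negatives) {
  stopifnot(is(embedding, "GeneEmbedding"))
  X <- embedding@features
  miss <- setdiff(c(positives, negatives), rownames(X))
  if (length(miss)) stop("genes missing from the embedding: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  if (length(intersect(positives, negatives)))
    stop("positives and negatives overlap")
  ids <- c(positives, negatives)
  structure(list(features = X[ids, , drop = FALSE],
                 labels = rep(1:0, c(length(positives), length(negatives))),
                 geneIds = ids,
                 pool = X[setdiff(rownames(X), ids), , drop = FALSE]),
            class = "LabeledFeatures")
}

#' Train an SVM on labeled gene features
#'
#' Z-scores the labeled features, then fits a max-margin classifier with
#' a standard SMO-family dual solver (libsvm via e1071). The contract is
#' the continuous decision function; its sign is oriented so that higher
#' scores mean more disease-like, regardless of internal label ordering.
#'
#' @param data a [labeledFeatures()] object with both classes present.
#' @param kernel "radial" (default), "linear", "polynomial" or "sigmoid".
#' @param C soft-margin cost (default 1).
#' @param gamma RBF width; default 1 / ncol(features).
#' @return list of class "SvmRwModel": svm fit, scaler, orientation sign.
#' @export
trainSvm <- function(data, kernel = "radial", C = 1, gamma = NULL) {
  stopifnot(inherits(data, "LabeledFeatures"))
  if (length(unique(data$labels)) < 2)
    stop("training data must contain both classes")
  if (is.null(gamma)) gamma <- 1 / ncol(data$features)
  zs <- zscoreFitTransform(data$features)
  y <- factor(data$labels, levels = c(0, 1))
  fit <- e1071::svm(zs$normalized, y, kernel = kernel, cost = C,
                    gamma = gamma, scale = FALSE)
  dv <- attr(stats::predict(fit, zs$normalized, decision.values = TRUE),
             "decision.values")[, 1]
  sgn <- if (mean(dv[data$labels == 1]) >= mean(dv[data$labels == 0]))
    1 else -1
  structure(list(fit = fit, scaler = zs$scaler, sign = sgn,
                 kernel = kernel, C = C, gamma = gamma),
            class = "SvmRwModel")
}

#' Decision scores of a trained model on new genes
#'
#' @param model an "SvmRwModel" from [trainSvm()].
#' @param features raw (unnormalized) feature matrix with gene rownames;
#'   the training scaler is applied internally.
#' @return named numeric vector of oriented decision scores.
#' @export
decisionScores <- function(model, features) {
  stopifnot(inherits(model, "SvmRwModel"))
  Xn <- .zscoreApply(features, model$scaler)
  dv <- attr(stats::predict(model$fit, Xn, decision.values = TRUE),
             "decision.values")[, 1]
  stats::setNames(model$sign * dv, rownames(features))
}

#' Predict novel disease genes
#'
#' Scores the unlabeled gene pool with a trained model (normalized with
#' the training scaler) and calls genes above the decision threshold.
#' Seed genes are excluded by construction because the pool never
#' contains labeled genes.
#'
#' @param model an "SvmRwModel".
#' @param data the [labeledFeatures()] object the model was trained on
#'   (supplies the unlabeled pool).
#' @param threshold decision-score cutoff (default 0, the SVM margin).
#' @return list: \code{scores} (named vector over the pool) and
#'   \code{predictedPositive} (character vector of called genes).
#' @export
predictNovel <- function(model, data, threshold = 0) {
  stopifnot(inherits(data, "LabeledFeatures"))
  if (!nrow(data$pool)) {
    warning("empty unlabeled pool: no genes to predict")
    return(list(scores = numeric(0), predictedPositive = character(0)))
  }
  sc <- decisionScores(model, data$pool)
  list(scores = sc, predictedPositive = sort(names(sc)[sc > threshold]))
}

# stratified fold assignment: each class spread as evenly as possible
.stratifiedFolds <- function(labels, k, seed) {
  if (min(table(labels)) < k)
    stop("stratification error: k exceeds the size of a class")
  withSeed(seed, {
    folds <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    folds
  })
}

#' Stratified k-fold cross-validation of the SVM
#'
#' Splits the labeled genes into k stratified folds; inside every fold the
#' Z-score scaler and the SVM are refitted on the training part only (no
#' leakage), and held-out decision scores are evaluated by trapezoidal
#' ROC AUC and step-function AUPR.
#'
#' @param data a [labeledFeatures()] object.
#' @param k number of folds (default 10).
#' @param seed RNG seed controlling fold assignment.
#' @param kernel,C,gamma passed to [trainSvm()].
#' @return a [CvReport-class].
#' @export
crossValidate <- function(data, k = 10, seed = 1L, kernel = "radial",
                          C = 1, gamma = NULL) {
  stopifnot(inherits(data, "LabeledFeatures"))
  folds <- .stratifiedFolds(data$labels, k, seed)
  aucs <- auprs <- numeric(k)
  pooled <- vector("list", k)
  for (fd in seq_len(k)) {
    tr <- folds != fd
    sub <- structure(list(features = data$features[tr, , drop = FALSE],
                          labels = data$labels[tr],
                          geneIds = data$geneIds[tr],
                          pool = data$pool), class = "LabeledFeatures")
    model <- trainSvm(sub, kernel = kernel, C = C, gamma = gamma)
    sc <- decisionScores(model, data$features[!tr, , drop = FALSE])
    yte <- data$labels[!tr]
    aucs[fd] <- rocAuc(sc, yte)
    auprs[fd] <- prAupr(sc, yte)
    pooled[[fd]] <- data.frame(score = sc, label = yte)
  }
  all <- do.call(rbind, pooled)
  new("CvReport", foldAuc = aucs, foldAupr = auprs,
      meanAuc = mean(aucs), meanAupr = mean(auprs),
      roc = rocCurve(all$score, all$label),
      folds = stats::setNames(folds, data$geneIds))
}

setMethod("show", "CvReport", function(object) {
  cat("CvReport:", length(object@foldAuc), "fold metric(s)\n",
      " mean AUC  =", round(object@meanAuc, 3), "\n",
      " mean AUPR =", round(object@meanAupr, 3), "\n")
})

#' Cross-validate with resampled negative sets
#'
#' A single negative sample makes the cross-validated metrics
#' high-variance, so the evaluation is averaged over \code{nResamples}
#' independent draws of the negative set; the final model elsewhere still
#' uses a single draw.
#'
#' @param embedding a [GeneEmbedding-class].
#' @param net the [GeneNetwork-class] supplying seeds and the unlabeled
#'   pool.
#' @param k folds (default 10).
#' @param seed global seed; per-resample seeds are derived from it.
#' @param nResamples negative-set draws to average over (default 10).
#' @param nNegatives negatives per draw (default: number of seeds).
#' @param kernel,C,gamma passed to [trainSvm()].
#' @return a [CvReport-class]; \code{foldAuc}/\code{foldAupr} concatenate
#'   the per-fold metrics of every resample (nResamples x k values),
#'   \code{folds} reports the assignment of the first resample.
#' @export
cvResampledNegatives <- function(embedding, net, k = 10, seed = 1L,
                                 nResamples = 10,
                                 nNegatives = length(seedGenes(net)),
                                 kernel = "radial", C = 1, gamma = NULL) {
  stopifnot(is(embedding, "GeneEmbedding"), is(net, "GeneNetwork"))
  reports <- lapply(seq_len(nResamples), function(r) {
    negs <- sampleNegatives(net, nNegatives,
                            seed = deriveSeed(seed, paste0("negs", r)))
    lf <- labeledFeatures(embedding, seedGenes(net), negs)
    crossValidate(lf, k = k, seed = deriveSeed(seed, paste0("folds", r)),
                  kernel = kernel, C = C, gamma = gamma)
  })
  new("CvReport",
      foldAuc = unlist(lapply(reports, slot, "foldAuc")),
      foldAupr = unlist(lapply(reports, slot, "foldAupr")),
      meanAuc = mean(vapply(reports, slot, numeric(1), "meanAuc")),
      meanAupr = mean(vapply(reports, slot, numeric(1), "meanAupr")),
      roc = reports[[1]]@roc, folds = reports[[1]]@folds)
}

#' Compare classifiers on identical folds
#'
#' Runs the SVM and standard baselines (random forest, naive Bayes, a
#' single-hidden-layer backpropagation neural network, logistic
#' regression) over the same stratified folds with the same in-fold
#' Z-scoring and the same metric code path, so differences reflect the
#' learners only.
#'
#' @param data a [labeledFeatures()] object.
#' @param k folds (default 10).
#' @param seed RNG seed (folds and stochastic learners).
#' @return data.frame with columns algorithm, auc, aupr.
#' @export
compareBaselines <- function(data, k = 10, seed = 1L) {
  stopifnot(inherits(data, "LabeledFeatures"))
  folds <- .stratifiedFolds(data$labels, k, seed)
  scoreFns <- list(
    svm = function(xtr, ytr, xte) {
      fit <- e1071::svm(xtr, factor(ytr, levels = 0:1), kernel = "radial",
                        cost = 1, gamma = 1 / ncol(xtr), scale = FALSE)
      dv <- attr(stats::predict(fit, xte, decision.values = TRUE),
                 "decision.values")[, 1]
      dtr <- attr(stats::predict(fit, xtr, decision.values = TRUE),
                  "decision.values")[, 1]
      if (mean(dtr[ytr == 1]) < mean(dtr[ytr == 0])) -dv else dv
    },
    random_forest = function(xtr, ytr, xte) {
      fit <- randomForest::randomForest(xtr, factor(ytr, levels = 0:1))
      stats::predict(fit, xte, type = "prob")[, "1"]
    },
    naive_bayes = function(xtr, ytr, xte) {
      fit <- e1071::naiveBayes(xtr, factor(ytr, levels = 0:1))
      stats::predict(fit, xte, type = "raw")[, "1"]
    },
    bp_ann = function(xtr, ytr, xte) {
      fit <- nnet::nnet(xtr, ytr, size = 4, decay = 0.01, maxit = 300,
                        trace = FALSE)
      as.numeric(stats::predict(fit, xte))
    },
    logistic = function(xtr, ytr, xte) {
      df <- data.frame(y = ytr, xtr)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      suppressWarnings(
        stats::predict(fit, data.frame(xte), type = "link"))
    })
  res <- lapply(names(scoreFns), function(alg) {
    scores <- numeric(length(data$labels))
    withSeed(deriveSeed(seed, paste0("alg-", alg)), {
      for (fd in seq_len(k)) {
        tr <- folds != fd
        zs <- zscoreFitTransform(data$features, which(tr))
        scores[!tr] <- scoreFns[[alg]](zs$normalized[tr, , drop = FALSE],
                                       data$labels[tr],
                                       zs$normalized[!tr, , drop = FALSE])
      }
    })
    perFoldAuc <- vapply(seq_len(k), function(fd)
      rocAuc(scores[folds == fd], data$labels[folds == fd]), numeric(1))
    perFoldAupr <- vapply(seq_len(k), function(fd)
      prAupr(scores[folds == fd], data$labels[folds == fd]), numeric(1))
    data.frame(algorithm = alg, auc = mean(perFoldAuc),
               aupr = mean(perFoldAupr))
  })
  do.call(rbind, res)
}
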