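#' Random-forest configuration
#'
#' @param ntree_grid candidate tree counts (default 250/500/1000).
#' @param mtry_grid candidate features-per-split counts; `NULL` derives
#'   `floor(sqrt(p)/2)`, `floor(sqrt(p))`, `floor(2*sqrt(p))` from the
#'   feature count at fit time.
#' @param class_weighting `"balanced"` (inverse class frequency) or
#'   `"none"`.
#' @param n_folds cross-validation folds (default 10).
#' @param seed master seed for bootstraps, folds and permutations.
#' @return list of class `ForestConfig`.
#' @export
forestConfig <- function(ntree_grid = c(250L, 500L, 1000L), mtry_grid = NULL,
                         class_weighting = c("balanced", "none"),
                         n_folds = 10L, seed = 1L) {
  class_weighting <- match.arg(class_weighting)
  if (!length(ntree_grid)) stopf("ntree_grid must be non-empty")
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  structure(list(ntree_grid = sort(unique(as.integer(ntree_grid))),
                 mtry_grid = if (is.null(mtry_grid)) NULL
                             else sort(unique(as.integer(mtry_grid))),
                 class_weighting = class_weighting,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "ForestConfig")
}

.resolve_mtry <- function(cfg, p) {
  if (!is.null(cfg$mtry_grid)) return(pmin(cfg$mtry_grid, p))
  s <- sqrt(p)
  sort(unique(pmax(1L, pmin(p, c(floor(s / 2), floor(s), floor(2 * s))))))
}

#' One-vs-rest labels from translation calls
#'
#' The positive class is the chosen translational response; every other
#' transcript (the opposite class and the unchanged) is negative.
#'
#' @param calls translation-call data.frame.
#' @param positive `"up"` or `"down"`.
#' @return factor with levels `c("other", "pos")`, named by gene.
#' @export
makeBinaryLabels <- function(calls, positive = c("up", "down")) {
  positive <- match.arg(positive)
  if (!nrow(calls)) stopf("no translation calls supplied")
  if (!any(calls$label == positive))
    stopf("positive class '%s' is empty", positive)
  y <- factor(ifelse(calls$label == positive, "pos", "other"),
              levels = c("other", "pos"))
  names(y) <- calls$gene
  y
}

.class_weights <- function(y, mode) {
  if (mode == "none") return(NULL)
  w <- 1 / table(y)
  w / sum(w)
}

#' Tune and train a class-weighted random forest
#'
#' Grid search over (ntree, mtry) selecting the lowest out-of-bag (OOB)
#' classification error, ties broken by smaller ntree then smaller mtry;
#' the winning configuration is refit with importance tracking. Class
#' weights default to inverse class frequency, so the minority response
#' class is not swamped by the unchanged majority.
#'
#' @param X feature matrix (numeric, no NA) or a [FeatureMatrix-class].
#' @param y binary factor from [makeBinaryLabels()].
#' @param cfg a [forestConfig()].
#' @return list with `forest` (the fitted randomForest), `best`
#'   (ntree/mtry), `oob_error`, `confusion` (TP/FP/TN/FN from OOB
#'   predictions), and `grid` (the OOB-error trace).
#' @export
tuneForest <- function(X, y, cfg = forestConfig()) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  if (anyNA(X)) stopf("feature matrix contains NA")
  if (length(unique(y)) < 2L) stopf("y must contain both classes")
  if (length(y) != nrow(X)) stopf("length(y) must equal nrow(X)")
  classwt <- .class_weights(y, cfg$class_weighting)
  mtries <- .resolve_mtry(cfg, ncol(X))
  grid <- expand.grid(ntree = cfg$ntree_grid, mtry = mtries)
  grid$oob_error <- NA_real_
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- with_seed(cfg$seed, randomForest::randomForest(
      x = X, y = y, ntree = grid$ntree[i], mtry = grid$mtry[i],
      classwt = classwt, importance = FALSE))
    grid$oob_error[i] <- fits[[i]]$err.rate[grid$ntree[i], "OOB"]
  }
  ord <- order(grid$oob_error, grid$ntree, grid$mtry)
  best <- grid[ord[1], ]
  forest <- with_seed(cfg$seed, randomForest::randomForest(
    x = X, y = y, ntree = best$ntree, mtry = best$mtry,
    classwt = classwt, importance = TRUE))
  pred <- forest$predicted
  conf <- c(TP = sum(pred == "pos" & y == "pos"),
            FP = sum(pred == "pos" & y == "other"),
            TN = sum(pred == "other" & y == "other"),
            FN = sum(pred == "other" & y == "pos"))
  list(forest = forest,
       best = list(ntree = best$ntree, mtry = best$mtry),
       oob_error = forest$err.rate[best$ntree, "OOB"],
       confusion = conf, grid = grid)
}

#' ROC curve points from scores
#'
#' Sweeps the decision threshold over the unique scores; ties share a
#' threshold, so the curve (and its trapezoid AUC) equals the pairwise
#' concordance probability with ties counted 1/2.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary factor/logical; positive = `"pos"`/`TRUE`.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
rocPoints <- function(scores, labels) {
  pos <- labels == if (is.factor(labels)) "pos" else TRUE
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of [rocPoints()]; equals the Mann-Whitney
#' concordance probability.
#'
#' @inheritParams rocPoints
#' @return AUC in \[0, 1\].
#' @export
aucFromScores <- function(scores, labels) {
  pts <- rocPoints(scores, labels)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}

#' Stratified k-fold cross-validated ROC
#'
#' Splits samples into class-stratified folds, fits a forest on each
#' training part and pools out-of-fold positive-class vote fractions into
#' one ROC curve.
#'
#' @inheritParams tuneForest
#' @param ntree,mtry forest parameters for the fold fits (e.g. the tuned
#'   best pair).
#' @return list with `points` (ROC data.frame), `auc`, and `scores`
#'   (pooled out-of-fold vote fractions, named by sample).
#' @export
crossvalRoc <- function(X, y, cfg = forestConfig(), ntree = 500L, mtry = NULL) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  k <- cfg$n_folds
  if (min(table(y)) < k)
    k <- max(2L, min(table(y)))
  folds <- with_seed(cfg$seed + 1L, {
    f <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  classwt <- .class_weights(y, cfg$class_weighting)
  scores <- numeric(length(y))
  for (fold in seq_len(k)) {
    test <- folds == fold
    fit <- with_seed(cfg$seed + 100L + fold, randomForest::randomForest(
      x = X[!test, , drop = FALSE], y = y[!test], ntree = ntree,
      mtry = mtry, classwt = classwt))
    scores[test] <- stats::predict(fit, X[test, , drop = FALSE],
                                   type = "prob")[, "pos"]
  }
  names(scores) <- rownames(X)
  list(points = rocPoints(scores, y), auc = aucFromScores(scores, y),
       scores = scores, folds = folds)
}

#' Feature importance with effect direction
#'
#' Mean decrease in Gini impurity and permutation importance (mean decrease
#' in OOB accuracy) from a fitted forest, plus an effect sign per feature:
#' the sign of the rank-biserial correlation between the feature and the
#' positive class (`2*AUC - 1`), robust to heavy-tailed count features.
#'
#' @param fit result of [tuneForest()] (or a fitted randomForest grown with
#'   `importance = TRUE`).
#' @param X feature matrix used for training.
#' @param y binary labels used for training.
#' @return data.frame sorted by decreasing Gini importance: `feature`,
#'   `gini`, `permutation`, `effect` (`"+"`/`"-"`), `rank`.
#' @export
importanceReport <- function(fit, X, y) {
  forest <- if (is.list(fit) && !is.null(fit$forest)) fit$forest else fit
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  imp <- randomForest::importance(forest)
  gini <- imp[, "MeanDecreaseGini"]
  perm <- if ("MeanDecreaseAccuracy" %in% colnames(imp))
    imp[, "MeanDecreaseAccuracy"] else rep(NA_real_, length(gini))
  eff <- vapply(colnames(X), function(f) {
    rb <- 2 * aucFromScores(X[, f], y) - 1
    if (rb >= 0) "+" else "-"
  }, character(1))
  out <- data.frame(feature = names(gini), gini = unname(gini),
                    permutation = unname(perm),
                    effect = unname(eff[names(gini)]), row.names = NULL)
  out <- out[order(-out$gini, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Tune, evaluate and explain one one-vs-rest forest task
#'
#' Convenience wrapper running [tuneForest()], [crossvalRoc()] at the tuned
#' parameters, and [importanceReport()].
#'
#' @inheritParams tuneForest
#' @param positive name of the positive translational class (for reporting).
#' @return a `ForestReport` list: `positive`, `best`, `oob_error`,
#'   `confusion`, `auc`, `roc_points`, `importance`, `grid`, `n`.
#' @export
forestReport <- function(X, y, cfg = forestConfig(), positive = "pos") {
  tuned <- tuneForest(X, y, cfg)
  cv <- crossvalRoc(X, y, cfg, ntree = tuned$best$ntree,
                    mtry = tuned$best$mtry)
  imp <- importanceReport(tuned, X, y)
  list(positive = positive, best = tuned$best, oob_error = tuned$oob_error,
       confusion = as.list(tuned$confusion), auc = cv$auc,
       roc_points = cv$points, importance = imp, grid = tuned$grid,
       n = length(y), seed = cfg$seed)
}
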