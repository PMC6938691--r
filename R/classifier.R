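# Classification stage: balanced training-set construction, the 50-tree
# random forest over the seven features, prediction of undetermined
# variants, feature importances, the final merge, model persistence, and a
# small cross-algorithm comparison harness.

.MODEL_FORMAT_VERSION <- "1"

#' Build a balanced training set from filter-stage labels
#'
#' Takes the HIGH and LOW variants from the filter stage and downsamples the
#' majority class uniformly without replacement to the minority size, so the
#' balanced set has twice the minority class count. `NA` feature cells are
#' imputed with the training-set median of the feature and flagged. Sampling
#' is deterministic given `seed`.
#'
#' @param stats data.frame from [computeVariantStats()] containing the seven
#'   feature columns and a `key` column.
#' @param labels factor from [classifyByFilters()], parallel to `stats`.
#' @param seed integer seed controlling the downsampling.
#' @return a [TrainingSet-class].
#' @export
buildTrainingSet <- function(stats, labels, seed = 1L) {
  seed <- as.integer(seed)
  idx <- list(HIGH = which(labels == "HIGH"), LOW = which(labels == "LOW"))
  nH <- length(idx$HIGH); nL <- length(idx$LOW)
  if (nH == 0L || nL == 0L)
    stop("cannot train: filter stage produced ", nH, " HIGH and ", nL,
         " LOW variants; relax or tighten the filter thresholds")
  nKeep <- min(nH, nL)
  keep <- withr::with_seed(seed, {
    list(HIGH = if (nH > nKeep) sort(sample(idx$HIGH, nKeep)) else idx$HIGH,
         LOW = if (nL > nKeep) sort(sample(idx$LOW, nKeep)) else idx$LOW)
  })
  rows <- c(keep$HIGH, keep$LOW)
  x <- as.matrix(stats[rows, .FEATURES, drop = FALSE])
  allNA <- colnames(x)[colSums(!is.na(x)) == 0L]
  if (length(allNA))
    stop("feature(s) with no observed values in the training set: ",
         paste(allNA, collapse = ", "))
  medians <- apply(x, 2L, median, na.rm = TRUE)
  imputed <- rowSums(is.na(x)) > 0L
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- medians[j]
  y <- factor(rep(c("HIGH", "LOW"), c(length(keep$HIGH), length(keep$LOW))),
              levels = c("LOW", "HIGH"))
  ids <- if ("key" %in% colnames(stats)) stats$key[rows]
         else as.character(rows)
  new("TrainingSet", features = x, labels = y, ids = ids, seed = seed,
      medians = medians, imputed = imputed)
}

#' Train the random-forest quality classifier
#'
#' Fits an ensemble of classification trees (bootstrap resampling with
#' random feature subsetting at each split; other tree hyperparameters at
#' the randomForest package defaults) on a balanced training set. The class
#' probability of a variant is the fraction of trees voting HIGH.
#'
#' @param ts a [TrainingSet-class].
#' @param nTrees number of trees (default 50).
#' @param probabilityThreshold probability above which (strictly) an
#'   undetermined variant is labeled HIGH (default 0.5).
#' @param seed integer seed for the forest (defaults to the training set's).
#' @return a [QcModel-class].
#' @export
trainQcModel <- function(ts, nTrees = 50L, probabilityThreshold = 0.5,
                         seed = ts@seed) {
  stopifnot(is(ts, "TrainingSet"))
  if (min(table(ts@labels)) < 2L)
    stop("need at least 2 training rows per class")
  constant <- vapply(seq_len(ncol(ts@features)), function(j)
    length(unique(ts@features[, j])) == 1L, logical(1))
  if (any(constant))
    warning("zero-information (constant) feature(s): ",
            paste(colnames(ts@features)[constant], collapse = ", "))
  forest <- withr::with_seed(as.integer(seed),
    randomForest::randomForest(x = ts@features, y = ts@labels,
                               ntree = as.integer(nTrees)))
  imp <- forest$importance[, "MeanDecreaseGini"]
  imp <- imp[colnames(ts@features)]
  names(imp) <- colnames(ts@features)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  else imp[] <- 1 / length(imp)
  new("QcModel", forest = forest, nTrees = as.integer(nTrees),
      probabilityThreshold = probabilityThreshold,
      featureOrder = colnames(ts@features), featureImportances = imp,
      trainingSeed = as.integer(seed), featureMedians = ts@medians,
      version = .MODEL_FORMAT_VERSION)
}

#' Predict quality of undetermined variants
#'
#' Features must have been computed with the same outlier thresholds and GC
#' index as the training data. `NA` features are imputed with the stored
#' training-set medians and flagged. A variant is labeled HIGH iff its
#' predicted probability of being high-quality is strictly greater than the
#' model's threshold (ties go to LOW).
#'
#' @param model a [QcModel-class].
#' @param stats data.frame with the model's feature columns.
#' @param probabilityThreshold optional override of the stored threshold.
#' @return data.frame with columns `probability`, `label`, `imputed`.
#' @export
predictQc <- function(model, stats, probabilityThreshold = NULL) {
  thr <- probabilityThreshold %||% model@probabilityThreshold
  missing <- setdiff(model@featureOrder, colnames(stats))
  if (length(missing))
    stop("feature-order mismatch: statistics table lacks feature(s) ",
         paste(missing, collapse = ", "))
  x <- as.matrix(stats[, model@featureOrder, drop = FALSE])
  imputed <- rowSums(is.na(x)) > 0L
  for (j in seq_len(ncol(x)))
    x[is.na(x[, j]), j] <- model@featureMedians[model@featureOrder[j]]
  prob <- if (nrow(x)) predict(model@forest, x, type = "prob")[, "HIGH"]
          else numeric(0)
  data.frame(probability = unname(prob),
             label = factor(ifelse(prob > thr, "HIGH", "LOW"),
                            levels = .QC_LEVELS),
             imputed = imputed)
}

#' Normalized feature importances of a fitted model
#'
#' Mean-decrease-in-impurity importances normalized to sum to 1, in the
#' model's feature order.
#'
#' @param model a [QcModel-class].
#' @return named numeric vector.
#' @export
featureImportance <- function(model) model@featureImportances

#' Merge filter-stage and predicted labels into the final sets
#'
#' Final HIGH is the union of filter-stage HIGH and predicted HIGH; same for
#' LOW. The three inputs must be pairwise disjoint (an overlap indicates a
#' pipeline bug and is fatal); together the outputs cover all inputs.
#'
#' @param filterHigh,filterLow character vectors of variant keys from the
#'   filter stage.
#' @param predictedHigh,predictedLow character vectors of keys of predicted
#'   undetermined variants.
#' @return list with character vectors `high` and `low`.
#' @export
mergeFinalSets <- function(filterHigh, filterLow, predictedHigh,
                           predictedLow = character()) {
  predicted <- c(predictedHigh, predictedLow)
  sets <- list(filterHigh, filterLow, predicted)
  for (i in 1:2) for (j in (i + 1):3) {
    ov <- intersect(sets[[i]], sets[[j]])
    if (length(ov))
      stop("variant sets overlap (pipeline bug): e.g. ", ov[1])
  }
  list(high = c(filterHigh, predictedHigh),
       low = c(filterLow, predictedLow))
}

#' F1 score from a confusion summary
#'
#' The harmonic mean of precision and recall,
#' `2 * precision * recall / (precision + recall)`.
#'
#' @param truth,pred factors/characters with positive class `positive`; or
#'   pass `tp`, `fp`, `fn` directly.
#' @param positive label of the positive class (default `"HIGH"`).
#' @param tp,fp,fn confusion counts, used when `truth` is missing.
#' @return F1 in \[0, 1\] (`NaN` when precision + recall is 0).
#' @export
f1Score <- function(truth = NULL, pred = NULL, positive = "HIGH",
                    tp = NULL, fp = NULL, fn = NULL) {
  if (!is.null(truth)) {
    tp <- sum(truth == positive & pred == positive)
    fp <- sum(truth != positive & pred == positive)
    fn <- sum(truth == positive & pred != positive)
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  2 * precision * recall / (precision + recall)
}

#' Compare classification algorithms on a common train/test split
#'
#' Fits a random forest, logistic regression and naive Bayes on the same
#' balanced training set, evaluates F1 and AUC on the held-out test set,
#' adds a k-fold cross-validated F1 on the training set, and reports fit +
#' predict runtime. Rows are sorted by held-out F1.
#'
#' @param train,test [TrainingSet-class] objects.
#' @param folds cross-validation folds (default 10).
#' @param seed seed for fold assignment and the forest.
#' @return data.frame with columns `algorithm`, `f1`, `auc`, `cv_f1`,
#'   `runtime`.
#' @export
compareAlgorithms <- function(train, test, folds = 10L, seed = 1L) {
  algos <- list(
    random_forest = function(x, y) {
      fit <- randomForest::randomForest(x = x, y = y, ntree = 50L)
      function(newx) predict(fit, newx, type = "prob")[, "HIGH"]
    },
    logistic_regression = function(x, y) {
      df <- data.frame(x, .y = as.integer(y == "HIGH"))
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      function(newx) unname(predict(fit, data.frame(newx),
                                    type = "response"))
    },
    naive_bayes = function(x, y) {
      fit <- e1071::naiveBayes(x = data.frame(x), y = y)
      function(newx) predict(fit, data.frame(newx), type = "raw")[, "HIGH"]
    })

  evalOne <- function(name) {
    t0 <- proc.time()[["elapsed"]]
    predFun <- withr::with_seed(as.integer(seed),
                                algos[[name]](train@features, train@labels))
    prob <- predFun(test@features)
    runtime <- proc.time()[["elapsed"]] - t0
    predLab <- ifelse(prob > 0.5, "HIGH", "LOW")
    f1 <- f1Score(as.character(test@labels), predLab)
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = test@labels, predictor = prob,
      levels = c("LOW", "HIGH"), direction = "<", quiet = TRUE)))
    ## k-fold CV on the training set
    foldId <- withr::with_seed(as.integer(seed),
      sample(rep_len(seq_len(folds), nrow(train@features))))
    cvF1 <- vapply(seq_len(folds), function(k) {
      tr <- foldId != k
      pf <- withr::with_seed(as.integer(seed) + k,
        algos[[name]](train@features[tr, , drop = FALSE],
                      droplevels(train@labels[tr])))
      p <- pf(train@features[!tr, , drop = FALSE])
      f1Score(as.character(train@labels[!tr]),
              ifelse(p > 0.5, "HIGH", "LOW"))
    }, numeric(1))
    data.frame(algorithm = name, f1 = f1, auc = auc,
               cv_f1 = mean(cvF1, na.rm = TRUE), runtime = runtime)
  }
  out <- do.call(rbind, lapply(names(algos), evalOne))
  out[order(-out$f1), , drop = FALSE]
}

#' Save a fitted model to disk
#'
#' Writes a versioned archive holding the forest, hyperparameters, feature
#' order, imputation medians and seed, so a reloaded model reproduces its
#' predictions exactly.
#'
#' @param model a [QcModel-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
saveQcModel <- function(model, path) {
  stopifnot(is(model, "QcModel"))
  payload <- list(format = "VariantForest-qcmodel",
                  formatVersion = model@version,
                  package = as.character(packageVersion("VariantForest")),
                  forest = model@forest, nTrees = model@nTrees,
                  probabilityThreshold = model@probabilityThreshold,
                  featureOrder = model@featureOrder,
                  featureImportances = model@featureImportances,
                  trainingSeed = model@trainingSeed,
                  featureMedians = model@featureMedians)
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model saved by [saveQcModel()]
#'
#' A model whose feature order differs from the current canonical order is
#' loaded as-is (prediction matches columns by the stored order); an archive
#' that is not a model file is fatal.
#'
#' @param path file written by [saveQcModel()].
#' @return a [QcModel-class].
#' @export
readQcModel <- function(path) {
  p <- readRDS(path)
  if (!identical(p$format, "VariantForest-qcmodel"))
    stop("not a VariantForest model archive: ", path)
  new("QcModel", forest = p$forest, nTrees = p$nTrees,
      probabilityThreshold = p$probabilityThreshold,
      featureOrder = p$featureOrder,
      featureImportances = p$featureImportances,
      trainingSeed = p$trainingSeed, featureMedians = p$featureMedians,
      version = p$formatVersion)
}
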