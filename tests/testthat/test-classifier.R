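featStats <- function(n, seed = 1L) {
  ## random feature table with a key column, for training-set tests
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * 7), n,
                dimnames = list(NULL, c("mean_dp", "sd_dp", "outlier_dp",
                                        "mean_gq", "sd_gq", "outlier_gq",
                                        "gc")))
    data.frame(key = sprintf("v%05d", seq_len(n)), m)
  })
}

test_that("training sets balance by downsampling the majority class", {
  st <- featStats(1100)
  lab <- factor(rep(c("HIGH", "LOW"), c(1000, 100)),
                levels = c("HIGH", "LOW", "UNDETERMINED"))
  ts <- buildTrainingSet(st, lab, seed = 9L)
  expect_equal(nrow(ts@features), 200L)        # twice the minority count
  expect_equal(unname(table(ts@labels)), c(LOW = 100L, HIGH = 100L),
               ignore_attr = TRUE)
  ## deterministic given the seed
  ts2 <- buildTrainingSet(st, lab, seed = 9L)
  expect_identical(ts@ids, ts2@ids)
  expect_false(identical(ts@ids, buildTrainingSet(st, lab, seed = 10L)@ids))

  ## symmetric when LOW is the majority
  labFlip <- factor(rep(c("HIGH", "LOW"), c(100, 1000)),
                    levels = levels(lab))
  expect_equal(unname(table(buildTrainingSet(st, labFlip, 1L)@labels)),
               c(100L, 100L), ignore_attr = TRUE)
  ## no sampling needed when already balanced
  labEq <- factor(rep(c("HIGH", "LOW"), c(550, 550)), levels = levels(lab))
  expect_equal(nrow(buildTrainingSet(st, labEq, 1L)@features), 1100L)

  expect_error(buildTrainingSet(st, factor(rep("HIGH", 1100),
                                           levels = levels(lab))),
               "relax or tighten")
})

test_that("NA feature cells are median-imputed and flagged", {
  st <- featStats(40)
  st$gc[1:4] <- NA
  lab <- factor(rep(c("HIGH", "LOW"), 20), levels = c("HIGH", "LOW"))
  ts <- buildTrainingSet(st, lab, seed = 2L)
  expect_false(anyNA(ts@features))
  expect_equal(sum(ts@imputed), 4L)
  expect_equal(unique(ts@features[ts@imputed, "gc"]),
               unname(ts@medians["gc"]))
})

test_that("a separable signal yields near-perfect held-out F1", {
  train <- makeTrainingSet(n = 300, shift = 6, seed = 41L)
  test <- makeTrainingSet(n = 300, shift = 6, seed = 42L)
  model <- trainQcModel(train, nTrees = 50L)
  pred <- predictQc(model, data.frame(test@features))
  expect_gte(f1Score(as.character(test@labels), as.character(pred$label)),
             0.99)
})

test_that("permuted labels give chance-level held-out F1", {
  train <- makeTrainingSet(n = 400, shift = 0, seed = 51L)  # no signal
  test <- makeTrainingSet(n = 400, shift = 0, seed = 52L)
  model <- trainQcModel(train, nTrees = 50L)
  pred <- predictQc(model, data.frame(test@features))
  f1 <- f1Score(as.character(test@labels), as.character(pred$label))
  expect_gt(f1, 0.4)
  expect_lt(f1, 0.6)
})

test_that("50 trees beat a single tree on noisy data in most seeds", {
  wins <- 0L
  for (s in 1:10) {
    train <- makeTrainingSet(n = 160, shift = 1.2, seed = 100L + s)
    test <- makeTrainingSet(n = 160, shift = 1.2, seed = 200L + s)
    f1For <- function(k) {
      m <- trainQcModel(train, nTrees = k, seed = 300L + s)
      f1Score(as.character(test@labels),
              as.character(predictQc(m, data.frame(test@features))$label))
    }
    wins <- wins + (f1For(50L) >= f1For(1L))
  }
  expect_gte(wins, 9L)
})

test_that("prediction labels HIGH strictly above the threshold", {
  train <- makeTrainingSet(n = 200, shift = 2, seed = 61L)
  model <- trainQcModel(train, nTrees = 50L)
  test <- makeTrainingSet(n = 200, shift = 2, seed = 62L)
  pred <- predictQc(model, data.frame(test@features))
  expect_identical(pred$label == "HIGH", pred$probability > 0.5)
  ## with 50 trees some probabilities sit exactly on attainable grid points;
  ## force the tie case via a threshold equal to an observed probability
  tie <- pred$probability[1]
  predTie <- predictQc(model, data.frame(test@features),
                       probabilityThreshold = tie)
  expect_equal(as.character(predTie$label[1]), "LOW")

  ## HIGH count is non-increasing in the threshold
  highs <- vapply(seq(0.1, 0.9, by = 0.1), function(t)
    sum(predictQc(model, data.frame(test@features),
                  probabilityThreshold = t)$label == "HIGH"), numeric(1))
  expect_true(all(diff(highs) <= 0))

  expect_error(predictQc(model, data.frame(test@features[, 1:3])),
               "feature-order mismatch")
})

test_that("feature importances are normalized and recover a planted signal", {
  model <- trainQcModel(makeTrainingSet(n = 200, shift = 5, seed = 71L))
  imp <- featureImportance(model)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_equal(names(which.max(imp)), "mean_gq")
  expect_equal(names(imp), model@featureOrder)
})

test_that("exchangeable noise spreads importance roughly uniformly", {
  imps <- sapply(1:5, function(s) {
    m <- trainQcModel(makeTrainingSet(n = 200, shift = 0, seed = 80L + s),
                      seed = 90L + s)
    featureImportance(m)
  })
  expect_true(all(abs(rowMeans(imps) - 1 / 7) < 0.1))
})

test_that("final sets merge by union and reject overlaps", {
  fH <- sprintf("h%02d", 1:70); fL <- sprintf("l%02d", 1:10)
  pH <- sprintf("u%02d", 1:12); pL <- sprintf("u%02d", 13:20)
  fin <- mergeFinalSets(fH, fL, pH, pL)
  expect_equal(length(fin$high), 82L)
  expect_equal(length(fin$low), 18L)
  expect_equal(length(intersect(fin$high, fin$low)), 0L)
  expect_equal(length(fin$high) + length(fin$low), 100L)
  ## zero undetermined: finals equal the filter outputs
  noU <- mergeFinalSets(fH, fL, character(), character())
  expect_identical(noU$high, fH)
  expect_error(mergeFinalSets(fH, fL, c("h01"), character()),
               "pipeline bug")
})

test_that("F1 follows the harmonic-mean formula", {
  expect_equal(f1Score(tp = 10, fp = 0, fn = 0), 1)
  expect_equal(f1Score(tp = 10, fp = 10, fn = 0), 2 / 3)
  expect_equal(f1Score(tp = 90, fp = 10, fn = 10), 0.9)
})

test_that("the algorithm comparison reports F1/AUC for all baselines, sorted", {
  train <- makeTrainingSet(n = 120, shift = 3, seed = 81L)
  test <- makeTrainingSet(n = 120, shift = 3, seed = 82L)
  tab <- compareAlgorithms(train, test, folds = 3L, seed = 5L)
  expect_setequal(tab$algorithm,
                  c("random_forest", "logistic_regression", "naive_bayes"))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(diff(tab$f1) <= 0))           # sorted by F1
  expect_gte(tab$f1[tab$algorithm == "random_forest"], 0.9)
})

test_that("models survive a save/load round trip with identical predictions", {
  dir <- withr::local_tempdir()
  train <- makeTrainingSet(n = 200, shift = 3, seed = 91L)
  model <- trainQcModel(train)
  test <- data.frame(makeTrainingSet(n = 100, shift = 3, seed = 92L)@features)
  path <- file.path(dir, "model.rds")
  saveQcModel(model, path)
  back <- readQcModel(path)
  expect_identical(predictQc(back, test), predictQc(model, test))
  expect_identical(back@featureOrder, model@featureOrder)

  saveRDS(list(a = 1), path)
  expect_error(readQcModel(path), "not a VariantForest model")
})
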