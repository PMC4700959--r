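# well-separated two-class blobs for classifier mechanics
makeBlobs <- function(n = 40, d = 5, sep = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n * d), ncol = d),
             matrix(stats::rnorm(n * d, mean = sep), ncol = d))
  y <- factor(rep(c("constrained", "unconstrained"), each = n),
              levels = c("constrained", "unconstrained"))
  list(x = x, y = y)
}

test_that("label rules follow the conservation/functional thresholds", {
  lay <- genomeLayout("chr1", 50000)
  win <- makeSlidingWindows(lay, 10000, 10000)[1:4]
  cons <- gr1(c(1, 20001), c(2600, 21000), layout = lay)   # 26%, 10%
  fun <- gr1(30001, 30100, layout = lay)
  lab <- labelTrainingWindows(win, cons, list(fun))
  expect_equal(as.character(lab),
               c("constrained",    # 26% conserved
                 "unconstrained",  # zero conservation, zero functional
                 "unlabeled",      # 10% conserved: between the criteria
                 "unlabeled"))     # functional overlap blocks unconstrained
})

test_that("balancing matches the minority class and is seed-reproducible", {
  lab <- rep(c("constrained", "unconstrained"), c(50, 1000))
  idx <- balanceTrainingSet(lab, seed = 3)
  expect_length(idx, 100)
  expect_equal(sum(lab[idx] == "constrained"), 50)
  expect_identical(idx, balanceTrainingSet(lab, seed = 3))
  expect_error(balanceTrainingSet(rep("constrained", 5)), "non-empty")
})

test_that("scaler maps the training range to [-1, 1] without clipping", {
  x <- cbind(a = c(0, 0.5, 1), b = c(2, 2, 2))
  sc <- fitScaler(x)
  xs <- applyScaler(x, sc)
  expect_equal(xs[, 1], c(-1, 0, 1))
  expect_equal(xs[, 2], c(-1, -1, -1))  # constant feature maps to lo
  expect_equal(unname(applyScaler(cbind(a = 2, b = 2), sc)[1, 1]), 3)
  expect_error(applyScaler(cbind(1), sc), "does not match")
})

test_that("grid search separates blobs, fixes folds, and breaks ties low", {
  bl <- makeBlobs()
  gs <- gridSearchCv(bl$x, bl$y, cGrid = c(1, 4), gammaGrid = c(0.1, 0.5),
                     folds = 5, seed = 2)
  expect_equal(max(gs$accuracy), 1)
  expect_true(all(gs$accuracy >= 0 & gs$accuracy <= 1))
  # every row is held out exactly once, stratified across folds
  expect_equal(sort(unique(gs$folds)), 1:5)
  expect_true(all(table(gs$folds, bl$y) == 8))
  # all grid points perfect -> tie broken toward smallest C then gamma
  expect_equal(gs$bestC, 1)
  expect_equal(gs$bestGamma, 0.1)
  gs2 <- gridSearchCv(bl$x, bl$y, cGrid = c(1, 4), gammaGrid = c(0.1, 0.5),
                      folds = 5, seed = 2)
  expect_identical(gs$accuracy, gs2$accuracy)
  expect_error(gridSearchCv(bl$x[1:3, ], bl$y[1:3], folds = 5), "fewer rows")
})

test_that("training and prediction satisfy the probability contracts", {
  bl <- makeBlobs()
  m <- trainModel(bl$x, bl$y, C = 2, gamma = 0.125, seed = 5)
  pred <- predictWindows(m, bl$x)
  expect_equal(mean(pred$label == bl$y), 1)  # separable: training accuracy 1
  expect_true(all(pred$posteriorConstrained >= 0 &
                  pred$posteriorConstrained <= 1))
  # the two class posteriors sum to one by construction
  expect_true(all(pred$posteriorConstrained[bl$y == "constrained"] > 0.5))
  m2 <- trainModel(bl$x, bl$y, C = 2, gamma = 0.125, seed = 5)
  expect_equal(predictWindows(m2, bl$x), pred)  # same seed, same predictions
  expect_error(trainModel(bl$x, rep("constrained", nrow(bl$x)), 2, 0.125),
               "single class")
  expect_error(predictWindows(m, bl$x[, 1:2]), "does not match")
})

test_that("model evaluation matches a brute-force AUC oracle", {
  bl <- makeBlobs()
  m <- trainModel(bl$x, bl$y, C = 2, gamma = 0.125, seed = 5)
  ev <- evaluateModel(m, bl$x, bl$y)
  expect_equal(ev$auc, 1)  # perfect ranking

  # noisy labels: AUC equals pairwise concordance of the posterior ranking
  set.seed(8)
  yNoisy <- bl$y[sample(length(bl$y))]
  evN <- evaluateModel(m, bl$x, yNoisy)
  p <- predictWindows(m, bl$x)$posteriorConstrained
  pos <- p[yNoisy == "constrained"]
  neg <- p[yNoisy == "unconstrained"]
  conc <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(evN$auc, mean(conc))
  expect_lt(abs(evN$auc - 0.5), 0.15)  # shuffled labels: near-null AUC
})

test_that("models survive a save/load round trip", {
  bl <- makeBlobs()
  m <- trainModel(bl$x, bl$y, C = 2, gamma = 0.125, seed = 5)
  f <- tempfile(fileext = ".rds")
  saveModel(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  m2 <- loadModel(f)
  expect_equal(predictWindows(m2, bl$x), predictWindows(m, bl$x))
  expect_equal(modelHyperparams(m2), list(C = 2, gamma = 0.125))
})
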