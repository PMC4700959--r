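#' ConstraintModel: a trained constraint classifier
#'
#' Bundles the fitted soft-margin RBF SVM (a LIBSVM model via
#' \pkg{e1071}), the min-max feature scaler saved from the training data,
#' the Platt sigmoid mapping decision values to calibrated class
#' probabilities, and training metadata. "constrained" is the positive class
#' everywhere: `predictWindows()` reports the posterior probability of
#' constraint.
#'
#' @slot svm the fitted `e1071::svm` object.
#' @slot scaler list with `min`, `max`, `lo`, `hi` (see [fitScaler()]).
#' @slot platt numeric `c(A, B)` of the sigmoid `P = 1/(1+exp(A f + B))`.
#' @slot orientation +1/-1 multiplier making decision values positive for
#'   the constrained class.
#' @slot hyperparams list with `C` and `gamma`.
#' @slot metadata list (seed, bins, window size, calibration folds, ...).
#' @exportClass ConstraintModel
setClass("ConstraintModel",
  representation(svm = "ANY", scaler = "list", platt = "numeric",
                 orientation = "numeric", hyperparams = "list",
                 metadata = "list"),
  validity = function(object) {
    if (length(object@platt) != 2) return("platt must be c(A, B)")
    if (!object@orientation %in% c(-1, 1)) return("orientation must be +/-1")
    if (object@hyperparams$C <= 0 || object@hyperparams$gamma <= 0)
      return("C and gamma must be positive")
    TRUE
  })

setMethod("show", "ConstraintModel", function(object) {
  cat("ConstraintModel (RBF SVM with Platt-calibrated probabilities)\n",
      " C =", object@hyperparams$C, "| gamma =", object@hyperparams$gamma,
      "\n  support vectors:", object@svm$tot.nSV,
      "| features:", length(object@scaler$min), "\n")
})

#' @describeIn ConstraintModel-class hyperparameter list.
#' @param x a `ConstraintModel`.
#' @export
setGeneric("modelHyperparams", function(x) standardGeneric("modelHyperparams"))
#' @rdname ConstraintModel-class
#' @export
setMethod("modelHyperparams", "ConstraintModel", function(x) x@hyperparams)

#' @describeIn ConstraintModel-class training metadata list.
#' @export
setGeneric("modelMetadata", function(x) standardGeneric("modelMetadata"))
#' @rdname ConstraintModel-class
#' @export
setMethod("modelMetadata", "ConstraintModel", function(x) x@metadata)

.classLevels <- c("constrained", "unconstrained")

# evaluate expr under a temporary RNG seed, restoring global state after
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

asFeatureMatrix <- function(x) {
  if (methods::is(x, "ConstraintFeatures")) featureMatrix(x) else as.matrix(x)
}

#' Label training windows from annotation tracks
#'
#' A window is labelled `constrained` when more than `minConsFraction` of
#' its bases lie in the conservation track; `unconstrained` when it overlaps
#' the conservation track and every supplied functional track by zero base
#' pairs; otherwise `unlabeled`.
#'
#' @param windows `GRanges` of candidate training windows (already filtered
#'   for informativeness).
#' @param conservation `GRanges` conservation track (phastCons-like).
#' @param functionalTracks list of `GRanges` (exons, TF binding sites,
#'   regulatory elements, ...) that must have zero overlap for the
#'   unconstrained label.
#' @param minConsFraction constrained threshold (strict >), default 0.25.
#' @return Factor with levels constrained / unconstrained / unlabeled.
#' @export
labelTrainingWindows <- function(windows, conservation,
                                 functionalTracks = list(),
                                 minConsFraction = 0.25) {
  stopifnot(minConsFraction > 0, minConsFraction < 1)
  consFrac <- coverageFraction(windows, conservation)
  zeroCons <- coveredBp(windows, conservation) == 0
  zeroFun <- rep(TRUE, length(windows))
  for (tr in functionalTracks)
    zeroFun <- zeroFun & coveredBp(windows, tr) == 0
  lab <- rep("unlabeled", length(windows))
  lab[consFrac > minConsFraction] <- "constrained"
  lab[zeroCons & zeroFun] <- "unconstrained"
  factor(lab, levels = c(.classLevels, "unlabeled"))
}

#' Balance a labelled training set
#'
#' Downsamples the majority class without replacement until both classes
#' match the minority class in size, reproducibly under `seed`.
#'
#' @param labels factor from [labelTrainingWindows()] (or any vector with
#'   constrained/unconstrained entries).
#' @param seed optional integer seed; the global RNG state is restored.
#' @return Sorted integer indices of the selected balanced set.
#' @export
balanceTrainingSet <- function(labels, seed = NULL) {
  idxC <- which(labels == "constrained")
  idxU <- which(labels == "unconstrained")
  if (!length(idxC) || !length(idxU))
    stop("both classes must be non-empty to balance the training set")
  k <- min(length(idxC), length(idxU))
  withSeed(seed, {
    if (length(idxC) > k) idxC <- sample(idxC, k)
    if (length(idxU) > k) idxU <- sample(idxU, k)
  })
  sort(c(idxC, idxU))
}

#' Min-max feature scaling with saved scalars
#'
#' `fitScaler` records per-feature training minima and maxima;
#' `applyScaler` maps each feature linearly so the training range spans
#' exactly \[lo, hi\] (default \[-1, 1\]). Constant features map to `lo`.
#' Prediction-time data are scaled with the SAVED scalars and may exceed the
#' range; values are deliberately not clipped.
#'
#' @param x numeric feature matrix (rows = windows).
#' @param range numeric length-2 target range.
#' @return `fitScaler`: a scaler list; `applyScaler`: the scaled matrix.
#' @export
fitScaler <- function(x, range = c(-1, 1)) {
  x <- asFeatureMatrix(x)
  list(min = apply(x, 2, min), max = apply(x, 2, max),
       lo = range[1], hi = range[2])
}

#' @param scaler a scaler list from `fitScaler`.
#' @rdname fitScaler
#' @export
applyScaler <- function(x, scaler) {
  x <- asFeatureMatrix(x)
  if (ncol(x) != length(scaler$min))
    stop("feature count does not match the scaler (", ncol(x), " vs ",
         length(scaler$min), ")")
  span <- scaler$max - scaler$min
  out <- sweep(x, 2, scaler$min)
  const <- span == 0
  span[const] <- 1
  out <- sweep(out, 2, span, "/") * (scaler$hi - scaler$lo) + scaler$lo
  out[, const] <- scaler$lo
  out
}

# stratified fold assignment, fixed across grid points
stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Grid search of SVM hyperparameters by stratified cross-validation
#'
#' Evaluates every (C, gamma) pair on the same stratified k-fold partition
#' and returns the pair maximising CV accuracy, breaking ties toward the
#' smallest C and then the smallest gamma. Test folds are never seen during
#' the corresponding fit.
#'
#' @param x scaled feature matrix (or `ConstraintFeatures`).
#' @param y labels (constrained/unconstrained), balanced.
#' @param cGrid,gammaGrid candidate values; the defaults are the classic
#'   exponentially spaced LIBSVM grids (C = 2^-5..2^15, gamma = 2^-15..2^3)
#'   and contain the operating point C = 2, gamma = 0.125.
#' @param folds number of CV folds (default 10).
#' @param seed optional seed governing the fold assignment.
#' @return List with `bestC`, `bestGamma`, `accuracy` (surface matrix,
#'   rows = C), `folds` (per-row fold ids).
#' @export
gridSearchCv <- function(x, y, cGrid = 2^seq(-5, 15, by = 2),
                         gammaGrid = 2^seq(-15, 3, by = 2),
                         folds = 10, seed = NULL) {
  x <- asFeatureMatrix(x)
  y <- factor(as.character(y), levels = .classLevels)
  if (folds < 2) stop("folds must be >= 2")
  if (nrow(x) < folds) stop("fewer rows than folds")
  fold <- withSeed(seed, stratifiedFolds(y, folds))
  acc <- matrix(NA_real_, nrow = length(cGrid), ncol = length(gammaGrid),
                dimnames = list(C = signif(cGrid, 4),
                                gamma = signif(gammaGrid, 4)))
  for (ci in seq_along(cGrid)) {
    for (gi in seq_along(gammaGrid)) {
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- fold != f
        if (all(tr)) next
        fit <- fitSvm(x[tr, , drop = FALSE], y[tr], cGrid[ci], gammaGrid[gi])
        pr <- predict(fit, x[!tr, , drop = FALSE])
        correct <- correct + sum(pr == y[!tr])
      }
      acc[ci, gi] <- correct / nrow(x)
    }
  }
  best <- which(acc == max(acc), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(bestC = cGrid[best[1]], bestGamma = gammaGrid[best[2]],
       accuracy = acc, folds = fold)
}

# Platt's sigmoid fit (robust Newton with backtracking) on decision values f
# against binary labels y (TRUE = constrained). Targets are regularised as
# in Platt (1999) / Lin et al. (2007).
plattFit <- function(f, y, maxIter = 100) {
  prior1 <- sum(y)
  prior0 <- sum(!y)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y, hi, lo)
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  eps <- 1e-5; sigma <- 1e-12
  fval <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  Fv <- fval(A, B)
  for (it in seq_len(maxIter)) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < eps && abs(g2) < eps) break
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= 1e-10) {
      newA <- A + step * dA
      newB <- B + step * dB
      newF <- fval(newA, newB)
      if (newF < Fv + 1e-4 * step * gd) {
        A <- newA; B <- newB; Fv <- newF
        break
      }
      step <- step / 2
    }
    if (step < 1e-10) break
  }
  c(A = A, B = B)
}

orientedDecision <- function(fit, x, orientation = 1) {
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  as.numeric(dv[, 1]) * orientation
}

# fit with rows ordered constrained-first so LIBSVM's internal class order,
# and hence the sign of decision values, is deterministic
fitSvm <- function(x, y, C, gamma) {
  ord <- order(y)
  svm(x[ord, , drop = FALSE], y[ord], type = "C-classification",
      kernel = "radial", cost = C, gamma = gamma, scale = FALSE)
}

#' Train the constraint classifier
#'
#' Fits the min-max scaler on the training features, trains an RBF
#' soft-margin SVM on all rows, and calibrates class probabilities by
#' fitting a Platt sigmoid to decision values collected under stratified
#' cross-validation (so calibration never scores a point with the model
#' that saw it).
#'
#' @param x feature matrix or `ConstraintFeatures` (raw, unscaled).
#' @param y labels, both classes present.
#' @param C,gamma SVM hyperparameters (e.g. from [gridSearchCv()]).
#' @param calibrationFolds folds for the calibration CV (default 5).
#' @param seed optional seed (calibration fold assignment).
#' @param metadata optional list stored in the model.
#' @return A [ConstraintModel-class].
#' @export
trainModel <- function(x, y, C = 2, gamma = 0.125, calibrationFolds = 5,
                       seed = NULL, metadata = list()) {
  xm <- asFeatureMatrix(x)
  y <- factor(as.character(y), levels = .classLevels)
  if (any(is.na(y))) stop("labels must be constrained/unconstrained")
  if (length(unique(y)) < 2) stop("training data contain a single class")
  scaler <- fitScaler(xm)
  xs <- applyScaler(xm, scaler)

  fit <- fitSvm(xs, y, C, gamma)
  f <- orientedDecision(fit, xs)
  orientation <- if (mean(f[y == "constrained"]) >=
                     mean(f[y == "unconstrained"])) 1 else -1

  fold <- withSeed(seed, stratifiedFolds(y, calibrationFolds))
  fcv <- numeric(nrow(xs))
  for (k in seq_len(calibrationFolds)) {
    tr <- fold != k
    if (all(tr)) next  # empty fold (fewer rows per class than folds)
    sub <- fitSvm(xs[tr, , drop = FALSE], y[tr], C, gamma)
    fcv[!tr] <- orientedDecision(sub, xs[!tr, , drop = FALSE]) * orientation
  }
  platt <- plattFit(fcv, y == "constrained")

  new("ConstraintModel", svm = fit, scaler = scaler, platt = unname(platt),
      orientation = orientation,
      hyperparams = list(C = C, gamma = gamma),
      metadata = c(metadata,
                   list(nTrain = nrow(xs), calibrationFolds = calibrationFolds,
                        scalingRange = c(scaler$lo, scaler$hi))))
}

#' Classify windows and report calibrated posteriors
#'
#' @param model a [ConstraintModel-class].
#' @param x feature matrix or `ConstraintFeatures` with the same bin count
#'   as the training data (raw; the saved scaler is applied internally).
#' @return `data.frame` with `label` (posterior > 0.5 rule) and
#'   `posteriorConstrained`; the two class posteriors sum to 1.
#' @export
predictWindows <- function(model, x) {
  xs <- applyScaler(asFeatureMatrix(x), model@scaler)
  f <- orientedDecision(model@svm, xs) * model@orientation
  A <- model@platt[1]; B <- model@platt[2]
  fApB <- A * f + B
  post <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
  data.frame(label = factor(ifelse(post > 0.5, "constrained", "unconstrained"),
                            levels = .classLevels),
             posteriorConstrained = post)
}

#' Evaluate a classifier on labelled data
#'
#' @param model a [ConstraintModel-class].
#' @param x features of a held-out labelled set.
#' @param y true labels.
#' @return List with `accuracy`, `auc` and `roc` (a data.frame of ROC
#'   points) computed from the posterior ranking.
#' @export
evaluateModel <- function(model, x, y) {
  y <- factor(as.character(y), levels = .classLevels)
  pred <- predictWindows(model, x)
  accuracy <- mean(pred$label == y)
  rocObj <- pROC::roc(response = y, predictor = pred$posteriorConstrained,
                      levels = c("unconstrained", "constrained"),
                      direction = "<", quiet = TRUE)
  list(accuracy = accuracy, auc = as.numeric(pROC::auc(rocObj)),
       roc = data.frame(fpr = 1 - rocObj$specificities,
                        tpr = rocObj$sensitivities))
}

#' Save or load a trained model
#'
#' The fitted model is serialized with `saveRDS`; a JSON sidecar
#' (`<path>.json`) records the hyperparameters, scaler and metadata for
#' inspection without loading the model.
#'
#' @param model a [ConstraintModel-class].
#' @param path output path (".rds").
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  meta <- list(hyperparams = model@hyperparams,
               platt = model@platt, orientation = model@orientation,
               scaler = model@scaler, metadata = model@metadata)
  write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(methods::is(model, "ConstraintModel"))
  model
}
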