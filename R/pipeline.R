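#' Run the full constraint-classification pipeline on a genome bundle
#'
#' Convenience driver chaining every step of the method on an in-memory
#' bundle (as produced by [generateSyntheticGenome()], or assembled from
#' files): polarization, informative masking, windowed modified-SFS
#' features, conservation-based labelling of adjacent windows, balanced
#' training, RBF-SVM fitting with calibrated probabilities, sliding-window
#' classification, element calling with the strict-mask filter, and GOF/LOF
#' candidate calling.
#'
#' @param bundle list with `layout`, `snps`, `outgroups`, `mappability`,
#'   `repeats`, `ancestralCallable`, `conservation`, `functional`,
#'   `strictMask`, `n`.
#' @param windowSize,step sliding-window geometry for classification
#'   (training always uses adjacent windows of `windowSize`).
#' @param bins feature bins (default: no binning beyond the sample size).
#' @param minInformativeFraction informative-window retention threshold.
#' @param C,gamma SVM hyperparameters; when `gridSearch = TRUE` they are
#'   chosen by [gridSearchCv()] over a reduced grid instead.
#' @param cutoff element-calling posterior cutoff.
#' @param seed seed for balancing/calibration (and grid-search folds).
#' @param gridSearch run a hyperparameter grid search (slower).
#' @return List with `sites`, `mask`, `model`, `windows` (classified
#'   sliding windows with `label` and `posteriorConstrained`), `elements`
#'   (popCons/popUncons, strict-mask filtered), `gof`, `lof`.
#' @export
runConstraintPipeline <- function(bundle, windowSize = 10000, step = 1000,
                                  bins = NULL, minInformativeFraction = 0.25,
                                  C = 2, gamma = 0.125, cutoff = 0.95,
                                  seed = 1, gridSearch = FALSE) {
  n <- bundle$n
  sites <- polarizeSites(bundle$snps, bundle$outgroups, n = n)
  mask <- buildInformativeMask(bundle$mappability, bundle$repeats,
                               bundle$ancestralCallable, bundle$layout)
  if (is.null(bins)) bins <- min(1000L, n)

  # training set: adjacent windows labelled from the annotation tracks
  twin <- makeSlidingWindows(bundle$layout, windowSize, windowSize)
  tfeat <- filterWindows(computeModifiedSFS(twin, sites, mask, n = n),
                         minInformativeFraction)
  tfeat <- binSFS(tfeat, bins)
  labels <- labelTrainingWindows(featureWindows(tfeat), bundle$conservation,
                                 bundle$functional)
  bal <- balanceTrainingSet(labels, seed = seed)
  xTrain <- featureMatrix(tfeat)[bal, , drop = FALSE]
  yTrain <- droplevels(labels[bal])
  if (gridSearch) {
    gs <- gridSearchCv(applyScaler(xTrain, fitScaler(xTrain)), yTrain,
                       cGrid = 2^seq(-1, 7, by = 2),
                       gammaGrid = 2^seq(-9, -1, by = 2),
                       folds = 5, seed = seed)
    C <- gs$bestC
    gamma <- gs$bestGamma
  }
  model <- trainModel(xTrain, yTrain, C = C, gamma = gamma, seed = seed,
                      metadata = list(bins = bins, windowSize = windowSize))

  # classification on overlapping windows
  swin <- makeSlidingWindows(bundle$layout, windowSize, step)
  sfeat <- filterWindows(computeModifiedSFS(swin, sites, mask, n = n),
                         minInformativeFraction)
  sfeat <- binSFS(sfeat, bins)
  pred <- predictWindows(model, sfeat)
  cls <- featureWindows(sfeat)
  cls$label <- pred$label
  cls$posteriorConstrained <- pred$posteriorConstrained

  els <- callElements(cls, cutoff = cutoff)
  els <- lapply(els, strictMaskFilter, informativeMask = mask,
                strictMask = bundle$strictMask)
  gof <- callGof(els$popCons, bundle$conservation, cls)
  lof <- callLof(els$popUncons, bundle$conservation)
  list(sites = sites, mask = mask, model = model, windows = cls,
       elements = els, gof = gof, lof = lof)
}
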