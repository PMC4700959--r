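# Shared fixtures. The simulation-study objects (training corpus, grid-searched
# hyperparameters, trained classifier) are expensive, so they are built once per
# test run and cached in an environment.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, builder(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

simStudyDem <- function() fixture("dem", function()
  demographyPreset("tennessen", Q = 100))

simStudyCfg <- function() simConfig(sampleN = 100)

# neutral vs 75%-selected (2Ns = 100) training corpus, 200 windows per class,
# per-window mutation/recombination rates drawn from the three-value grids
simStudyTrain <- function() fixture("train", function()
  simulateTrainingCorpus(simStudyDem(), selectionConfig(0.75, 100),
                         simStudyCfg(), nPerClass = 200,
                         muGrid = rateGrid(), rGrid = rateGrid(), seed = 101))

# hyperparameters selected once by 10-fold CV over the exponential grid
simStudyHyper <- function() fixture("hyper", function() {
  tr <- simStudyTrain()
  x <- featureMatrix(tr)
  gs <- gridSearchCv(applyScaler(x, fitScaler(x)), featureWindows(tr)$label,
                     folds = 10, seed = 101)
  list(C = gs$bestC, gamma = gs$bestGamma, cv = max(gs$accuracy))
})

simStudyModel <- function() fixture("model", function() {
  tr <- simStudyTrain()
  h <- simStudyHyper()
  trainModel(featureMatrix(tr), featureWindows(tr)$label,
             C = h$C, gamma = h$gamma, seed = 101)
})

# a test corpus: central rates by default, or the variable-rate genome mixture
simStudyTest <- function(sel, seed, nPerClass = 200, variable = FALSE) {
  simulateTrainingCorpus(simStudyDem(), sel, simStudyCfg(),
                         nPerClass = nPerClass,
                         muGrid = if (variable) rateGrid(),
                         rGrid = if (variable) rateGrid(), seed = seed)
}

corpusAccuracy <- function(model, corpus) {
  pred <- predictWindows(model, featureMatrix(corpus))
  mean(pred$label == featureWindows(corpus)$label)
}

# small deterministic GRanges builders
gr1 <- function(starts, ends, chrom = "chr1", layout = NULL) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                         seqinfo = layout)
}

pointSites <- function(pos, chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
}
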