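#' DemographicModel: staged demography for the forward simulator
#'
#' An ordered sequence of epochs, each with a duration in generations and
#' per-deme start/end diploid sizes (exponentially interpolated within the
#' epoch) plus a symmetric per-generation migration probability between the
#' two demes. A second deme appears in the first epoch with a positive size
#' and is founded from deme 1. Sizes and durations are stored already
#' divided by the rescaling factor Q; the simulator multiplies mutation,
#' recombination, selection and migration rates by Q so that the
#' population-scaled parameters theta = 4 N mu, rho = 4 N r and 2Ns are
#' invariant under rescaling.
#'
#' @slot epochs `data.frame` with columns `duration`, `n1Start`, `n1End`,
#'   `n2Start`, `n2End`, `migration` (rescaled units; `n2* = 0` means the
#'   deme is absent).
#' @slot q rescaling factor Q (>= 1).
#' @slot burnInMult burn-in length as a multiple of the first epoch's
#'   diploid size (default 10).
#' @slot name preset name, for display.
#' @exportClass DemographicModel
setClass("DemographicModel",
  representation(epochs = "data.frame", q = "numeric",
                 burnInMult = "numeric", name = "character"),
  validity = function(object) {
    ep <- object@epochs
    need <- c("duration", "n1Start", "n1End", "n2Start", "n2End", "migration")
    if (!all(need %in% names(ep))) return("missing epoch columns")
    if (any(ep$duration <= 0)) return("epoch durations must be > 0")
    if (any(ep$n1Start < 2 | ep$n1End < 2))
      return("deme 1 sizes must be >= 2 diploids")
    if (object@q < 1) return("Q must be >= 1")
    TRUE
  })

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel '", object@name, "' (Q = ", object@q, ")\n",
      sep = "")
  print(object@epochs, row.names = FALSE)
})

#' @describeIn DemographicModel-class the rescaled epoch table.
#' @param x a `DemographicModel`.
#' @export
setGeneric("demographyEpochs", function(x) standardGeneric("demographyEpochs"))
#' @rdname DemographicModel-class
#' @export
setMethod("demographyEpochs", "DemographicModel", function(x) x@epochs)

#' @describeIn DemographicModel-class the rescaling factor Q.
#' @export
setGeneric("rescalingFactor", function(x) standardGeneric("rescalingFactor"))
#' @rdname DemographicModel-class
#' @export
setMethod("rescalingFactor", "DemographicModel", function(x) x@q)

#' Construct a demographic model from unscaled epochs
#'
#' @param epochs `data.frame` with columns `duration`, `n1Start`, `n1End`,
#'   `n2Start`, `n2End`, `migration` in natural (unscaled) units:
#'   generations, diploids, per-generation migration probability.
#' @param Q rescaling factor; sizes and durations are divided by Q
#'   (minimum 2 diploids / 1 generation) and migration multiplied by Q.
#' @param burnInMult burn-in multiple of the ancestral diploid size.
#' @param name display name.
#' @return A [DemographicModel-class].
#' @export
demographicModel <- function(epochs, Q = 1, burnInMult = 10,
                             name = "custom") {
  sc <- function(n) ifelse(n <= 0, 0, pmax(2, round(n / Q)))
  ep <- data.frame(duration = pmax(1, round(epochs$duration / Q)),
                   n1Start = sc(epochs$n1Start), n1End = sc(epochs$n1End),
                   n2Start = sc(epochs$n2Start), n2End = sc(epochs$n2End),
                   migration = pmin(0.49, epochs$migration * Q))
  new("DemographicModel", epochs = ep, q = Q, burnInMult = burnInMult,
      name = name)
}

#' Built-in demography presets
#'
#' `"tennessen"`: a two-deme out-of-Africa model in the style of Tennessen
#' et al. (2012): ancestral size 7,310 diploids; African growth to 14,474 at
#' 5,920 generations ago; out-of-Africa split 2,040 generations ago with a
#' bottleneck to 1,861 and symmetric migration 1.5e-4; a second European
#' bottleneck to 1,032 at 920 generations ago followed by exponential growth
#' to 9,237 with migration 2.5e-5; and recent accelerated growth from 205
#' generations ago to ~424,000 (Africa) and ~512,000 (Europe).
#' `"tennessen-african"`: the single-deme African collapse of the same
#' model, for speed. `"constant"`: a single deme of constant size `N`.
#'
#' @param name preset name.
#' @param Q rescaling factor (default 100, keeping the largest pre-growth
#'   epoch under 1,000 diploids at desk scale).
#' @param N diploid size for the `"constant"` preset.
#' @return A [DemographicModel-class].
#' @export
demographyPreset <- function(name = c("tennessen", "tennessen-african",
                                      "constant"),
                             Q = 100, N = 10000) {
  name <- match.arg(name)
  ep <- switch(name,
    "tennessen" = data.frame(
      duration = c(1, 3879, 1120, 715, 205),
      n1Start = c(7310, 14474, 14474, 14474, 14474),
      n1End   = c(7310, 14474, 14474, 14474, 424000),
      n2Start = c(0, 0, 1861, 1032, 9237),
      n2End   = c(0, 0, 1861, 9237, 512000),
      migration = c(0, 0, 1.5e-4, 2.5e-5, 2.5e-5)),
    "tennessen-african" = data.frame(
      duration = c(1, 5714, 205),
      n1Start = c(7310, 14474, 14474),
      n1End   = c(7310, 14474, 424000),
      n2Start = 0, n2End = 0, migration = 0),
    "constant" = data.frame(
      duration = 1, n1Start = N, n1End = N,
      n2Start = 0, n2End = 0, migration = 0))
  demographicModel(ep, Q = Q, name = name)
}
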