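#' Simulation configuration objects
#'
#' `simConfig` describes the simulated window: length, per-site
#' per-generation mutation and recombination rates (unscaled; the
#' demography's Q multiplies them internally) and the number of chromosomes
#' sampled at the end. `selectionConfig` describes purifying selection on
#' the window: the fraction of sites under selection (a single value, or a
#' length-2 range sampled uniformly per window), their arrangement
#' (a contiguous central block, or scattered sites) and the
#' population-scaled coefficient 2Ns per selected site (relative to the
#' ancestral size; 0 is neutral). `sweepConfig` describes a single
#' beneficial mutation conditioned to fix before sampling.
#'
#' @param L window length in bp.
#' @param mu,r per-site per-generation mutation / recombination rates.
#' @param sampleN chromosomes sampled at the end of the simulation (split
#'   evenly across demes when two demes exist).
#' @return A configuration list.
#' @export
simConfig <- function(L = 10000, mu = 1.2e-8, r = 1.2e-8, sampleN = 100) {
  stopifnot(L > 0, mu >= 0, r >= 0, sampleN >= 2)
  list(L = L, mu = mu, r = r, sampleN = as.integer(sampleN))
}

#' @param fractionSelected fraction of window sites under selection, in
#'   \[0, 1\]; a length-2 vector gives a per-window uniform range.
#' @param twoNs population-scaled selection coefficient 2Ns (>= 0).
#' @param arrangement "central_block" or "scattered".
#' @rdname simConfig
#' @export
selectionConfig <- function(fractionSelected = 0.75, twoNs = 100,
                            arrangement = c("central_block", "scattered")) {
  arrangement <- match.arg(arrangement)
  stopifnot(all(fractionSelected >= 0 & fractionSelected <= 1),
            length(fractionSelected) %in% 1:2, twoNs >= 0)
  list(fractionSelected = fractionSelected, twoNs = twoNs,
       arrangement = arrangement)
}

#' @param position sweep position as a fraction of the window length.
#' @param introGen post-burn-in generation (1-based) at which the
#'   beneficial mutation is introduced.
#' @param maxRetries attempts to achieve fixation before erroring.
#' @rdname simConfig
#' @export
sweepConfig <- function(twoNs = 1000, position = 0.5, introGen = 1,
                        maxRetries = 200) {
  stopifnot(twoNs > 0, position >= 0, position <= 1)
  list(twoNs = twoNs, position = position, introGen = as.integer(introGen),
       maxRetries = as.integer(maxRetries))
}

#' The default mutation/recombination rate grid
#'
#' Three values spanning one order of magnitude around the human point
#' estimate of 1.2e-8 per site per generation; training corpora draw each
#' window's rates from this grid to expose the classifier to rate
#' heterogeneity.
#'
#' @param center central rate.
#' @return Numeric vector of three rates.
#' @export
rateGrid <- function(center = 1.2e-8) {
  center * c(1 / sqrt(10), 1, sqrt(10))
}

epochMatrix <- function(dem) {
  ep <- demographyEpochs(dem)
  as.matrix(ep[, c("duration", "n1Start", "n1End", "n2Start", "n2End",
                   "migration")])
}

rescaledS <- function(dem, twoNs) {
  # s' = Q * s = twoNs / (2 * N_ancestral_rescaled)
  if (twoNs == 0) 0 else twoNs / (2 * demographyEpochs(dem)$n1Start[1])
}

sampleSplit <- function(dem, n) {
  ep <- demographyEpochs(dem)
  if (ep$n2End[nrow(ep)] > 0) {
    n1 <- ceiling(n / 2)
    c(n1, n - n1)
  } else {
    c(n, 0L)
  }
}

#' Forward-simulate one genomic window
#'
#' Forward Wright-Fisher dynamics over the demography's epochs after a
#' burn-in of `burnInMult * N_ancestral` generations: per-generation
#' infinite-sites mutation within the window, uniform crossover,
#' multiplicative selection against selected mutations (fitness exp(-s k)),
#' multinomial drift, and optional symmetric two-deme migration. Sampling
#' draws `sampleN` chromosomes at the end (half from each deme when two
#' demes exist).
#'
#' @param dem a [DemographicModel-class].
#' @param sel a [selectionConfig()]; `twoNs = 0` or `fractionSelected = 0`
#'   is neutral.
#' @param cfg a [simConfig()].
#' @param sweep optional [sweepConfig()]; when supplied a single beneficial
#'   mutation is introduced at `introGen` and the simulation is conditioned
#'   on its fixation before sampling (retrying from the introduction point
#'   on loss).
#' @param returnHaplotypes also return the 0/1 haplotype matrix
#'   (chromosomes x segregating sites).
#' @return List with `positions` (bp offsets in \[0, L)), `derivedCount`,
#'   `selected` (logical), `n`, `pi` (per-site nucleotide diversity over the
#'   window), `S` (segregating sites with 1 <= d <= n-1), `sweepAttempts`,
#'   and optionally `haplotypes`.
#' @export
simulateWindow <- function(dem, sel = selectionConfig(), cfg = simConfig(),
                           sweep = NULL, returnHaplotypes = FALSE) {
  frac <- sel$fractionSelected
  if (length(frac) == 2) frac <- runif(1, frac[1], frac[2])
  sDel <- rescaledS(dem, sel$twoNs)
  if (frac == 0) sDel <- 0
  lo <- (cfg$L - frac * cfg$L) / 2
  hi <- lo + frac * cfg$L
  scattered <- sel$arrangement == "scattered"
  split <- sampleSplit(dem, cfg$sampleN)
  q <- rescalingFactor(dem)
  burnIn <- round(dem@burnInMult * demographyEpochs(dem)$n1Start[1])
  res <- .simWindowCpp(epochMatrix(dem), cfg$L, cfg$mu * q, cfg$r * q,
                       sDel, lo, hi, scattered, frac,
                       as.integer(burnIn), split[1], split[2],
                       if (is.null(sweep)) 0 else rescaledS(dem, sweep$twoNs),
                       if (is.null(sweep)) 0 else sweep$position * cfg$L,
                       if (is.null(sweep)) 0L else sweep$introGen,
                       if (is.null(sweep)) 0L else sweep$maxRetries,
                       returnHaplotypes)
  d <- res$derived_count
  n <- res$n
  seg <- d >= 1 & d <= n - 1
  out <- list(positions = res$positions, derivedCount = d,
              selected = res$type == 1, n = n,
              pi = nucleotideDiversity(d[seg], n, cfg$L),
              S = sum(seg), sweepAttempts = res$sweep_attempts,
              fractionSelected = frac, L = cfg$L)
  if (returnHaplotypes) out$haplotypes = res$haplotypes
  out
}

#' @rdname simulateWindow
#' @export
simulateSweepWindow <- function(dem, sweep = sweepConfig(),
                                cfg = simConfig(),
                                returnHaplotypes = FALSE) {
  simulateWindow(dem, selectionConfig(fractionSelected = 0, twoNs = 0),
                 cfg, sweep = sweep, returnHaplotypes = returnHaplotypes)
}

# build a ConstraintFeatures corpus from a list of simulateWindow results
corpusFromSims <- function(sims, labels, L, n, mu, r) {
  xi <- matrix(0, nrow = length(sims), ncol = n)
  for (i in seq_along(sims)) {
    d <- sims[[i]]$derivedCount
    seg <- d[d >= 1 & d <= n - 1]
    if (length(seg)) {
      tb <- tabulate(seg, nbins = n - 1)
      xi[i, 2:n] <- tb / L
    }
    xi[i, 1] <- 1 - sum(xi[i, -1])
  }
  win <- GRanges("sim", IRanges(start = (seq_along(sims) - 1) * L + 1,
                                width = L))
  win$label <- labels
  win$pi <- vapply(sims, `[[`, numeric(1), "pi")
  win$S <- vapply(sims, function(s) as.numeric(s$S), numeric(1))
  win$mu <- mu
  win$r <- r
  win$fractionSelected <- vapply(sims, `[[`, numeric(1), "fractionSelected")
  new("ConstraintFeatures", windows = win, values = xi,
      sampleSize = as.integer(n), bins = as.integer(n),
      nInformative = rep(as.numeric(L), length(sims)),
      informativeFraction = rep(1, length(sims)))
}

#' Simulate a labelled training or test corpus
#'
#' Simulates `nPerClass` neutral windows and `nPerClass` windows under the
#' supplied selection configuration(s), each window drawing its mutation and
#' recombination rates from `muGrid` / `rGrid` (default: the window-level
#' rates in `cfg`, i.e. no heterogeneity). Returns the windows in the exact
#' feature format of the SFS module with class labels in
#' `featureWindows()$label`.
#'
#' @inheritParams simulateWindow
#' @param nPerClass windows per class.
#' @param muGrid,rGrid optional rate grids sampled per window (see
#'   [rateGrid()]).
#' @param seed optional seed; the global RNG state is restored.
#' @return A [ConstraintFeatures-class] with `label`, `pi`, `S`, `mu`, `r`
#'   and `fractionSelected` window metadata. Rows are neutral first.
#' @export
simulateTrainingCorpus <- function(dem, sel = selectionConfig(),
                                   cfg = simConfig(), nPerClass = 200,
                                   muGrid = NULL, rGrid = NULL,
                                   seed = NULL) {
  if (!is.list(sel[[1]]) && !is.null(sel$twoNs)) sel <- list(sel)
  withSeed(seed, {
    total <- 2L * nPerClass
    mu <- if (is.null(muGrid)) rep(cfg$mu, total)
          else sample(muGrid, total, replace = TRUE)
    r <- if (is.null(rGrid)) rep(cfg$r, total)
         else sample(rGrid, total, replace = TRUE)
    sims <- vector("list", total)
    for (i in seq_len(nPerClass)) {
      cfgI <- simConfig(L = cfg$L, mu = mu[i], r = r[i],
                        sampleN = cfg$sampleN)
      sims[[i]] <- simulateWindow(dem, selectionConfig(0, 0), cfgI)
    }
    for (i in seq_len(nPerClass)) {
      j <- nPerClass + i
      cfgI <- simConfig(L = cfg$L, mu = mu[j], r = r[j],
                        sampleN = cfg$sampleN)
      selI <- sel[[((i - 1) %% length(sel)) + 1]]
      sims[[j]] <- simulateWindow(dem, selI, cfgI)
    }
    corpusFromSims(sims,
                   rep(c("unconstrained", "constrained"), each = nPerClass),
                   cfg$L, cfg$sampleN, mu, r)
  })
}

#' Simulate a corpus of selective-sweep windows
#'
#' @inheritParams simulateWindow
#' @param nWindows number of sweep windows.
#' @param muGrid,rGrid optional per-window rate grids.
#' @param seed optional seed.
#' @return A [ConstraintFeatures-class]; labels are `"sweep"`.
#' @export
simulateSweepCorpus <- function(dem, sweep = sweepConfig(),
                                cfg = simConfig(), nWindows = 50,
                                muGrid = NULL, rGrid = NULL, seed = NULL) {
  withSeed(seed, {
    mu <- if (is.null(muGrid)) rep(cfg$mu, nWindows)
          else sample(muGrid, nWindows, replace = TRUE)
    r <- if (is.null(rGrid)) rep(cfg$r, nWindows)
         else sample(rGrid, nWindows, replace = TRUE)
    sims <- vector("list", nWindows)
    for (i in seq_len(nWindows)) {
      cfgI <- simConfig(L = cfg$L, mu = mu[i], r = r[i],
                        sampleN = cfg$sampleN)
      sims[[i]] <- simulateSweepWindow(dem, sweep, cfgI)
    }
    corpusFromSims(sims, rep("sweep", nWindows), cfg$L, cfg$sampleN, mu, r)
  })
}
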