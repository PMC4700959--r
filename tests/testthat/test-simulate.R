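constDem <- function(N = 50) demographyPreset("constant", Q = 1, N = N)

test_that("zero mutation rate yields zero segregating sites", {
  set.seed(1)
  sim <- simulateWindow(constDem(20), selectionConfig(0, 0),
                        simConfig(L = 5000, mu = 0, r = 1e-6, sampleN = 10))
  expect_equal(sim$S, 0)
  expect_equal(sim$pi, 0)
})

test_that("neutral equilibrium matches Watterson's expected S", {
  dem <- constDem(50)
  cfg <- simConfig(L = 10000, mu = 2.5e-6, r = 1.2e-6, sampleN = 20)
  set.seed(2)
  S <- replicate(120, simulateWindow(dem, selectionConfig(0, 0), cfg)$S)
  expectS <- 4 * 50 * cfg$mu * cfg$L * sum(1 / (1:19))
  expect_lt(abs(mean(S) - expectS), 4 * stats::sd(S) / sqrt(length(S)))
})

test_that("purifying selection lowers diversity against paired neutrals", {
  dem <- constDem(50)
  cfg <- simConfig(L = 10000, mu = 2.5e-6, r = 1.2e-6, sampleN = 20)
  set.seed(3)
  piNeu <- replicate(100, simulateWindow(dem, selectionConfig(0, 0), cfg)$pi)
  piSel <- replicate(100,
    simulateWindow(dem, selectionConfig(0.75, 100), cfg)$pi)
  tt <- stats::t.test(piSel, piNeu, alternative = "less")
  expect_lt(tt$p.value, 1e-6)
  # selected mutations are confined to the central block
  sim <- simulateWindow(dem, selectionConfig(0.5, 100), cfg)
  selPos <- sim$positions[sim$selected]
  if (length(selPos))
    expect_true(all(selPos >= 2500 & selPos < 7500))
})

test_that("training corpora are balanced, labelled, and reproducible", {
  dem <- constDem(30)
  cfg <- simConfig(L = 5000, mu = 2e-6, r = 1e-6, sampleN = 10)
  co <- simulateTrainingCorpus(dem, selectionConfig(0.75, 50), cfg,
                               nPerClass = 15, muGrid = rateGrid(2e-6),
                               seed = 7)
  expect_length(co, 30)
  expect_equal(as.vector(table(featureWindows(co)$label)), c(15, 15))
  expect_equal(featureBins(co), 10L)
  expect_true(all(abs(rowSums(featureMatrix(co)) - 1) < 1e-9))
  co2 <- simulateTrainingCorpus(dem, selectionConfig(0.75, 50), cfg,
                                nPerClass = 15, muGrid = rateGrid(2e-6),
                                seed = 7)
  expect_equal(featureMatrix(co2), featureMatrix(co))
})

test_that("conditioned sweeps fix, reduce diversity, and can fail", {
  # constant N = 50 with 120 post-burn-in generations for the sweep to run
  dem <- demographicModel(data.frame(duration = 120, n1Start = 50,
                                     n1End = 50, n2Start = 0, n2End = 0,
                                     migration = 0))
  cfg <- simConfig(L = 10000, mu = 2.5e-6, r = 1.2e-6, sampleN = 20)
  set.seed(5)
  piNeu <- replicate(40, simulateWindow(dem, selectionConfig(0, 0), cfg)$pi)
  sw <- replicate(40, simulateSweepWindow(
    dem, sweepConfig(twoNs = 1000, introGen = 1), cfg)$pi)
  tt <- stats::t.test(sw, piNeu, alternative = "less")
  expect_lt(tt$p.value, 1e-4)
  # a sweep introduced in the final generation cannot fix: explicit failure
  dem1 <- demographicModel(data.frame(duration = 1, n1Start = 50, n1End = 50,
                                      n2Start = 0, n2End = 0, migration = 0))
  expect_error(
    simulateSweepWindow(dem1, sweepConfig(twoNs = 1000, introGen = 1,
                                          maxRetries = 1), cfg),
    "failed to fix")
})

test_that("synthetic genome bundles have consistent tracks and truth", {
  cfgS <- synthGenomeConfig(nNeutral = 3, nConstrained = 3, nGof = 1,
                            nLof = 1, regionLength = 10000, spacing = 5000,
                            cfg = simConfig(L = 10000, mu = 2.4e-8,
                                            sampleN = 20),
                            dem = demographyPreset("tennessen-african",
                                                   Q = 200))
  bundle <- generateSyntheticGenome(cfgS, seed = 9, outdir = td <- tempfile())
  expect_length(bundle$truth, 8)
  expect_equal(sort(unique(bundle$truth$name)),
               c("constrained", "gof", "lof", "neutral"))
  # sites only inside regions
  expect_true(all(countOverlaps(bundle$snps, bundle$regions) == 1))
  # planted GOF regions overlap the conservation track by zero bases
  gofR <- bundle$regions[bundle$regions$kind == "gof"]
  expect_equal(overlapBp(gofR, bundle$conservation), 0)
  # constrained regions cross the training threshold; LOF regions carry
  # conservation above the candidate cutoff but below the training rule
  consR <- bundle$regions[bundle$regions$kind == "constrained"]
  expect_true(all(coverageFraction(consR, bundle$conservation) > 0.25))
  lofRg <- bundle$regions[bundle$regions$kind == "lof"]
  lofFrac <- coverageFraction(lofRg, bundle$conservation)
  expect_true(all(lofFrac > 0.15 & lofFrac < 0.25))
  # written files parse back with the package's own readers
  expect_equal(readGenomeLayout(bundle$paths$layout), bundle$layout)
  vcf <- readSitesVcf(bundle$paths$vcf, bundle$layout)
  expect_equal(length(vcf), length(bundle$snps))
  expect_equal(vcf$ac, bundle$snps$ac)
  tr <- readBed(bundle$paths$truth, bundle$layout)
  expect_equal(length(tr), 8)
  og <- readOutgroupsTsv(bundle$paths$outgroups)
  expect_equal(nrow(og), length(bundle$snps))
})
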