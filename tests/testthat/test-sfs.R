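test_that("sliding windows follow the size/step/drop-partial contract", {
  expect_length(makeSlidingWindows(genomeLayout("c", 10200), 10000, 100), 3)
  expect_equal(BiocGenerics::start(
    makeSlidingWindows(genomeLayout("c", 10200), 10000, 100)),
    c(1, 101, 201))
  expect_length(makeSlidingWindows(genomeLayout("c", 9999), 10000, 100), 0)
  # floor((L - size)/step) + 1 windows over 1 Mb
  expect_length(makeSlidingWindows(genomeLayout("c", 1e6), 10000, 100), 9901)
})

test_that("modified SFS counts derived classes over informative sites", {
  lay <- genomeLayout("chr1", 20000)
  win <- gr1(1, 10000, layout = lay)
  mask <- gr1(1, 10, layout = lay)  # 10 informative sites
  snp <- pointSites(3)
  snp$ref <- "A"; snp$alt <- "G"; snp$ancestral <- "A"
  snp$derivedCount <- 3L; snp$n <- 4L; snp$informative <- TRUE
  sfs <- computeModifiedSFS(win, snp, mask, n = 4)
  expect_equal(featureMatrix(sfs)[1, ], c(0.9, 0, 0, 0.1))
  expect_equal(nInformative(sfs), 10)

  # a fixed derived allele (d = n) folds into xi0
  snp$derivedCount <- 4L
  sfs2 <- computeModifiedSFS(win, snp, mask, n = 4)
  expect_equal(featureMatrix(sfs2)[1, ], c(1, 0, 0, 0))

  # an ambiguous SNP inside the mask removes one informative site
  snp$derivedCount <- NA_integer_; snp$ancestral <- NA_character_
  snp$informative <- FALSE
  sfs3 <- computeModifiedSFS(win, snp, mask, n = 4)
  expect_equal(nInformative(sfs3), 9)
})

test_that("the unbinned feature vector has one entry per chromosome", {
  # 1,064 diploid individuals = 2,128 chromosomes = 2,128 frequency classes
  lay <- genomeLayout("chr1", 20000)
  win <- gr1(1, 10000, layout = lay)
  mask <- gr1(1, 5000, layout = lay)
  snp <- pointSites(c(10, 20))
  snp$ref <- c("A", "C"); snp$alt <- c("G", "T")
  snp$ancestral <- c("A", "C")
  snp$derivedCount <- c(3L, 2127L); snp$n <- 2128L
  snp$informative <- c(TRUE, TRUE)
  sfs <- computeModifiedSFS(win, snp, mask, n = 2128)
  expect_equal(ncol(featureMatrix(sfs)), 2128L)
  expect_equal(sum(featureMatrix(sfs)), 1)
})

test_that("binning conserves mass and follows the index partition", {
  x <- sfsFromCounts(c(3), n = 4, L = 10)
  expect_equal(featureMatrix(binSFS(x, 4)), featureMatrix(x))  # identity
  expect_equal(featureMatrix(binSFS(x, 1))[1, ], 1)            # total mass
  expect_equal(featureMatrix(binSFS(x, 2))[1, ], c(0.9, 0.1))
  expect_error(binSFS(x, 5), "bin")

  # property: for random spectra and every feasible B, binned mass equals the
  # oracle sum over the index partition floor(i*B/n)
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    counts <- sample(0:n, sample(0:8, 1), replace = TRUE)
    xr <- sfsFromCounts(counts, n = n, L = 100)
    for (B in unique(pmin(n, c(1, 2, 3, n %/% 2, n)))) {
      b <- featureMatrix(binSFS(xr, B))[1, ]
      idx <- floor((seq_len(n) - 1) * B / n)
      oracle <- as.numeric(tapply(featureMatrix(xr)[1, ], idx, sum))
      expect_equal(b, oracle)
      expect_equal(sum(b), sum(featureMatrix(xr)))
    }
  }
})

test_that("window filtering keeps strictly more than the threshold", {
  lay <- genomeLayout("chr1", 50000)
  win <- makeSlidingWindows(lay, 10000, 10000)
  # windows with informative fractions 0.25, 0.2501, 0.9
  mask <- gr1(c(1, 10001, 20001), c(2500, 12501, 29000), layout = lay)
  snp <- pointSites(5)
  snp$ref <- "A"; snp$alt <- "G"; snp$ancestral <- "A"
  snp$derivedCount <- 1L; snp$n <- 4L; snp$informative <- TRUE
  sfs <- computeModifiedSFS(win[1:3], snp, mask, n = 4)
  kept <- filterWindows(sfs)
  expect_equal(BiocGenerics::start(featureWindows(kept)), c(10001, 20001))
})

test_that("site order never changes the spectrum", {
  lay <- genomeLayout("chr1", 20000)
  win <- gr1(1, 10000, layout = lay)
  mask <- gr1(1, 10000, layout = lay)
  set.seed(3)
  snp <- pointSites(sample(10000, 50))
  snp$ref <- "A"; snp$alt <- "G"; snp$ancestral <- "A"
  snp$derivedCount <- sample(1:9, 50, replace = TRUE); snp$n <- 10L
  snp$informative <- TRUE
  a <- computeModifiedSFS(win, snp, mask, n = 10)
  b <- computeModifiedSFS(win, snp[sample(50)], mask, n = 10)
  expect_equal(featureMatrix(a), featureMatrix(b))
})
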