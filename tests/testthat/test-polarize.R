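# independently coded truth-table oracles for the parsimony rules
oracleSnp <- function(a, b, ch, ma) {
  if (!is.na(ch) && !is.na(ma)) {
    if (ch == ma && (ch == a || ch == b)) return(ch)
    return(NA_character_)
  }
  one <- if (!is.na(ch)) ch else if (!is.na(ma)) ma else return(NA_character_)
  if (one == a || one == b) one else NA_character_
}

oracleMono <- function(a, ch, ma) {
  if (!is.na(ch) && !is.na(ma)) {
    if (ch == ma) return(ch)
    return(NA_character_)
  }
  if (!is.na(ch)) return(ch)
  if (!is.na(ma)) return(ma)
  NA_character_
}

test_that("SNP polarization equals the truth-table oracle exhaustively", {
  bases <- c("A", "C", "G", "T")
  og <- c(bases, NA)
  pairs <- subset(expand.grid(a = bases, b = bases,
                              stringsAsFactors = FALSE), a != b)
  grid <- merge(pairs, expand.grid(ch = og, ma = og,
                                   stringsAsFactors = FALSE))
  got <- polarizeSnp(grid$a, grid$b, grid$ch, grid$ma)
  want <- mapply(oracleSnp, grid$a, grid$b, grid$ch, grid$ma)
  expect_equal(unname(got), unname(want))
  # spot checks straight from the parsimony rules
  expect_equal(polarizeSnp("A", "G", "A", "A"), "A")
  expect_true(is.na(polarizeSnp("A", "G", "A", "G")))
  expect_equal(polarizeSnp("A", "G", "A", NA), "A")
  expect_true(is.na(polarizeSnp("A", "G", "C", NA)))
  expect_true(is.na(polarizeSnp("A", "G", NA, NA)))
  expect_error(polarizeSnp("A", "A", "A", "A"), "differ")
  expect_error(polarizeSnp("A", "G", "N", "A"), "invalid base")
})

test_that("monomorphic polarization equals its oracle exhaustively", {
  bases <- c("A", "C", "G", "T")
  og <- c(bases, NA)
  grid <- expand.grid(a = bases, ch = og, ma = og, stringsAsFactors = FALSE)
  got <- polarizeMonomorphic(grid$a, grid$ch, grid$ma)
  want <- mapply(oracleMono, grid$a, grid$ch, grid$ma)
  expect_equal(unname(got), unname(want))
  # a fixed derived human allele is revealed by agreeing outgroups
  expect_equal(polarizeMonomorphic("A", "G", "G"), "G")
  expect_true(is.na(polarizeMonomorphic("A", "G", "C")))
  expect_equal(polarizeMonomorphic("A", "G", NA), "G")
})

test_that("polarizeSites computes derived counts and informative flags", {
  snps <- pointSites(c(10, 20, 30, 40))
  snps$ref <- c("A", "A", "A", "A")
  snps$alt <- c("G", "G", "G", "G")
  snps$ac <- c(3L, 3L, 3L, 3L)
  snps$an <- c(10L, 10L, 10L, 8L)
  outg <- data.frame(chrom = "chr1", pos = c(10, 20, 30),
                     chimp = c("A", "G", "A"), macaque = c("A", "G", "C"))
  out <- polarizeSites(snps, outg, n = 10)
  expect_length(out, 3)  # the an != n site is dropped
  expect_equal(out$ancestral, c("A", "G", NA))
  expect_equal(out$derivedCount, c(3L, 7L, NA))  # alt derived vs ref derived
  expect_equal(out$informative, c(TRUE, TRUE, FALSE))
})

test_that("informative mask requires unique mappability, no repeat, callable", {
  lay <- genomeLayout("chr1", 1000)
  mapp <- gr1(c(1, 201, 401), c(200, 400, 1000), layout = lay)
  mapp$score <- c(1, 1 / 3, 1)
  repeats <- gr1(501, 600, layout = lay)
  callable <- gr1(1, 900, layout = lay)
  mask <- buildInformativeMask(mapp, repeats, callable, lay)
  inMask <- function(p) countOverlaps(pointSites(p), mask) > 0
  expect_true(inMask(100))    # score 1, non-repeat, callable
  expect_false(inMask(300))   # score 1/3
  expect_false(inMask(550))   # repeat-masked
  expect_false(inMask(950))   # not ancestral-callable
  expect_true(inMask(700))
  # property: mask membership <=> all three conditions, at random positions
  set.seed(5)
  p <- sample(1000, 200)
  cond <- p <= 200 | (p >= 401 & p <= 900)
  cond <- cond & !(p >= 501 & p <= 600)
  expect_equal(vapply(p, inMask, logical(1)), cond)
})

test_that("nucleotide diversity equals the brute-force pairwise oracle", {
  expect_equal(nucleotideDiversity(1, n = 4, L = 1), 0.5)
  expect_equal(nucleotideDiversity(integer(0), n = 10, L = 100), 0)
  expect_error(nucleotideDiversity(1, n = 4, L = 0), "L = 0")
  expect_error(nucleotideDiversity(5, n = 4, L = 1), "\\[0, n\\]")

  dem <- demographyPreset("constant", Q = 1, N = 30)
  cfg <- simConfig(L = 2000, mu = 5e-6, r = 1e-6, sampleN = 10)
  set.seed(11)
  for (rep in 1:5) {
    sim <- simulateWindow(dem, selectionConfig(0, 0), cfg,
                          returnHaplotypes = TRUE)
    H <- sim$haplotypes
    pairs <- utils::combn(nrow(H), 2)
    brute <- mean(apply(pairs, 2, function(ij)
      sum(H[ij[1], ] != H[ij[2], ]))) / cfg$L
    expect_equal(sim$pi, brute, tolerance = 1e-12)
  }
})
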