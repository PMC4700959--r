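test_that("overlapBp is exact, symmetric, and matches a per-base oracle", {
  expect_equal(overlapBp(gr1(1, 100), gr1(51, 150)), 50)
  expect_equal(overlapBp(gr1(1, 100), gr1(200, 300)), 0)
  set.seed(17)
  for (rep in 1:10) {
    a <- gr1(sa <- sample(1:400, 8), sa + sample(1:80, 8, TRUE))
    b <- gr1(sb <- sample(1:400, 8), sb + sample(1:80, 8, TRUE))
    inSet <- function(g) {
      v <- logical(600)
      for (i in seq_along(g))
        v[BiocGenerics::start(g)[i]:BiocGenerics::end(g)[i]] <- TRUE
      v
    }
    oracle <- sum(inSet(a) & inSet(b))
    expect_equal(overlapBp(a, b), oracle)
    expect_equal(overlapBp(b, a), oracle)
  }
})

test_that("permutation preserves lengths, disjointness, and constraints", {
  lay <- genomeLayout(c("chr1", "chr2"), c(50000, 30000))
  el <- gr1(c(1, 10001, 25001), c(4000, 12000, 25800), layout = lay)
  pe <- permuteElementSet(el, lay, seed = 4)
  expect_equal(sort(width(pe)), sort(width(el)))      # length multiset
  expect_true(all(countOverlaps(pe, pe) == 1))        # pairwise disjoint
  expect_identical(granges(permuteElementSet(el, lay, seed = 4)),
                   granges(pe))                       # determinism

  allowed <- gr1(c(5001, 20001), c(15000, 40000), layout = lay)
  pe2 <- permuteElementSet(el, lay, allowedSpace = allowed, seed = 9)
  expect_equal(coverageFraction(pe2, allowed), rep(1, 3))  # containment

  # allowed space smaller than the largest element -> explicit failure
  expect_error(
    permuteElementSet(el, lay, allowedSpace = gr1(1, 3000, layout = lay)),
    "length 4000")

  # strict-mask constraint: placements keep >= 80% passing bases
  strict <- gr1(1, 50000, layout = lay)  # chr2 entirely failing
  pe3 <- permuteElementSet(el, lay, strictMask = strict, seed = 12)
  expect_true(all(coverageFraction(pe3, strict) >= 0.8))
})

test_that("enrichment test reports one-sided empirical p-values", {
  lay <- genomeLayout("chr1", 200000)
  el <- gr1(c(1, 50001), c(5000, 56000), layout = lay)
  res <- enrichmentTest(el, el, lay, nPerm = 40, seed = 6)
  # the feature track IS the element set: observed overlap is maximal
  expect_equal(res$observedBp, 11000)
  expect_true(all(res$permutedBp <= res$observedBp))
  expect_equal(res$pDeplete, 1)
  expect_lte(res$pEnrich, 0.1)
  if (res$nGreaterEqual == 0) expect_match(res$pEnrichLabel, "^< ")
  expect_equal(res$pEnrich, res$nGreaterEqual / res$nPermutations)
})

test_that("permuted candidate sets follow the conservation rules", {
  lay <- genomeLayout("chr1", 1e6)
  set.seed(44)
  sets <- replicate(3, {
    s <- sort(sample(seq(1, 9e5, by = 1000), 30))
    gr1(s, s + 999, layout = lay)
  }, simplify = FALSE)
  # conserve a block inside roughly half of all 1 kb slots
  cons <- gr1(seq(1, 9.9e5, by = 2000), seq(1, 9.9e5, by = 2000) + 400,
              layout = lay)
  gof <- derivePermutedCandidateSets(sets, cons, "GOF", targetSize = 5,
                                     seed = 2)
  expect_true(all(vapply(gof, length, integer(1)) == 5))
  for (g in gof) expect_true(all(coverageFraction(g, cons) < 0.01))
  lof <- derivePermutedCandidateSets(sets, cons, "LOF", targetSize = 5,
                                     seed = 2)
  for (g in lof) expect_true(all(coverageFraction(g, cons) > 0.15))
  expect_identical(
    granges(derivePermutedCandidateSets(sets, cons, "LOF", 5, seed = 2)[[1]]),
    granges(lof[[1]]))
  expect_error(
    derivePermutedCandidateSets(sets, cons, "GOF", targetSize = 1000),
    "smaller than the target")
})

test_that("feature sets are filtered by the complementary conservation rule", {
  lay <- genomeLayout("chr1", 1e6)
  feat <- gr1(c(1, 1001, 2001), c(1000, 2000, 3000), layout = lay)
  # conserved fractions exactly 1.0%, 0.9%, 15.0%
  cons <- gr1(c(1, 1001, 2001), c(10, 1009, 2150), layout = lay)
  gof <- filterFeatureSetByConservation(feat, cons, "GOF")
  expect_equal(BiocGenerics::start(gof), 1001)  # 1.0% removed, 0.9% kept
  lof <- filterFeatureSetByConservation(feat, cons, "LOF")
  expect_length(lof, 0)  # 15.0% is removed by the strict > 15% rule
})
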