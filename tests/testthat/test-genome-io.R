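test_that("mergeIntervals merges strict overlaps but not abutting intervals", {
  expect_equal(
    as.data.frame(mergeIntervals(gr1(c(1, 101), c(10000, 10100))))[, 1:3],
    as.data.frame(gr1(1, 10100))[, 1:3])
  # half-open abutting intervals share no base: [0,5) and [5,10) stay apart
  ab <- mergeIntervals(gr1(c(1, 6), c(5, 10)))
  expect_length(ab, 2)
  expect_length(mergeIntervals(GenomicRanges::GRanges()), 0)
})

test_that("mergeIntervals is idempotent and conserves covered bases", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    s <- sample(1:5000, n, replace = TRUE)
    x <- gr1(s, s + sample(1:400, n, replace = TRUE))
    m <- mergeIntervals(x)
    expect_identical(granges(m), granges(mergeIntervals(m)))
    expect_true(all(BiocGenerics::start(m) <= BiocGenerics::end(m)))
    # covered bases identical to the union of the input
    covered <- function(g) sum(IRanges::width(GenomicRanges::reduce(g)))
    expect_equal(covered(m), covered(x))
    expect_true(all(countOverlaps(m, m) == 1))  # pairwise disjoint
  }
})

test_that("mergeIntervals rejects intervals outside chromosome bounds", {
  lay <- genomeLayout("chr1", 1000)
  bad <- suppressWarnings(gr1(900, 1200, layout = lay))
  expect_error(mergeIntervals(bad), "bounds")
})

test_that("coverageFraction matches exact fractions and is additive", {
  q <- gr1(1, 10000)
  expect_equal(coverageFraction(q, gr1(1, 2500)), 0.25)
  expect_equal(coverageFraction(gr1(1, 100), GenomicRanges::GRanges()), 0)
  expect_equal(coverageFraction(gr1(11, 20), gr1(1, 100)), 1)
  # additivity over a partition of the query
  set.seed(7)
  track <- mergeIntervals(gr1(sample(1:900, 15), sample(901:2000, 15)))
  whole <- coverageFraction(gr1(1, 2000), track)
  parts <- coverageFraction(gr1(c(1, 501, 1001), c(500, 1000, 2000)), track)
  expect_equal(whole, sum(parts * c(500, 500, 1000)) / 2000)
  expect_true(all(parts >= 0 & parts <= 1))
})

test_that("BED and bedGraph round-trip through files", {
  lay <- genomeLayout("chr1", 100000)
  gr <- gr1(c(1, 500, 2001), c(100, 1500, 2500), layout = lay)
  f <- tempfile(fileext = ".bed")
  writeBed(gr, f)
  # the BED line for [1,100] must be 0-based half-open: "chr1 0 100"
  expect_match(readLines(f)[1], "^chr1\t0\t100")
  back <- readBed(f, lay)
  expect_equal(as.data.frame(granges(back))[, 1:3],
               as.data.frame(granges(gr))[, 1:3])

  bg <- gr
  bg$score <- c(1, 0.5, 1)
  fb <- tempfile(fileext = ".bedGraph")
  writeBedGraph(bg, fb)
  back2 <- readBedGraph(fb, lay)
  expect_equal(back2$score, bg$score)
  expect_error(suppressWarnings(readBed(tempfile(), lay)),
               "malformed|cannot|exist")
})

test_that("genome layout validates and round-trips as JSON", {
  expect_error(genomeLayout(c("a", "a"), c(10, 20)), "unique")
  expect_error(genomeLayout("a", 0), "> 0")
  lay <- genomeLayout(c("chr1", "chr2"), c(12345, 678))
  f <- tempfile(fileext = ".json")
  writeGenomeLayout(lay, f)
  expect_equal(readGenomeLayout(f), lay)
})

test_that("VCF sites round-trip and multiallelic records are skipped", {
  lay <- genomeLayout("chr1", 100000)
  sites <- pointSites(c(100, 250, 999))
  sites$ref <- c("A", "C", "G")
  sites$alt <- c("G", "T", "A")
  sites$ac <- c(3L, 1L, 2127L)
  sites$an <- c(2128L, 2128L, 2128L)
  f <- tempfile(fileext = ".vcf")
  writeSitesVcf(sites, f)
  back <- readSitesVcf(f, lay)
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(sites))
  expect_equal(back$ref, sites$ref)
  expect_equal(back$alt, sites$alt)
  expect_equal(back$ac, sites$ac)
  expect_equal(back$an, sites$an)

  # a hand-written VCF with one multiallelic and one indel record
  f2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t10\t.\tA\tG\t.\tPASS\tAC=5;AN=100",
    "chr1\t20\t.\tA\tG,T\t.\tPASS\tAC=5,2;AN=100",
    "chr1\t30\t.\tAT\tA\t.\tPASS\tAC=9;AN=100"), f2)
  got <- readSitesVcf(f2)
  expect_equal(length(got), 1L)
  expect_equal(got$ac, 5L)
})
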