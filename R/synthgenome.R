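#' Configure a synthetic genome bundle
#'
#' Describes a small synthetic genome made of evenly spaced simulated
#' regions of four kinds: `neutral` (drift only, unconserved), `constrained`
#' (purifying selection, conserved and partially exonic), `gof` (purifying
#' selection today but zero phylogenetic conservation: a planted
#' human-specific gain of function) and `lof` (neutral today but strongly
#' conserved: a planted loss of function). Alongside the SNPs the generator
#' emits every companion track the pipeline consumes: mappability,
#' repeats, ancestral-callable intervals, conservation, a functional
#' (exon-like) track, a strict accessibility mask and the truth labels.
#'
#' @param nNeutral,nConstrained,nGof,nLof region counts per kind.
#' @param regionLength region length in bp (a multiple of `cfg$L`).
#' @param spacing gap between regions in bp (no sites, mappability 0).
#' @param consCoverage conserved fraction within constrained regions.
#' @param lofConsCoverage conserved fraction within planted LOF regions.
#'   The default 0.24 mirrors the observation that loss-of-function
#'   candidates carry substantial but sub-training-threshold conservation:
#'   above the 15% candidate cutoff even after element boundaries extend
#'   into flanking space, yet below the >25% training-label rule, so
#'   planted LOF regions never enter the constrained training class.
#' @param funCoverage functional-track (exon/TFBS-like) fraction within
#'   constrained and GOF regions. Planted GOF regions are annotated
#'   functional because gained elements in real data carry regulatory
#'   annotations; the overlap keeps them out of the unconstrained training
#'   class.
#' @param sel [selectionConfig()] for constrained and GOF regions; the
#'   default fully selected block at 2Ns = 100 is the strong-signal preset.
#' @param cfg [simConfig()] for every region.
#' @param dem [DemographicModel-class]; default the single-deme
#'   out-of-Africa style preset at Q = 100.
#' @param outgroupMissingRate per-outgroup probability of a missing call.
#' @param outgroupErrorRate probability an outgroup shows the derived
#'   allele (creating polarization ambiguity/misorientation).
#' @param repeatFraction fraction of each region that is repeat-masked.
#' @param strictFailFraction fraction of each region failing the strict
#'   mask.
#' @param callableGapFraction fraction of each region without outgroup
#'   alignment (ancestral-uncallable).
#' @param genomeLength optional total length; errors if the regions do not
#'   fit.
#' @return A config list for [generateSyntheticGenome()].
#' @export
synthGenomeConfig <- function(nNeutral = 60, nConstrained = 60, nGof = 5,
                              nLof = 5, regionLength = 30000,
                              spacing = 20000, consCoverage = 0.5,
                              lofConsCoverage = 0.24, funCoverage = 0.2,
                              sel = selectionConfig(1.0, 100),
                              cfg = simConfig(mu = 3.8e-8),
                              dem = demographyPreset("tennessen-african"),
                              outgroupMissingRate = 0.05,
                              outgroupErrorRate = 0.01,
                              repeatFraction = 0.02,
                              strictFailFraction = 0.05,
                              callableGapFraction = 0.03,
                              genomeLength = NULL) {
  if (regionLength %% cfg$L != 0)
    stop("regionLength must be a multiple of the simulated window length")
  nRegions <- nNeutral + nConstrained + nGof + nLof
  need <- nRegions * (regionLength + spacing) + spacing
  if (!is.null(genomeLength) && need > genomeLength)
    stop("configured regions (", need, " bp) exceed the genome length (",
         genomeLength, " bp)")
  list(nNeutral = nNeutral, nConstrained = nConstrained, nGof = nGof,
       nLof = nLof, regionLength = regionLength, spacing = spacing,
       consCoverage = consCoverage, lofConsCoverage = lofConsCoverage,
       funCoverage = funCoverage, sel = sel,
       cfg = cfg, dem = dem, outgroupMissingRate = outgroupMissingRate,
       outgroupErrorRate = outgroupErrorRate,
       repeatFraction = repeatFraction,
       strictFailFraction = strictFailFraction,
       callableGapFraction = callableGapFraction,
       genomeLength = if (is.null(genomeLength)) need else genomeLength)
}

randBases <- function(k) sample(c("A", "C", "G", "T"), k, replace = TRUE)

#' Generate a synthetic genome bundle
#'
#' Simulates every region of the configuration with the forward simulator
#' (selection for constrained/GOF regions, drift for neutral/LOF regions),
#' converts the sampled variation into VCF-style SNP records with AC/AN
#' counts, synthesises outgroup calls from the known ancestral alleles
#' (with configurable missingness and error), and lays down all companion
#' tracks. Conservation covers constrained and LOF regions only, so planted
#' GOF regions have zero conservation by construction.
#'
#' @param config from [synthGenomeConfig()].
#' @param seed integer seed (required: bundles are reproducible artifacts).
#' @param outdir optional directory; when supplied, all tracks are written
#'   as plain-text files (VCF, TSV, BED, bedGraph, JSON layout).
#' @return A list bundle: `layout`, `snps`, `outgroups`, `mappability`,
#'   `repeats`, `ancestralCallable`, `conservation`, `functional` (list of
#'   tracks), `strictMask`, `truth`, `n`, and `paths` when written.
#' @export
generateSyntheticGenome <- function(config, seed, outdir = NULL) {
  set.seed(seed)
  counts <- c(neutral = config$nNeutral, constrained = config$nConstrained,
              gof = config$nGof, lof = config$nLof)
  kinds <- sample(rep(names(counts), counts))
  nReg <- length(kinds)
  RL <- config$regionLength
  SP <- config$spacing
  regionStart <- SP + (seq_len(nReg) - 1) * (RL + SP) + 1
  chrom <- "chrS1"
  layout <- genomeLayout(chrom, config$genomeLength)
  regions <- GRanges(chrom, IRanges(regionStart, width = RL),
                     seqinfo = layout)
  regions$kind <- kinds

  L <- config$cfg$L
  nSub <- RL %/% L
  n <- config$cfg$sampleN

  snpList <- list()
  mapExtra <- list()
  for (i in seq_len(nReg)) {
    selected <- kinds[i] %in% c("constrained", "gof")
    for (s in seq_len(nSub)) {
      sim <- simulateWindow(config$dem,
                            if (selected) config$sel
                            else selectionConfig(0, 0),
                            config$cfg)
      if (!length(sim$positions)) next
      pos <- regionStart[i] + (s - 1) * L + floor(sim$positions)
      keep <- !duplicated(pos)
      pos <- pos[keep]
      d <- sim$derivedCount[keep]
      ref <- randBases(length(pos))
      alt <- vapply(ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      gr <- GRanges(chrom, IRanges(pos, width = 1L), seqinfo = layout)
      gr$ref <- unname(ref)
      gr$alt <- unname(alt)
      gr$ac <- as.integer(d)
      gr$an <- rep(as.integer(n), length(pos))
      snpList[[length(snpList) + 1]] <- gr
    }
  }
  snps <- sort(do.call(c, snpList))

  # outgroup calls: ancestral (= REF here) with error and missingness
  drawOutgroup <- function() {
    base <- ifelse(runif(length(snps)) < config$outgroupErrorRate,
                   snps$alt, snps$ref)
    base[runif(length(snps)) < config$outgroupMissingRate] <- NA
    base
  }
  outgroups <- data.frame(chrom = as.character(seqnames(snps)),
                          pos = start(snps),
                          chimp = drawOutgroup(), macaque = drawOutgroup(),
                          stringsAsFactors = FALSE)

  cutPatch <- function(fraction, minBp = 100) {
    # one random patch of the given fraction inside each region
    w <- max(minBp, round(RL * fraction))
    off <- floor(runif(nReg) * (RL - w))
    GRanges(chrom, IRanges(regionStart + off, width = w), seqinfo = layout)
  }
  repeats <- cutPatch(config$repeatFraction)
  strictFail <- cutPatch(config$strictFailFraction)
  callableGap <- cutPatch(config$callableGapFraction)

  mappability <- granges(regions)
  mappability$score <- rep(1, nReg)
  ancestralCallable <- GenomicRanges::setdiff(granges(regions), callableGap,
                                              ignore.strand = TRUE)
  strictMask <- GenomicRanges::setdiff(
    GRanges(chrom, IRanges(1L, config$genomeLength), seqinfo = layout),
    strictFail, ignore.strand = TRUE)

  stripeTrack <- function(which, coverage, block = 300) {
    sel <- regions[regions$kind %in% which]
    if (!length(sel) || coverage <= 0) return(GRanges(seqinfo = layout))
    period <- round(block / coverage)
    do.call(c, lapply(seq_along(sel), function(i) {
      starts <- seq(start(sel)[i], end(sel)[i] - block + 1, by = period)
      GRanges(chrom, IRanges(starts, width = block), seqinfo = layout)
    }))
  }
  conservation <- sort(c(
    stripeTrack("constrained", config$consCoverage),
    stripeTrack("lof", config$lofConsCoverage)))
  functional <- list(exons = stripeTrack(c("constrained", "gof"),
                                         config$funCoverage, block = 500))

  truth <- granges(regions)
  truth$name <- kinds
  bundle <- list(layout = layout, snps = snps, outgroups = outgroups,
                 mappability = mappability, repeats = repeats,
                 ancestralCallable = ancestralCallable,
                 conservation = conservation, functional = functional,
                 strictMask = strictMask, truth = truth, n = n,
                 regions = regions)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)
    writeGenomeLayout(layout, p("genome.json"))
    writeSitesVcf(snps, p("sites.vcf"))
    fwrite(outgroups, p("outgroups.tsv"), sep = "\t", na = ".",
           quote = FALSE)
    writeBedGraph(mappability, p("mappability.bedGraph"))
    writeBed(repeats, p("repeats.bed"))
    writeBed(ancestralCallable, p("ancestral_callable.bed"))
    writeBed(conservation, p("conservation.bed"))
    writeBed(functional$exons, p("exons.bed"))
    writeBed(strictMask, p("strict_mask.bed"))
    writeBed(truth, p("truth.bed"))
    bundle$paths <- list(
      layout = p("genome.json"), vcf = p("sites.vcf"),
      outgroups = p("outgroups.tsv"),
      mappability = p("mappability.bedGraph"), repeats = p("repeats.bed"),
      ancestralCallable = p("ancestral_callable.bed"),
      conservation = p("conservation.bed"), exons = p("exons.bed"),
      strictMask = p("strict_mask.bed"), truth = p("truth.bed"))
  }
  bundle
}
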