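#' Polarize a SNP by outgroup parsimony
#'
#' Infers the ancestral allele of a biallelic SNP from chimpanzee and macaque
#' base calls. The rules are strict parsimony: if both outgroups carry a base
#' it must be the same base and match one of the two human alleles; if only
#' one outgroup carries a base it must match one of the human alleles; in
#' every other situation (disagreement between outgroups, a base matching
#' neither human allele, or no outgroup call at all) the ancestral state is
#' ambiguous and the site is uninformative.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param alleleA,alleleB the two (distinct) human alleles, "A"/"C"/"G"/"T".
#' @param chimp,macaque outgroup base calls, or `NA` for a missing call.
#' @return Character vector of inferred ancestral bases, `NA` where
#'   ambiguous.
#' @examples
#' polarizeSnp("A", "G", chimp = "A", macaque = "A")   # "A"
#' polarizeSnp("A", "G", chimp = "A", macaque = "G")   # NA (outgroups differ)
#' polarizeSnp("A", "G", chimp = "A", macaque = NA)    # "A"
#' @export
polarizeSnp <- function(alleleA, alleleB, chimp, macaque) {
  n <- max(length(alleleA), length(alleleB), length(chimp), length(macaque))
  alleleA <- rep_len(toupper(alleleA), n)
  alleleB <- rep_len(toupper(alleleB), n)
  chimp <- rep_len(toupper(as.character(chimp)), n)
  macaque <- rep_len(toupper(as.character(macaque)), n)
  checkBases(c(alleleA, alleleB), allowMissing = FALSE)
  checkBases(c(chimp, macaque), allowMissing = TRUE)
  if (any(alleleA == alleleB))
    stop("the two human alleles of a SNP must differ")

  anc <- rep(NA_character_, n)
  both <- !is.na(chimp) & !is.na(macaque)
  agree <- both & chimp == macaque & (chimp == alleleA | chimp == alleleB)
  anc[agree] <- chimp[agree]
  oneC <- !is.na(chimp) & is.na(macaque) &
    (chimp == alleleA | chimp == alleleB)
  anc[oneC] <- chimp[oneC]
  oneM <- is.na(chimp) & !is.na(macaque) &
    (macaque == alleleA | macaque == alleleB)
  anc[oneM] <- macaque[oneM]
  anc
}

#' Polarize a monomorphic site by outgroup parsimony
#'
#' Same parsimony logic as [polarizeSnp()] but without the requirement that
#' the inferred ancestral base equal the single human allele: both outgroups
#' present and equal yields that base (possibly revealing a fixed derived
#' human allele); a single present outgroup yields its base; outgroups that
#' disagree, or two missing calls, yield an ambiguous state.
#'
#' @param allele the sole human allele.
#' @inheritParams polarizeSnp
#' @return Character vector of ancestral bases, `NA` where ambiguous.
#' @examples
#' polarizeMonomorphic("A", chimp = "G", macaque = "G")  # "G" (fixed derived)
#' polarizeMonomorphic("A", chimp = "G", macaque = "C")  # NA
#' @export
polarizeMonomorphic <- function(allele, chimp, macaque) {
  n <- max(length(allele), length(chimp), length(macaque))
  allele <- rep_len(toupper(allele), n)
  chimp <- rep_len(toupper(as.character(chimp)), n)
  macaque <- rep_len(toupper(as.character(macaque)), n)
  checkBases(allele, allowMissing = FALSE)
  checkBases(c(chimp, macaque), allowMissing = TRUE)

  anc <- rep(NA_character_, n)
  both <- !is.na(chimp) & !is.na(macaque) & chimp == macaque
  anc[both] <- chimp[both]
  oneC <- !is.na(chimp) & is.na(macaque)
  anc[oneC] <- chimp[oneC]
  oneM <- is.na(chimp) & !is.na(macaque)
  anc[oneM] <- macaque[oneM]
  anc
}

checkBases <- function(x, allowMissing) {
  ok <- x %in% c("A", "C", "G", "T") | (allowMissing & is.na(x))
  if (!all(ok))
    stop("invalid base symbol(s): ",
         paste(unique(x[!ok]), collapse = ", "),
         if (allowMissing) " (use NA or '.' for a missing call)")
  invisible(TRUE)
}

#' Polarize SNP records against an outgroup table
#'
#' Joins VCF-derived SNP sites (see [readSitesVcf()]) with per-position
#' chimp/macaque calls, infers ancestral states by parsimony, and computes
#' the per-site derived allele count d: `ac` when the alternate allele is
#' derived, `an - ac` when the reference allele is derived. Sites whose
#' ancestral state is ambiguous are flagged uninformative. Sites where the
#' observed allele number differs from `n` are dropped with a logged count so
#' that the spectrum mixes only one sample size.
#'
#' @param snps a `GRanges` from [readSitesVcf()].
#' @param outgroups a `data.frame` from [readOutgroupsTsv()]; positions not
#'   listed are treated as having no outgroup call.
#' @param n number of sampled chromosomes expected (e.g. 2128 for 1064
#'   diploids). Defaults to the modal `an` in the data.
#' @return The input `GRanges` with `ancestral`, `derivedCount`, `n`,
#'   `informative` metadata columns added.
#' @export
polarizeSites <- function(snps, outgroups = NULL, n = NULL) {
  if (is.null(n)) {
    tab <- table(snps$an)
    n <- as.integer(names(tab)[which.max(tab)])
  }
  badAn <- snps$an != n
  if (any(badAn))
    pcLog("dropping ", sum(badAn), " site(s) with allele number != ", n)
  snps <- snps[!badAn]

  chimp <- rep(NA_character_, length(snps))
  mac <- rep(NA_character_, length(snps))
  if (!is.null(outgroups) && nrow(outgroups)) {
    key <- paste0(as.character(seqnames(snps)), ":", start(snps))
    okey <- paste0(outgroups$chrom, ":", outgroups$pos)
    idx <- match(key, okey)
    chimp[!is.na(idx)] <- outgroups$chimp[idx[!is.na(idx)]]
    mac[!is.na(idx)] <- outgroups$macaque[idx[!is.na(idx)]]
  }

  if (!is.null(snps$aa)) {
    anc <- ifelse(snps$aa %in% c("A", "C", "G", "T"), snps$aa, NA_character_)
    anc[!(anc == snps$ref | anc == snps$alt)] <- NA_character_
  } else {
    anc <- polarizeSnp(snps$ref, snps$alt, chimp, mac)
  }
  d <- ifelse(is.na(anc), NA_integer_,
              ifelse(anc == snps$ref, snps$ac, snps$an - snps$ac))
  snps$ancestral <- anc
  snps$derivedCount <- as.integer(d)
  snps$n <- rep(as.integer(n), length(snps))
  snps$informative <- !is.na(anc)
  snps
}

#' Build the informative-site mask
#'
#' A genomic position is informative when (i) its short-read mappability
#' score is exactly 1 (the site maps uniquely), (ii) it is not repeat-masked,
#' and (iii) its ancestral state is resolvable from the outgroups. The third
#' condition for monomorphic sites is supplied as an interval track of
#' ancestral-callable positions (for SNPs the per-record parsimony outcome is
#' applied separately). Positions not covered by the mappability track score
#' 0 and are uninformative.
#'
#' @param mappability a `GRanges` with a `score` column (bedGraph track of
#'   1/n mappability values).
#' @param repeats a `GRanges` of repeat-masked intervals.
#' @param ancestralCallable a `GRanges` of intervals where outgroup parsimony
#'   resolves monomorphic ancestral states; `NULL` means everywhere.
#' @param layout optional `Seqinfo` used to bound the mask.
#' @return A reduced `GRanges` mask of informative positions.
#' @export
buildInformativeMask <- function(mappability, repeats = NULL,
                                 ancestralCallable = NULL, layout = NULL) {
  if (is.null(mappability$score))
    stop("mappability track must have a 'score' column")
  mask <- reduce(granges(mappability[mappability$score == 1]),
                 min.gapwidth = 0L)
  if (!is.null(repeats) && length(repeats))
    mask <- GenomicRanges::setdiff(mask, reduce(granges(repeats)),
                                   ignore.strand = TRUE)
  if (!is.null(ancestralCallable))
    mask <- GenomicRanges::intersect(mask, reduce(granges(ancestralCallable)),
                                     ignore.strand = TRUE)
  if (!is.null(layout)) {
    mask <- attachLayout(mask, layout)
  }
  mask
}

#' Nucleotide diversity from derived allele counts
#'
#' Average pairwise per-site difference: pi = (1/L) * sum over sites of
#' 2 d (n - d) / (n (n - 1)), where d is the derived allele count, n the
#' number of sampled chromosomes and L the number of informative sites.
#' Identical to the mean pairwise difference between sampled haplotypes.
#'
#' @param derivedCounts integer vector of per-SNP derived allele counts.
#' @param n number of sampled chromosomes (>= 2).
#' @param L number of informative sites the SNPs were drawn from (>= 1).
#' @return Per-site nucleotide diversity.
#' @examples
#' nucleotideDiversity(1, n = 4, L = 1)  # 0.5
#' @export
nucleotideDiversity <- function(derivedCounts, n, L) {
  stopifnot(n >= 2)
  if (L < 1)
    stop("nucleotide diversity undefined for L = 0 informative sites")
  if (any(derivedCounts < 0 | derivedCounts > n))
    stop("derived counts must lie in [0, n]")
  sum(2 * derivedCounts * (n - derivedCounts)) / (n * (n - 1)) / L
}
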