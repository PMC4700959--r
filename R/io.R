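#' Read and write BED / bedGraph tracks
#'
#' Thin wrappers around [rtracklayer::import()] / [rtracklayer::export()]
#' that attach a genome layout when one is supplied. BED files are 0-based
#' half-open on disk and converted to 1-based closed `GRanges` on read (and
#' back on write), so round-trips are bit-exact in BED coordinates.
#'
#' @param path file path.
#' @param layout optional `Seqinfo` genome layout to attach.
#' @return A `GRanges`; bedGraph tracks carry their value in the `score`
#'   metadata column.
#' @export
readBed <- function(path, layout = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file '", path, "': ",
                                          conditionMessage(e)))
  attachLayout(gr, layout)
}

#' @param gr a `GRanges` to write.
#' @rdname readBed
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname readBed
#' @export
readBedGraph <- function(path, layout = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) stop("malformed bedGraph file '", path,
                                          "': ", conditionMessage(e)))
  attachLayout(gr, layout)
}

#' @rdname readBed
#' @export
writeBedGraph <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

attachLayout <- function(gr, layout) {
  if (!is.null(layout)) {
    bad <- base::setdiff(seqlevels(gr), seqnames(layout))
    if (length(bad))
      stop("track contains chromosomes absent from the layout: ",
           paste(bad, collapse = ", "))
    mc <- mcols(gr)
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                   seqinfo = layout)
    mcols(out) <- mc
    checkBounds(out)
    gr <- out
  }
  gr
}

#' Read biallelic SNP sites from a VCF
#'
#' Extracts biallelic single-nucleotide records together with derived-allele
#' bookkeeping inputs: REF, ALT and the alternate/total allele counts (AC/AN
#' INFO fields, or counted from genotype columns when INFO is absent).
#' Multiallelic records and indels are skipped with a logged count, as the
#' method operates on biallelic SNPs only. If the VCF carries an `AA`
#' ancestral-allele INFO key it is retained for pre-polarized workflows.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param layout optional `Seqinfo` genome layout.
#' @return A `GRanges` of width-1 sites with metadata columns `ref`, `alt`,
#'   `ac`, `an` and optionally `aa`.
#' @export
readSitesVcf <- function(path, layout = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  nalt <- lengths(altList)
  alt1 <- rep(NA_character_, length(vcf))
  alt1[nalt == 1] <- as.character(unlist(altList[nalt == 1]))
  keep <- nalt == 1 & nchar(ref) == 1 & !is.na(alt1) & nchar(alt1) == 1 &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  nskip <- sum(!keep)
  if (nskip > 0)
    pcLog("skipped ", nskip, " multiallelic/indel record(s) in ", path)

  info <- VariantAnnotation::info(vcf)
  ac <- an <- rep(NA_integer_, length(vcf))
  if (all(c("AC", "AN") %in% names(info))) {
    acRaw <- info$AC
    if (is.list(acRaw) || methods::is(acRaw, "List"))
      acRaw <- vapply(acRaw, function(v) if (length(v)) v[[1]] else NA_integer_,
                      numeric(1))
    ac <- as.integer(acRaw)
    an <- as.integer(info$AN)
  } else {
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt))
      stop("VCF has neither AC/AN INFO fields nor genotypes: ", path)
    splitAlleles <- function(g) strsplit(g, "[/|]")
    for (i in seq_len(nrow(gt))) {
      al <- unlist(splitAlleles(gt[i, ]))
      al <- al[al != "."]
      an[i] <- length(al)
      ac[i] <- sum(al == "1")
    }
  }

  out <- granges(rr)[keep]
  mcols(out) <- NULL
  out$ref <- ref[keep]
  out$alt <- alt1[keep]
  out$ac <- ac[keep]
  out$an <- an[keep]
  if ("AA" %in% names(info)) out$aa <- toupper(as.character(info$AA))[keep]
  names(out) <- NULL
  attachLayout(out, layout)
}

#' Write biallelic SNP sites as a VCF
#'
#' Emits a minimal VCF 4.x with AC/AN INFO fields, the on-disk complement of
#' [readSitesVcf()]. Used by the synthetic-genome generator.
#'
#' @param sites a `GRanges` with `ref`, `alt`, `ac`, `an` metadata columns.
#' @param path output path (".vcf").
#' @return `path`, invisibly.
#' @export
writeSitesVcf <- function(sites, path) {
  sites <- sort(sites)
  vcf <- VariantAnnotation::VCF(
    rowRanges = granges(sites),
    fixed = DataFrame(
      REF = Biostrings::DNAStringSet(sites$ref),
      ALT = methods::as(as.list(sites$alt), "DNAStringSetList"),
      QUAL = rep(NA_real_, length(sites)),
      FILTER = rep("PASS", length(sites))),
    info = DataFrame(AC = as.integer(sites$ac), AN = as.integer(sites$an)),
    collapsed = TRUE)
  hdr <- VariantAnnotation::header(vcf)
  VariantAnnotation::info(hdr) <- DataFrame(
    Number = c("1", "1"), Type = c("Integer", "Integer"),
    Description = c("Alternate (derived-candidate) allele count",
                    "Total number of called alleles"),
    row.names = c("AC", "AN"))
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  # guarantee the mandatory leading fileformat line
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##fileformat")]
  writeLines(c("##fileformat=VCFv4.2", lines), path)
  invisible(path)
}

#' Read per-SNP outgroup alleles
#'
#' Tab-separated file with a header row and columns `chrom`, `pos` (1-based),
#' `chimp`, `macaque`; a "." or empty entry denotes a missing base call.
#'
#' @param path TSV path.
#' @return A `data.frame` with columns `chrom`, `pos`, `chimp`, `macaque`
#'   (missing calls as `NA`).
#' @export
readOutgroupsTsv <- function(path) {
  x <- as.data.frame(fread(path, sep = "\t", header = TRUE,
                           na.strings = c(".", "")))
  need <- c("chrom", "pos", "chimp", "macaque")
  if (!all(need %in% names(x)))
    stop("outgroups TSV must have columns ", paste(need, collapse = ", "))
  x$chimp <- toupper(x$chimp)
  x$macaque <- toupper(x$macaque)
  x
}

#' Read four-way ape alignment columns
#'
#' Tab-separated file with header columns `chrom`, `pos` (1-based), `human`,
#' `chimp`, `gorilla`, `orangutan`; "." / "-" / empty denote a missing base
#' or alignment gap.
#'
#' @param path TSV path.
#' @return A `data.frame` of alignment columns (missing/gap as `NA`).
#' @export
readAlignmentColumnsTsv <- function(path) {
  x <- as.data.frame(fread(path, sep = "\t", header = TRUE,
                           na.strings = c(".", "-", "")))
  need <- c("chrom", "pos", "human", "chimp", "gorilla", "orangutan")
  if (!all(need %in% names(x)))
    stop("alignment TSV must have columns ", paste(need, collapse = ", "))
  for (cc in need[-(1:2)]) x[[cc]] <- toupper(x[[cc]])
  x
}

#' Read or write a polarized site table
#'
#' The TSV interchange format between the polarization and SFS steps:
#' columns `chrom`, `pos`, `ref`, `alt`, `ancestral`, `derived_count`, `n`,
#' `informative`.
#'
#' @param path TSV path.
#' @param layout optional `Seqinfo`.
#' @return `readSitesTable` returns a `GRanges` of width-1 sites.
#' @export
readSitesTable <- function(path, layout = NULL) {
  x <- as.data.frame(fread(path, sep = "\t", header = TRUE,
                           na.strings = c(".", "NA", "")))
  gr <- GRanges(x$chrom, IRanges(x$pos, width = 1L))
  gr$ref <- x$ref
  gr$alt <- x$alt
  gr$ancestral <- x$ancestral
  gr$derivedCount <- as.integer(x$derived_count)
  gr$n <- as.integer(x$n)
  gr$informative <- as.logical(x$informative)
  attachLayout(gr, layout)
}

#' @param sites polarized site `GRanges` (see [polarizeSites()]).
#' @rdname readSitesTable
#' @export
writeSitesTable <- function(sites, path) {
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   pos = start(sites),
                   ref = sites$ref, alt = sites$alt,
                   ancestral = ifelse(is.na(sites$ancestral), ".",
                                      sites$ancestral),
                   derived_count = sites$derivedCount,
                   n = sites$n,
                   informative = sites$informative)
  fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
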