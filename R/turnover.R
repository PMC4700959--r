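#' Call human-specific loss-of-function candidates
#'
#' A LOF candidate is a popUncons element (no current population-genetic
#' signal of constraint) composed of at least `minFraction` (default 15%)
#' phylogenetically conserved bases: conserved for most of vertebrate
#' evolution, but apparently unconstrained in present-day humans.
#'
#' @param popUncons popUncons element `GRanges` (strict-mask filtered).
#' @param conservation conservation track `GRanges` (phastCons-like).
#' @param minFraction minimum conserved fraction (inclusive >=).
#' @return Candidate `GRanges` with `conservationFraction` and `kind`
#'   metadata.
#' @export
callLof <- function(popUncons, conservation, minFraction = 0.15) {
  frac <- coverageFraction(popUncons, conservation)
  out <- popUncons[frac >= minFraction]
  out$conservationFraction <- frac[frac >= minFraction]
  out$kind <- rep("LOF", length(out))
  out
}

#' Call human-specific gain-of-function candidates
#'
#' A GOF candidate is a popCons element (strong population-genetic signal of
#' constraint) with less than `maxFraction` (default 1%) conserved bases,
#' and with at least one classified (informative) window starting within
#' `flank` bp of the element on EACH side. The flank requirement ensures the
#' target of selection lies within the candidate itself rather than in a
#' neighbouring functional region too poor in informative sites to be
#' classified. Elements lacking a possible flank (e.g. at a chromosome end)
#' are excluded and logged.
#'
#' @param popCons popCons element `GRanges` (strict-mask filtered).
#' @param conservation conservation track `GRanges`.
#' @param classifiedWindows `GRanges` of every window on which
#'   classification was performed.
#' @param maxFraction conserved-fraction ceiling (strict <).
#' @param flank flank distance in bp (default 100 kb).
#' @return Candidate `GRanges` with `conservationFraction`, `kind` and
#'   `flankOk` metadata.
#' @export
callGof <- function(popCons, conservation, classifiedWindows,
                    maxFraction = 0.01, flank = 100000) {
  frac <- coverageFraction(popCons, conservation)
  cand <- popCons[frac < maxFraction]
  fracC <- frac[frac < maxFraction]
  if (!length(cand)) {
    cand$conservationFraction <- numeric()
    cand$kind <- character()
    cand$flankOk <- logical()
    return(cand)
  }
  wchr <- as.character(seqnames(classifiedWindows))
  wstart <- start(classifiedWindows)
  flankOk <- vapply(seq_along(cand), function(i) {
    chr <- as.character(seqnames(cand)[i])
    s <- start(cand)[i]; e <- end(cand)[i]
    onChr <- wchr == chr
    up <- any(onChr & wstart >= s - flank & wstart < s)
    dn <- any(onChr & wstart > e & wstart <= e + flank)
    up && dn
  }, logical(1))
  if (any(!flankOk))
    pcLog("excluding ", sum(!flankOk),
          " low-conservation popCons element(s) without classified windows ",
          "within ", flank, " bp on both sides")
  out <- cand[flankOk]
  out$conservationFraction <- fracC[flankOk]
  out$kind <- rep("GOF", length(out))
  out$flankOk <- rep(TRUE, length(out))
  out
}

#' Count human-specific substitutions in a window
#'
#' Parsimony rule over four-way great-ape alignment columns: a position is a
#' human-specific change when chimpanzee, gorilla and orangutan all carry
#' the same observed base and the human base differs. Columns with a gap or
#' missing call in any ape are not counted, since the criterion requires
#' observed invariance in the three outgroups.
#'
#' @param columns `data.frame` from [readAlignmentColumnsTsv()].
#' @param window optional `GRanges` restricting the count; `NULL` counts all
#'   columns.
#' @return Integer count of human-specific substitutions.
#' @export
countHumanSpecificChanges <- function(columns, window = NULL) {
  if (!is.null(window)) {
    keep <- columns$chrom %in% as.character(seqnames(window)) &
      columns$pos >= min(start(window)) & columns$pos <= max(end(window))
    columns <- columns[keep, , drop = FALSE]
  }
  bases <- c("A", "C", "G", "T")
  ok <- columns$human %in% bases & columns$chimp %in% bases &
    columns$gorilla %in% bases & columns$orangutan %in% bases
  x <- columns[ok, , drop = FALSE]
  sum(x$chimp == x$gorilla & x$gorilla == x$orangutan & x$human != x$chimp)
}

#' Overlap-weighted mean recombination rate of elements
#'
#' The element rate is the sum over overlapping rate windows of the window
#' rate weighted by the fraction of the element the window overlaps. On a
#' genome-average-normalised track a value of 1 is the genome-wide average.
#'
#' @param elements element `GRanges`.
#' @param rateTrack `GRanges` of (typically 10 kb) windows with a `score`
#'   column of rates.
#' @return Numeric vector of rates; `NA` (with a warning) for elements with
#'   zero rate-track overlap.
#' @export
elementMeanRecombinationRate <- function(elements, rateTrack) {
  if (is.null(rateTrack$score)) stop("rate track must have a 'score' column")
  out <- rep(NA_real_, length(elements))
  hits <- findOverlaps(granges(elements), granges(rateTrack))
  if (length(hits)) {
    ov <- width(pintersect(granges(elements)[queryHits(hits)],
                           granges(rateTrack)[subjectHits(hits)]))
    contrib <- rateTrack$score[subjectHits(hits)] * ov /
      width(elements)[queryHits(hits)]
    agg <- tapply(contrib, queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  if (anyNA(out))
    warning(sum(is.na(out)),
            " element(s) have no rate-track overlap; rate undefined (NA)")
  out
}
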