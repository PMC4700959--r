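#' Interval algebra helpers
#'
#' `mergeIntervals` merges strictly overlapping intervals into maximal runs.
#' Abutting intervals (where one ends exactly where the next begins) are NOT
#' merged, matching the element-calling convention that only windows sharing
#' at least one base are combined. The result is sorted and pairwise disjoint
#' and covers exactly the same bases as the input.
#'
#' @param x a `GRanges`.
#' @return A sorted, disjoint `GRanges`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), c(10000, 10100)))
#' mergeIntervals(gr)
#' @export
mergeIntervals <- function(x) {
  checkBounds(x)
  reduce(sort(granges(x)), min.gapwidth = 0L)
}

# bounds-check a GRanges against its seqinfo (no-op for NA seqlengths)
checkBounds <- function(x) {
  sl <- seqlengths(x)
  if (!length(x) || all(is.na(sl))) return(invisible(TRUE))
  lens <- sl[as.character(seqnames(x))]
  bad <- !is.na(lens) & (start(x) < 1L | end(x) > lens)
  if (any(bad))
    stop("interval outside chromosome bounds: ",
         paste0(seqnames(x)[bad][1], ":", start(x)[bad][1], "-", end(x)[bad][1]))
  invisible(TRUE)
}

#' Fraction of each query interval covered by a track
#'
#' Used throughout for label rules and candidate calling (e.g. the fraction
#' of a window lying in phastCons conserved elements).
#'
#' @param query a `GRanges` of query intervals.
#' @param track a `GRanges` track; overlapping track intervals are merged
#'   before computing coverage.
#' @return Numeric vector in \[0, 1\], one value per query interval.
#' @examples
#' q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
#' tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2500))
#' coverageFraction(q, tr)  # 0.25
#' @export
coverageFraction <- function(query, track) {
  coveredBp(query, track) / width(query)
}

# per-query covered base pairs (track reduced first)
coveredBp <- function(query, track) {
  track <- reduce(granges(track), min.gapwidth = 0L)
  out <- numeric(length(query))
  hits <- findOverlaps(granges(query), track)
  if (length(hits)) {
    w <- width(pintersect(granges(query)[queryHits(hits)],
                          track[subjectHits(hits)]))
    agg <- tapply(w, queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Total base pairs shared by two interval sets
#'
#' Exact count of bases lying within both sets, the overlap statistic used by
#' the permutation enrichment test. Symmetric in its arguments.
#'
#' @param a,b `GRanges` interval sets (need not be disjoint).
#' @return A single numeric base-pair count.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' overlapBp(a, b)  # 50
#' @export
overlapBp <- function(a, b) {
  a <- reduce(granges(a), min.gapwidth = 0L)
  b <- reduce(granges(b), min.gapwidth = 0L)
  sum(as.numeric(width(GenomicRanges::intersect(a, b, ignore.strand = TRUE))))
}
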