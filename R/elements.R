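#' Call popCons and popUncons elements from classified windows
#'
#' Windows assigned to a class with posterior probability strictly greater
#' than `cutoff` (default 0.95) are merged, per class, into maximal runs of
#' strictly overlapping windows. Constrained runs become popCons elements
#' and unconstrained runs popUncons elements. Because classification is
#' performed on overlapping windows the two element sets may overlap each
#' other, but same-class elements are pairwise disjoint.
#'
#' @param windows `GRanges` of classified windows with metadata columns
#'   `label` and `posteriorConstrained` (as produced by binding
#'   [predictWindows()] output onto the window ranges).
#' @param cutoff posterior probability cutoff (strict >).
#' @return A list with `popCons` and `popUncons` element `GRanges`, each
#'   annotated with `nWindows`, `minPosterior`, `maxPosterior` (posterior of
#'   the element's own class) and `elementClass`.
#' @export
callElements <- function(windows, cutoff = 0.95) {
  stopifnot(all(c("label", "posteriorConstrained") %in%
                names(mcols(windows))))
  post <- windows$posteriorConstrained
  callOne <- function(cls) {
    p <- if (cls == "constrained") post else 1 - post
    keep <- windows$label == cls & p > cutoff
    sel <- windows[keep]
    if (!length(sel)) {
      out <- GRanges(seqinfo = seqinfo(windows))
      mcols(out) <- DataFrame(nWindows = integer(), minPosterior = numeric(),
                              maxPosterior = numeric(),
                              elementClass = character())
      return(out)
    }
    el <- reduce(sort(granges(sel)), min.gapwidth = 0L)
    hits <- findOverlaps(el, sel)
    pw <- p[keep][subjectHits(hits)]
    el$nWindows <- as.integer(countOverlaps(el, sel))
    el$minPosterior <- as.numeric(tapply(pw, queryHits(hits), min))
    el$maxPosterior <- as.numeric(tapply(pw, queryHits(hits), max))
    el$elementClass <- if (cls == "constrained") "popCons" else "popUncons"
    el
  }
  list(popCons = callOne("constrained"), popUncons = callOne("unconstrained"))
}

#' Remove elements failing the strict accessibility mask
#'
#' Retains an element only when strictly more than `minPass` (default 80%)
#' of its informative sites pass the strict accessibility mask, i.e. drops
#' elements with >= 20% of informative sites masked. Elements with zero
#' informative sites are removed (and logged).
#'
#' @param elements element `GRanges` (from [callElements()]).
#' @param informativeMask informative-site mask `GRanges` (see
#'   [buildInformativeMask()]).
#' @param strictMask `GRanges` of intervals PASSING the strict filters.
#' @param minPass retention threshold on the passing fraction (strict >).
#' @return The retained elements.
#' @export
strictMaskFilter <- function(elements, informativeMask, strictMask,
                             minPass = 0.8) {
  if (!length(elements)) return(elements)
  inf <- coveredBp(elements, informativeMask)
  passMask <- GenomicRanges::intersect(reduce(granges(informativeMask)),
                                       reduce(granges(strictMask)),
                                       ignore.strand = TRUE)
  pass <- coveredBp(elements, passMask)
  empty <- inf == 0
  if (any(empty))
    pcLog("removing ", sum(empty), " element(s) with zero informative sites")
  keep <- !empty & (pass / pmax(inf, 1)) > minPass
  elements[keep]
}

#' Write elements as BED6
#'
#' The BED score column carries the minimum constituent-window posterior
#' scaled to 0-1000; the name column the element class.
#'
#' @param elements element `GRanges`.
#' @param path output BED path.
#' @export
writeElementsBed <- function(elements, path) {
  gr <- granges(elements)
  gr$name <- if (length(elements)) elements$elementClass else character()
  gr$score <- if (length(elements))
    round(1000 * elements$minPosterior) else numeric()
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
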