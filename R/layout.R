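#' Construct a genome layout
#'
#' A genome layout records the chromosome names and lengths against which all
#' interval operations are bounds-checked. It is represented as a
#' [GenomeInfoDb::Seqinfo] object, the standard Bioconductor container for
#' this information.
#'
#' @param chromNames character vector of unique chromosome identifiers.
#' @param chromLengths integer vector of chromosome lengths in bp (> 0).
#' @return A `Seqinfo` object.
#' @examples
#' genomeLayout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genomeLayout <- function(chromNames, chromLengths) {
  if (anyDuplicated(chromNames))
    stop("chromosome names must be unique")
  if (any(chromLengths <= 0))
    stop("chromosome lengths must be > 0")
  Seqinfo(seqnames = as.character(chromNames),
          seqlengths = as.integer(chromLengths))
}

#' Read or write a genome layout as JSON
#'
#' The on-disk form is a JSON object with `chrom_names` and `chrom_lengths`
#' arrays.
#'
#' @param path file path.
#' @return `readGenomeLayout` returns a `Seqinfo`; `writeGenomeLayout`
#'   returns `path` invisibly.
#' @export
readGenomeLayout <- function(path) {
  x <- fromJSON(path)
  genomeLayout(x$chrom_names, x$chrom_lengths)
}

#' @param layout a `Seqinfo` genome layout.
#' @rdname readGenomeLayout
#' @export
writeGenomeLayout <- function(layout, path) {
  write_json(list(chrom_names = seqnames(layout),
                  chrom_lengths = unname(seqlengths(layout))),
             path, auto_unbox = FALSE)
  invisible(path)
}

#' Sliding windows over a genome layout
#'
#' Generates the overlapping fixed-size windows on which classification is
#' performed (default 10 kb windows with a 100 bp step). Windows start at
#' offsets 0, step, 2*step, ... on every chromosome; a final partial window
#' shorter than `size` is dropped.
#'
#' @param layout a `Seqinfo` genome layout.
#' @param size window size in bp.
#' @param step step size in bp.
#' @return A `GRanges` of windows carrying the layout as its `seqinfo`.
#' @examples
#' makeSlidingWindows(genomeLayout("chr1", 10200), size = 10000, step = 100)
#' @export
makeSlidingWindows <- function(layout, size = 10000L, step = 100L) {
  stopifnot(size > 0, step > 0)
  chroms <- seqnames(layout)
  lens <- seqlengths(layout)
  grl <- lapply(seq_along(chroms), function(i) {
    if (lens[i] < size) return(NULL)
    starts <- seq.int(1L, lens[i] - size + 1L, by = step)
    GRanges(chroms[i], IRanges(starts, width = size), seqinfo = layout)
  })
  grl <- grl[!vapply(grl, is.null, logical(1))]
  if (!length(grl)) return(GRanges(seqinfo = layout))
  do.call(c, grl)
}
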