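#' Constrained permutation of element coordinates
#'
#' Places the elements one at a time, largest first, each uniformly at
#' random among the currently feasible start positions: starts where the
#' element fits entirely inside the allowed space and does not touch any
#' previously placed element. Feasible starts are enumerated by interval
#' arithmetic, so placement terminates whenever a feasible position exists.
#' When a strict accessibility mask is supplied, a placement is additionally
#' required to have at least `strictPassMin` of its bases passing; failing
#' placements are redrawn up to `maxAttempts` times.
#'
#' The permuted set preserves the multiset of element lengths and is
#' pairwise disjoint. Runs out of room with an explicit error naming the
#' element length that could not be placed.
#'
#' @param elements element `GRanges` to permute.
#' @param layout `Seqinfo` genome layout.
#' @param allowedSpace optional `GRanges`; permuted elements must lie
#'   entirely within it (e.g. the union of classified windows for popCons
#'   permutations). `NULL` allows the whole genome — the relaxation used for
#'   popUncons permutations, whose total length typically exceeds the
#'   classified fraction of the genome and cannot satisfy the containment
#'   constraint.
#' @param strictMask optional `GRanges` of strict-pass intervals.
#' @param strictPassMin minimum passing fraction (default 0.8).
#' @param maxAttempts redraws allowed per element for the strict-mask check.
#' @param seed optional seed; the global RNG state is restored.
#' @return A `GRanges` of permuted elements (sorted), one per input element.
#' @export
permuteElementSet <- function(elements, layout, allowedSpace = NULL,
                              strictMask = NULL, strictPassMin = 0.8,
                              maxAttempts = 100, seed = NULL) {
  free <- .freeSpace(layout, allowedSpace)
  maskIdx <- if (!is.null(strictMask)) .prefixTrack(strictMask)
  withSeed(seed, {
    df <- .placeAll(width(elements), free, maskIdx, strictPassMin,
                    maxAttempts)
  })
  sort(GRanges(df$chrom, IRanges(df$start, width = df$len),
               seqinfo = layout))
}

# free space as a plain data.frame of disjoint intervals
.freeSpace <- function(layout, allowedSpace) {
  if (is.null(allowedSpace)) {
    data.frame(chrom = as.character(seqnames(layout)), start = 1,
               end = as.numeric(unname(seqlengths(layout))),
               stringsAsFactors = FALSE)
  } else {
    g <- reduce(sort(granges(allowedSpace)), min.gapwidth = 0L)
    data.frame(chrom = as.character(seqnames(g)), start = start(g),
               end = end(g), stringsAsFactors = FALSE)
  }
}

# per-chromosome sorted intervals with cumulative widths, for O(log n)
# covered-bp range queries
.prefixTrack <- function(gr) {
  g <- reduce(sort(granges(gr)), min.gapwidth = 0L)
  sp <- split(data.frame(s = start(g), e = end(g)),
              as.character(seqnames(g)))
  lapply(sp, function(d) {
    d <- d[order(d$s), ]
    list(s = d$s, e = d$e, cum = cumsum(d$e - d$s + 1))
  })
}

.coveredInRange <- function(idx, chrom, s, e) {
  tr <- idx[[chrom]]
  if (is.null(tr)) return(0)
  i1 <- findInterval(s - 1, tr$e) + 1  # first interval ending >= s
  i2 <- findInterval(e, tr$s)          # last interval starting <= e
  if (i2 < i1) return(0)
  tot <- tr$cum[i2] - if (i1 > 1) tr$cum[i1 - 1] else 0
  tot - max(0, s - tr$s[i1]) - max(0, tr$e[i2] - e)
}

.placeAll <- function(lens, free, maskIdx, strictPassMin, maxAttempts) {
  fc <- free$chrom
  fs <- free$start
  fe <- free$end
  n <- length(lens)
  ord <- order(lens, decreasing = TRUE)
  oc <- character(n); os <- numeric(n); ol <- numeric(n)
  for (k in ord) {
    L <- lens[k]
    ok <- FALSE
    for (att in seq_len(max(1, maxAttempts))) {
      slots <- fe - fs + 1 - L + 1
      slots[slots < 0] <- 0
      cum <- cumsum(slots)
      tot <- cum[length(cum)]
      if (is.na(tot) || tot <= 0)
        stop("no feasible placement for an element of length ", L)
      u <- ceiling(runif(1) * tot)
      j <- findInterval(u - 0.5, cum) + 1
      s <- fs[j] + (u - c(0, cum)[j]) - 1
      e <- s + L - 1
      if (is.null(maskIdx) ||
          .coveredInRange(maskIdx, fc[j], s, e) / L >= strictPassMin) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("strict-mask constraint unsatisfiable after ", maxAttempts,
           " attempts for an element of length ", L)
    oc[k] <- fc[j]; os[k] <- s; ol[k] <- L
    # carve the placement out of the free interval
    if (s > fs[j] && e < fe[j]) {
      fc <- c(fc, fc[j]); fs <- c(fs, e + 1); fe <- c(fe, fe[j])
      fe[j] <- s - 1
    } else if (s > fs[j]) {
      fe[j] <- s - 1
    } else if (e < fe[j]) {
      fs[j] <- e + 1
    } else {
      fc <- fc[-j]; fs <- fs[-j]; fe <- fe[-j]
    }
  }
  list(chrom = oc, start = os, len = ol)
}

#' Permutation test of element overlap with a feature track
#'
#' Counts the base pairs shared by the elements and the feature track, then
#' compares against `nPerm` constrained permutations of the element
#' coordinates. The enrichment p-value is the fraction of permuted sets with
#' overlap greater than or equal to the observed count; the depletion
#' p-value uses less than or equal. A zero exceedance count is reported as
#' "< 1/nPerm" in the label fields; the raw counts are also returned so a
#' (k+1)/(N+1) estimator can be applied downstream.
#'
#' @inheritParams permuteElementSet
#' @param features feature track `GRanges`.
#' @param nPerm number of permutations (default 1000).
#' @return List with `observedBp`, `permutedBp`, `pEnrich`, `pDeplete`,
#'   `nGreaterEqual`, `nLessEqual`, `nPermutations` and display labels.
#' @export
enrichmentTest <- function(elements, features, layout, allowedSpace = NULL,
                           strictMask = NULL, strictPassMin = 0.8,
                           maxAttempts = 100, nPerm = 1000, seed = NULL) {
  observed <- overlapBp(elements, features)
  free <- .freeSpace(layout, allowedSpace)
  maskIdx <- if (!is.null(strictMask)) .prefixTrack(strictMask)
  featIdx <- .prefixTrack(features)
  lens <- width(elements)
  permuted <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    df <- .placeAll(lens, free, maskIdx, strictPassMin, maxAttempts)
    sum(vapply(seq_along(df$start), function(r)
      .coveredInRange(featIdx, df$chrom[r], df$start[r],
                      df$start[r] + df$len[r] - 1), numeric(1)))
  }, numeric(1)))
  nGE <- sum(permuted >= observed)
  nLE <- sum(permuted <= observed)
  list(observedBp = observed, permutedBp = permuted,
       pEnrich = nGE / nPerm, pDeplete = nLE / nPerm,
       nGreaterEqual = nGE, nLessEqual = nLE, nPermutations = nPerm,
       pEnrichLabel = if (nGE == 0) paste0("< ", signif(1 / nPerm, 3))
                      else as.character(nGE / nPerm),
       pDepleteLabel = if (nLE == 0) paste0("< ", signif(1 / nPerm, 3))
                       else as.character(nLE / nPerm))
}

#' Derive permuted GOF/LOF candidate sets
#'
#' Applies the candidate conservation rule to each permuted element set
#' (GOF: < 1% conserved bases; LOF: > 15%), then samples without replacement
#' down to the true candidate-set size so permuted and observed sets are
#' comparable.
#'
#' @param permutedSets list of permuted element `GRanges`.
#' @param conservation conservation track `GRanges`.
#' @param kind "GOF" or "LOF".
#' @param targetSize size of the true candidate set.
#' @param gofMax,lofMin conservation cutoffs.
#' @param seed optional seed.
#' @return List of permuted candidate `GRanges`, each of `targetSize`.
#' @export
derivePermutedCandidateSets <- function(permutedSets, conservation, kind,
                                        targetSize, gofMax = 0.01,
                                        lofMin = 0.15, seed = NULL) {
  kind <- match.arg(kind, c("GOF", "LOF"))
  withSeed(seed, lapply(permutedSets, function(pe) {
    frac <- coverageFraction(pe, conservation)
    keep <- if (kind == "GOF") frac < gofMax else frac > lofMin
    filt <- pe[keep]
    if (length(filt) < targetSize)
      stop("permuted ", kind, " set (", length(filt),
           " elements) smaller than the target size ", targetSize)
    sort(filt[sample(length(filt), targetSize)])
  }))
}

#' Filter a feature set by the complementary conservation rule
#'
#' Before testing GOF candidates for enrichment, features composed of >= 1%
#' conserved bases are removed (retain < 1%); before testing LOF candidates,
#' features composed of <= 15% conserved bases are removed (retain > 15%).
#'
#' @param features feature `GRanges`.
#' @param conservation conservation track `GRanges`.
#' @param kind "GOF" or "LOF".
#' @param gofMax,lofMin conservation cutoffs.
#' @return The retained features.
#' @export
filterFeatureSetByConservation <- function(features, conservation, kind,
                                           gofMax = 0.01, lofMin = 0.15) {
  kind <- match.arg(kind, c("GOF", "LOF"))
  frac <- coverageFraction(features, conservation)
  if (kind == "GOF") features[frac < gofMax] else features[frac > lofMin]
}
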