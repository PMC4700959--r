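#' ConstraintFeatures: windowed modified site frequency spectra
#'
#' Container for the per-window feature vectors used for classification. For
#' a sample of n chromosomes the unbinned modified SFS of a window is
#' xi = \[xi_0 ... xi_(n-1)\], where xi_i (i >= 1) is the fraction of
#' informative sites carrying a derived allele on i chromosomes and xi_0 the
#' fraction that is ancestral-monomorphic or fixed derived (d = 0 or d = n;
#' fixed derived alleles fold into xi_0 so classification uses polymorphism
#' only). Rows sum to 1 whenever the window has at least one informative
#' site. `bins` records the current feature dimension (equal to `sampleSize`
#' before binning).
#'
#' @slot windows `GRanges` of the feature windows (one row per window).
#' @slot values numeric matrix, one row per window, `bins` columns.
#' @slot sampleSize integer, number of sampled chromosomes n.
#' @slot bins integer, current number of feature bins B.
#' @slot nInformative numeric vector of informative-site counts per window.
#' @slot informativeFraction numeric vector, informative sites / window
#'   length.
#' @exportClass ConstraintFeatures
setClass("ConstraintFeatures",
  representation(windows = "GRanges", values = "matrix",
                 sampleSize = "integer", bins = "integer",
                 nInformative = "numeric", informativeFraction = "numeric"),
  validity = function(object) {
    msg <- NULL
    nw <- length(object@windows)
    if (nrow(object@values) != nw)
      msg <- c(msg, "values must have one row per window")
    if (ncol(object@values) != object@bins)
      msg <- c(msg, "values must have 'bins' columns")
    if (length(object@nInformative) != nw ||
        length(object@informativeFraction) != nw)
      msg <- c(msg, "per-window vectors must match the number of windows")
    if (object@bins > object@sampleSize)
      msg <- c(msg, "bins cannot exceed the sample size")
    usable <- object@nInformative >= 1
    if (any(usable)) {
      rs <- rowSums(object@values[usable, , drop = FALSE])
      if (any(abs(rs - 1) > 1e-9))
        msg <- c(msg, "xi rows must sum to 1 for usable windows")
    }
    if (any(object@values < -1e-12))
      msg <- c(msg, "xi values must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn ConstraintFeatures-class number of windows.
#' @param x,object a `ConstraintFeatures`.
#' @export
setMethod("length", "ConstraintFeatures", function(x) length(x@windows))

#' @describeIn ConstraintFeatures-class the feature windows as `GRanges`
#'   (with any labels in `mcols`).
#' @export
setGeneric("featureWindows", function(x) standardGeneric("featureWindows"))
#' @rdname ConstraintFeatures-class
#' @export
setMethod("featureWindows", "ConstraintFeatures", function(x) x@windows)

#' @describeIn ConstraintFeatures-class the feature matrix (windows x bins).
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname ConstraintFeatures-class
#' @export
setMethod("featureMatrix", "ConstraintFeatures", function(x) x@values)

#' @describeIn ConstraintFeatures-class sample size n (chromosomes).
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))
#' @rdname ConstraintFeatures-class
#' @export
setMethod("sampleSize", "ConstraintFeatures", function(x) x@sampleSize)

#' @describeIn ConstraintFeatures-class current bin count B.
#' @export
setGeneric("featureBins", function(x) standardGeneric("featureBins"))
#' @rdname ConstraintFeatures-class
#' @export
setMethod("featureBins", "ConstraintFeatures", function(x) x@bins)

#' @describeIn ConstraintFeatures-class informative sites per window.
#' @export
setGeneric("nInformative", function(x) standardGeneric("nInformative"))
#' @rdname ConstraintFeatures-class
#' @export
setMethod("nInformative", "ConstraintFeatures", function(x) x@nInformative)

#' @describeIn ConstraintFeatures-class informative fraction per window.
#' @export
setGeneric("informativeFraction",
           function(x) standardGeneric("informativeFraction"))
#' @rdname ConstraintFeatures-class
#' @export
setMethod("informativeFraction", "ConstraintFeatures",
          function(x) x@informativeFraction)

setMethod("show", "ConstraintFeatures", function(object) {
  cat("ConstraintFeatures with", length(object), "window(s)\n",
      " sample size n =", object@sampleSize,
      "| bins =", object@bins, "\n",
      " median informative fraction =",
      signif(stats::median(object@informativeFraction), 3), "\n")
})

#' @describeIn ConstraintFeatures-class subset windows.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ConstraintFeatures", function(x, i, j, ..., drop = FALSE) {
  new("ConstraintFeatures", windows = x@windows[i],
      values = x@values[i, , drop = FALSE], sampleSize = x@sampleSize,
      bins = x@bins, nInformative = x@nInformative[i],
      informativeFraction = x@informativeFraction[i])
})

#' Compute the modified SFS of windows from polarized sites
#'
#' For each window, xi_i (1 <= i <= n-1) is the number of informative SNPs
#' with derived count i divided by the number of informative sites in the
#' window; everything else (ancestral-monomorphic and fixed-derived sites)
#' falls into xi_0. The informative-site count of a window is the base-pair
#' overlap with the informative mask, minus SNPs inside the mask whose
#' ancestral state could not be resolved (those sites are uninformative and
#' contribute nothing).
#'
#' @param windows `GRanges` of windows (see [makeSlidingWindows()]).
#' @param sites polarized SNP `GRanges` from [polarizeSites()].
#' @param mask informative-site mask from [buildInformativeMask()].
#' @param n sample chromosomes; defaults to the sites' `n`.
#' @return A [ConstraintFeatures-class] with `bins = n` (unbinned). Windows
#'   with zero informative sites have all-zero rows and
#'   `nInformative == 0` (flagged unusable; see [filterWindows()]).
#' @export
computeModifiedSFS <- function(windows, sites, mask, n = NULL) {
  if (is.null(n)) n <- sites$n[1]
  n <- as.integer(n)
  stopifnot(n >= 2)
  nw <- length(windows)

  nInf <- coveredBp(windows, mask)
  inMask <- countOverlaps(sites, mask) > 0
  ambig <- sites[inMask & !sites$informative]
  if (length(ambig))
    nInf <- nInf - countOverlaps(windows, ambig)

  snp <- sites[inMask & sites$informative]
  xi <- matrix(0, nrow = nw, ncol = n)
  hits <- findOverlaps(windows, snp)
  if (length(hits)) {
    d <- snp$derivedCount[subjectHits(hits)]
    w <- queryHits(hits)
    seg <- d >= 1L & d <= n - 1L
    if (any(seg)) {
      tab <- table(factor(w[seg], levels = seq_len(nw)),
                   factor(d[seg], levels = seq_len(n - 1L)))
      xi[, 2:n] <- as.matrix(tab)
    }
  }
  usable <- nInf >= 1
  xi[usable, ] <- xi[usable, , drop = FALSE] / nInf[usable]
  xi[usable, 1] <- pmax(0, 1 - rowSums(xi[usable, -1, drop = FALSE]))
  xi[!usable, ] <- 0

  new("ConstraintFeatures", windows = granges(windows), values = xi,
      sampleSize = n, bins = n, nInformative = as.numeric(nInf),
      informativeFraction = as.numeric(nInf) / width(windows))
}

#' Build features directly from simulated derived counts
#'
#' Simulated windows have every site informative, so the modified SFS is
#' simply the tabulated derived counts over the window length.
#'
#' @param derivedCounts integer vector of per-SNP derived counts (0..n).
#' @param n sampled chromosomes.
#' @param L window length (= informative sites).
#' @param window optional `GRanges` row describing the window.
#' @return A one-window [ConstraintFeatures-class].
#' @export
sfsFromCounts <- function(derivedCounts, n, L,
                          window = GRanges("sim", IRanges(1, L))) {
  n <- as.integer(n)
  xi <- numeric(n)
  seg <- derivedCounts[derivedCounts >= 1 & derivedCounts <= n - 1]
  if (length(seg)) {
    tb <- table(factor(seg, levels = seq_len(n - 1L)))
    xi[2:n] <- as.numeric(tb) / L
  }
  xi[1] <- 1 - sum(xi[-1])
  new("ConstraintFeatures", windows = window,
      values = matrix(xi, nrow = 1), sampleSize = n, bins = n,
      nInformative = as.numeric(L), informativeFraction = 1)
}

#' Bin the modified SFS into B features
#'
#' Groups the n frequency classes into B equal-width index bins: class i
#' (0-based) maps to bin floor(i * B / n). Mass is conserved exactly; xi_0
#' shares its bin with the lowest frequency classes. `B = n` is the identity
#' mapping.
#'
#' @param x a [ConstraintFeatures-class] (unbinned, i.e. `bins == n`).
#' @param B target bin count, 1 <= B <= n.
#' @return A [ConstraintFeatures-class] with `bins = B`.
#' @export
binSFS <- function(x, B) {
  B <- as.integer(B)
  n <- x@bins
  if (B > n) stop("cannot bin ", n, " classes into ", B, " bins")
  if (B < 1) stop("B must be >= 1")
  if (B == n) return(x)
  idx <- floor((seq_len(n) - 1) * B / n)  # 0-based bin per class
  agg <- t(rowsum(t(x@values), group = idx))
  colnames(agg) <- NULL
  methods::initialize(x, values = agg, bins = B)
}

#' Drop windows with too few informative sites
#'
#' Windows comprised of at most `minInformativeFraction` informative sites
#' (default 25% of the window length) are removed; only strictly greater
#' fractions are retained. The remaining windows are the "informative
#' windows" on which training and classification operate.
#'
#' @param x a [ConstraintFeatures-class].
#' @param minInformativeFraction retention threshold (strict >).
#' @return The filtered [ConstraintFeatures-class].
#' @export
filterWindows <- function(x, minInformativeFraction = 0.25) {
  x[x@informativeFraction > minInformativeFraction]
}

#' Write a feature table as TSV
#'
#' Columns: chrom, start (1-based), end, n_informative,
#' informative_fraction, then one column per feature bin (`xi0`, `xi1`, ...).
#'
#' @param x a [ConstraintFeatures-class].
#' @param path output TSV path.
#' @export
writeFeaturesTsv <- function(x, path) {
  vals <- x@values
  colnames(vals) <- paste0("xi", seq_len(ncol(vals)) - 1)
  df <- data.frame(chrom = as.character(seqnames(x@windows)),
                   start = start(x@windows), end = end(x@windows),
                   n_informative = x@nInformative,
                   informative_fraction = x@informativeFraction)
  extra <- mcols(x@windows)
  if (ncol(extra)) df <- cbind(df, as.data.frame(extra))
  fwrite(cbind(df, as.data.frame(vals)), path, sep = "\t", quote = FALSE)
  invisible(path)
}
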