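# Central S4 data containers. Coordinates are 1-based closed throughout;
# BED/bedGraph inputs are converted on read (see readPeaks/readBedgraph).

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' TadPartition: ordered non-overlapping domains on one chromosome
#'
#' A partition of (part of) a chromosome into ordered, non-overlapping,
#' bin-aligned topologically associating domains (TADs). Coordinates are
#' 1-based closed, the convention used when caller outputs are exported as
#' three-column text (e.g. `chr1 1 10000` is the first 10-kb bin).
#' Uncovered stretches between domains are inter-TAD gaps; [gapsOf()]
#' materialises them and concordance analyses treat them as clusters.
#'
#' @slot chrom single chromosome name.
#' @slot domains an [IRanges::IRanges] of domain intervals, sorted,
#'   disjoint, with `start - 1` and `end` multiples of `binSize`.
#' @slot binSize bin size in bp of the contact matrix the domains were
#'   called on.
#' @slot chromLength chromosome length in bp, or `NA` when unknown (gap
#'   computation then stops at the last domain end).
#' @slot label free-text identifier (caller name, condition).
#'
#' @seealso [TadPartition()] constructor, [readPartition()],
#'   [boundariesOf()], [gapsOf()]
#' @aliases TadPartition-class
#' @exportClass TadPartition
setClass("TadPartition",
  slots = c(chrom = "character", domains = "IRanges", binSize = "numeric",
            chromLength = "numeric", label = "character"),
  prototype = prototype(chrom = "chr", domains = IRanges::IRanges(),
                        binSize = 1, chromLength = NA_real_, label = ""))

.checkAlignment <- function(s, e, B) {
  bad <- which((s - 1) %% B != 0 | e %% B != 0)
  if (!length(bad)) return(character())
  i <- bad[1L]
  sprintf(
    "domain %d (%.0f-%.0f) is not aligned to %.0f-bp bins (nearest aligned: %.0f-%.0f)",
    i, s[i], e[i], B, round((s[i] - 1) / B) * B + 1, max(B, round(e[i] / B) * B))
}

.validIntervalSlots <- function(chrom, d, B, chromLength = NA_real_,
                                requireDisjoint = TRUE) {
  msg <- character()
  if (length(chrom) != 1L || is.na(chrom) || !nzchar(chrom))
    msg <- c(msg, "'chrom' must be a single non-empty string")
  if (length(B) != 1L || is.na(B) || B < 1 || B != floor(B))
    msg <- c(msg, "'binSize' must be a single positive integer")
  if (length(d)) {
    s <- IRanges::start(d); e <- IRanges::end(d)
    if (any(s > e)) msg <- c(msg, "each domain must have start <= end")
    if (is.unsorted(s)) msg <- c(msg, "domains must be sorted by start")
    if (requireDisjoint && length(d) > 1L) {
      ov <- which(s[-1L] <= e[-length(e)])
      if (length(ov))
        msg <- c(msg, sprintf("domains overlap (rows %s)",
                              paste(ov, "and", ov + 1L, collapse = "; ")))
    }
    if (length(msg) == 0L) msg <- c(msg, .checkAlignment(s, e, B))
    if (any(s < 1)) msg <- c(msg, "coordinates must be >= 1")
    if (!is.na(chromLength) && any(e > chromLength))
      msg <- c(msg, "domain end exceeds chromLength")
  }
  msg
}

setValidity("TadPartition", function(object) {
  msg <- .validIntervalSlots(object@chrom, object@domains, object@binSize,
                             object@chromLength, requireDisjoint = TRUE)
  if (length(msg)) msg else TRUE
})

#' Construct a TadPartition
#'
#' @param chrom chromosome name.
#' @param starts,ends 1-based closed domain coordinates (bp), bin-aligned.
#' @param binSize bin size in bp.
#' @param chromLength optional chromosome length in bp.
#' @param label free-text identifier.
#' @return a validated [TadPartition-class] object.
#' @examples
#' TadPartition("chr1", c(1, 10001), c(10000, 20000), binSize = 10000)
#' @export
TadPartition <- function(chrom, starts = numeric(), ends = numeric(),
                         binSize, chromLength = NA_real_, label = "") {
  o <- order(starts, -(ends - starts))
  new("TadPartition", chrom = as.character(chrom),
      domains = IRanges::IRanges(start = as.numeric(starts)[o],
                                 end = as.numeric(ends)[o]),
      binSize = as.numeric(binSize),
      chromLength = as.numeric(chromLength), label = as.character(label))
}

#' DomainSet: possibly nested or overlapping domains
#'
#' Output of hierarchical or overlapping TAD callers: domains may nest or
#' overlap. Sorted by (start, -length); exact duplicates are allowed on
#' input and flagged by [extractLevels()]. Same coordinate conventions as
#' [TadPartition-class].
#'
#' @slot chrom,domains,binSize,label see [TadPartition-class].
#' @aliases DomainSet-class
#' @exportClass DomainSet
setClass("DomainSet",
  slots = c(chrom = "character", domains = "IRanges", binSize = "numeric",
            label = "character"),
  prototype = prototype(chrom = "chr", domains = IRanges::IRanges(),
                        binSize = 1, label = ""))

setValidity("DomainSet", function(object) {
  msg <- .validIntervalSlots(object@chrom, object@domains, object@binSize,
                             requireDisjoint = FALSE)
  if (length(msg)) msg else TRUE
})

#' Construct a DomainSet
#'
#' @inheritParams TadPartition
#' @return a validated [DomainSet-class] object.
#' @export
DomainSet <- function(chrom, starts = numeric(), ends = numeric(),
                      binSize, label = "") {
  o <- order(starts, -(ends - starts))
  new("DomainSet", chrom = as.character(chrom),
      domains = IRanges::IRanges(start = as.numeric(starts)[o],
                                 end = as.numeric(ends)[o]),
      binSize = as.numeric(binSize), label = as.character(label))
}

#' ContactMatrix: sparse symmetric intra-chromosomal contacts
#'
#' Binned intra-chromosomal Hi-C contact counts at a fixed bin size.
#' Only the upper triangle (including the diagonal) is stored, in a sparse
#' `dgCMatrix`. `totalReads` is the sum of stored entries, i.e. every
#' off-diagonal contact counted once.
#'
#' @slot chrom chromosome name.
#' @slot binSize bin size in bp.
#' @slot nBins number of bins spanned by the matrix.
#' @slot counts upper-triangular sparse matrix (`nBins x nBins`) of
#'   non-negative contact counts (real after normalization).
#' @slot normalized logical flag set by the normalization routines.
#' @slot totalReads sum of stored counts.
#' @seealso [contactMatrix()] constructor, [readTriplets()],
#'   [iceNormalize()], [lgfNormalize()]
#' @aliases ContactMatrix-class
#' @exportClass ContactMatrix
setClass("ContactMatrix",
  slots = c(chrom = "character", binSize = "numeric", nBins = "integer",
            counts = "dgCMatrix", normalized = "logical",
            totalReads = "numeric"))

setValidity("ContactMatrix", function(object) {
  msg <- character()
  m <- object@counts
  n <- object@nBins
  if (length(n) != 1L || n < 1L) msg <- c(msg, "'nBins' must be a positive integer")
  if (!all(dim(m) == n)) msg <- c(msg, "'counts' must be nBins x nBins")
  tm <- methods::as(m, "TsparseMatrix")
  if (any(tm@i > tm@j)) msg <- c(msg, "'counts' must be upper-triangular (i <= j)")
  if (any(!is.finite(tm@x)) || any(tm@x < 0))
    msg <- c(msg, "counts must be finite and >= 0")
  if (!isTRUE(all.equal(object@totalReads, sum(tm@x), tolerance = 1e-8,
                        check.attributes = FALSE)))
    msg <- c(msg, "'totalReads' must equal the sum of counts")
  if (length(msg)) msg else TRUE
})

#' Construct a ContactMatrix from triplets
#'
#' Entries with `i > j` are mirrored into the upper triangle; duplicate
#' `(i, j)` entries are summed.
#'
#' @param chrom chromosome name.
#' @param binSize bin size in bp.
#' @param nBins number of bins.
#' @param i,j 1-based bin indices of each contact entry.
#' @param x non-negative contact counts.
#' @param normalized logical flag.
#' @return a validated [ContactMatrix-class] object.
#' @examples
#' contactMatrix("chr1", 10000, 3, i = c(1, 1, 2), j = c(2, 3, 3),
#'               x = c(2, 4, 8))
#' @export
contactMatrix <- function(chrom, binSize, nBins, i = integer(),
                          j = integer(), x = numeric(), normalized = FALSE) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("contact counts must be finite and >= 0")
  ii <- pmin(i, j); jj <- pmax(i, j)
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(x),
                            dims = c(nBins, nBins))
  new("ContactMatrix", chrom = as.character(chrom),
      binSize = as.numeric(binSize), nBins = as.integer(nBins),
      counts = methods::as(m, "CsparseMatrix"), normalized = normalized,
      totalReads = sum(x))
}

#' PeakSet: ChIP-seq peak intervals on one chromosome
#'
#' Peak intervals stored 1-based closed (BED input is 0-based half-open
#' and converted by [readPeaks()]).
#'
#' @slot chrom chromosome name.
#' @slot peaks sorted [IRanges::IRanges] of peak intervals.
#' @slot label e.g. the factor assayed (CTCF, RAD21, SMC3).
#' @aliases PeakSet-class
#' @exportClass PeakSet
setClass("PeakSet",
  slots = c(chrom = "character", peaks = "IRanges", label = "character"),
  prototype = prototype(chrom = "chr", peaks = IRanges::IRanges(), label = ""))

setValidity("PeakSet", function(object) {
  msg <- character()
  p <- object@peaks
  if (length(p)) {
    if (is.unsorted(IRanges::start(p))) msg <- c(msg, "peaks must be sorted")
    if (any(IRanges::width(p) < 1)) msg <- c(msg, "peaks must have start <= end")
    if (any(IRanges::start(p) < 1)) msg <- c(msg, "coordinates must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param chrom chromosome name.
#' @param starts,ends 1-based closed peak coordinates.
#' @param label factor name.
#' @return a [PeakSet-class] object.
#' @export
peakSet <- function(chrom, starts = numeric(), ends = numeric(), label = "") {
  o <- order(starts)
  new("PeakSet", chrom = as.character(chrom),
      peaks = IRanges::IRanges(start = as.numeric(starts)[o],
                               end = as.numeric(ends)[o]),
      label = as.character(label))
}

#' SignalTrack: piecewise-constant signal over intervals
#'
#' A non-negative signal (e.g. ChIP-seq fold change over control) defined
#' over sorted, non-overlapping 1-based closed intervals. Positions not
#' covered by any interval carry no value; analyses either error or
#' zero-fill there (see [histoneLrSignificance()]).
#'
#' @slot chrom chromosome name.
#' @slot intervals sorted disjoint [IRanges::IRanges].
#' @slot values one finite non-negative value per interval.
#' @slot label e.g. the histone mark (H3K27me3, H3K36me3).
#' @aliases SignalTrack-class
#' @exportClass SignalTrack
setClass("SignalTrack",
  slots = c(chrom = "character", intervals = "IRanges", values = "numeric",
            label = "character"),
  prototype = prototype(chrom = "chr", intervals = IRanges::IRanges(),
                        values = numeric(), label = ""))

setValidity("SignalTrack", function(object) {
  msg <- character()
  iv <- object@intervals
  if (length(iv) != length(object@values))
    msg <- c(msg, "one value per interval required")
  if (length(iv) > 1L) {
    s <- IRanges::start(iv); e <- IRanges::end(iv)
    if (is.unsorted(s)) msg <- c(msg, "intervals must be sorted")
    else if (any(s[-1L] <= e[-length(e)])) msg <- c(msg, "intervals must not overlap")
  }
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SignalTrack
#'
#' @param chrom chromosome name.
#' @param starts,ends 1-based closed interval coordinates.
#' @param values non-negative signal values, one per interval.
#' @param label track name.
#' @return a [SignalTrack-class] object.
#' @export
signalTrack <- function(chrom, starts = numeric(), ends = numeric(),
                        values = numeric(), label = "") {
  o <- order(starts)
  new("SignalTrack", chrom = as.character(chrom),
      intervals = IRanges::IRanges(start = as.numeric(starts)[o],
                                   end = as.numeric(ends)[o]),
      values = as.numeric(values)[o], label = as.character(label))
}

#' BinCovariates: per-bin local genomic features
#'
#' Bin-level covariates for Poisson-regression normalization
#' ([lgfNormalize()]): mappability in `[0, 1]`, GC content in `[0, 1]`,
#' and mean restriction-fragment length (bp), aligned to the bins of a
#' [ContactMatrix-class].
#'
#' @slot mappability,gc,fragLength numeric vectors, one entry per bin.
#' @aliases BinCovariates-class
#' @exportClass BinCovariates
setClass("BinCovariates",
  slots = c(mappability = "numeric", gc = "numeric", fragLength = "numeric"))

setValidity("BinCovariates", function(object) {
  msg <- character()
  n <- length(object@mappability)
  if (length(object@gc) != n || length(object@fragLength) != n)
    msg <- c(msg, "covariate vectors must have equal length")
  if (any(!is.finite(c(object@mappability, object@gc, object@fragLength))))
    msg <- c(msg, "covariates must be finite")
  if (any(object@mappability < 0 | object@mappability > 1))
    msg <- c(msg, "mappability must lie in [0, 1]")
  if (any(object@gc < 0 | object@gc > 1)) msg <- c(msg, "gc must lie in [0, 1]")
  if (any(object@fragLength <= 0)) msg <- c(msg, "fragLength must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct BinCovariates
#'
#' @param mappability,gc,fragLength numeric vectors, one entry per bin.
#' @return a [BinCovariates-class] object.
#' @export
binCovariates <- function(mappability, gc, fragLength) {
  new("BinCovariates", mappability = as.numeric(mappability),
      gc = as.numeric(gc), fragLength = as.numeric(fragLength))
}

#' SimulationConfig: parameters of the synthetic-data generators
#'
#' Holds the generative parameters shared by [simulatePartition()],
#' [simulateContacts()], [simulatePeaks()] and [simulateMarks()]. Defaults
#' describe a 50-Mb chromosome binned at 10 kb with TADs of mean size
#' 500 kb (log-normal, right-skewed, within the commonly reported
#' 100 kb - 5 Mb range), a distance-decay exponent of 1, twofold
#' within-TAD contact enrichment, 5e6 intra-chromosomal reads, a
#' structural-protein background of one peak per 5 kb with planted
#' boundary enrichment rho = 2 (boundary windows reach three times the
#' background rate), and 80% of TADs carrying a dominant histone mark.
#' See the package vignette for the rationale behind each value.
#'
#' @slot chromLength chromosome length (bp).
#' @slot binSize bin size (bp).
#' @slot nLevels number of nested hierarchy levels to plant.
#' @slot meanTadSize mean TAD size (bp) of the outermost level.
#' @slot sizeSdlog log-sd of the log-normal TAD length distribution.
#' @slot alpha contact distance-decay exponent.
#' @slot gamma within-TAD contact enrichment factor per nesting level.
#' @slot depth total expected intra-chromosomal read count.
#' @slot rho boundary peak enrichment: extra peaks within one bin of a
#'   boundary are planted at `rho` times the background rate.
#' @slot backgroundPeakRate background peak density (peaks per bp).
#' @slot markCoherence fraction of TADs with a dominant histone mark.
#' @slot markHigh,markLow mean signal of the dominant / recessive mark.
#' @slot noiseSdlog log-sd of the multiplicative signal noise.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(chromLength = "numeric", binSize = "numeric", nLevels = "integer",
            meanTadSize = "numeric", sizeSdlog = "numeric", alpha = "numeric",
            gamma = "numeric", depth = "numeric", rho = "numeric",
            backgroundPeakRate = "numeric", markCoherence = "numeric",
            markHigh = "numeric", markLow = "numeric", noiseSdlog = "numeric"),
  prototype = prototype(chromLength = 5e7, binSize = 1e4, nLevels = 1L,
                        meanTadSize = 5e5, sizeSdlog = 0.3, alpha = 1,
                        gamma = 2, depth = 5e6, rho = 2,
                        backgroundPeakRate = 2e-4, markCoherence = 0.8,
                        markHigh = 4, markLow = 0.25, noiseSdlog = 0.25))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pos <- c(chromLength = object@chromLength, binSize = object@binSize,
           meanTadSize = object@meanTadSize, alpha = object@alpha,
           gamma = object@gamma, markHigh = object@markHigh,
           markLow = object@markLow)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, paste("must be positive:", paste(bad, collapse = ", ")))
  nonneg <- c(depth = object@depth, rho = object@rho,
              backgroundPeakRate = object@backgroundPeakRate,
              sizeSdlog = object@sizeSdlog, noiseSdlog = object@noiseSdlog)
  bad <- names(nonneg)[!is.finite(nonneg) | nonneg < 0]
  if (length(bad)) msg <- c(msg, paste("must be non-negative:", paste(bad, collapse = ", ")))
  if (object@markCoherence < 0 || object@markCoherence > 1)
    msg <- c(msg, "markCoherence must lie in [0, 1]")
  if (object@nLevels < 1L) msg <- c(msg, "nLevels must be >= 1")
  if (object@chromLength %% object@binSize != 0)
    msg <- c(msg, "chromLength must be a multiple of binSize")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Any slot of [SimulationConfig-class] can be overridden by name; the
#' remaining parameters keep their defaults.
#'
#' @param ... named slot values, e.g. `chromLength = 1e7`.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' simulationConfig(chromLength = 1e7, meanTadSize = 4e5)
#' @export
simulationConfig <- function(...) {
  args <- list(...)
  if ("nLevels" %in% names(args)) args$nLevels <- as.integer(args$nLevels)
  do.call(new, c(list(Class = "SimulationConfig"), args))
}

#' HierarchyLevels: nesting levels extracted from a DomainSet
#'
#' Result of [extractLevels()]. Level 1 holds domains that contain no
#' other domain of the set; a level-`i` domain strictly contains at least
#' one level-`(i-1)` domain (equality allowed on at most one endpoint).
#' Coincident duplicates and partial overlaps are reported in `discarded`,
#' never assigned to a level; levels with fewer than `minDomains` domains
#' are retained in `levels` but listed in `smallLevels` so downstream
#' summaries can exclude them.
#'
#' @slot chrom,binSize,label as in [DomainSet-class].
#' @slot levels list of [IRanges::IRanges], innermost (L1) first.
#' @slot discarded data.frame with columns `start`, `end`, `reason`
#'   (`"duplicate"` or `"partial_overlap"`).
#' @slot smallLevels integer indices of levels below the size threshold.
#' @slot minDomains the threshold used.
#' @aliases HierarchyLevels-class
#' @exportClass HierarchyLevels
setClass("HierarchyLevels",
  slots = c(chrom = "character", binSize = "numeric", label = "character",
            levels = "list", discarded = "data.frame",
            smallLevels = "integer", minDomains = "integer"))

setValidity("HierarchyLevels", function(object) {
  if (!all(vapply(object@levels, is, logical(1), class2 = "IRanges")))
    return("'levels' must be a list of IRanges")
  TRUE
})
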