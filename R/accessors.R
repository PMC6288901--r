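#' Accessors for the TADconcord data classes
#'
#' Slot access for the S4 containers: `chromName()` and `binSize()` work
#' on every class carrying coordinates; `domainRanges()`/`nDomains()` on
#' [TadPartition-class] and [DomainSet-class]; `contactCounts()` (upper
#' triangle, sparse), `totalReads()`, `nBins()` and `isNormalized()` on
#' [ContactMatrix-class]; `peakRanges()` on [PeakSet-class];
#' `trackRanges()`/`trackValues()` on [SignalTrack-class]; `nLevels()`
#' and `levelDomains()` on [HierarchyLevels-class].
#'
#' @param x an object of the appropriate class.
#' @param i level index (1 = innermost) for `levelDomains()`.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("chromName", "TadPartition", function(x) x@chrom)
#' @rdname accessors
setMethod("chromName", "DomainSet", function(x) x@chrom)
#' @rdname accessors
setMethod("chromName", "ContactMatrix", function(x) x@chrom)
#' @rdname accessors
setMethod("chromName", "PeakSet", function(x) x@chrom)
#' @rdname accessors
setMethod("chromName", "SignalTrack", function(x) x@chrom)
#' @rdname accessors
setMethod("chromName", "HierarchyLevels", function(x) x@chrom)

#' @rdname accessors
setMethod("binSize", "TadPartition", function(x) x@binSize)
#' @rdname accessors
setMethod("binSize", "DomainSet", function(x) x@binSize)
#' @rdname accessors
setMethod("binSize", "ContactMatrix", function(x) x@binSize)
#' @rdname accessors
setMethod("binSize", "HierarchyLevels", function(x) x@binSize)

#' @rdname accessors
setMethod("chromLength", "TadPartition", function(x) x@chromLength)

#' @rdname accessors
setMethod("domainRanges", "TadPartition", function(x) x@domains)
#' @rdname accessors
setMethod("domainRanges", "DomainSet", function(x) x@domains)

#' @rdname accessors
setMethod("nDomains", "TadPartition", function(x) length(x@domains))
#' @rdname accessors
setMethod("nDomains", "DomainSet", function(x) length(x@domains))

#' @rdname accessors
setMethod("labelOf", "TadPartition", function(x) x@label)
#' @rdname accessors
setMethod("labelOf", "DomainSet", function(x) x@label)
#' @rdname accessors
setMethod("labelOf", "PeakSet", function(x) x@label)
#' @rdname accessors
setMethod("labelOf", "SignalTrack", function(x) x@label)

#' @rdname accessors
setMethod("contactCounts", "ContactMatrix", function(x) x@counts)
#' @rdname accessors
setMethod("totalReads", "ContactMatrix", function(x) x@totalReads)
#' @rdname accessors
setMethod("nBins", "ContactMatrix", function(x) x@nBins)
#' @rdname accessors
setMethod("isNormalized", "ContactMatrix", function(x) x@normalized)

#' @rdname accessors
setMethod("peakRanges", "PeakSet", function(x) x@peaks)

#' @rdname accessors
setMethod("trackRanges", "SignalTrack", function(x) x@intervals)
#' @rdname accessors
setMethod("trackValues", "SignalTrack", function(x) x@values)

#' @rdname accessors
setMethod("nLevels", "HierarchyLevels", function(x) length(x@levels))
#' @rdname accessors
setMethod("levelDomains", "HierarchyLevels", function(x, i) {
  stopifnot(i >= 1L, i <= length(x@levels))
  x@levels[[i]]
})

#' Discarded domains of a hierarchy extraction
#'
#' @param x a [HierarchyLevels-class] object.
#' @return data.frame with columns `start`, `end`, `reason`.
#' @export
discardedDomains <- function(x) {
  stopifnot(is(x, "HierarchyLevels"))
  x@discarded
}

#' Indices of levels below the domain-count threshold
#'
#' @param x a [HierarchyLevels-class] object.
#' @return integer vector of level indices.
#' @export
smallLevels <- function(x) {
  stopifnot(is(x, "HierarchyLevels"))
  x@smallLevels
}

.fmtBp <- function(x) {
  ifelse(x >= 1e6, sprintf("%.3g Mb", x / 1e6),
         ifelse(x >= 1e3, sprintf("%.3g kb", x / 1e3), sprintf("%g bp", x)))
}

setMethod("show", "TadPartition", function(object) {
  cat(sprintf("TadPartition '%s' on %s: %d domain(s), bin size %s",
              object@label, object@chrom, length(object@domains),
              .fmtBp(object@binSize)))
  if (!is.na(object@chromLength))
    cat(sprintf(", chrom length %s", .fmtBp(object@chromLength)))
  cat("\n")
  if (length(object@domains)) {
    cat(sprintf("  span %.0f-%.0f, mean domain size %s\n",
                min(IRanges::start(object@domains)),
                max(IRanges::end(object@domains)),
                .fmtBp(mean(IRanges::width(object@domains)))))
  }
})

setMethod("show", "DomainSet", function(object) {
  cat(sprintf("DomainSet '%s' on %s: %d domain(s), bin size %s\n",
              object@label, object@chrom, length(object@domains),
              .fmtBp(object@binSize)))
})

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf(
    "ContactMatrix on %s: %d bins of %s, %.4g reads (%s), %d non-zero entries\n",
    object@chrom, object@nBins, .fmtBp(object@binSize), object@totalReads,
    if (object@normalized) "normalized" else "raw",
    length(object@counts@x)))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet '%s' on %s: %d peak(s)\n", object@label,
              object@chrom, length(object@peaks)))
})

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack '%s' on %s: %d interval(s)", object@label,
              object@chrom, length(object@intervals)))
  if (length(object@values))
    cat(sprintf(", mean value %.4g", mean(object@values)))
  cat("\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:\n")
  for (sl in methods::slotNames(object))
    cat(sprintf("  %-19s %s\n", sl, format(methods::slot(object, sl))))
})

setMethod("show", "HierarchyLevels", function(object) {
  cat(sprintf("HierarchyLevels '%s' on %s: %d level(s)\n", object@label,
              object@chrom, length(object@levels)))
  for (i in seq_along(object@levels))
    cat(sprintf("  L%d: %d domain(s)%s\n", i, length(object@levels[[i]]),
                if (i %in% object@smallLevels) sprintf(
                  " [below minDomains = %d]", object@minDomains) else ""))
  if (nrow(object@discarded))
    cat(sprintf("  discarded: %d (%s)\n", nrow(object@discarded),
                paste(sprintf("%d %s", table(object@discarded$reason),
                              names(table(object@discarded$reason))),
                      collapse = ", ")))
})

#' Coerce a TadPartition or DomainSet to a data.frame
#'
#' @param x the object.
#' @param row.names,optional,... ignored (S3 signature compatibility).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
as.data.frame.TadPartition <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(chrom = rep(x@chrom, length(x@domains)),
             start = IRanges::start(x@domains),
             end = IRanges::end(x@domains))
}

#' @rdname as.data.frame.TadPartition
#' @export
as.data.frame.DomainSet <- as.data.frame.TadPartition
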