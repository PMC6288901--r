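#' @rdname accessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname accessors
#' @export
setGeneric("chromLength", function(x) standardGeneric("chromLength"))

#' @rdname accessors
#' @export
setGeneric("domainRanges", function(x) standardGeneric("domainRanges"))

#' @rdname accessors
#' @export
setGeneric("nDomains", function(x) standardGeneric("nDomains"))

#' @rdname accessors
#' @export
setGeneric("labelOf", function(x) standardGeneric("labelOf"))

#' @rdname accessors
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @rdname accessors
#' @export
setGeneric("trackRanges", function(x) standardGeneric("trackRanges"))

#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname gapsOf
#' @export
setGeneric("gapsOf", function(p) standardGeneric("gapsOf"))

#' @rdname boundariesOf
#' @export
setGeneric("boundariesOf", function(p, dedupe = TRUE)
  standardGeneric("boundariesOf"))

#' @rdname accessors
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname accessors
#' @export
setGeneric("levelDomains", function(x, i) standardGeneric("levelDomains"))
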