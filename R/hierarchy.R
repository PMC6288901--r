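# Nesting-level extraction from nested/overlapping domain sets and
# per-level feature summaries.

#' Extract nesting levels from a domain set
#'
#' Assigns every retained domain to a nesting level: level 1 (the
#' innermost) holds domains that contain no other domain of the set, and
#' a level-`i` domain contains (start and end inclusive) at least one
#' level-`(i - 1)` domain — i.e. the level is the length of the longest
#' containment chain below the domain, which also resolves domains
#' containing members of several earlier levels (they join the next
#' level after the deepest one). Containment allows equality on at most
#' one endpoint: exact coincidence is a duplicate and is discarded, as
#' are partial overlaps (neither containment nor disjointness), which
#' are never promoted to a level — only perfectly nested domains are
#' retained. Levels with fewer than `minDomains` domains are kept in the
#' result but flagged so downstream summaries exclude them.
#'
#' @param d a [DomainSet-class].
#' @param minDomains minimum domain count for a level to enter
#'   downstream summaries (default 10).
#' @return a [HierarchyLevels-class]; an empty set yields an empty
#'   hierarchy.
#' @examples
#' d <- DomainSet("chr1", c(1, 11, 21), c(100, 90, 80), binSize = 10)
#' extractLevels(d, minDomains = 1)  # three levels of one domain each
#' @export
extractLevels <- function(d, minDomains = 10) {
  stopifnot(is(d, "DomainSet"), minDomains >= 1)
  ir <- d@domains
  disc <- data.frame(start = numeric(), end = numeric(),
                     reason = character())
  empty <- function() new("HierarchyLevels", chrom = d@chrom,
                          binSize = d@binSize, label = d@label,
                          levels = list(), discarded = disc,
                          smallLevels = integer(),
                          minDomains = as.integer(minDomains))
  if (!length(ir)) return(empty())
  key <- paste(IRanges::start(ir), IRanges::end(ir))
  dup <- duplicated(key)
  if (any(dup))
    disc <- rbind(disc, data.frame(start = IRanges::start(ir)[dup],
                                   end = IRanges::end(ir)[dup],
                                   reason = "duplicate"))
  ir <- ir[!dup]
  # greedy laminar filter: scan in (start, -length) order and discard any
  # domain that partially overlaps an already retained one
  keep <- logical(length(ir))
  ks <- IRanges::start(ir); ke <- IRanges::end(ir)
  retained <- integer()
  for (k in seq_along(ir)) {
    ov <- retained[ks[retained] <= ke[k] & ke[retained] >= ks[k]]
    laminar <- all((ks[ov] <= ks[k] & ke[ov] >= ke[k]) |
                     (ks[ov] >= ks[k] & ke[ov] <= ke[k]))
    if (laminar) { keep[k] <- TRUE; retained <- c(retained, k) }
  }
  if (any(!keep))
    disc <- rbind(disc, data.frame(start = ks[!keep], end = ke[!keep],
                                   reason = "partial_overlap"))
  ir <- ir[keep]
  if (!length(ir)) return(empty())
  # level = longest containment chain below the domain
  hits <- IRanges::findOverlaps(ir, ir, type = "within")
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  self <- qh == sh
  qh <- qh[!self]; sh <- sh[!self]
  ord <- order(IRanges::width(ir))
  lev <- integer(length(ir))
  for (k in ord) {
    kids <- qh[sh == k]
    lev[k] <- if (length(kids)) max(lev[kids]) + 1L else 1L
  }
  levels <- lapply(seq_len(max(lev)), function(i) {
    li <- ir[lev == i]
    li[order(IRanges::start(li))]
  })
  counts <- vapply(levels, length, integer(1))
  new("HierarchyLevels", chrom = d@chrom, binSize = d@binSize,
      label = d@label, levels = levels, discarded = disc,
      smallLevels = which(counts < minDomains),
      minDomains = as.integer(minDomains))
}

#' Convert a hierarchy level to a TadPartition
#'
#' Domains of one nesting level are mutually disjoint (two nested
#' domains cannot share a level), so each level is a valid partition.
#'
#' @param h a [HierarchyLevels-class].
#' @param i level index (1 = innermost).
#' @param chromLength optional chromosome length.
#' @return a [TadPartition-class].
#' @export
levelPartition <- function(h, i, chromLength = NA_real_) {
  stopifnot(is(h, "HierarchyLevels"))
  ir <- levelDomains(h, i)
  TadPartition(h@chrom, IRanges::start(ir), IRanges::end(ir),
               binSize = h@binSize, chromLength = chromLength,
               label = sprintf("%s_L%d", h@label, i))
}

#' Per-level feature summaries of a hierarchy
#'
#' For every retained level, reports the domain count and mean size and
#' — when the corresponding inputs are supplied — the pooled
#' structural-protein fold change at the level's boundaries, the tagged
#' boundary fraction, and the fraction of domains with a significant
#' histone-mark log ratio. Levels below the hierarchy's `minDomains`
#' threshold are listed but carry `NA` statistics and
#' `included = FALSE`.
#'
#' @param h a [HierarchyLevels-class].
#' @param peaks optional [PeakSet-class] for fold change / tagging.
#' @param sig27,sig36 optional [SignalTrack-class] pair for the LR test.
#' @param chromLength chromosome length (needed for the fold-change edge
#'   rule and the LR tiling).
#' @param seed seed forwarded to [histoneLrSignificance()].
#' @param ... further arguments to [histoneLrSignificance()].
#' @return data.frame with one row per level: `level`, `nDomains`,
#'   `meanSizeBp`, `included`, and the requested statistics
#'   (`foldChange`, `taggedFraction`, `lrSignificantFraction`).
#' @export
levelSummaries <- function(h, peaks = NULL, sig27 = NULL, sig36 = NULL,
                           chromLength = NA_real_, seed = NULL, ...) {
  stopifnot(is(h, "HierarchyLevels"))
  rows <- lapply(seq_len(nLevels(h)), function(i) {
    ir <- levelDomains(h, i)
    out <- data.frame(level = i, nDomains = length(ir),
                      meanSizeBp = if (length(ir))
                        mean(IRanges::width(ir)) else NA_real_,
                      included = !(i %in% h@smallLevels),
                      foldChange = NA_real_, taggedFraction = NA_real_,
                      lrSignificantFraction = NA_real_)
    if (!out$included || !length(ir)) return(out)
    p <- levelPartition(h, i, chromLength = chromLength)
    if (!is.null(peaks)) {
      out$foldChange <- boundaryFoldChange(p, peaks)$foldChange
      out$taggedFraction <- taggedFraction(p, peaks)$fraction
    }
    if (!is.null(sig27) && !is.null(sig36))
      out$lrSignificantFraction <- histoneLrSignificance(
        p, sig27, sig36, seed = seed, ...)$fractionSignificant
    out
  })
  do.call(rbind, rows)
}
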