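# Biological-feature statistics: structural-protein profiles and fold
# changes at boundaries, tagged-boundary fractions, shared-vs-private
# boundary enrichment, and histone-mark log-ratio significance within
# TADs with a permutation null and Benjamini-Hochberg FDR.

.boundaryPositions <- function(boundaries, binSizeBp = NULL) {
  if (is(boundaries, "TadPartition"))
    return(list(pos = boundariesOf(boundaries) * boundaries@binSize,
                chromLength = .spanEnd(boundaries),
                binSize = boundaries@binSize))
  if (!is.numeric(boundaries))
    stop("'boundaries' must be a TadPartition or numeric bp positions")
  list(pos = sort(unique(boundaries)), chromLength = NA_real_,
       binSize = binSizeBp)
}

#' Structural protein profile (SPP) at TAD boundaries
#'
#' For each boundary, counts ChIP-seq peak midpoints in consecutive
#' 5-kb intervals across the +/- 500-kb window centred on the boundary
#' (200 intervals with the defaults). The aggregate profile — the average
#' number of peaks per interval across boundaries — is what boundary
#' pile-up plots show. Boundaries closer than `windowBp` to either
#' chromosome end would have truncated windows and are dropped; the
#' dropped count is reported.
#'
#' @param boundaries a [TadPartition-class] (its unique boundaries are
#'   used; positions are junction offsets in bp) or a numeric vector of
#'   boundary positions in bp.
#' @param peaks a [PeakSet-class].
#' @param windowBp half-width of the profiled window (default 500 kb).
#' @param intervalBp profile interval size (default 5 kb).
#' @param chromLength chromosome length used for the edge rule; taken
#'   from the partition when available.
#' @return a list with `profiles` (boundary x interval count matrix),
#'   `aggregate` (mean profile across boundaries), `positions` (retained
#'   boundary positions), `offsets` (interval centre offsets in bp),
#'   `nDropped`, and `params`.
#' @export
sppProfile <- function(boundaries, peaks, windowBp = 5e5, intervalBp = 5e3,
                       chromLength = NULL) {
  stopifnot(is(peaks, "PeakSet"), windowBp %% intervalBp == 0)
  bp <- .boundaryPositions(boundaries)
  L <- if (!is.null(chromLength)) chromLength else bp$chromLength
  pos <- bp$pos
  keep <- if (is.na(L)) pos - windowBp >= 0 else
    pos - windowBp >= 0 & pos + windowBp <= L
  nDropped <- sum(!keep)
  pos <- pos[keep]
  nInt <- as.integer(2 * windowBp / intervalBp)
  mids <- sort((as.numeric(IRanges::start(peaks@peaks)) +
                  as.numeric(IRanges::end(peaks@peaks))) / 2)
  prof <- matrix(0L, nrow = length(pos), ncol = nInt)
  for (b in seq_along(pos)) {
    lo <- pos[b] - windowBp
    k0 <- findInterval(lo, mids)
    k1 <- findInterval(pos[b] + windowBp, mids)
    if (k1 > k0)
      prof[b, ] <- tabulate(ceiling((mids[(k0 + 1):k1] - lo) / intervalBp),
                            nbins = nInt)
  }
  list(profiles = prof,
       aggregate = if (length(pos)) colMeans(prof) else rep(NA_real_, nInt),
       positions = pos,
       offsets = -windowBp + (seq_len(nInt) - 0.5) * intervalBp,
       nDropped = nDropped,
       params = list(windowBp = windowBp, intervalBp = intervalBp))
}

#' Fold change of structural-protein signal at boundaries
#'
#' Ratio of the average SPP in a narrow window around a boundary
#' (+/- `peakRadiusBp`, default 10 kb) to the average SPP in two flanking
#' regions of `flankWidthBp` (default 100 kb) located `flankOffsetBp`
#' (default 400 kb) away from the boundary, minus 1. A uniform peak
#' density gives a value near 0; threefold enrichment at boundaries gives
#' a value near 2.
#'
#' The default estimate (`aggregate = "pooled"`) averages the SPP across
#' boundaries first and then takes the ratio; `"perBoundary"` computes a
#' fold change per boundary and averages those, excluding boundaries with
#' a zero flank mean (their count is reported). If the pooled flank mean
#' is zero the fold change is undefined and `NA` is returned.
#'
#' @inheritParams sppProfile
#' @param peakRadiusBp half-width of the boundary window.
#' @param flankWidthBp width of each flanking region.
#' @param flankOffsetBp distance from the boundary to the near edge of
#'   each flanking region.
#' @param aggregate `"pooled"` (average SPP, then ratio; default) or
#'   `"perBoundary"` (ratio per boundary, then average).
#' @return a list with `foldChange` (the summary estimate),
#'   `perBoundary` (data.frame: `position`, `foldChange`),
#'   `nExcludedZeroFlank`, `nDropped`, and `params`.
#' @export
boundaryFoldChange <- function(boundaries, peaks, windowBp = 5e5,
                               intervalBp = 5e3, peakRadiusBp = 1e4,
                               flankWidthBp = 1e5, flankOffsetBp = 4e5,
                               chromLength = NULL,
                               aggregate = c("pooled", "perBoundary")) {
  aggregate <- match.arg(aggregate)
  stopifnot(peakRadiusBp %% intervalBp == 0, flankWidthBp %% intervalBp == 0,
            flankOffsetBp + flankWidthBp <= windowBp)
  spp <- sppProfile(boundaries, peaks, windowBp, intervalBp, chromLength)
  nInt <- ncol(spp$profiles)
  mid <- nInt / 2
  central <- (mid - peakRadiusBp / intervalBp + 1):(mid + peakRadiusBp / intervalBp)
  fl <- flankWidthBp / intervalBp
  offL <- (windowBp - flankOffsetBp - flankWidthBp) / intervalBp
  flank <- c(offL + seq_len(fl), nInt - offL - fl + seq_len(fl))
  cMean <- rowMeans(spp$profiles[, central, drop = FALSE])
  fMean <- rowMeans(spp$profiles[, flank, drop = FALSE])
  perB <- ifelse(fMean > 0, cMean / fMean - 1, NA_real_)
  fc <- if (aggregate == "pooled") {
    aggF <- mean(fMean)
    if (!length(fMean) || aggF == 0) NA_real_ else mean(cMean) / aggF - 1
  } else {
    if (!any(fMean > 0)) NA_real_ else mean(perB, na.rm = TRUE)
  }
  list(foldChange = fc,
       perBoundary = data.frame(position = spp$positions, foldChange = perB),
       nExcludedZeroFlank = sum(fMean == 0),
       nDropped = spp$nDropped,
       params = list(windowBp = windowBp, intervalBp = intervalBp,
                     peakRadiusBp = peakRadiusBp, flankWidthBp = flankWidthBp,
                     flankOffsetBp = flankOffsetBp, aggregate = aggregate))
}

#' Fraction of boundaries tagged by a peak
#'
#' A boundary is tagged when at least one peak overlaps its boundary bin
#' or one of the two adjacent bins (+/- one bin from the boundary). The
#' boundary bin of a junction is the bin to its right (the start bin of
#' the following domain), except for the final junction of the span,
#' which keeps the bin to its left.
#'
#' @param p a [TadPartition-class].
#' @param peaks a [PeakSet-class].
#' @return a list with `fraction`, `tagged` (data.frame: `junction`,
#'   `tagged`), and `params`.
#' @export
taggedFraction <- function(p, peaks) {
  stopifnot(is(p, "TadPartition"), is(peaks, "PeakSet"))
  B <- p@binSize
  ju <- boundariesOf(p)
  if (!length(ju))
    return(list(fraction = NA_real_,
                tagged = data.frame(junction = numeric(), tagged = logical()),
                params = list(binSize = B)))
  maxBin <- .spanEnd(p) / B
  bin <- .junctionBin(ju, maxBin)
  win <- IRanges::IRanges(start = pmax(1, (bin - 2) * B + 1),
                          end = (bin + 1) * B)
  tagged <- IRanges::overlapsAny(win, peaks@peaks)
  list(fraction = mean(tagged),
       tagged = data.frame(junction = ju, tagged = tagged),
       params = list(binSize = B))
}

#' Peak fold change at shared versus private boundaries
#'
#' Splits each caller's boundaries into those consolidated with
#' boundaries of at least `minCallers` callers ([sharedBoundaries()],
#' tolerance `radiusBins`) and the rest, and computes the pooled
#' [boundaryFoldChange()] of each class. Supplying several `minCallers`
#' values traces the trend of the shared-class fold change as the
#' sharing requirement grows.
#'
#' @param partitions list of at least two [TadPartition-class] objects
#'   (equal bin size, same chromosome).
#' @param peaks a [PeakSet-class].
#' @param minCallers integer vector of sharing thresholds.
#' @param radiusBins consolidation tolerance in bins (default 2).
#' @param ... further arguments passed to [boundaryFoldChange()].
#' @return a list with `perCaller` (data.frame: `minCallers`, `caller`,
#'   `class`, `n`, `foldChange`), `trend` (data.frame: `minCallers`,
#'   `class`, `meanFoldChange`), and `params`.
#' @export
sharedBoundaryEnrichment <- function(partitions, peaks, minCallers,
                                     radiusBins = 2, ...) {
  sb <- sharedBoundaries(partitions, radiusBins)
  labs <- unique(sb$assignments$caller)
  B <- partitions[[1L]]@binSize
  chromLen <- max(vapply(partitions, .spanEnd, numeric(1)))
  nPerJunction <- sb$clusters$nCallers[match(sb$assignments$cluster,
                                             sb$clusters$cluster)]
  rows <- list()
  for (mc in minCallers) {
    for (ca in labs) {
      sel <- sb$assignments$caller == ca
      for (cls in c("shared", "not_shared")) {
        inCls <- if (cls == "shared") nPerJunction[sel] >= mc
                 else nPerJunction[sel] < mc
        pos <- sb$assignments$junction[sel][inCls] * B
        fc <- if (length(pos))
          boundaryFoldChange(pos, peaks, chromLength = chromLen,
                             ...)$foldChange else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          minCallers = mc, caller = ca, class = cls, n = length(pos),
          foldChange = fc)
      }
    }
  }
  perCaller <- do.call(rbind, rows)
  trend <- do.call(rbind, lapply(split(
    perCaller, list(perCaller$minCallers, perCaller$class)), function(d) {
      data.frame(minCallers = d$minCallers[1L], class = d$class[1L],
                 meanFoldChange = mean(d$foldChange, na.rm = TRUE))
    }))
  trend <- trend[order(trend$minCallers, trend$class), , drop = FALSE]
  rownames(trend) <- NULL
  list(perCaller = perCaller, trend = trend,
       params = list(minCallers = minCallers, radiusBins = radiusBins))
}

.intervalMeans <- function(track, tiles, gaps) {
  n <- length(tiles)
  m <- numeric(n)
  cov <- numeric(n)
  hits <- IRanges::findOverlaps(tiles, track@intervals)
  if (length(hits)) {
    w <- IRanges::width(IRanges::pintersect(
      tiles[S4Vectors::queryHits(hits)],
      track@intervals[S4Vectors::subjectHits(hits)]))
    v <- track@values[S4Vectors::subjectHits(hits)]
    qh <- S4Vectors::queryHits(hits)
    m <- as.numeric(tapply(w * v, factor(qh, levels = seq_len(n)), sum,
                           default = 0))
    cov <- as.numeric(tapply(w, factor(qh, levels = seq_len(n)), sum,
                             default = 0))
  }
  if (gaps == "error" && any(cov < IRanges::width(tiles)))
    stop("track '", track@label, "' does not cover the tiled span; ",
         "zero-fill the gaps or pass gaps = \"zero\"")
  m / IRanges::width(tiles)
}

#' Histone-mark log-ratio significance within TADs
#'
#' Tests whether each TAD is biased towards one of two histone marks
#' (canonically repressive H3K27me3 versus active H3K36me3). The
#' chromosome is tiled into intervals of 10% of the mean TAD size
#' (rounded down to a bin multiple, at least one bin); each interval gets
#' `LR = log10((m27 + eps27) / (m36 + eps36))` where `m` are mean
#' signals and `eps` is a pseudo-count (1% of the track's global mean by
#' default). The observed statistic per TAD is the mean LR of the
#' intervals whose midpoints fall inside it. The null shuffles the LR
#' values over interval positions `nShuffles` times and recomputes the
#' per-TAD means; the empirical p value is two-sided via the deviation
#' from the chromosome-wide mean LR, with a +1/+1 correction so p is
#' never 0 (`correction = "none"` drops the correction and allows p = 0,
#' the permissive variant). p values are Benjamini-Hochberg adjusted
#' across TADs and the fraction of TADs with `q < fdr` is reported.
#'
#' @param tads a [TadPartition-class].
#' @param sig27,sig36 [SignalTrack-class] objects covering the chromosome
#'   span (fold change over control).
#' @param nShuffles number of LR-interval shuffles (default 10).
#' @param seed integer seed for the shuffles.
#' @param fdr significance threshold on the adjusted p value
#'   (default 0.1).
#' @param pseudocount per-track pseudo-count; default 1% of each track's
#'   global mean.
#' @param gaps `"error"` (default) to reject tracks with uncovered
#'   positions, `"zero"` to treat them as zero signal.
#' @param sided `"two"` (default) or `"high"` (one-sided, observed above
#'   the shuffled values).
#' @param correction `"add-one"` (default) or `"none"`.
#' @return a list with `intervals` (data.frame: `start`, `end`, `m27`,
#'   `m36`, `lr`), `tads` (data.frame: `start`, `end`, `nIntervals`,
#'   `observedLr`, `p`, `q`, `significant`), `fractionSignificant`, and
#'   `params`.
#' @export
histoneLrSignificance <- function(tads, sig27, sig36, nShuffles = 10,
                                  seed = NULL, fdr = 0.1,
                                  pseudocount = NULL,
                                  gaps = c("error", "zero"),
                                  sided = c("two", "high"),
                                  correction = c("add-one", "none")) {
  stopifnot(is(tads, "TadPartition"), is(sig27, "SignalTrack"),
            is(sig36, "SignalTrack"), nShuffles >= 1)
  gaps <- match.arg(gaps)
  sided <- match.arg(sided)
  correction <- match.arg(correction)
  if (!nDomains(tads)) stop("empty partition")
  B <- tads@binSize
  meanSize <- mean(IRanges::width(tads@domains))
  intSize <- max(B, floor(0.1 * meanSize / B) * B)
  span <- .spanEnd(tads)
  nInt <- floor(span / intSize)
  if (nInt < 2L) stop("chromosome span too short for the interval size")
  tiles <- IRanges::IRanges(start = (seq_len(nInt) - 1) * intSize + 1,
                            width = intSize)
  m27 <- .intervalMeans(sig27, tiles, gaps)
  m36 <- .intervalMeans(sig36, tiles, gaps)
  globalMean <- function(track) {
    if (!length(track@values)) return(0)
    sum(track@values * IRanges::width(track@intervals)) /
      sum(IRanges::width(track@intervals))
  }
  eps27 <- if (is.null(pseudocount)) 0.01 * globalMean(sig27) else pseudocount
  eps36 <- if (is.null(pseudocount)) 0.01 * globalMean(sig36) else pseudocount
  if (eps27 <= 0 || eps36 <= 0)
    stop("pseudo-count must be positive (is a track all zero?)")
  lr <- log10((m27 + eps27) / (m36 + eps36))
  mids <- (as.numeric(IRanges::start(tiles)) +
             as.numeric(IRanges::end(tiles))) / 2
  memb <- findInterval(mids, IRanges::start(tads@domains))
  inTad <- memb >= 1 & mids <= IRanges::end(tads@domains)[pmax(memb, 1L)]
  memb[!inTad] <- NA
  nT <- nDomains(tads)
  tadMeans <- function(values) {
    as.numeric(tapply(values[inTad], factor(memb[inTad], levels = seq_len(nT)),
                      mean))
  }
  obs <- tadMeans(lr)
  mu <- mean(lr)
  shuf <- .withSeed(seed, {
    vapply(seq_len(nShuffles), function(s) tadMeans(sample(lr)),
           numeric(nT))
  })
  shuf <- matrix(shuf, nrow = nT)
  stat <- function(x) if (sided == "two") abs(x - mu) else x - mu
  exceed <- rowSums(stat(shuf) >= stat(obs), na.rm = TRUE)
  p <- if (correction == "add-one") (1 + exceed) / (1 + nShuffles)
       else exceed / nShuffles
  p[is.na(obs)] <- NA
  q <- rep(NA_real_, nT)
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  sig <- q < fdr
  nIntPerTad <- as.numeric(table(factor(memb[inTad], levels = seq_len(nT))))
  list(intervals = data.frame(start = IRanges::start(tiles),
                              end = IRanges::end(tiles), m27 = m27,
                              m36 = m36, lr = lr),
       tads = data.frame(start = IRanges::start(tads@domains),
                         end = IRanges::end(tads@domains),
                         nIntervals = nIntPerTad, observedLr = obs,
                         p = p, q = q, significant = sig),
       fractionSignificant = mean(sig[ok]),
       params = list(intervalSize = intSize, nShuffles = nShuffles,
                     seed = seed, fdr = fdr, eps27 = eps27, eps36 = eps36,
                     mu = mu, sided = sided, correction = correction))
}

#' Intersect two peak sets
#'
#' Plumbing helper mirroring how replicate ENCODE peak sets are combined
#' upstream: returns the merged regions covered by peaks of both sets.
#'
#' @param a,b [PeakSet-class] objects on the same chromosome.
#' @param label label of the result.
#' @return a [PeakSet-class].
#' @export
intersectPeaks <- function(a, b, label = paste(a@label, b@label, sep = "&")) {
  stopifnot(is(a, "PeakSet"), is(b, "PeakSet"))
  if (a@chrom != b@chrom) stop("peak sets are on different chromosomes")
  ints <- IRanges::intersect(IRanges::reduce(a@peaks), IRanges::reduce(b@peaks))
  peakSet(a@chrom, IRanges::start(ints), IRanges::end(ints), label = label)
}
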