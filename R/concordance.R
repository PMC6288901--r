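# Partition-vs-partition statistics: Measure of Concordance, boundary and
# TAD conservation at a bin tolerance radius, cross-resolution boundary
# containment, shared-boundary consolidation, conservation ratio, and
# TAD-size scaling summaries.

.clusters <- function(p, span, gapsAsClusters) {
  cl <- p@domains
  if (gapsAsClusters) {
    g <- if (span >= 1) IRanges::gaps(p@domains, start = 1, end = span)
         else IRanges::IRanges()
    cl <- c(cl, g)
    cl <- cl[order(IRanges::start(cl))]
  }
  cl
}

#' Measure of Concordance between two TAD partitions
#'
#' Treats base pairs as the clustered elements: each TAD is a cluster
#' and, by default, each inter-TAD gap is a cluster too, so that both
#' partitions cluster the same element set. With `N_P` and `N_Q` clusters
#' of sizes `||P_i||`, `||Q_j||` (bp) and pairwise overlaps `||F_ij||`,
#'
#' \deqn{MoC(P,Q) = 1 \textrm{ if } N_P = N_Q = 1, \textrm{ else }
#'   \frac{1}{\sqrt{N_P N_Q} - 1}\left(\sum_{i}\sum_{j}
#'   \frac{\|F_{ij}\|^2}{\|P_i\| \|Q_j\|} - 1\right)}
#'
#' MoC is symmetric and ranges from 0 (absence of concordance) to 1
#' (full concordance). When the two partitions cover different spans the
#' union span is used and the uncovered tail becomes a gap cluster on the
#' deficient side. If exactly one side has a single cluster the general
#' branch applies and the double sum telescopes to 1, giving 0. Values
#' within 1e-12 of 0 or 1 are snapped to the exact bound (the formula is
#' evaluated in floating point; the bounds are attained exactly in exact
#' arithmetic).
#'
#' @param p,q [TadPartition-class] objects on the same chromosome.
#' @param gapsAsClusters treat inter-TAD gaps as clusters (default
#'   `TRUE`).
#' @return a single number in `[0, 1]`.
#' @examples
#' p <- TadPartition("chr1", c(1, 41), c(40, 100), binSize = 1)
#' q <- TadPartition("chr1", c(1, 51), c(50, 100), binSize = 1)
#' moc(p, q)  # 2/3
#' @export
moc <- function(p, q, gapsAsClusters = TRUE) {
  stopifnot(is(p, "TadPartition"), is(q, "TadPartition"))
  if (p@chrom != q@chrom)
    stop("partitions are on different chromosomes: ", p@chrom, " vs ", q@chrom)
  span <- max(.spanEnd(p), .spanEnd(q))
  clP <- .clusters(p, span, gapsAsClusters)
  clQ <- .clusters(q, span, gapsAsClusters)
  nP <- length(clP); nQ <- length(clQ)
  if (nP == 0L || nQ == 0L)
    stop("cannot compute MoC with an empty cluster set")
  if (nP == 1L && nQ == 1L) return(1)
  hits <- IRanges::findOverlaps(clP, clQ)
  w <- as.numeric(IRanges::width(IRanges::pintersect(
    clP[S4Vectors::queryHits(hits)], clQ[S4Vectors::subjectHits(hits)])))
  wp <- as.numeric(IRanges::width(clP)[S4Vectors::queryHits(hits)])
  wq <- as.numeric(IRanges::width(clQ)[S4Vectors::subjectHits(hits)])
  val <- (sum(w^2 / (wp * wq)) - 1) / (sqrt(nP * nQ) - 1)
  if (abs(val) < 1e-12) val <- 0
  if (abs(val - 1) < 1e-12) val <- 1
  min(1, max(0, val))
}

.nearestDist <- function(a, b) {
  # for each value in a, distance (in bins) to the nearest value in b
  if (!length(b)) return(rep(Inf, length(a)))
  sb <- sort(b)
  pos <- findInterval(a, sb)
  lo <- ifelse(pos >= 1, abs(a - sb[pmax(pos, 1)]), Inf)
  hi <- ifelse(pos < length(sb), abs(sb[pmin(pos + 1, length(sb))] - a), Inf)
  pmin(lo, hi)
}

#' Boundary conservation between two partitions at equal bin size
#'
#' A boundary of `p` is conserved if some boundary of `q` lies within
#' `radiusBins` bins of it (and vice versa; the counts are asymmetric in
#' general). Boundaries are unique junctions ([boundariesOf()]) and
#' distances are measured between junction indices, so a radius of 5
#' bins at 10 kb is +/- 50 kb.
#'
#' @param p,q [TadPartition-class] objects with equal bin sizes.
#' @param radiusBins tolerance radius in bins (integer >= 0).
#' @return a list with `radiusBins`, per-side data.frames `a`/`b`
#'   (columns `junction`, `conserved`), and `fractionA`/`fractionB`.
#' @seealso [conservedTads()], [crossResolutionConserved()]
#' @export
conservedBoundaries <- function(p, q, radiusBins) {
  stopifnot(is(p, "TadPartition"), is(q, "TadPartition"), radiusBins >= 0)
  if (p@binSize != q@binSize)
    stop("bin sizes differ (", p@binSize, " vs ", q@binSize,
         "); use crossResolutionConserved() instead")
  jp <- boundariesOf(p); jq <- boundariesOf(q)
  consA <- .nearestDist(jp, jq) <= radiusBins
  consB <- .nearestDist(jq, jp) <= radiusBins
  list(radiusBins = radiusBins,
       a = data.frame(junction = jp, conserved = consA),
       b = data.frame(junction = jq, conserved = consB),
       fractionA = if (length(jp)) mean(consA) else NA_real_,
       fractionB = if (length(jq)) mean(consB) else NA_real_)
}

.tadConservedFlags <- function(p, q, radiusBins) {
  # TAD of p conserved iff exactly one TAD of q matches both of its
  # boundaries within the radius
  B <- p@binSize
  lp <- (IRanges::start(p@domains) - 1) / B; rp <- IRanges::end(p@domains) / B
  lq <- (IRanges::start(q@domains) - 1) / B; rq <- IRanges::end(q@domains) / B
  vapply(seq_along(lp), function(i) {
    sum(abs(lq - lp[i]) <= radiusBins & abs(rq - rp[i]) <= radiusBins) == 1L
  }, logical(1))
}

#' TAD conservation between two partitions at equal bin size
#'
#' A TAD of `p` is conserved if both its boundaries are conserved and
#' they correspond, within `radiusBins` bins, to the start and end of
#' exactly one TAD of `q`. A TAD spanning two `q` TADs whose outer
#' boundaries coincide with it is therefore *not* conserved.
#'
#' @inheritParams conservedBoundaries
#' @return a list with `radiusBins`, per-side data.frames `a`/`b`
#'   (columns `start`, `end`, `conserved`), `fractionA`/`fractionB`, and
#'   `conservedA`/`conservedB` counts.
#' @export
conservedTads <- function(p, q, radiusBins) {
  stopifnot(is(p, "TadPartition"), is(q, "TadPartition"), radiusBins >= 0)
  if (p@binSize != q@binSize)
    stop("bin sizes differ (", p@binSize, " vs ", q@binSize,
         "); use crossResolutionConserved() instead")
  fa <- .tadConservedFlags(p, q, radiusBins)
  fb <- .tadConservedFlags(q, p, radiusBins)
  list(radiusBins = radiusBins,
       a = data.frame(start = IRanges::start(p@domains),
                      end = IRanges::end(p@domains), conserved = fa),
       b = data.frame(start = IRanges::start(q@domains),
                      end = IRanges::end(q@domains), conserved = fb),
       fractionA = if (length(fa)) mean(fa) else NA_real_,
       fractionB = if (length(fb)) mean(fb) else NA_real_,
       conservedA = sum(fa), conservedB = sum(fb))
}

#' Cross-resolution boundary conservation
#'
#' Compares boundaries called at a bigger bin size with boundaries called
#' at a smaller one: a coarse boundary is conserved if at least one fine
#' boundary position (a domain start or end, in bp) falls inside the
#' genomic interval of the coarse bin delimited by that boundary (the
#' start bin for a domain start, the end bin for a domain end; an
#' interior junction is conserved if either of its two delimiting bins
#' contains a fine boundary).
#'
#' @param coarse [TadPartition-class] at the bigger bin size (a multiple
#'   of the fine bin size).
#' @param fine [TadPartition-class] at the smaller bin size.
#' @return a list with a data.frame `a` (columns `junction`,
#'   `conserved`) for the coarse boundaries and the conserved `fraction`.
#' @export
crossResolutionConserved <- function(coarse, fine) {
  stopifnot(is(coarse, "TadPartition"), is(fine, "TadPartition"))
  if (coarse@binSize %% fine@binSize != 0)
    stop("coarse bin size must be a multiple of the fine bin size")
  if (coarse@binSize == fine@binSize)
    stop("bin sizes are equal; use conservedBoundaries() instead")
  B <- coarse@binSize
  tab <- .junctionTable(coarse)
  finePos <- sort(unique(c(IRanges::start(fine@domains),
                           IRanges::end(fine@domains))))
  # bin interval delimited by each boundary record
  lo <- ifelse(tab$side == "start", tab$pos + 1, tab$pos - B + 1)
  hi <- ifelse(tab$side == "start", tab$pos + B, tab$pos)
  rec <- vapply(seq_len(nrow(tab)), function(k) {
    i <- findInterval(hi[k], finePos)
    i >= 1 && finePos[i] >= lo[k]
  }, logical(1))
  ju <- sort(unique(tab$junction))
  consJ <- vapply(ju, function(j) any(rec[tab$junction == j]), logical(1))
  list(a = data.frame(junction = ju, conserved = consJ),
       fraction = if (length(ju)) mean(consJ) else NA_real_)
}

#' Consolidate boundaries shared across callers
#'
#' Pools the unique boundaries of two or more partitions (equal bin
#' size) and consolidates them into clusters of nearby junctions:
#' single-linkage joins junctions whose consecutive distance is at most
#' `radiusBins` (the default; complete linkage, capping the cluster
#' diameter at `radiusBins`, is available since the consolidation rule is
#' a convention). Each cluster reports the number of distinct callers
#' represented, supporting histograms of boundaries found by a given
#' number of callers and shared/not-shared splits.
#'
#' @param partitions list of at least two [TadPartition-class] objects
#'   with equal bin sizes on the same chromosome.
#' @param radiusBins tolerance radius in bins.
#' @param linkage `"single"` (default) or `"complete"`.
#' @return a list with `assignments` (data.frame: `caller`, `junction`,
#'   `cluster`), `clusters` (data.frame: `cluster`, `nCallers`,
#'   `minJunction`, `maxJunction`), and `params`.
#' @export
sharedBoundaries <- function(partitions, radiusBins,
                             linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (!is.list(partitions) || length(partitions) < 2L)
    stop("at least two partitions are required")
  stopifnot(all(vapply(partitions, is, logical(1), class2 = "TadPartition")))
  B <- unique(vapply(partitions, function(p) p@binSize, numeric(1)))
  if (length(B) != 1L) stop("all partitions must share the same bin size")
  if (length(unique(vapply(partitions, function(p) p@chrom, character(1)))) != 1L)
    stop("all partitions must be on the same chromosome")
  labs <- vapply(seq_along(partitions), function(i) {
    l <- partitions[[i]]@label
    if (nzchar(l)) l else paste0("caller", i)
  }, character(1))
  if (anyDuplicated(labs)) labs <- make.unique(labs)
  asg <- do.call(rbind, lapply(seq_along(partitions), function(i) {
    data.frame(caller = labs[i], junction = boundariesOf(partitions[[i]]))
  }))
  asg <- asg[order(asg$junction), , drop = FALSE]
  ju <- sort(unique(asg$junction))
  if (linkage == "single" || length(ju) == 1L) {
    cl <- cumsum(c(1, diff(ju) > radiusBins))
  } else {
    hc <- stats::hclust(stats::dist(ju), method = "complete")
    cl <- stats::cutree(hc, h = radiusBins)
    cl <- match(cl, unique(cl[order(ju)]))
  }
  asg$cluster <- cl[match(asg$junction, ju)]
  cs <- split(asg, asg$cluster)
  clusters <- data.frame(
    cluster = as.integer(names(cs)),
    nCallers = vapply(cs, function(d) length(unique(d$caller)), integer(1)),
    minJunction = vapply(cs, function(d) min(d$junction), numeric(1)),
    maxJunction = vapply(cs, function(d) max(d$junction), numeric(1)))
  rownames(clusters) <- NULL
  list(assignments = asg, clusters = clusters,
       params = list(radiusBins = radiusBins, linkage = linkage,
                     nCallers = length(partitions)))
}

#' Conservation ratio between two partitions
#'
#' Number of conserved TADs divided by the minimum total number of TADs
#' found by the two callers, i.e. the maximum possible number of
#' conserved TADs. The conserved count is taken as the minimum of the
#' two per-side counts of [conservedTads()], making the ratio symmetric.
#'
#' @inheritParams conservedBoundaries
#' @return a single number in `[0, 1]`.
#' @export
conservationRatio <- function(p, q, radiusBins) {
  ct <- conservedTads(p, q, radiusBins)
  denom <- min(nDomains(p), nDomains(q))
  if (denom == 0L) return(NA_real_)
  min(ct$conservedA, ct$conservedB) / denom
}

#' TAD-size scaling across resolutions
#'
#' Mean TAD size per resolution, in bp and in bins, with the ordinary
#' least-squares slopes of mean size against bin size. Callers that keep
#' the number of bins per TAD constant show `slopeBins` near 0 and
#' `slopeBp` near that bin count; callers tracking fixed genomic regions
#' show `slopeBp` near 0.
#'
#' @param partitions list of [TadPartition-class] objects for the same
#'   caller at two or more distinct bin sizes.
#' @return a list with `summary` (data.frame: `binSize`, `meanSizeBp`,
#'   `meanSizeBins`, `nTads`) and slopes `slopeBp`, `slopeBins` (per bp
#'   of bin size).
#' @export
sizeSummary <- function(partitions) {
  stopifnot(is.list(partitions),
            all(vapply(partitions, is, logical(1), class2 = "TadPartition")))
  df <- do.call(rbind, lapply(partitions, function(p) {
    w <- IRanges::width(p@domains)
    data.frame(binSize = p@binSize, meanSizeBp = mean(w),
               meanSizeBins = mean(w / p@binSize), nTads = length(w))
  }))
  if (length(unique(df$binSize)) < 2L)
    stop("at least two distinct bin sizes are required to fit slopes")
  df <- df[order(df$binSize), , drop = FALSE]
  rownames(df) <- NULL
  list(summary = df,
       slopeBp = unname(stats::coef(stats::lm(meanSizeBp ~ binSize, df))[2L]),
       slopeBins = unname(stats::coef(stats::lm(meanSizeBins ~ binSize, df))[2L]))
}
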