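# Seeded generators of synthetic inputs with planted structure: TAD
# partitions (optionally nested), contact matrices with distance decay
# and within-TAD enrichment, boundary-enriched peak sets, mutually
# exclusive histone-mark tracks, and controlled partition perturbations.

.drawTiling <- function(cfg, minWidthBins) {
  B <- cfg@binSize
  L <- cfg@chromLength
  meanlog <- log(cfg@meanTadSize) - cfg@sizeSdlog^2 / 2
  starts <- numeric(); ends <- numeric()
  at <- 0
  while (at < L) {
    len <- stats::rlnorm(1, meanlog, cfg@sizeSdlog)
    len <- max(minWidthBins * B, round(len / B) * B)
    if (at + len > L || L - (at + len) < cfg@meanTadSize / 2) len <- L - at
    starts <- c(starts, at + 1)
    ends <- c(ends, at + len)
    at <- at + len
  }
  # a truncated remainder shorter than the minimum width is absorbed into
  # the previous domain
  n <- length(starts)
  if (n > 1L && (ends[n] - starts[n] + 1) < minWidthBins * B) {
    ends[n - 1L] <- ends[n]
    starts <- starts[-n]; ends <- ends[-n]
  }
  list(starts = starts, ends = ends)
}

#' Simulate a TAD partition (optionally with a planted hierarchy)
#'
#' Draws domain lengths from a log-normal distribution with mean
#' `meanTadSize` (bin-aligned, right-skewed like reported TAD-size
#' spreads) and tiles the chromosome contiguously; a terminal remainder
#' shorter than half the mean size is absorbed into the last domain, so
#' a mean equal to the chromosome length yields a single domain. With
#' `nLevels > 1` a laminar hierarchy is planted: each level-`i` domain
#' contains exactly one level-`(i - 1)` domain, inset by one bin on each
#' side, so every planted level has the same domain count and
#' [extractLevels()] recovers the levels exactly. Deterministic under a
#' fixed seed.
#'
#' @param cfg a [SimulationConfig-class].
#' @param seed integer seed.
#' @return for `nLevels = 1`, a [TadPartition-class] (the truth
#'   partition); otherwise a list with `partition` (the outermost
#'   tiling), `domains` (a [DomainSet-class] pooling all levels), and
#'   `levels` (list of [TadPartition-class], innermost first).
#' @export
simulatePartition <- function(cfg, seed = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  nl <- cfg@nLevels
  minWidth <- max(2L, 2L * (nl - 1L) + 1L)
  tl <- .withSeed(seed, .drawTiling(cfg, minWidth))
  top <- TadPartition(chrom = "chrS", starts = tl$starts, ends = tl$ends,
                      binSize = cfg@binSize, chromLength = cfg@chromLength,
                      label = "truth")
  if (nl == 1L) return(top)
  B <- cfg@binSize
  levels <- vector("list", nl)
  levels[[nl]] <- top
  for (k in seq(nl - 1L, 1L)) {
    inset <- (nl - k) * B
    levels[[k]] <- TadPartition(
      chrom = "chrS", starts = tl$starts + inset, ends = tl$ends - inset,
      binSize = B, chromLength = cfg@chromLength,
      label = sprintf("truth_L%d", k))
  }
  allS <- unlist(lapply(levels, function(p) IRanges::start(p@domains)))
  allE <- unlist(lapply(levels, function(p) IRanges::end(p@domains)))
  list(partition = top,
       domains = DomainSet("chrS", allS, allE, binSize = B, label = "truth"),
       levels = levels)
}

.binMembership <- function(p, n, B) {
  mids <- (seq_len(n) - 0.5) * B
  memb <- findInterval(mids, IRanges::start(p@domains))
  inD <- memb >= 1 & mids <= IRanges::end(p@domains)[pmax(memb, 1L)]
  memb[!inD] <- 0L
  memb
}

#' Simulate a contact matrix with planted domain structure
#'
#' Expected count for bin pair `(i, j)` is proportional to
#' `(1 + |i - j|)^(-alpha) * gamma^e`, where `e` is the number of truth
#' domains containing both bins (across levels when `truth` is a list of
#' partitions), implementing the premise that loci interact more
#' frequently within domains than across them. Expected counts are
#' scaled so their total equals `depth` and entries are drawn Poisson.
#'
#' @param cfg a [SimulationConfig-class].
#' @param truth a [TadPartition-class], or a list of them for nested
#'   enrichment (innermost first).
#' @param seed integer seed.
#' @return a [ContactMatrix-class].
#' @export
simulateContacts <- function(cfg, truth, seed = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (is(truth, "TadPartition")) truth <- list(truth)
  B <- cfg@binSize
  n <- as.integer(cfg@chromLength / B)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  w <- (1 + abs(j - i))^(-cfg@alpha)
  if (cfg@gamma != 1) {
    e <- integer(length(i))
    for (lvl in truth) {
      memb <- .binMembership(lvl, n, B)
      e <- e + as.integer(memb[i] != 0L & memb[i] == memb[j])
    }
    w <- w * cfg@gamma^e
  }
  if (cfg@depth == 0)
    return(contactMatrix(truth[[1L]]@chrom, B, n))
  lam <- w * (cfg@depth / sum(w))
  x <- .withSeed(seed, stats::rpois(length(lam), lam))
  keep <- x > 0
  contactMatrix(truth[[1L]]@chrom, B, n, i = i[keep], j = j[keep],
                x = x[keep])
}

#' Simulate a boundary-enriched peak set
#'
#' Background peaks follow a homogeneous Poisson process at
#' `backgroundPeakRate` peaks per bp; additional peaks are planted
#' within one bin of every truth boundary at `rho` times the background
#' rate (so `rho = 0` gives a uniform peak set and the total rate in
#' boundary windows is `(1 + rho)` times the background).
#'
#' @param cfg a [SimulationConfig-class].
#' @param truth a [TadPartition-class] (its unique boundaries are the
#'   planted enrichment sites); an empty partition yields background
#'   only.
#' @param seed integer seed.
#' @param peakWidth peak width in bp (default 200).
#' @return a [PeakSet-class].
#' @export
simulatePeaks <- function(cfg, truth, seed = NULL, peakWidth = 200) {
  stopifnot(is(cfg, "SimulationConfig"), is(truth, "TadPartition"))
  B <- cfg@binSize
  L <- cfg@chromLength
  .withSeed(seed, {
    nBg <- stats::rpois(1, cfg@backgroundPeakRate * L)
    mids <- stats::runif(nBg, 1, L)
    if (cfg@rho > 0 && nDomains(truth) > 0) {
      for (pos in boundariesOf(truth) * truth@binSize) {
        lo <- max(1, pos - B); hi <- min(L, pos + B)
        nEx <- stats::rpois(1, cfg@rho * cfg@backgroundPeakRate * (hi - lo))
        if (nEx > 0) mids <- c(mids, stats::runif(nEx, lo, hi))
      }
    }
    mids <- sort(mids)
    s <- pmax(1, round(mids - peakWidth / 2))
    peakSet(truth@chrom, s, pmin(L, s + peakWidth - 1), label = "simPeaks")
  })
}

#' Simulate mutually exclusive histone-mark tracks
#'
#' A fraction `markCoherence` of the truth TADs is randomly assigned a
#' dominant mark (one of the two, with equal probability); within such a
#' TAD the dominant track has mean signal `markHigh` and the other
#' `markLow`, with multiplicative log-normal noise per bin. The
#' remaining TADs and inter-TAD gaps are balanced at the midpoint of the
#' two means. Tracks cover the whole chromosome with bin-sized
#' intervals.
#'
#' @param cfg a [SimulationConfig-class].
#' @param truth a [TadPartition-class].
#' @param seed integer seed.
#' @return a list with `sig27`, `sig36` ([SignalTrack-class]) and
#'   `assignment` (data.frame: `start`, `end`, `mark` with values
#'   `"27"`, `"36"` or `"balanced"`).
#' @export
simulateMarks <- function(cfg, truth, seed = NULL) {
  stopifnot(is(cfg, "SimulationConfig"), is(truth, "TadPartition"))
  B <- cfg@binSize
  n <- as.integer(cfg@chromLength / B)
  .withSeed(seed, {
    memb <- .binMembership(truth, n, B)
    nT <- nDomains(truth)
    biased <- stats::runif(nT) < cfg@markCoherence
    dominant <- ifelse(biased, ifelse(stats::runif(nT) < 0.5, "27", "36"),
                       "balanced")
    balMean <- (cfg@markHigh + cfg@markLow) / 2
    mark <- ifelse(memb > 0L, dominant[pmax(memb, 1L)], "balanced")
    mu27 <- ifelse(mark == "27", cfg@markHigh,
                   ifelse(mark == "36", cfg@markLow, balMean))
    mu36 <- ifelse(mark == "36", cfg@markHigh,
                   ifelse(mark == "27", cfg@markLow, balMean))
    noise <- function(mu) mu * stats::rlnorm(n, -cfg@noiseSdlog^2 / 2,
                                             cfg@noiseSdlog)
    starts <- (seq_len(n) - 1) * B + 1
    ends <- seq_len(n) * B
    list(sig27 = signalTrack(truth@chrom, starts, ends, noise(mu27),
                             label = "H3K27me3_sim"),
         sig36 = signalTrack(truth@chrom, starts, ends, noise(mu36),
                             label = "H3K36me3_sim"),
         assignment = data.frame(
           start = IRanges::start(truth@domains),
           end = IRanges::end(truth@domains), mark = dominant))
  })
}

#' Perturb a partition by boundary jitter, splits and merges
#'
#' Moves every interior boundary by a uniform offset in
#' `[-jitterBins, jitterBins]` bins (clamped so domains keep at least
#' one bin and their order), then splits each domain at a random
#' interior junction with probability `splitProb`, then merges each
#' contiguous adjacent pair with probability `mergeProb` (scanning left
#' to right, so `mergeProb = 1` collapses a contiguous partition into a
#' single domain). The output is always a valid partition; with all
#' three perturbations zero the input is returned unchanged. Drives the
#' concordance-degradation harnesses.
#'
#' @param p a [TadPartition-class].
#' @param jitterBins maximum boundary displacement in bins.
#' @param splitProb per-domain split probability.
#' @param mergeProb per-junction merge probability.
#' @param seed integer seed.
#' @return a [TadPartition-class].
#' @export
perturbPartition <- function(p, jitterBins = 0, splitProb = 0,
                             mergeProb = 0, seed = NULL) {
  stopifnot(is(p, "TadPartition"), jitterBins >= 0,
            splitProb >= 0, splitProb <= 1, mergeProb >= 0, mergeProb <= 1)
  if (jitterBins == 0 && splitProb == 0 && mergeProb == 0) return(p)
  B <- p@binSize
  l <- (IRanges::start(p@domains) - 1) / B
  r <- IRanges::end(p@domains) / B
  .withSeed(seed, {
    edges <- sort(unique(c(l, r)))
    newE <- edges
    if (jitterBins > 0 && length(edges) > 2L) {
      for (k in 2:(length(edges) - 1L)) {
        off <- sample(seq.int(-jitterBins, jitterBins), 1L)
        newE[k] <- min(max(edges[k] + off, newE[k - 1L] + 1),
                       edges[k + 1L] - 1)
      }
    }
    li <- newE[match(l, edges)]
    ri <- newE[match(r, edges)]
    if (splitProb > 0) {
      nl <- numeric(); nr <- numeric()
      for (k in seq_along(li)) {
        if (ri[k] - li[k] >= 2 && stats::runif(1) < splitProb) {
          cut <- sample(seq.int(li[k] + 1, ri[k] - 1), 1L)
          nl <- c(nl, li[k], cut); nr <- c(nr, cut, ri[k])
        } else {
          nl <- c(nl, li[k]); nr <- c(nr, ri[k])
        }
      }
      li <- nl; ri <- nr
    }
    if (mergeProb > 0 && length(li) > 1L) {
      ml <- li[1L]; mr <- ri[1L]
      for (k in 2:length(li)) {
        if (li[k] == mr[length(mr)] && stats::runif(1) < mergeProb) {
          mr[length(mr)] <- ri[k]
        } else {
          ml <- c(ml, li[k]); mr <- c(mr, ri[k])
        }
      }
      li <- ml; ri <- mr
    }
    TadPartition(p@chrom, li * B + 1, ri * B, binSize = B,
                 chromLength = p@chromLength,
                 label = paste0(p@label, "_perturbed"))
  })
}
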