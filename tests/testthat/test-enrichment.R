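# Structural-protein profiles and fold changes at boundaries, tagged
# fractions, shared-vs-private enrichment, and histone-mark log-ratio
# significance.

# a partition with interior boundaries at least 500 kb from both ends
wideTruth <- function(nT = 10, B = 1e4, tadBins = 80, chrom = "chrT") {
  TadPartition(chrom, (0:(nT - 1)) * tadBins * B + 1, (1:nT) * tadBins * B,
               binSize = B, chromLength = nT * tadBins * B)
}

test_that("structural-protein profiles count peak midpoints per interval", {
  p <- wideTruth()
  empty <- peakSet("chrT", label = "none")
  spp <- sppProfile(p, empty)
  expect_true(all(spp$profiles == 0))
  expect_equal(length(spp$aggregate), 200L)

  # a single peak exactly at a boundary lands in one central interval
  pos <- boundariesOf(p)[3] * binSize(p)
  onepk <- peakSet("chrT", pos - 50, pos + 49, label = "one")
  spp1 <- sppProfile(p, onepk)
  hit <- which(spp1$profiles > 0, arr.ind = TRUE)
  expect_equal(nrow(hit), 1L)
  expect_true(hit[1, "col"] %in% c(100L, 101L))
  expect_equal(sum(spp1$profiles), 1)

  # boundaries within the window of the chromosome ends are dropped
  expect_equal(spp$nDropped, 2L)
  expect_equal(length(spp$positions), length(boundariesOf(p)) - 2L)

  # aggregate equals the mean of the per-boundary profiles
  cfg <- simulationConfig(chromLength = 8e6, rho = 0)
  pk <- simulatePeaks(cfg, wideTruth(), seed = 3)
  spp2 <- sppProfile(wideTruth(), pk)
  expect_equal(spp2$aggregate, colMeans(spp2$profiles))

  # uniform random peaks give a flat profile within Poisson noise
  lam <- length(peakRanges(pk)) / 8e6 * 5e3 * nrow(spp2$profiles)
  counts <- colSums(spp2$profiles)
  expect_true(all(abs(counts - lam) < 4 * sqrt(lam) + 4))
})

test_that("boundary fold change is calibrated and scale-invariant", {
  p <- wideTruth()
  cfg <- simulationConfig(chromLength = 8e6, rho = 0)
  pk <- simulatePeaks(cfg, p, seed = 13)
  fc <- boundaryFoldChange(p, pk)
  expect_lt(abs(fc$foldChange), 0.3)  # few boundaries, loose bound

  # duplicating every peak scales the profile but not the ratio
  pr <- peakRanges(pk)
  dbl <- peakSet("chrT", rep(IRanges::start(pr), 2), rep(IRanges::end(pr), 2))
  expect_equal(boundaryFoldChange(p, dbl)$foldChange, fc$foldChange,
               tolerance = 1e-12)

  # peaks only at boundaries: zero flanks, explicit sentinel
  ju <- boundariesOf(p) * binSize(p)
  ju <- ju[ju >= 1000]
  near <- peakSet("chrT", ju - 1000, ju + 1000)
  fcz <- boundaryFoldChange(p, near)
  expect_true(is.na(fcz$foldChange))
  expect_equal(fcz$nExcludedZeroFlank, length(fcz$perBoundary$position))

  # planted enrichment raises the fold change monotonically
  fcs <- sapply(c(0, 2, 6), function(r) {
    pkr <- simulatePeaks(simulationConfig(chromLength = 8e6, rho = r), p,
                         seed = 23)
    boundaryFoldChange(p, pkr)$foldChange
  })
  expect_true(all(diff(fcs) > 0))
})

test_that("tagged fraction checks the boundary bin and its neighbours", {
  p <- wideTruth(nT = 4)
  everywhere <- peakSet("chrT", seq(1, 3.2e6, 5e3), seq(1, 3.2e6, 5e3) + 4999)
  expect_equal(taggedFraction(p, everywhere)$fraction, 1)
  expect_equal(taggedFraction(p, peakSet("chrT"))$fraction, 0)

  # constructed case against a direct interval-overlap check
  B <- binSize(p)
  pk <- peakSet("chrT", c(100, 81 * B + 500), c(150, 81 * B + 600))
  tf <- taggedFraction(p, pk)
  ju <- boundariesOf(p)
  maxBin <- chromLength(p) / B
  expWin <- sapply(ju, function(j) {
    bin <- if (j < maxBin) j + 1 else maxBin
    lo <- (bin - 2) * B + 1; hi <- (bin + 1) * B
    any(c(100, 81 * B + 500) <= hi & c(150, 81 * B + 600) >= lo)
  })
  expect_equal(tf$tagged$tagged, expWin)
})

test_that("shared boundaries show higher fold change when peaks are planted
           at the consensus", {
  expect_error(sharedBoundaryEnrichment(list(wideTruth()), peakSet("chrT"),
                                        2), "at least two")
  truth <- wideTruth(nT = 12)
  # three callers: two reproduce the truth, one is shifted far off
  shifted <- perturbPartition(truth, jitterBins = 20, seed = 5)
  parts <- list(truth, perturbPartition(truth, jitterBins = 1, seed = 6),
                shifted)
  for (i in seq_along(parts)) parts[[i]]@label <- paste0("c", i)
  # CTCF-like peaks planted only at the truth boundaries
  cfg <- simulationConfig(chromLength = chromLength(truth), rho = 8)
  pk <- simulatePeaks(cfg, truth, seed = 7)
  sbe <- sharedBoundaryEnrichment(parts, pk, minCallers = 2, radiusBins = 2)
  tr <- sbe$trend
  expect_gt(tr$meanFoldChange[tr$class == "shared"],
            tr$meanFoldChange[tr$class == "not_shared"])

  # identical callers: every boundary is shared for any threshold <= N
  same <- lapply(1:3, function(i) {
    x <- truth; x@label <- paste0("s", i); x
  })
  sbe2 <- sharedBoundaryEnrichment(same, pk, minCallers = 3, radiusBins = 0)
  expect_true(all(sbe2$perCaller$n[sbe2$perCaller$class == "not_shared"] == 0))
})

test_that("histone LR significance behaves at the trivial fixed points", {
  cfg <- simulationConfig(chromLength = 8e6)
  tads <- simulatePartition(cfg, seed = 31)
  mk <- simulateMarks(cfg, tads, seed = 32)

  # identical tracks: every LR is exactly 0, nothing is significant
  same <- histoneLrSignificance(tads, mk$sig27, mk$sig27, seed = 33)
  expect_true(all(same$intervals$lr == 0))
  expect_equal(same$fractionSignificant, 0)

  # swapping the marks flips every LR sign and keeps the fraction
  a <- histoneLrSignificance(tads, mk$sig27, mk$sig36, seed = 34)
  b <- histoneLrSignificance(tads, mk$sig36, mk$sig27, seed = 34)
  expect_equal(a$intervals$lr, -b$intervals$lr, tolerance = 1e-12)
  expect_equal(a$fractionSignificant, b$fractionSignificant)

  # interval size is 10% of the mean TAD size, floored to a bin multiple
  meanSize <- mean(IRanges::width(domainRanges(tads)))
  expect_equal(a$params$intervalSize,
               max(binSize(tads),
                   floor(0.1 * meanSize / binSize(tads)) * binSize(tads)))

  # a track with gaps is rejected unless zero-filling is requested
  short <- signalTrack("chrS", 1, 4e6, 1, label = "short")
  expect_error(histoneLrSignificance(tads, short, mk$sig36, seed = 1),
               "cover")
  zf <- histoneLrSignificance(tads, short, mk$sig36, seed = 1,
                              gaps = "zero")
  expect_true(is.finite(zf$fractionSignificant))
})

test_that("planted mark bias is recovered and the null is controlled", {
  # strong exclusive marks in every TAD: without the +1 correction the
  # biased TADs reach p = 0 and the recovered fraction approaches the
  # planted one
  cfgS <- simulationConfig(chromLength = 2e7, markCoherence = 1,
                           markHigh = 10, markLow = 0.1, noiseSdlog = 0.1)
  fr <- sapply(1:5, function(s) {
    tp <- simulatePartition(cfgS, seed = s)
    mkS <- simulateMarks(cfgS, tp, seed = 100 + s)
    histoneLrSignificance(tp, mkS$sig27, mkS$sig36, seed = 200 + s,
                          correction = "none")$fractionSignificant
  })
  expect_gt(mean(fr), 0.9)

  # null marks: the FDR target is respected on average
  cfg0 <- simulationConfig(chromLength = 8e6, markCoherence = 0)
  fr0 <- sapply(1:20, function(s) {
    tp <- simulatePartition(cfg0, seed = s)
    mk0 <- simulateMarks(cfg0, tp, seed = 300 + s)
    histoneLrSignificance(tp, mk0$sig27, mk0$sig36,
                          seed = 400 + s)$fractionSignificant
  })
  mc <- sd(fr0) / sqrt(length(fr0))
  expect_lte(mean(fr0), 0.1 + 3 * mc)
})

test_that("peak-set intersection keeps regions covered by both inputs", {
  a <- peakSet("chr1", c(1, 100, 500), c(50, 200, 600), label = "r1")
  b <- peakSet("chr1", c(40, 150), c(120, 210), label = "r2")
  i <- intersectPeaks(a, b)
  expect_equal(IRanges::start(peakRanges(i)), c(40, 100, 150))
  expect_equal(IRanges::end(peakRanges(i)), c(50, 120, 200))
  expect_error(intersectPeaks(a, peakSet("chr2")), "different")
})
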