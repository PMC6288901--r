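# Measure of Concordance, conservation at a tolerance radius, shared
# boundaries, conservation ratio and size-scaling summaries.

test_that("MoC matches hand-evaluated values and its bounds", {
  p <- TadPartition("chr1", c(1, 41), c(40, 100), binSize = 1)
  q <- TadPartition("chr1", c(1, 51), c(50, 100), binSize = 1)
  # (0.8 + 1/30 + 5/6 - 1) / (sqrt(4) - 1) = 2/3
  expect_equal(moc(p, q), 2 / 3, tolerance = 1e-12)
  expect_identical(moc(p, p), 1)
  expect_identical(moc(q, q), 1)

  # one whole-span cluster vs many: the inner sum telescopes to 1
  one <- TadPartition("chr1", 1, 2e6, binSize = 1e5)
  many <- TadPartition("chr1", seq(1, 1.9e6 + 1, 1e5), seq(1e5, 2e6, 1e5),
                       binSize = 1e5)
  expect_identical(moc(one, many), 0)
  expect_identical(moc(many, one), 0)
  expect_identical(moc(one, one), 1)  # the N_P = N_Q = 1 branch

  expect_error(moc(p, TadPartition("chr2", 1, 100, binSize = 1)),
               "different chromosomes")
})

test_that("MoC is symmetric, bounded and agrees with the brute-force oracle", {
  set.seed(71)
  for (rep in 1:30) {
    p <- randomPartition()
    q <- randomPartition()
    m1 <- moc(p, q); m2 <- moc(q, p)
    expect_identical(m1, m2)
    expect_gte(m1, 0); expect_lte(m1, 1)
    expect_equal(m1, mocOracle(p, q), tolerance = 1e-12)
    expect_identical(moc(p, p), 1)
  }
  # different spans: the union span is used, tails become gap clusters
  a <- TadPartition("chr1", 1, 100, binSize = 100)
  b <- TadPartition("chr1", c(1, 101), c(100, 300), binSize = 100)
  expect_equal(moc(a, b), mocOracle(a, b), tolerance = 1e-12)
})

test_that("MoC degrades with boundary jitter on average", {
  cfg <- simulationConfig(chromLength = 5e6)
  means <- sapply(c(1, 5), function(j) {
    mean(sapply(1:15, function(s) {
      p <- simulatePartition(cfg, seed = s)
      moc(p, perturbPartition(p, jitterBins = j, seed = 1000 + s))
    }))
  })
  expect_gt(means[1], means[2])
})

test_that("boundary conservation respects the radius and the oracle", {
  p <- TadPartition("chr1", c(1, 101), c(100, 200), binSize = 100,
                    chromLength = 200)
  cb0 <- conservedBoundaries(p, p, 0)
  expect_true(all(cb0$a$conserved))
  expect_equal(cb0$fractionA, 1)

  # boundaries offset by exactly 3 bins: radius 2 finds none, radius 3 all
  a <- TadPartition("chr1", 1, 1000, binSize = 100, chromLength = 2000)
  b <- TadPartition("chr1", 301, 1300, binSize = 100, chromLength = 2000)
  expect_equal(conservedBoundaries(a, b, 2)$fractionA, 0)
  expect_equal(conservedBoundaries(a, b, 3)$fractionA, 1)

  expect_error(conservedBoundaries(
    a, TadPartition("chr1", 1, 1000, binSize = 200), 1), "bin sizes differ")

  set.seed(81)
  for (rep in 1:20) {
    p <- randomPartition(); q <- randomPartition()
    r <- sample(0:5, 1)
    cb <- conservedBoundaries(p, q, r)
    expect_equal(cb$a$conserved, conservedBoundariesOracle(p, q, r))
    expect_equal(cb$b$conserved, conservedBoundariesOracle(q, p, r))
    # fractions non-decreasing in the radius
    fr <- sapply(0:5, function(rr) conservedBoundaries(p, q, rr)$fractionA)
    expect_true(all(diff(fr) >= 0))
  }
})

test_that("TAD conservation requires both ends to match a single TAD", {
  p <- TadPartition("chr1", c(1, 101), c(100, 200), binSize = 100)
  ct <- conservedTads(p, p, 0)
  expect_true(all(ct$a$conserved))
  expect_equal(conservationRatio(p, p, 0), 1)

  # one TAD spanning two whose outer boundaries coincide is not conserved
  big <- TadPartition("chr1", 1, 200, binSize = 100)
  two <- TadPartition("chr1", c(1, 101), c(100, 200), binSize = 100)
  expect_false(conservedTads(big, two, 0)$a$conserved)

  disjoint <- TadPartition("chr1", 501, 700, binSize = 100,
                           chromLength = 1000)
  p2 <- TadPartition("chr1", 1, 200, binSize = 100, chromLength = 1000)
  expect_equal(conservationRatio(p2, disjoint, 0), 0)

  set.seed(91)
  for (rep in 1:20) {
    p <- randomPartition(); q <- randomPartition()
    r <- sample(0:5, 1)
    ct <- conservedTads(p, q, r)
    expect_equal(ct$a$conserved, conservedTadsOracle(p, q, r))
    expect_equal(ct$b$conserved, conservedTadsOracle(q, p, r))
    expect_equal(conservationRatio(p, q, r),
                 min(sum(conservedTadsOracle(p, q, r)),
                     sum(conservedTadsOracle(q, p, r))) /
                   min(nDomains(p), nDomains(q)))
  }
})

test_that("cross-resolution conservation checks the coarse boundary bin", {
  # a refinement retains every coarse boundary
  coarse <- TadPartition("chr1", c(1, 501), c(500, 1000), binSize = 500)
  fine <- TadPartition("chr1", c(1, 201, 501, 801), c(200, 500, 800, 1000),
                       binSize = 100)
  cr <- crossResolutionConserved(coarse, fine)
  expect_equal(cr$fraction, 1)

  # fine boundaries strictly interior to coarse domains, outside the
  # boundary bins
  fine2 <- TadPartition("chr1", c(601, 801), c(800, 900), binSize = 100,
                        chromLength = 2500)
  coarse2 <- TadPartition("chr1", c(1, 1501), c(1500, 2500), binSize = 500)
  expect_equal(crossResolutionConserved(coarse2, fine2)$fraction, 0)

  expect_error(crossResolutionConserved(coarse, coarse), "equal")
  expect_error(crossResolutionConserved(
    TadPartition("chr1", 1, 250, binSize = 250), fine), "multiple")

  # mixed case against a direct interval-membership oracle
  set.seed(101)
  for (rep in 1:10) {
    f <- 5; B <- 500
    coarse <- randomPartition(nBins = 10, B = B, gapProb = 0.2)
    fine <- randomPartition(nBins = 50, B = B / f, gapProb = 0.2)
    got <- crossResolutionConserved(coarse, fine)
    dfc <- as.data.frame(coarse)
    finePos <- sort(unique(c(as.data.frame(fine)$start,
                             as.data.frame(fine)$end)))
    expRec <- sapply(got$a$junction, function(j) {
      hit <- FALSE
      for (k in seq_len(nrow(dfc))) {
        if ((dfc$start[k] - 1) / B == j)
          hit <- hit || any(finePos >= dfc$start[k] &
                              finePos <= dfc$start[k] + B - 1)
        if (dfc$end[k] / B == j)
          hit <- hit || any(finePos >= dfc$end[k] - B + 1 &
                              finePos <= dfc$end[k])
      }
      hit
    })
    expect_equal(got$a$conserved, expRec)
  }
})

test_that("shared-boundary consolidation counts distinct callers", {
  p <- TadPartition("chr1", c(1, 101), c(100, 200), binSize = 100)
  sb <- sharedBoundaries(list(p, p, p), 0)
  expect_true(all(sb$clusters$nCallers == 3))

  a <- TadPartition("chr1", 1, 300, binSize = 100, chromLength = 1500)
  b <- TadPartition("chr1", 701, 1000, binSize = 100, chromLength = 1500)
  sb2 <- sharedBoundaries(list(a, b), 0)
  expect_true(all(sb2$clusters$nCallers == 1))

  expect_error(sharedBoundaries(list(p), 0), "at least two")

  # staggered offsets within the radius agree with a union-find oracle
  set.seed(111)
  for (rep in 1:10) {
    parts <- lapply(1:3, function(i) randomPartition(nBins = 40))
    r <- sample(1:3, 1)
    sb <- sharedBoundaries(parts, r)
    ju <- sort(unique(sb$assignments$junction))
    implCl <- sb$assignments$cluster[match(ju, sb$assignments$junction)]
    expect_equal(implCl, singleLinkOracle(ju, r))
    # every caller boundary is assigned to exactly one cluster
    expect_false(anyNA(sb$assignments$cluster))
  }
})

test_that("TAD size scaling yields the expected least-squares slopes", {
  # constant 10-bin TADs at every resolution
  mk <- function(B, nT = 12) {
    TadPartition("chr1", (0:(nT - 1)) * 10 * B + 1, (1:nT) * 10 * B,
                 binSize = B)
  }
  res <- sizeSummary(lapply(c(1e4, 5e4, 1e5, 2.5e5), mk))
  expect_equal(res$slopeBins, 0)
  expect_equal(res$slopeBp, 10)

  # closed-form OLS on four points
  Bs <- c(1e4, 5e4, 1e5, 2.5e5)
  means <- c(3e5, 5e5, 1.1e6, 2e6)
  parts <- mapply(function(B, m) {
    TadPartition("chr1", 1, round(m / B) * B, binSize = B)
  }, Bs, means)
  res2 <- sizeSummary(parts)
  mb <- sapply(parts, function(p) mean(IRanges::width(domainRanges(p))))
  slopeHand <- sum((Bs - mean(Bs)) * (mb - mean(mb))) / sum((Bs - mean(Bs))^2)
  expect_equal(res2$slopeBp, slopeHand)

  expect_error(sizeSummary(list(mk(1e4), mk(1e4))), "two distinct")
})
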