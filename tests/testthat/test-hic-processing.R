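# Map-resolution selection, subsampling, and the two normalization
# procedures.

test_that("map resolution follows the 80%/1000-contacts rule", {
  # every 10-kb bin at 1500 contacts: smallest candidate qualifies
  cm <- diagonalMatrix(rep(1500, 20))
  expect_equal(resolutionFor(cm, c(1e4, 5e4)), 1e4)

  # all-zero matrix never qualifies
  z <- contactMatrix("chr1", 1e4, 20)
  expect_true(is.na(resolutionFor(z, c(1e4, 5e4, 1e5))))

  # candidates must be multiples of the base bin size
  expect_error(resolutionFor(cm, c(15000)), "multiple")
  expect_error(resolutionFor(cm, c(5e4, 1e4)), "ascending")

  # 75% of 10-kb bins but 95% of 50-kb bins qualify -> 50 kb
  vals <- rep(1200, 100)
  vals[96:100] <- 0                      # coarse bin 20 fails entirely
  vals[seq(4, 80, by = 4)] <- 0          # 20 more zeros spread over 1-16
  cm2 <- diagonalMatrix(vals)
  # confirm the construction by brute force on the dense marginals
  dense <- as.matrix(contactCounts(cm2))
  dense <- dense + t(dense) - diag(diag(dense))
  margFine <- rowSums(dense)
  expect_equal(mean(margFine >= 1000), 0.75)
  margCoarse <- sapply(1:20, function(k)
    sum(margFine[((k - 1) * 5 + 1):(k * 5)]))
  expect_equal(mean(margCoarse >= 1000), 0.95)
  expect_equal(resolutionFor(cm2, c(1e4, 5e4)), 5e4)

  # property: if a bin size qualifies, so does every larger candidate
  set.seed(41)
  for (rep in 1:10) {
    n <- 60
    idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    x <- rpois(nrow(idx), 40 * runif(1, 0.5, 2))
    keep <- x > 0
    cmr <- contactMatrix("chr1", 1e4, n, i = idx[keep, 1], j = idx[keep, 2],
                         x = x[keep])
    cands <- c(1e4, 2e4, 3e4, 6e4)
    qual <- sapply(cands, function(B)
      !is.na(resolutionFor(cmr, B, minContacts = 1500)))
    expect_true(all(diff(qual) >= 0))
  }
})

test_that("subsampling is binomial thinning, seeded and mean-preserving", {
  big <- contactMatrix("chr1", 1e4, 2, i = 1, j = 2, x = 1e6)
  expect_identical(subsampleContacts(big, 1), big)
  s <- subsampleContacts(big, 0.5, seed = 5)
  # within 3 binomial standard deviations of n * p
  expect_lt(abs(totalReads(s) - 5e5), 3 * sqrt(1e6 * 0.25))
  expect_equal(totalReads(subsampleContacts(big, 0.5, seed = 5)),
               totalReads(s))

  empty <- contactMatrix("chr1", 1e4, 4)
  expect_equal(totalReads(subsampleContacts(empty, 0.01, seed = 1)), 0)

  expect_error(subsampleContacts(big, 0), "fraction")
  expect_error(subsampleContacts(big, 1.2), "fraction")
  frac <- contactMatrix("chr1", 1e4, 2, i = 1, j = 2, x = 1.5)
  expect_error(subsampleContacts(frac, 0.5), "integer")

  # expectation preserved over replicates
  mid <- contactMatrix("chr1", 1e4, 3, i = c(1, 2, 3), j = c(2, 3, 3),
                       x = c(4000, 6000, 2000))
  tot <- sapply(1:40, function(s) totalReads(subsampleContacts(mid, 0.3,
                                                               seed = s)))
  expect_lt(abs(mean(tot) - 0.3 * totalReads(mid)),
            3 * sqrt(totalReads(mid) * 0.3 * 0.7 / 40))
})

test_that("iterative correction balances rows and factorises biases", {
  # constant matrix is a fixed point: unit biases, output equal to input
  # up to a global scale
  n <- 6
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  const <- contactMatrix("chr1", 1, n, i = idx[, 1], j = idx[, 2],
                         x = rep(2, nrow(idx)))
  res <- iceNormalize(const)
  expect_equal(res$bias / res$bias[1], rep(1, n))
  ratio <- as.matrix(contactCounts(res$matrix)) /
    as.matrix(contactCounts(const))
  expect_equal(max(ratio[idx]) / min(ratio[idx]), 1, tolerance = 1e-10)

  # 3x3 worked example converges to equal row sums
  cm <- contactMatrix("chr1", 1, 3, i = c(1, 1, 2), j = c(2, 3, 3),
                      x = c(2, 4, 8))
  r <- iceNormalize(cm, tol = 1e-12)
  expect_true(r$converged)
  W <- as.matrix(contactCounts(r$matrix))
  W <- W + t(W) - diag(diag(W))
  rs <- rowSums(W)
  expect_lt(max(rs) - min(rs), 1e-4 * mean(rs))
  # bias factorisation reproduces the raw matrix
  raw <- W * outer(r$bias, r$bias)
  rawIn <- as.matrix(contactCounts(cm))
  rawIn <- rawIn + t(rawIn) - diag(diag(rawIn))
  expect_equal(raw / rawIn[1, 2] * rawIn[1, 2], rawIn, tolerance = 1e-6)

  # an empty row is masked and the rest balanced
  hole <- contactMatrix("chr1", 1, 4, i = c(1, 1, 2), j = c(2, 4, 4),
                        x = c(3, 5, 7))
  rh <- iceNormalize(hole, tol = 1e-12)
  expect_true(is.na(rh$bias[3]))
  Wh <- as.matrix(contactCounts(rh$matrix))
  Wh <- Wh + t(Wh) - diag(diag(Wh))
  rsh <- rowSums(Wh)[-3]
  expect_lt((max(rsh) - min(rsh)) / mean(rsh), 1e-3)

  expect_error(iceNormalize(contactMatrix("chr1", 1, 3)), "all-zero")

  # random positive matrices: symmetric output, row-sum CV below 1e-3
  set.seed(51)
  for (rep in 1:3) {
    nn <- sample(30:120, 1)
    M <- matrix(runif(nn * nn, 0.1, 5), nn, nn)
    M <- (M + t(M)) / 2
    tu <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
    cmr <- contactMatrix("chr1", 1, nn, i = tu[, 1], j = tu[, 2],
                         x = M[tu])
    rr <- iceNormalize(cmr)
    Wr <- as.matrix(contactCounts(rr$matrix))
    Wr <- Wr + t(Wr) - diag(diag(Wr))
    expect_true(isSymmetric(Wr))
    rs <- rowSums(Wr)
    expect_lt(sd(rs) / mean(rs), 1e-3)
  }
})

test_that("local-genomic-feature regression recovers planted coefficients", {
  set.seed(61)
  n <- 80
  cov <- binCovariates(mappability = runif(n, 0.5, 1),
                       gc = runif(n, 0.3, 0.7),
                       fragLength = runif(n, 200, 800))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  lenT <- log(cov@fragLength[idx[, 1]] * cov@fragLength[idx[, 2]])
  gcT <- log(cov@gc[idx[, 1]] * cov@gc[idx[, 2]])
  mapT <- log(cov@mappability[idx[, 1]] * cov@mappability[idx[, 2]])
  beta <- c(intercept = 2, fragLength = 0.35, gc = 0.9)
  # large-count regime so the MLE is tight
  y <- rpois(nrow(idx), exp(beta[1] + 6 + beta[2] * lenT + beta[3] * gcT +
                              mapT))
  cm <- contactMatrix("chr1", 1e4, n, i = idx[, 1], j = idx[, 2], x = y)
  fit <- lgfNormalize(cm, cov)
  expect_lt(abs(fit$coefficients[["fragLength"]] - beta[["fragLength"]]),
            1e-3)
  expect_lt(abs(fit$coefficients[["gc"]] - beta[["gc"]]), 1e-3)
  expect_true(isNormalized(fit$matrix))
  # ratio residuals hover around 1 for the fitted model
  expect_equal(mean(fit$matrix@counts@x), 1, tolerance = 0.01)

  # identical covariates: intercept-only fit, output proportional to input
  flat <- binCovariates(rep(0.8, n), rep(0.5, n), rep(400, n))
  expect_warning(f2 <- lgfNormalize(cm, flat), "zero-variance")
  expect_setequal(f2$dropped, c("fragLength", "gc"))
  m0 <- as.matrix(contactCounts(cm)); m1 <- as.matrix(contactCounts(f2$matrix))
  expect_equal(m1 / sum(m1), m0 / sum(m0), tolerance = 1e-12)

  # pearson residuals can be negative, so no ContactMatrix is returned
  pr <- suppressWarnings(lgfNormalize(cm, flat, residuals = "pearson"))
  expect_null(pr$matrix)
  expect_true(any(pr$residuals@x < 0))

  expect_error(lgfNormalize(contactMatrix("chr1", 1e4, n), cov), "empty")
  expect_error(lgfNormalize(cm, binCovariates(0.5, 0.5, 400)), "per bin")
})
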