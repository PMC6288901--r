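# Hi-C preprocessing: bin aggregation, map-resolution selection,
# binomial read subsampling, and the two normalization procedures
# (iterative correction; Poisson regression on local genomic features).

#' Aggregate a contact matrix to a larger bin size
#'
#' Sums counts of base-resolution bin pairs into coarse bins. The new bin
#' size must be a multiple of the current one; the last coarse bin may
#' cover fewer base bins.
#'
#' @param cm a [ContactMatrix-class].
#' @param newBinSize target bin size in bp.
#' @return a [ContactMatrix-class] at `newBinSize`.
#' @export
aggregateBins <- function(cm, newBinSize) {
  stopifnot(is(cm, "ContactMatrix"))
  if (newBinSize %% cm@binSize != 0)
    stop(sprintf("new bin size %.0f is not a multiple of the base bin size %.0f",
                 newBinSize, cm@binSize))
  f <- newBinSize / cm@binSize
  if (f == 1) return(cm)
  tm <- methods::as(cm@counts, "TsparseMatrix")
  nb <- as.integer(ceiling(cm@nBins / f))
  contactMatrix(cm@chrom, newBinSize, nb,
                i = ceiling((tm@i + 1L) / f), j = ceiling((tm@j + 1L) / f),
                x = tm@x, normalized = cm@normalized)
}

#' Select the map resolution by the 80% / 1000-contacts rule
#'
#' The map resolution of a contact matrix is the smallest bin size such
#' that at least `minFraction` (default 80%) of the bins make at least
#' `minContacts` (default 1000) contacts. The marginal contact count of a
#' bin is its row sum in the symmetric matrix with the diagonal counted
#' once, and the denominator is all bins in the chromosome span at the
#' candidate size (bins overlapping `exclude` are removed from both
#' counts).
#'
#' @param cm a [ContactMatrix-class] at the base bin size.
#' @param candidateBins ascending candidate bin sizes (bp), each a
#'   multiple of the base bin size.
#' @param minContacts minimum marginal contact count per bin.
#' @param minFraction minimum fraction of qualifying bins.
#' @param exclude optional [IRanges::IRanges] of genomic regions whose
#'   bins are excluded from the rule.
#' @return the smallest qualifying candidate bin size, or `NA` if none
#'   qualifies.
#' @examples
#' cm <- contactMatrix("chr1", 10000, 4, i = 1:4, j = 1:4,
#'                     x = rep(1500, 4))
#' resolutionFor(cm, c(10000, 50000))  # 10000
#' @export
resolutionFor <- function(cm, candidateBins, minContacts = 1000,
                          minFraction = 0.8, exclude = NULL) {
  stopifnot(is(cm, "ContactMatrix"))
  if (is.unsorted(candidateBins))
    stop("'candidateBins' must be ascending")
  for (B in candidateBins) {
    agg <- aggregateBins(cm, B)
    marg <- .marginals(agg)
    keep <- rep(TRUE, agg@nBins)
    if (!is.null(exclude) && length(exclude)) {
      binRanges <- IRanges::IRanges(start = (seq_len(agg@nBins) - 1) * B + 1,
                                    width = B)
      keep <- !IRanges::overlapsAny(binRanges, exclude)
    }
    if (!any(keep)) next
    if (mean(marg[keep] >= minContacts) >= minFraction) return(B)
  }
  NA_real_
}

#' Subsample a contact matrix to a fraction of its reads
#'
#' Binomial thinning of the binned counts: each contact is retained
#' independently with probability `fraction`, so each entry `n` becomes a
#' `Binomial(n, fraction)` draw and the retained total has expectation
#' `fraction * totalReads`. Equivalent in distribution to subsampling the
#' read-pair list before binning. Deterministic under a fixed seed.
#'
#' @param cm a [ContactMatrix-class] with integer counts.
#' @param fraction retention probability in `(0, 1]`.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return a [ContactMatrix-class]; `fraction = 1` returns `cm` unchanged.
#' @export
subsampleContacts <- function(cm, fraction, seed = NULL) {
  stopifnot(is(cm, "ContactMatrix"))
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]")
  if (any(cm@counts@x != floor(cm@counts@x)))
    stop("subsampling requires integer (raw) counts")
  if (fraction == 1) return(cm)
  tm <- methods::as(cm@counts, "TsparseMatrix")
  x <- .withSeed(seed, stats::rbinom(length(tm@x), size = as.integer(tm@x),
                                     prob = fraction))
  keep <- x > 0
  contactMatrix(cm@chrom, cm@binSize, cm@nBins,
                i = tm@i[keep] + 1L, j = tm@j[keep] + 1L, x = x[keep],
                normalized = cm@normalized)
}

#' Iterative correction (matrix balancing) of a contact matrix
#'
#' Assumes equal visibility of every bin: observed counts factorise into
#' bin biases times true contact probabilities. Each iteration divides
#' every row by its mean (restricted to unmasked bins), accumulates the
#' per-bin biases, and stops when the variance of the log bias update is
#' negligible (below `tol`) or after `maxIter` iterations. Bins with zero
#' marginal count are masked and left untouched. At convergence the
#' unmasked row sums of the output are equal up to a small relative
#' tolerance, and `raw[i, j] = normalized[i, j] * bias[i] * bias[j]` up to
#' a global scale.
#'
#' @param cm a [ContactMatrix-class] with symmetric (upper-triangle
#'   stored) counts.
#' @param maxIter maximum number of iterations.
#' @param tol convergence threshold on the variance of the log bias
#'   update.
#' @return a list with elements `matrix` (normalized
#'   [ContactMatrix-class]), `bias` (per-bin bias vector, `NA` for masked
#'   bins), `iterations`, and `converged`.
#' @examples
#' cm <- contactMatrix("chr1", 1, 3, i = c(1, 1, 2), j = c(2, 3, 3),
#'                     x = c(2, 4, 8))
#' res <- iceNormalize(cm)
#' res$bias
#' @export
iceNormalize <- function(cm, maxIter = 1000, tol = 1e-5) {
  stopifnot(is(cm, "ContactMatrix"))
  W <- .denseSymmetric(cm)
  n <- nrow(W)
  mask <- rowSums(W) == 0
  if (all(mask)) stop("cannot balance an all-zero matrix")
  idx <- which(!mask)
  Wu <- W[idx, idx, drop = FALSE]
  bias <- rep(NA_real_, n)
  bias[idx] <- 1
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    s <- rowMeans(Wu)
    s <- s / mean(s)
    Wu <- Wu / outer(s, s)
    bias[idx] <- bias[idx] * s
    if (stats::var(log(s)) < tol) { converged <- TRUE; break }
  }
  W[idx, idx] <- Wu
  list(matrix = .fromDense(cm, W, normalized = TRUE), bias = bias,
       iterations = it, converged = converged)
}

#' Normalization by Poisson regression on local genomic features
#'
#' Models the three systematic bias sources of a Hi-C experiment —
#' mappability, GC content, and restriction fragment length — with a
#' log-linear Poisson regression of the pairwise counts
#' (HiCNorm-style): for a bin pair `(i, j)`,
#' `log E[y_ij] = b0 + b_len * log(len_i * len_j) + b_gc * log(gc_i * gc_j)`
#' with `log(map_i * map_j)` as offset. The normalized matrix holds the
#' residuals of the fit: by default the observed/fitted ratio; raw
#' Pearson residuals `(y - mu) / sqrt(mu)` are available as an option
#' (they can be negative, so they are returned as a plain sparse matrix
#' rather than a [ContactMatrix-class]).
#'
#' The fit uses every off-diagonal upper-triangle bin pair, including
#' zeros. Bins with non-positive mappability, GC, or fragment length are
#' masked; their pairs are excluded from the fit and left at zero.
#' Covariates with zero variance across unmasked bins carry no
#' information and are dropped from the model with a warning naming them
#' (with all covariates constant the model reduces to an intercept and
#' the output is proportional to the input).
#'
#' @param cm a [ContactMatrix-class] with integer counts.
#' @param covariates a [BinCovariates-class] aligned to the bins of `cm`.
#' @param residuals `"ratio"` (default) or `"pearson"`.
#' @return a list with elements `matrix` (normalized
#'   [ContactMatrix-class] of ratio residuals, or `NULL` for
#'   `residuals = "pearson"`), `residuals` (sparse upper-triangle residual
#'   matrix), `coefficients` (fitted regression coefficients), `dropped`
#'   (names of zero-variance covariates removed), and `residualType`.
#' @export
lgfNormalize <- function(cm, covariates, residuals = c("ratio", "pearson")) {
  stopifnot(is(cm, "ContactMatrix"), is(covariates, "BinCovariates"))
  residuals <- match.arg(residuals)
  n <- cm@nBins
  if (length(covariates@mappability) != n)
    stop("covariates must have one record per bin (", n, " bins)")
  if (cm@totalReads == 0 || n < 2L)
    stop("cannot normalize an empty contact matrix")
  usable <- covariates@mappability > 0 & covariates@gc > 0 &
    covariates@fragLength > 0
  if (sum(usable) < 2L) stop("fewer than two bins with usable covariates")
  idx <- which(usable)
  pairs <- which(upper.tri(matrix(0, length(idx), length(idx))), arr.ind = TRUE)
  bi <- idx[pairs[, 1L]]
  bj <- idx[pairs[, 2L]]
  dense <- .denseSymmetric(cm)
  y <- dense[cbind(bi, bj)]
  terms <- list(
    fragLength = log(covariates@fragLength[bi] * covariates@fragLength[bj]),
    gc = log(covariates@gc[bi] * covariates@gc[bj]))
  off <- log(covariates@mappability[bi] * covariates@mappability[bj])
  dropped <- names(terms)[vapply(terms, function(v) stats::var(v) == 0,
                                 logical(1))]
  if (length(dropped))
    warning("zero-variance covariate(s) dropped from the model: ",
            paste(dropped, collapse = ", "))
  keepTerms <- setdiff(names(terms), dropped)
  dat <- data.frame(y = y, off = off)
  for (nm in keepTerms) dat[[nm]] <- terms[[nm]]
  form <- stats::as.formula(paste(
    "y ~", if (length(keepTerms)) paste(keepTerms, collapse = " + ") else "1",
    "+ offset(off)"))
  fit <- stats::glm(form, family = stats::poisson(), data = dat)
  mu <- stats::fitted(fit)
  res <- switch(residuals, ratio = y / mu, pearson = (y - mu) / sqrt(mu))
  keep <- res != 0
  resMat <- Matrix::sparseMatrix(i = bi[keep], j = bj[keep], x = res[keep],
                                 dims = c(n, n))
  out <- list(matrix = NULL,
              residuals = methods::as(resMat, "CsparseMatrix"),
              coefficients = stats::coef(fit), dropped = dropped,
              residualType = residuals)
  if (residuals == "ratio") {
    tm <- methods::as(resMat, "TsparseMatrix")
    out$matrix <- contactMatrix(cm@chrom, cm@binSize, n, i = tm@i + 1L,
                                j = tm@j + 1L, x = tm@x, normalized = TRUE)
  }
  out
}
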