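# Independent brute-force oracles and random-instance generators used by
# the property-style tests. Everything here works on plain data.frames /
# vectors with explicit loops, independently of the package's IRanges-
# based code paths.

# clusters (domains + gaps) of a partition over [1, span] as a data.frame
clustersOracle <- function(df, span) {
  out <- data.frame(start = numeric(), end = numeric())
  at <- 1
  for (k in seq_len(nrow(df))) {
    if (df$start[k] > at)
      out <- rbind(out, data.frame(start = at, end = df$start[k] - 1))
    out <- rbind(out, data.frame(start = df$start[k], end = df$end[k]))
    at <- df$end[k] + 1
  }
  if (at <= span) out <- rbind(out, data.frame(start = at, end = span))
  out
}

mocOracle <- function(p, q) {
  dp <- as.data.frame(p); dq <- as.data.frame(q)
  span <- max(c(dp$end, dq$end,
                if (!is.na(chromLength(p))) chromLength(p),
                if (!is.na(chromLength(q))) chromLength(q)))
  cp <- clustersOracle(dp, span)
  cq <- clustersOracle(dq, span)
  nP <- nrow(cp); nQ <- nrow(cq)
  if (nP == 1 && nQ == 1) return(1)
  s <- 0
  for (i in seq_len(nP)) for (j in seq_len(nQ)) {
    ov <- min(cp$end[i], cq$end[j]) - max(cp$start[i], cq$start[j]) + 1
    if (ov > 0)
      s <- s + ov^2 / ((cp$end[i] - cp$start[i] + 1) *
                         (cq$end[j] - cq$start[j] + 1))
  }
  (s - 1) / (sqrt(nP * nQ) - 1)
}

junctionsOracle <- function(p) {
  df <- as.data.frame(p)
  B <- binSize(p)
  sort(unique(c((df$start - 1) / B, df$end / B)))
}

conservedBoundariesOracle <- function(p, q, r) {
  jp <- junctionsOracle(p); jq <- junctionsOracle(q)
  sapply(jp, function(a) any(abs(jq - a) <= r))
}

conservedTadsOracle <- function(p, q, r) {
  dp <- as.data.frame(p); dq <- as.data.frame(q)
  B <- binSize(p)
  sapply(seq_len(nrow(dp)), function(i) {
    hits <- 0
    for (j in seq_len(nrow(dq))) {
      if (abs((dq$start[j] - 1) / B - (dp$start[i] - 1) / B) <= r &&
          abs(dq$end[j] / B - dp$end[i] / B) <= r)
        hits <- hits + 1
    }
    hits == 1
  })
}

# single-linkage clustering of junctions within a radius, by union-find
singleLinkOracle <- function(ju, r) {
  n <- length(ju)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(ju[i] - ju[j]) <= r && comp[i] != comp[j]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp[order(ju)]))
}

# nesting level per domain = longest containment chain below it, computed
# by fixpoint relaxation over an explicit containment matrix
hierarchyOracle <- function(starts, ends) {
  n <- length(starts)
  contains <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && starts[j] >= starts[i] && ends[j] <= ends[i] &&
        !(starts[j] == starts[i] && ends[j] == ends[i]))
      contains[i, j] <- TRUE
  }
  lev <- rep(1L, n)
  repeat {
    new <- sapply(seq_len(n), function(i) {
      kids <- which(contains[i, ])
      if (length(kids)) max(lev[kids]) + 1L else 1L
    })
    if (identical(new, lev)) break
    lev <- new
  }
  lev
}

# random bin-aligned partition, optionally with inter-TAD gaps
randomPartition <- function(nBins = 60, B = 1e4, maxSegments = 8,
                            gapProb = 0.3, chrom = "chr1") {
  k <- sample(2:maxSegments, 1)
  cuts <- sort(sample(seq_len(nBins - 1), k - 1))
  lo <- c(0, cuts); hi <- c(cuts, nBins)
  isDom <- runif(length(lo)) > gapProb
  if (!any(isDom)) isDom[sample(length(lo), 1)] <- TRUE
  TadPartition(chrom, lo[isDom] * B + 1, hi[isDom] * B, binSize = B,
               chromLength = nBins * B)
}

# random laminar (perfectly nested) family over [0, nBins] junctions
randomLaminar <- function(nBins = 120, B = 1e4, depth = 3, chrom = "chr1") {
  acc <- new.env(); acc$s <- numeric(); acc$e <- numeric()
  rec <- function(l, r, d) {
    acc$s <- c(acc$s, l); acc$e <- c(acc$e, r)
    if (d <= 0 || r - l < 4) return()
    nKids <- sample(2:3, 1)
    cuts <- sort(sample(seq(l + 1, r - 1), nKids - 1))
    kl <- c(l, cuts); kr <- c(cuts, r)
    for (k in seq_along(kl))
      if (runif(1) < 0.7) rec(kl[k], kr[k], d - 1)
  }
  nTop <- sample(2:4, 1)
  cuts <- sort(sample(seq_len(nBins - 1), nTop - 1))
  tl <- c(0, cuts); tr <- c(cuts, nBins)
  for (k in seq_along(tl)) rec(tl[k], tr[k], depth - 1)
  DomainSet(chrom, acc$s * B + 1, acc$e * B, binSize = B)
}

# contact matrix where exactly nPass of n base bins reach the marginal
# threshold, built from diagonal-only entries
diagonalMatrix <- function(vals, B = 1e4, chrom = "chr1") {
  n <- length(vals)
  keep <- vals > 0
  contactMatrix(chrom, B, n, i = which(keep), j = which(keep),
                x = vals[keep])
}
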