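# Internal helpers shared across modules.

# Genomic span covered by a partition: [1, chromLength], falling back to
# the last domain end when the chromosome length is unknown.
.spanEnd <- function(p) {
  if (!is.na(p@chromLength)) return(p@chromLength)
  if (length(p@domains)) max(IRanges::end(p@domains)) else 0
}

# A boundary is a junction between bins: junction j sits between bin j and
# bin j + 1, i.e. at genomic offset j * binSize. Junction 0 is the
# chromosome-start edge. A domain [s, e] contributes its left junction
# (s - 1) / B and its right junction e / B.
.junctionTable <- function(p) {
  d <- p@domains
  B <- p@binSize
  if (!length(d))
    return(data.frame(domain = integer(), side = character(),
                      junction = numeric(), pos = numeric()))
  lj <- (IRanges::start(d) - 1) / B
  rj <- IRanges::end(d) / B
  out <- data.frame(
    domain = rep(seq_along(d), 2L),
    side = rep(c("start", "end"), each = length(d)),
    junction = c(lj, rj))
  out$pos <- out$junction * B
  out[order(out$junction, out$domain), , drop = FALSE]
}

# Map a junction to its representative bin: the bin to its right, except
# for the last junction of the chromosome span which keeps the bin to its
# left (there is no bin beyond it).
.junctionBin <- function(junction, maxBin) {
  ifelse(junction < maxBin, junction + 1, maxBin)
}

# Seed an expression locally without clobbering the caller's RNG stream
# beyond the call (generators are deterministic under a fixed seed).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.finite(seed)) stop("'seed' must be a finite integer")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Symmetrise the stored upper triangle into a dense matrix (diagonal once).
.denseSymmetric <- function(cm) {
  m <- as.matrix(cm@counts)
  m + t(m) - diag(diag(m), nrow = nrow(m))
}

# Rebuild a ContactMatrix from a dense symmetric matrix, keeping the upper
# triangle only.
.fromDense <- function(cm, dense, normalized = cm@normalized) {
  dense[lower.tri(dense)] <- 0
  sp <- methods::as(methods::as(Matrix::Matrix(dense, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  methods::new("ContactMatrix", chrom = cm@chrom, binSize = cm@binSize,
               nBins = cm@nBins, counts = sp, normalized = normalized,
               totalReads = sum(sp@x))
}

# Marginal contact count per bin: row sum of the symmetric matrix with the
# diagonal counted once ("contacts made by a bin").
.marginals <- function(cm) {
  m <- cm@counts
  as.numeric(Matrix::rowSums(m) + Matrix::colSums(m) - Matrix::diag(m))
}
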