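# Reading, validating and writing the interval/track/matrix formats the
# toolkit touches. Internal convention: 1-based closed coordinates.
# BED and bedGraph are 0-based half-open on disk and converted on read
# (rtracklayer does the conversion) and on write.

.readTabular <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  sep <- if (grepl(",", lines[1L])) "," else ""
  con <- textConnection(lines)
  on.exit(close(con))
  df <- tryCatch(
    utils::read.table(con, sep = sep, header = FALSE,
                      stringsAsFactors = FALSE, fill = FALSE),
    error = function(e) stop("malformed ", what, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  df
}

#' Read a TAD partition from three-column text
#'
#' Reads caller output in the uniform three-column format
#' `chrom start end` (tab-, whitespace- or comma-separated; autodetected;
#' `#` comment lines ignored) with 1-based closed coordinates, e.g.
#' `chr1 1 10000` followed by `chr1 10001 20000`. The rows are sorted and
#' validated: overlapping domains and coordinates not aligned to
#' `binSize` are rejected with an informative error.
#'
#' @param path file path.
#' @param binSize bin size in bp of the matrix the TADs were called on.
#' @param chromLength optional chromosome length in bp.
#' @param chrom restrict a multi-chromosome file to this chromosome; by
#'   default the file must contain a single chromosome.
#' @param label free-text identifier stored in the object.
#' @return a [TadPartition-class]; an empty file yields an empty partition.
#' @seealso [writePartition()], [readDomainSet()]
#' @export
readPartition <- function(path, binSize, chromLength = NA_real_,
                          chrom = NULL, label = basename(path)) {
  df <- .readTabular(path, "partition")
  if (!nrow(df))
    return(TadPartition(chrom = if (is.null(chrom)) "chr" else chrom,
                        binSize = binSize, chromLength = chromLength,
                        label = label))
  if (ncol(df) < 3L) stop("partition file must have 3 columns (chrom, start, end)")
  names(df)[1:3] <- c("chrom", "start", "end")
  s <- suppressWarnings(as.numeric(df$start))
  e <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop("malformed partition row(s): ", paste(bad, collapse = ", "))
  df$start <- s; df$end <- e
  if (!is.null(chrom)) df <- df[df$chrom == chrom, , drop = FALSE]
  chroms <- unique(df$chrom)
  if (length(chroms) > 1L)
    stop("file contains multiple chromosomes (", paste(chroms, collapse = ", "),
         "); read them one at a time with the 'chrom' argument")
  TadPartition(chrom = chroms, starts = df$start, ends = df$end,
               binSize = binSize, chromLength = chromLength, label = label)
}

#' Read a possibly nested/overlapping domain set
#'
#' Like [readPartition()] but without the non-overlap requirement, for the
#' output of hierarchical or overlapping callers. Input to
#' [extractLevels()].
#'
#' @inheritParams readPartition
#' @return a [DomainSet-class].
#' @export
readDomainSet <- function(path, binSize, chrom = NULL,
                          label = basename(path)) {
  df <- .readTabular(path, "domain")
  if (!nrow(df))
    return(DomainSet(chrom = if (is.null(chrom)) "chr" else chrom,
                     binSize = binSize, label = label))
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(chrom)) df <- df[df$chrom == chrom, , drop = FALSE]
  chroms <- unique(df$chrom)
  if (length(chroms) > 1L)
    stop("file contains multiple chromosomes (", paste(chroms, collapse = ", "),
         "); read them one at a time with the 'chrom' argument")
  DomainSet(chrom = chroms, starts = df$start, ends = df$end,
            binSize = binSize, label = label)
}

#' Write a TAD partition as three-column text
#'
#' Inverse of [readPartition()]: writes `chrom start end` rows, 1-based
#' closed, tab-separated. `readPartition(writePartition(p))` is the
#' identity on valid partitions.
#'
#' @param p a [TadPartition-class] or [DomainSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePartition <- function(p, path) {
  stopifnot(is(p, "TadPartition") || is(p, "DomainSet"))
  utils::write.table(as.data.frame(p), file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ChIP-seq peaks from BED
#'
#' BED intervals are 0-based half-open on disk; they are converted to the
#' internal 1-based closed convention (row `chr1 0 100` becomes
#' `[1, 100]`).
#'
#' @param path BED file path.
#' @param chrom restrict to this chromosome (required for
#'   multi-chromosome files).
#' @param label factor name stored in the object.
#' @return a [PeakSet-class].
#' @export
readPeaks <- function(path, chrom = NULL, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(chrom)) gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(chroms) > 1L)
    stop("BED file contains multiple chromosomes (",
         paste(chroms, collapse = ", "), "); use the 'chrom' argument")
  if (!length(gr))
    return(peakSet(chrom = if (is.null(chrom)) "chr" else chrom, label = label))
  r <- GenomicRanges::ranges(gr)
  peakSet(chrom = chroms, starts = IRanges::start(r), ends = IRanges::end(r),
          label = label)
}

#' Write a PeakSet as BED
#'
#' @param p a [PeakSet-class].
#' @param path output path (written 0-based half-open).
#' @return `path`, invisibly.
#' @export
writePeaks <- function(p, path) {
  stopifnot(is(p, "PeakSet"))
  gr <- GenomicRanges::GRanges(p@chrom, p@peaks)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a signal track from bedGraph
#'
#' bedGraph intervals are 0-based half-open on disk and converted to
#' 1-based closed; the fourth column becomes the interval value.
#'
#' @inheritParams readPeaks
#' @return a [SignalTrack-class].
#' @export
readBedgraph <- function(path, chrom = NULL, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(chrom)) gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(chroms) > 1L)
    stop("bedGraph file contains multiple chromosomes (",
         paste(chroms, collapse = ", "), "); use the 'chrom' argument")
  if (!length(gr))
    return(signalTrack(chrom = if (is.null(chrom)) "chr" else chrom,
                       label = label))
  r <- GenomicRanges::ranges(gr)
  signalTrack(chrom = chroms, starts = IRanges::start(r),
              ends = IRanges::end(r), values = GenomicRanges::mcols(gr)$score,
              label = label)
}

#' Write a SignalTrack as bedGraph
#'
#' @param x a [SignalTrack-class].
#' @param path output path (written 0-based half-open).
#' @return `path`, invisibly.
#' @export
writeBedgraph <- function(x, path) {
  stopifnot(is(x, "SignalTrack"))
  gr <- GenomicRanges::GRanges(x@chrom, x@intervals, score = x@values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a sparse contact matrix from triplet text
#'
#' Format: one header line `# chrom=<name> binSize=<bp> nBins=<n>`
#' followed by rows `i<TAB>j<TAB>count` with 1-based bin indices.
#'
#' @param path triplet file path.
#' @return a [ContactMatrix-class].
#' @seealso [writeTriplets()]
#' @export
readTriplets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#", lines[1L]))
    stop("triplet file must start with a '# chrom=... binSize=... nBins=...' header")
  hdr <- lines[1L]
  getField <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    if (!length(m)) stop("triplet header is missing '", key, "='")
    sub(paste0(key, "="), "", m)
  }
  chrom <- getField("chrom")
  binSize <- as.numeric(getField("binSize"))
  nb <- as.integer(getField("nBins"))
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    return(contactMatrix(chrom, binSize, nb))
  parts <- strsplit(body, "[\t ,]+")
  lens <- lengths(parts)
  if (any(lens != 3L))
    stop("malformed triplet line ", which(lens != 3L)[1L] + 1L)
  m <- matrix(as.numeric(unlist(parts)), ncol = 3L, byrow = TRUE)
  if (any(is.na(m)))
    stop("malformed triplet line ",
         which(apply(is.na(m), 1L, any))[1L] + 1L)
  if (any(m[, 3L] < 0))
    stop("negative count at triplet line ", which(m[, 3L] < 0)[1L] + 1L)
  if (any(m[, 1:2] < 1 | m[, 1:2] > nb))
    stop("bin index out of range at triplet line ",
         which(apply(m[, 1:2, drop = FALSE] < 1 |
                       m[, 1:2, drop = FALSE] > nb, 1L, any))[1L] + 1L)
  contactMatrix(chrom, binSize, nb, i = m[, 1L], j = m[, 2L], x = m[, 3L])
}

#' Write a contact matrix as triplet text
#'
#' Inverse of [readTriplets()]; only non-zero upper-triangle entries are
#' written.
#'
#' @param cm a [ContactMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTriplets <- function(cm, path) {
  stopifnot(is(cm, "ContactMatrix"))
  tm <- methods::as(cm@counts, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chrom=%s binSize=%.0f nBins=%d", cm@chrom,
                     cm@binSize, cm@nBins), con)
  if (length(tm@x))
    writeLines(sprintf("%d\t%d\t%s", tm@i + 1L, tm@j + 1L,
                       format(tm@x, scientific = FALSE, trim = TRUE)), con)
  invisible(path)
}

#' Inter-TAD gaps of a partition
#'
#' Maximal intervals of the chromosome span not covered by any domain.
#' The span runs from position 1 to the chromosome length when known,
#' otherwise to the last domain end. Domains and gaps together tile the
#' span exactly once; concordance analyses treat gaps as clusters.
#'
#' @param p a [TadPartition-class].
#' @return an [IRanges::IRanges] of gap intervals (possibly empty).
#' @examples
#' p <- TadPartition("chr1", c(1, 201), c(100, 300), binSize = 100,
#'                   chromLength = 400)
#' gapsOf(p)  # [101, 200] and [301, 400]
#' @rdname gapsOf
#' @export
setMethod("gapsOf", "TadPartition", function(p) {
  span <- .spanEnd(p)
  if (span < 1) return(IRanges::IRanges())
  IRanges::gaps(p@domains, start = 1, end = span)
})

#' TAD boundaries of a partition
#'
#' A boundary is a junction between bins: junction `j` sits between bin
#' `j` and bin `j + 1` (genomic offset `j * binSize`); junction 0 is the
#' chromosome-start edge. Every domain contributes its left junction
#' (from its start) and its right junction (from its end). With
#' `dedupe = TRUE` (the default, matching the counting of *unique*
#' boundaries) the junction shared by an end at bin `e` and a following
#' start at bin `e + 1`, and any coincident junctions across domains,
#' collapse to a single value.
#'
#' @param p a [TadPartition-class].
#' @param dedupe collapse coincident junctions (default `TRUE`).
#' @return with `dedupe = TRUE`, a sorted numeric vector of unique
#'   junction indices; otherwise a data.frame with one row per domain
#'   side and columns `domain`, `side`, `junction`, `pos` (bp offset of
#'   the junction).
#' @examples
#' p <- TadPartition("chr1", c(1, 101), c(100, 200), binSize = 100)
#' boundariesOf(p)                  # junctions 0, 1, 2
#' nrow(boundariesOf(p, dedupe = FALSE))  # 4 records
#' @rdname boundariesOf
#' @export
setMethod("boundariesOf", "TadPartition", function(p, dedupe = TRUE) {
  tab <- .junctionTable(p)
  if (!dedupe) return(tab)
  sort(unique(tab$junction))
})
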