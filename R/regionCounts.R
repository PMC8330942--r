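#' @importFrom GenomicRanges slidingWindows countOverlaps seqnames start end
#'   width strand GRanges
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment rowRanges<-
#' @importFrom rtracklayer import
NULL

.bedScan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L || all(!nzchar(lines)))
    stop("empty BED file: ", path)
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t| +")[[1]]
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (length(f) < 3L || is.na(s) || is.na(e) || e < s)
      stop("malformed BED line ", i, " in ", path, ": '", lines[i], "'")
  }
  invisible(TRUE)
}

.importBed <- function(path) {
  gr <- tryCatch(import(path, format = "BED"),
                 error = function(e) {
                   .bedScan(path)  # produce a line-numbered error if possible
                   stop("failed to parse BED file ", path, ": ",
                        conditionMessage(e))
                 })
  if (length(gr) == 0L) .bedScan(path)
  gr
}

#' Load candidate regions and tile them into fixed-width bins
#'
#' Each BED interval is partitioned into consecutive `binSize`-bp bins; a
#' partial terminal bin is dropped so that every region has exactly the width
#' assumed by the count models. Coordinates are BED-native 0-based half-open
#' on disk and 1-based closed in the returned `GRanges`.
#'
#' @param path BED3+ file of candidate intervals.
#' @param binSize bin width in bp (default 500).
#' @param promoterSpan promoter window d_p in bp recorded in the metadata
#'   (default 20000, i.e. +/- 10 kb around a TSS).
#' @return `GRanges` of bins with `region_id`, `region_class` and
#'   `tss_distance` metadata columns.
#' @export
loadRegions <- function(path, binSize = 500L, promoterSpan = 20000L) {
  if (binSize <= 0) stop("binSize must be positive")
  gr <- .importBed(path)
  if (length(gr) == 0L) stop("empty BED file: ", path)
  wins <- slidingWindows(gr, width = binSize, step = binSize)
  bins <- unlist(wins, use.names = FALSE)
  bins <- bins[width(bins) == binSize]
  if (length(bins) == 0L)
    stop("no interval is at least one bin (", binSize, " bp) wide")
  mcols(bins) <- NULL
  ids <- sprintf("%s:%d-%d", as.character(seqnames(bins)),
                 start(bins) - 1L, end(bins))
  if (anyDuplicated(ids)) {
    dup <- duplicated(ids)
    ids[dup] <- paste0(ids[dup], "_", cumsum(dup)[dup])
  }
  mcols(bins)$region_id <- ids
  mcols(bins)$region_class <- rep("unannotated", length(bins))
  mcols(bins)$tss_distance <- rep(NA_real_, length(bins))
  metadata(bins)$binSize <- as.integer(binSize)
  metadata(bins)$promoterSpan <- as.integer(promoterSpan)
  bins
}

.countOneBed <- function(path, regions, targetLibSize) {
  reads <- .importBed(path)
  lib <- length(reads)
  pos <- GRanges(seqnames(reads), IRanges(start(reads), width = 1L))
  known <- as.character(seqnames(pos)) %in%
    unique(as.character(seqnames(regions)))
  if (any(!known))
    message("countReads: skipped ", sum(!known),
            " reads on chromosomes absent from the region table (", path, ")")
  raw <- countOverlaps(regions, pos[known], ignore.strand = TRUE)
  if (is.null(targetLibSize) || is.na(targetLibSize)) return(raw)
  if (lib == 0L) stop("read file has no reads: ", path)
  floor(raw * (targetLibSize / lib) + 0.5)  # round half-up
}

#' Count read 5' positions per bin and TF
#'
#' Counts the number of fragment 5' positions (BED interval starts; strand is
#' ignored) falling into each region bin, then scales every TF library to a
#' common size and rounds half-up to integers. Reads on chromosomes absent
#' from the region table are skipped with a logged count.
#'
#' @param readFiles named character vector of per-TF BED files (names become
#'   TF names).
#' @param regions binned `GRanges` from [loadRegions()].
#' @param inputFile BED file of the matched input control (shared across TFs).
#' @param targetLibSize common library size to scale to (default 1e7 reads);
#'   `NA` disables scaling.
#' @return a [BindingCounts-class] object.
#' @export
countReads <- function(readFiles, regions, inputFile,
                       targetLibSize = 1e7) {
  if (is.null(names(readFiles)) || any(!nzchar(names(readFiles))))
    names(readFiles) <- paste0("TF", seq_along(readFiles))
  Y <- vapply(readFiles, .countOneBed, numeric(length(regions)),
              regions = regions, targetLibSize = targetLibSize)
  Y <- matrix(Y, nrow = length(regions),
              dimnames = list(NULL, names(readFiles)))
  ic <- .countOneBed(inputFile, regions, targetLibSize)
  BindingCounts(Y, matrix(ic, ncol = 1L), regions = regions,
                tfNames = names(readFiles))
}

#' Read a precomputed count matrix
#'
#' Reads a tab-separated count table (header row of TF names, first column
#' region_id) and passes it through unchanged. Negative counts are an error.
#'
#' @param path counts TSV.
#' @param inputPath matched input TSV (same layout; a single count column is
#'   recycled across TFs). When missing, input counts are set to zero.
#' @param regions optional binned `GRanges` aligned to the table rows.
#' @return a [BindingCounts-class] object.
#' @export
readCountMatrix <- function(path, inputPath = NULL, regions = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(tab[[1L]])
  Y <- as.matrix(tab[, -1L, drop = FALSE])
  if (any(Y < 0)) stop("negative counts in ", path)
  if (!is.null(inputPath)) {
    itab <- utils::read.delim(inputPath, check.names = FALSE)
    ic <- as.matrix(itab[, -1L, drop = FALSE])
    if (any(ic < 0)) stop("negative counts in ", inputPath)
  } else {
    ic <- matrix(0, nrow(Y), 1L)
  }
  bc <- BindingCounts(Y, ic, regions = regions)
  if (is.null(regions)) {
    mcols(rowRanges(bc))$region_id <- ids
    rownames(bc) <- ids
  }
  bc
}

.readTssPositions <- function(tss) {
  if (inherits(tss, "GRanges"))
    return(data.frame(chrom = as.character(seqnames(tss)),
                      pos = start(tss) - 1L))
  if (is.character(tss) && length(tss) == 1L && file.exists(tss)) {
    first <- readLines(tss, n = 1L)
    nf <- length(strsplit(first, "\t| +")[[1]])
    if (nf >= 3L) {
      gr <- .importBed(tss)
      return(data.frame(chrom = as.character(seqnames(gr)),
                        pos = start(gr) - 1L))
    }
    tab <- utils::read.table(tss, header = FALSE)
    return(data.frame(chrom = as.character(tab[[1L]]),
                      pos = as.numeric(tab[[2L]])))
  }
  stop("'tss' must be a GRanges or a BED / two-column position file")
}

#' Annotate bins with the signed distance to the nearest TSS
#'
#' The distance d_k is measured from the bin center (0-based) to the nearest
#' TSS; ties between two equidistant TSSs are broken toward the
#' smaller-coordinate TSS. Bins with |d_k| <= promoterSpan/2 are classed as
#' `promoter`, the rest keep class `unannotated`. Strand is ignored.
#'
#' @param regions binned `GRanges` (or a [BindingCounts-class] whose row
#'   ranges are annotated in place).
#' @param tss TSS positions: `GRanges`, BED file, or two-column
#'   chrom/position file (0-based positions).
#' @param promoterSpan promoter window d_p in bp (default from the region
#'   metadata, else 20000).
#' @return the input with `tss_distance` and `region_class` filled in.
#' @export
annotateTssDistance <- function(regions, tss, promoterSpan = NULL) {
  if (is(regions, "BindingCounts")) {
    rr <- annotateTssDistance(rowRanges(regions), tss, promoterSpan)
    rowRanges(regions) <- rr
    return(regions)
  }
  tssTab <- .readTssPositions(tss)
  if (nrow(tssTab) == 0L) stop("no TSS positions supplied")
  if (is.null(promoterSpan)) {
    promoterSpan <- metadata(regions)$promoterSpan
    if (is.null(promoterSpan)) promoterSpan <- 20000L
  }
  center <- floor(((start(regions) - 1L) + end(regions)) / 2)
  chrom <- as.character(seqnames(regions))
  d <- rep(NA_real_, length(regions))
  for (ch in unique(chrom)) {
    p <- sort(tssTab$pos[tssTab$chrom == ch])
    sel <- which(chrom == ch)
    if (length(p) == 0L) {
      warning("no TSS on chromosome ", ch,
              "; tss_distance left NA for its bins")
      next
    }
    cc <- center[sel]
    idx <- findInterval(cc, p)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, length(p))
    dl <- abs(cc - p[left]); dr <- abs(cc - p[right])
    useLeft <- idx >= 1L & (idx >= length(p) | dl <= dr)  # tie -> smaller TSS
    nearest <- ifelse(useLeft, p[left], p[right])
    d[sel] <- cc - nearest
  }
  mcols(regions)$tss_distance <- d
  cls <- mcols(regions)$region_class
  promoter <- !is.na(d) & abs(d) <= promoterSpan / 2
  cls[promoter] <- "promoter"
  cls[!promoter & !is.na(d)] <- "unannotated"
  mcols(regions)$region_class <- cls
  metadata(regions)$promoterSpan <- as.integer(promoterSpan)
  regions
}

#' Select candidate regions for module inference
#'
#' A region is a module candidate when more than `minCount` reads are
#' observed from each of at least `minTFs` TFs.
#'
#' @param x [BindingCounts-class] or a count matrix.
#' @param minCount per-TF read-count threshold (strict; default 10).
#' @param minTFs minimum number of TFs exceeding it (default 2).
#' @return integer vector of region indices passing the filter.
#' @export
filterCandidateRegions <- function(x, minCount = 10L, minTFs = 2L) {
  if (minCount < 0L) stop("minCount must be >= 0")
  if (minTFs < 1L) stop("minTFs must be >= 1")
  Y <- if (is(x, "BindingCounts")) counts(x) else as.matrix(x)
  which(rowSums(Y > minCount) >= minTFs)
}
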