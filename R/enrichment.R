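#' @importFrom stats phyper lm p.adjust cor hclust cutree as.dist
NULL

#' Label regions by nearby marker ChIP-seq peaks
#'
#' A region is labeled `+` for a marker when at least one peak overlaps the
#' half-open window `[center - window, center + window)` around the region
#' center (0-based coordinates), `-` otherwise.
#'
#' @param regions binned `GRanges` (or [BindingCounts-class]).
#' @param peaks named list of per-marker peak sets (`GRanges` or BED paths).
#' @param window half-width of the window in bp (default 2000).
#' @return character matrix (regions x markers) of `"+"` / `"-"`.
#' @export
labelMarkerRegions <- function(regions, peaks, window = 2000) {
  if (window <= 0) stop("window must be positive")
  if (is(regions, "BindingCounts")) regions <- rowRanges(regions)
  center0 <- floor(((start(regions) - 1L) + end(regions)) / 2)
  win <- GRanges(seqnames(regions),
                 IRanges(start = center0 - window + 1L,
                         end = center0 + window))
  out <- matrix("-", length(regions), length(peaks),
                dimnames = list(mcols(regions)$region_id, names(peaks)))
  for (j in seq_along(peaks)) {
    pk <- peaks[[j]]
    if (is.character(pk)) pk <- .importBedAllowEmpty(pk)
    if (length(pk) == 0L) {
      warning("empty peak set for marker ",
              if (!is.null(names(peaks))) names(peaks)[j] else j,
              "; all regions labeled '-'")
      next
    }
    hit <- countOverlaps(win, pk, ignore.strand = TRUE) > 0L
    out[hit, j] <- "+"
  }
  out
}

.importBedAllowEmpty <- function(path) {
  tryCatch(import(path, format = "BED"),
           error = function(e) GRanges())
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least `Htop` labeled regions among the
#' `Ktop` top-predicted regions when `Hall` of all `Kall` regions are
#' labeled: `p(h >= Htop)` under the hypergeometric distribution.
#'
#' @param Kall number of regions in the reference set.
#' @param Hall labeled regions among them.
#' @param Ktop number of top-predicted regions.
#' @param Htop labeled regions among the top predictions.
#' @return the tail probability in (0, 1].
#' @export
hypergeomEnrichment <- function(Kall, Hall, Ktop, Htop) {
  if (Hall > Kall || Ktop > Kall || Htop > Ktop || Htop > Hall ||
      any(c(Kall, Hall, Ktop, Htop) < 0))
    stop("inconsistent enrichment counts")
  phyper(Htop - 1, Hall, Kall - Hall, Ktop, lower.tail = FALSE)
}

.readBedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("BEDPE needs at least 6 columns")
  list(a = GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]])),
       b = GRanges(df[[4]], IRanges(df[[5]] + 1L, df[[6]])))
}

#' Correlate predicted activity with chromatin-loop counts
#'
#' Counts, per region, the loop anchors overlapping it and fits the
#' ordinary-least-squares line `loops ~ activity`, returning the slope and
#' its t-test p-value.
#'
#' @param scores per-region predicted activity.
#' @param loops interval pairs: BEDPE path, or a list with `GRanges`
#'   elements `a` and `b`.
#' @param regions `GRanges` aligned with `scores`.
#' @return list with `slope`, `pValue`, `loopCounts`.
#' @export
loopCorrelation <- function(scores, loops, regions) {
  if (is(regions, "BindingCounts")) regions <- rowRanges(regions)
  if (is.character(loops)) loops <- .readBedpe(loops)
  anchors <- c(loops$a, loops$b)
  n <- countOverlaps(regions, anchors, ignore.strand = TRUE)
  if (length(scores) != length(n))
    stop("scores and regions lengths differ")
  if (length(scores) < 3L) stop("need at least 3 regions")
  if (var(n) == 0) stop("loop counts have zero variance; correlation undefined")
  fit <- lm(n ~ scores)
  s <- summary(fit)$coefficients
  list(slope = unname(s["scores", "Estimate"]),
       pValue = unname(s["scores", "Pr(>|t|)"]),
       loopCounts = n)
}

#' Select differentially expressed genes from a two-replicate time course
#'
#' A gene is selected when, at some time point i > 0, all four log2
#' fold-change comparisons between baseline replicates (A0, B0) and
#' time-i replicates (Ai, Bi) exceed 1 in absolute value.
#'
#' @param expr gene x sample matrix of positive expression values.
#' @param replicate character vector (`"A"`/`"B"`) per column.
#' @param time numeric time per column; baseline is time 0.
#' @param lfcThreshold log2 fold-change threshold (default 1).
#' @return character vector of selected gene names (or row indices).
#' @export
selectDEGenes <- function(expr, replicate, time, lfcThreshold = 1) {
  expr <- as.matrix(expr)
  if (any(expr <= 0)) stop("expression values must be positive (log2 used)")
  if (length(replicate) != ncol(expr) || length(time) != ncol(expr))
    stop("replicate/time annotations must match the columns")
  a0 <- which(replicate == "A" & time == 0)
  b0 <- which(replicate == "B" & time == 0)
  if (length(a0) != 1L || length(b0) != 1L)
    stop("need exactly one A and one B baseline column (time 0)")
  lx <- log2(expr)
  later <- setdiff(sort(unique(time)), 0)
  if (length(later) == 0L) stop("need at least one post-baseline time point")
  hit <- rep(FALSE, nrow(expr))
  for (ti in later) {
    ai <- which(replicate == "A" & time == ti)
    bi <- which(replicate == "B" & time == ti)
    if (length(ai) != 1L || length(bi) != 1L) next
    ok <- abs(lx[, a0] - lx[, ai]) > lfcThreshold &
      abs(lx[, a0] - lx[, bi]) > lfcThreshold &
      abs(lx[, b0] - lx[, ai]) > lfcThreshold &
      abs(lx[, b0] - lx[, bi]) > lfcThreshold
    hit <- hit | ok
  }
  if (is.null(rownames(expr))) which(hit) else rownames(expr)[hit]
}

#' Cluster gene expression profiles
#'
#' Agglomerative hierarchical clustering with correlation distance
#' (1 - Pearson) and average linkage, cut at `nClusters`; deterministic in
#' the gene set (independent of row order).
#'
#' @param expr gene x sample matrix of the selected genes.
#' @param nClusters number of clusters (default 8).
#' @return named integer vector of cluster assignments.
#' @export
clusterGenes <- function(expr, nClusters = 8L) {
  expr <- as.matrix(expr)
  if (nrow(expr) < nClusters)
    stop("fewer genes (", nrow(expr), ") than clusters (", nClusters, ")")
  d <- as.dist(1 - cor(t(expr)))
  if (anyNA(d)) stop("zero-variance gene profiles; correlation undefined")
  hc <- hclust(d, method = "average")
  cutree(hc, k = nClusters)
}

#' Module-cluster hypergeometric enrichment
#'
#' Tests every (module target set, gene cluster) pair for enrichment with
#' the upper-tail hypergeometric probability over the clustered-gene
#' universe; p-values are Benjamini-Hochberg adjusted across all pairs.
#'
#' @param moduleTargets named list of per-module target gene sets.
#' @param clusters named cluster assignment from [clusterGenes()].
#' @param alpha adjusted-p significance cutoff (default 0.001).
#' @return data.frame of all pairs with raw/adjusted p-values and a
#'   `significant` flag.
#' @export
moduleClusterEnrichment <- function(moduleTargets, clusters,
                                    alpha = 0.001) {
  universe <- names(clusters)
  if (is.null(universe)) stop("clusters must be named by gene")
  rows <- list()
  for (m in names(moduleTargets)) {
    targets <- intersect(moduleTargets[[m]], universe)
    if (length(targets) == 0L) {
      message("module ", m, ": no targets in the clustered universe; skipped")
      next
    }
    for (cl in sort(unique(clusters))) {
      inCl <- universe[clusters == cl]
      h <- length(intersect(targets, inCl))
      p <- hypergeomEnrichment(Kall = length(universe),
                               Hall = length(targets),
                               Ktop = length(inCl), Htop = h)
      rows[[length(rows) + 1L]] <-
        data.frame(module = m, cluster = cl, overlap = h,
                   clusterSize = length(inCl),
                   targetSize = length(targets), pValue = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$pAdjusted <- p.adjust(out$pValue, method = "BH")
  out$significant <- out$pAdjusted < alpha
  out[order(out$pAdjusted), ]
}
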