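test_that("marker labeling uses a half-open window around the region center", {
  regions <- loadRegions(writeBed(data.frame("chr1", 10000L, 10500L)), 500L)
  # center (0-based) = 10250; window 2000 -> [8250, 12250)
  peaks <- list(
    endsAtEdge = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = 8201, end = 8250)),   # [8200,8250): excluded
    insideEdge = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = 8202, end = 8251)),   # [8201,8251): included
    spansCenter = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = 10001, end = 10600)))
  lab <- labelMarkerRegions(regions, peaks, window = 2000)
  expect_equal(unname(lab[1, ]), c("-", "+", "+"))
  expect_warning(
    lab0 <- labelMarkerRegions(regions,
                               list(empty = GenomicRanges::GRanges()),
                               window = 2000),
    "empty peak set")
  expect_equal(unname(lab0[1, 1]), "-")
})

test_that("hypergeometric tail matches exact combinatorics", {
  expect_equal(hypergeomEnrichment(10, 5, 4, 4), choose(5, 4) / choose(10, 4))
  expect_equal(hypergeomEnrichment(10, 5, 10, 5), 1)  # Ktop = Kall
  expect_equal(hypergeomEnrichment(50, 20, 10, 0), 1) # tail from 0
  expect_error(hypergeomEnrichment(10, 11, 4, 2), "inconsistent")
  # monotone decreasing in Htop for fixed margins
  p <- vapply(0:8, function(h) hypergeomEnrichment(30, 12, 8, h), numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("loop correlation counts anchors and fits the linear model", {
  regions <- loadRegions(
    writeBed(data.frame("chr1", seq(0L, 4500L, 500L),
                        seq(500L, 5000L, 500L))), 500L)
  # region 1 overlaps 3 anchors
  loops <- list(
    a = GenomicRanges::GRanges("chr1",
          IRanges::IRanges(c(1, 100, 200, 2001), width = 50)),
    b = GenomicRanges::GRanges("chr1",
          IRanges::IRanges(c(3001, 3101, 3201, 4001), width = 50)))
  n <- countOverlaps(regions, c(loops$a, loops$b))
  expect_equal(n[1], 3)
  # perfect line: loop counts equal to scores -> slope 1, p ~ 0
  res <- suppressWarnings(loopCorrelation(scores = as.numeric(n), loops,
                                          regions))  # perfect-fit warning
  expect_equal(res$slope, 1, tolerance = 1e-10)
  expect_lt(res$pValue, 1e-10)
  expect_error(
    loopCorrelation(runif(10), list(a = GenomicRanges::GRanges(),
                                    b = GenomicRanges::GRanges()), regions),
    "zero variance")
})

test_that("permuted activity scores give a uniform loop-correlation null", {
  set.seed(30)
  regions <- loadRegions(
    writeBed(data.frame("chr1", seq(0L, 499500L, 500L),
                        seq(500L, 500000L, 500L))), 500L)
  anchors <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(499000, 800), width = 100))
  loops <- list(a = anchors[1:400], b = anchors[401:800])
  pvals <- replicate(40, {
    sc <- runif(length(regions))
    loopCorrelation(sc, loops, regions)$pValue
  })
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("time-course gene selection applies the four-way log2FC rule", {
  expr <- rbind(
    allFour = c(2, 2, 8, 8),     # Ai = Bi = 4 * baseline -> selected
    small  = c(2, 2, 3, 3),      # 1.5-fold -> not selected
    oneFails = c(2, 2, 8, 3.5))  # |log2(2/3.5)| < 1 fails the conjunction
  rep_ <- c("A", "B", "A", "B"); tim <- c(0, 0, 6, 6)
  sel <- selectDEGenes(expr, rep_, tim)
  expect_equal(sel, "allFour")
  # scale invariance
  sel2 <- selectDEGenes(expr * 7.3, rep_, tim)
  expect_equal(sel2, sel)
  expect_error(selectDEGenes(rbind(c(0, 1, 2, 3)), rep_, tim), "positive")
})

test_that("hierarchical clustering separates orthogonal patterns", {
  set.seed(31)
  base <- diag(8)
  expr <- base[rep(1:8, each = 8), ] + matrix(rnorm(64 * 8, 0, 0.01), 64, 8)
  rownames(expr) <- paste0("g", 1:64)
  cl <- clusterGenes(expr, nClusters = 8)
  expect_equal(length(unique(cl)), 8L)
  purity <- tapply(rep(1:8, each = 8), cl, function(x)
    max(table(x)) / length(x))
  expect_true(all(purity == 1))
  # permuting gene order leaves the partition unchanged
  perm <- sample(64)
  cl2 <- clusterGenes(expr[perm, ], nClusters = 8)
  agree <- outer(cl, cl, "==")
  agree2 <- outer(cl2[rownames(expr)], cl2[rownames(expr)], "==")
  expect_true(all(agree == agree2))
  expect_error(clusterGenes(expr[1:5, ], nClusters = 8), "fewer genes")
})

test_that("module-cluster enrichment flags a module matching a cluster", {
  set.seed(32)
  genes <- paste0("g", 1:200)
  clusters <- setNames(rep(1:8, each = 25), genes)
  targets <- list(hit = genes[clusters == 3],
                  rand = sample(genes, 25))
  res <- moduleClusterEnrichment(targets, clusters, alpha = 0.001)
  best <- res[1, ]
  expect_equal(best$module, "hit")
  expect_equal(best$cluster, 3)
  expect_true(best$significant)
  # random targets under BH should rarely be significant at alpha = 0.001
  expect_lte(sum(res$significant[res$module == "rand"]), 1)
  expect_message(
    moduleClusterEnrichment(list(none = "not_a_gene"), clusters),
    "skipped")
})
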