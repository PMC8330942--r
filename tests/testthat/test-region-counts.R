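test_that("interval tiling partitions intervals into fixed-width bins", {
  bed <- writeBed(data.frame(chrom = c("chr1", "chr1", "chr2"),
                             start = c(0L, 5000L, 100L),
                             end = c(1500L, 6499L, 600L)))
  bins <- loadRegions(bed, binSize = 500L)
  # chr1:0-1500 -> 3 full bins; chr1:5000-6499 -> 2 (partial dropped);
  # chr2:100-600 -> 1
  expect_equal(length(bins), 6L)
  expect_true(all(GenomicRanges::width(bins) == 500L))
  b1 <- bins[as.character(GenomicRanges::seqnames(bins)) == "chr1"][1:3]
  s0 <- GenomicRanges::start(b1) - 1L
  expect_equal(s0, c(0L, 500L, 1000L))          # ordered, disjoint, tiled
  expect_false(anyDuplicated(S4Vectors::mcols(bins)$region_id) > 0)
})

test_that("malformed and empty BED files are rejected with diagnostics", {
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000", "chr1\tnotanumber\t500"), bad)
  expect_error(loadRegions(bad), "line 2")
  empty <- tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_error(loadRegions(empty), "empty")
  expect_error(loadRegions(writeBed(data.frame("chr1", 0, 1000)),
                           binSize = 0), "positive")
})

test_that("read counting counts 5' positions, is deterministic and additive", {
  regions <- loadRegions(writeBed(data.frame("chr1", 0L, 1000L)), 500L)
  reads <- data.frame(chrom = "chr1",
                      start = c(10L, 20L, 499L, 500L, 900L),
                      end = c(60L, 70L, 549L, 550L, 950L))
  f <- writeBed(reads)
  bc <- countReads(c(A = f, B = f), regions, inputFile = f,
                   targetLibSize = NA)
  # 3 read starts fall in bin 1 ([0,500)), 2 in bin 2
  expect_equal(unname(counts(bc)[, "A"]), c(3, 2))
  expect_equal(unname(counts(bc)[, "A"]), unname(counts(bc)[, "B"]))
  # additivity: counting a concatenated file equals the sum of the parts
  f1 <- writeBed(reads[1:2, ]); f2 <- writeBed(reads[3:5, ])
  fc <- writeBed(reads)
  c1 <- counts(countReads(c(A = f1), regions, f1, targetLibSize = NA))
  c2 <- counts(countReads(c(A = f2), regions, f2, targetLibSize = NA))
  cc <- counts(countReads(c(A = fc), regions, fc, targetLibSize = NA))
  expect_equal(unname(cc), unname(c1 + c2))
})

test_that("library scaling rescales to the target size with half-up rounding", {
  regions <- loadRegions(writeBed(data.frame("chr1", 0L, 500L)), 500L)
  # 10-read library, all in the bin; target 25 reads -> each read counts 2.5
  reads <- data.frame("chr1", seq(0L, 90L, by = 10L),
                      seq(50L, 140L, by = 10L))
  f <- writeBed(reads)
  bc <- countReads(c(A = f), regions, inputFile = f, targetLibSize = 25)
  expect_equal(unname(counts(bc)[1, "A"]), floor(10 * 25 / 10 + 0.5))
  # independent recomputation: raw count 10, scale 2.5 -> 25
  expect_equal(unname(counts(bc)[1, "A"]), 25)
})

test_that("reads on chromosomes absent from the region table are skipped", {
  regions <- loadRegions(writeBed(data.frame("chr1", 0L, 500L)), 500L)
  f <- writeBed(data.frame(chrom = c("chr1", "chrUn"),
                           start = c(10L, 10L), end = c(60L, 60L)))
  expect_message(
    bc <- countReads(c(A = f), regions, inputFile = f, targetLibSize = NA),
    "skipped 1 reads")
  expect_equal(unname(counts(bc)[1, "A"]), 1)
})

test_that("precomputed count tables pass through and reject negatives", {
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(region_id = c("r1", "r2"),
                                TF1 = c(5L, 11L), TF2 = c(0L, 20L)),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  bc <- readCountMatrix(tsv)
  expect_equal(unname(counts(bc)), matrix(c(5, 11, 0, 20), 2))
  expect_equal(regionIds(bc), c("r1", "r2"))
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(region_id = "r1", TF1 = -3L), bad,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCountMatrix(bad), "negative")
})

test_that("TSS distances are signed, tie-broken and class-assigned", {
  regions <- loadRegions(writeBed(data.frame("chr1", c(0L, 22000L, 49750L),
                                             c(500L, 22500L, 50250L))), 500L)
  # bin centers (0-based): 250, 22250, 50000
  tss <- data.frame(chrom = "chr1", pos = c(250L, 10250L, 40000L, 60000L))
  tf <- tempfile(); utils::write.table(tss, tf, sep = "\t", quote = FALSE,
                                       row.names = FALSE, col.names = FALSE)
  ann <- annotateTssDistance(regions, tf, promoterSpan = 20000L)
  d <- S4Vectors::mcols(ann)$tss_distance
  expect_equal(d[1], 0)                       # centered exactly on a TSS
  expect_equal(d[2], 12000)                   # 22250 - 10250
  expect_equal(S4Vectors::mcols(ann)$region_class[1], "promoter")
  expect_false(S4Vectors::mcols(ann)$region_class[2] == "promoter")
  # center 50000 is equidistant (10000) from 40000 and 60000:
  # tie broken toward the smaller coordinate -> d = +10000
  expect_equal(d[3], 10000)
})

test_that("candidate-region filter applies the >minCount from >=minTFs rule", {
  Y <- rbind(c(11, 12, 0),    # kept: two TFs > 10
             c(11, 10, 10),   # dropped: only one TF strictly > 10
             c(0, 0, 0),      # dropped
             c(25, 25, 25))   # kept
  expect_equal(filterCandidateRegions(Y), c(1L, 4L))
  expect_equal(filterCandidateRegions(matrix(0, 5, 3)), integer(0))
  expect_error(filterCandidateRegions(Y, minTFs = 0), "minTFs")
})

test_that("filter is monotone in minCount", {
  set.seed(3)
  Y <- matrix(rpois(600, 8), 200, 3)
  for (m in c(2, 5, 8, 12)) {
    hi <- filterCandidateRegions(Y, minCount = m)
    lo <- filterCandidateRegions(Y, minCount = m - 1)
    expect_true(all(hi %in% lo))
  }
})
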