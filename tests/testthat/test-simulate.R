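test_that("simulation is bit-reproducible given the seed", {
  s1 <- simulateCounts(simulationSpec(1, nRegions = 500, seed = 9))
  s2 <- simulateCounts(simulationSpec(1, nRegions = 500, seed = 9))
  expect_identical(counts(s1$counts), counts(s2$counts))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateCounts(simulationSpec(1, nRegions = 500, seed = 10))
  expect_false(identical(counts(s1$counts), counts(s3$counts)))
})

test_that("case presets match the benchmark design", {
  expect_equal(simulationSpec(1)$nTFs, 4L)
  expect_equal(simulationSpec(2)$nTFs, 7L)
  expect_equal(simulationSpec(3)$nTFs, 18L)
  expect_equal(simulationSpec(1)$nRegions, 100000L)
  expect_equal(simulationSpec(1)$nReplicates, 10L)
  spec <- simulationSpec(1, nRegions = 100)
  expect_prob_vector(spec$abundance)
  # single-TF modules carry no truth mass; >=2-TF modules and background do
  sizes <- rowSums(moduleMatrix(spec$catalog))
  expect_true(all(spec$abundance[sizes == 1] == 0))
  expect_error(simulationSpec(1, weakMax = 5), "infeasible")
})

test_that("a background-only noiseless spec yields pure Gamma columns", {
  spec <- simulationSpec(1, nRegions = 20000, seed = 33, noiseSd = 0)
  spec$abundance <- c(1, rep(0, length(spec$abundance) - 1L))
  sim <- simulateCounts(spec)
  expect_true(all(sim$truth == 0L))
  Y <- counts(sim$counts)
  for (t in 1:4) {
    expect_equal(mean(Y[, t]), spec$alphaMean[t], tolerance = 0.05)
    shape <- mean(Y[, t])^2 / var(Y[, t])
    # rounding slightly inflates the variance; generous Monte-Carlo band
    expect_equal(shape, spec$betaShape[t], tolerance = 0.15)
  }
})

test_that("bound counts above the floor follow the generating Power-Law", {
  set.seed(34)
  g <- 2.2
  x <- rPowerLaw(50000, gamma = g, xmin = 10)
  # chi-square against the theoretical pmf on the low support + pooled tail
  cells <- 10:59
  obs <- c(tabulate(factor(x[x < 60], levels = cells)), sum(x >= 60))
  pTail <- 1 - sum(dPowerLaw(cells, g, 10))
  expected <- c(dPowerLaw(cells, g, 10), pTail)
  chi <- suppressWarnings(chisq.test(obs, p = expected / sum(expected)))
  expect_gt(chi$p.value, 0.01)
  # weak-TF truncation clamps the range
  w <- rPowerLaw(5000, gamma = 2.5, xmin = 10, xmax = 30)
  expect_true(all(w >= 10 & w <= 30))
})

test_that("noise replicates share the truth but differ in noise", {
  spec <- simulationSpec(1, nRegions = 300, seed = 35, nReplicates = 3)
  reps <- simulateReplicates(spec)
  expect_length(reps$replicates, 3L)
  expect_false(identical(counts(reps$replicates[[1]]),
                         counts(reps$replicates[[2]])))
  # noise is +/- a few reads around the shared noise-free signal
  base <- reps$binding * reps$boundCounts
  y1 <- counts(reps$replicates[[1]])
  bound1 <- reps$binding == 1L
  expect_lt(max(abs(y1[bound1] - base[bound1])), 6 * spec$noiseSd + 1)
})

test_that("simulated labels round-trip through labelRegions", {
  spec <- simulationSpec(1, nRegions = 2000, seed = 36)
  sim <- simulateCounts(spec)
  full <- which(rowSums(moduleMatrix(spec$catalog)) == 4) - 1L
  labs <- simulateLabels(sim$truth, activeModules = full, flipRate = 0,
                         seed = 2)
  rec <- labelRegions(labs$tpm, focalSamples = labs$focalSamples)
  expect_equal(as.character(rec), as.character(labs$labels))
  expect_equal(as.character(labs$labels), as.character(labs$truthLabels))
  # flipped labels disagree with the truth at ~ the flip rate
  labs2 <- simulateLabels(sim$truth, activeModules = full, flipRate = 0.1,
                          seed = 2)
  labeled <- labs2$truthLabels != "unlabeled"
  rate <- mean(labs2$labels[labeled] != labs2$truthLabels[labeled])
  ci <- 3 * sqrt(0.1 * 0.9 / sum(labeled))
  expect_lt(abs(rate - 0.1), ci)
  expect_error(simulateLabels(sim$truth, integer(0)), "non-empty")
})

test_that("binding-recovery scoring reproduces closed-form F-measures", {
  ct <- enumerateModules(c("A", "B"))
  truth <- c(3L, 3L, 0L, 1L)   # A+B, A+B, bg, A
  # perfect recovery
  perfect <- list(3L, 3L, integer(0), 1L)
  expect_equal(scoreBindingRecovery(truth, perfect, ct)$overall$F, 1)
  # all background -> recall 0, F 0
  none <- replicate(4, integer(0), simplify = FALSE)
  sc0 <- scoreBindingRecovery(truth, none, ct)$overall
  expect_equal(sc0$recall, 0); expect_equal(sc0$F, 0)
  # hand-built 8 TP / 2 FP / 2 FN -> precision = recall = F = 0.8
  truth10 <- c(rep(3L, 5), 0L)             # 10 true events + 1 bg region
  inferred <- list(3L, 3L, 3L, 1L, 2L, 3L) # 2 events dropped, 2 invented
  sc <- scoreBindingRecovery(truth10, inferred, ct)$overall
  expect_equal(sc$tp, 8); expect_equal(sc$fn, 2); expect_equal(sc$fp, 2)
  expect_equal(sc$F, 0.8)
})
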