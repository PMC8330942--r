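# Small programmatic fixtures shared across test files.

writeBed <- function(df, path = tempfile(fileext = ".bed")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# A tiny BindingCounts with hand-chosen counts.
toyBindingCounts <- function(Y, input = NULL) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("TF", seq_len(ncol(Y)))
  if (is.null(input)) input <- matrix(1, nrow(Y), 1L)
  BindingCounts(Y, input)
}

# Deterministic small simulated dataset reused by several files.
smallSim <- function(K = 800, seed = 42) {
  spec <- simulationSpec(case = 1, nRegions = K, seed = seed)
  list(spec = spec, sim = simulateCounts(spec))
}

expect_prob_vector <- function(x, tol = 1e-9) {
  expect_true(all(x >= 0))
  expect_equal(sum(x), 1, tolerance = tol)
}
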