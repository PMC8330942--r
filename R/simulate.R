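#' @importFrom stats rnorm rexp rbinom
NULL

.caseGamma <- function(case) {
  switch(as.character(case),
         "1" = list(gamma = c(1.6, 1.8, 2.0, 2.5), weak = 4L),
         "2" = list(gamma = c(seq(1.6, 2.1, length.out = 5), 2.5, 2.5),
                    weak = c(6L, 7L)),
         "3" = list(gamma = c(seq(1.6, 2.2, length.out = 13),
                              rep(2.5, 5)), weak = 14:18),
         stop("case must be 1, 2 or 3"))
}

.caseCatalog <- function(case, tfNames) {
  T <- length(tfNames)
  if (case %in% c(1, 2)) return(enumerateModules(tfNames))
  # case 3: a fixed panel of co-binding modules (pairs, triples and
  # strong+weak mixtures) mimicking retained real TF associations
  rowsOf <- function(sets) {
    t(vapply(sets, function(s) {
      b <- integer(T); b[s] <- 1L; b
    }, integer(T)))
  }
  pairs <- lapply(seq(1, 17, by = 2), function(i) c(i, i + 1))
  triples <- lapply(seq(1, 16, by = 3), function(i) i:(i + 2))
  mixed <- list(c(1, 2, 14), c(3, 4, 15), c(5, 6, 16), c(7, 8, 17),
                c(9, 10, 18))
  B <- rowsOf(c(pairs, triples, mixed))
  colnames(B) <- tfNames
  ModuleCatalog(B, tfNames = tfNames, provenance = "truth")
}

.caseAbundance <- function(case, catalog) {
  B <- moduleMatrix(catalog)
  M <- nrow(B) - 1L
  sizes <- rowSums(B)[-1L]
  ab <- numeric(M + 1L)
  if (case == 1) {
    # background 29%, the full 4-TF module 29% (echoing a strongly
    # associated TF panel), remainder spread over the >=2-TF sub-modules
    ab[1L] <- 0.29
    full <- which(sizes == max(sizes)) + 1L
    ab[full] <- 0.29
    rest <- which(sizes >= 2 & sizes < max(sizes)) + 1L
    ab[rest] <- 0.42 / length(rest)
  } else if (case == 2) {
    ab[1L] <- 0.30
    full <- which(sizes == max(sizes)) + 1L
    ab[full] <- 0.10
    pairs <- which(sizes == 2) + 1L
    triples <- which(sizes == 3) + 1L
    ab[pairs] <- 0.25 / length(pairs)
    ab[triples] <- 0.35 / length(triples)
  } else {
    ab[1L] <- 0.30
    ab[-1L] <- 0.70 / M
  }
  ab / sum(ab)
}

#' Specify a ground-truthed ChIP-seq count simulation
#'
#' Builds the preset for one of the three benchmark scenarios: Case 1
#' (4 TFs, low difficulty), Case 2 (7 TFs, medium) and Case 3 (18 TFs,
#' high), each with a known module catalog, per-TF Power-Law/Gamma
#' parameters, a weak-TF stratum whose bound counts concentrate near the
#' Power-Law floor, and additive rounded Gaussian read noise.
#'
#' @param case 1, 2 or 3.
#' @param nRegions number of 500-bp regions (default 1e5; scale down for
#'   desk-sized runs).
#' @param seed RNG seed for the draw.
#' @param noiseSd standard deviation of the additive read noise (default 1
#'   read, the jitter of resampled replicate libraries).
#' @param nReplicates number of noise replicates [simulateReplicates()]
#'   generates (default 10).
#' @param mode `"enhancer"` (default; no TSS distances) or `"promoter"`.
#' @param xmin Power-Law floor (default 10).
#' @param weakMax upper truncation of weak bound counts (default 3*xmin).
#' @return a `SimulationSpec` list.
#' @export
simulationSpec <- function(case = 1, nRegions = 1e5, seed = 1L,
                           noiseSd = 1, nReplicates = 10L,
                           mode = c("enhancer", "promoter"), xmin = 10,
                           weakMax = 3 * xmin) {
  mode <- match.arg(mode)
  if (weakMax < xmin) stop("infeasible truncation: weakMax < xmin")
  cs <- .caseGamma(case)
  T <- length(cs$gamma)
  tfNames <- paste0("TF", seq_len(T))
  catalog <- .caseCatalog(case, tfNames)
  spec <- list(case = case, nRegions = as.integer(nRegions),
               nTFs = T, tfNames = tfNames,
               gamma = cs$gamma, weakTFs = cs$weak,
               alphaMean = 2.8 + 0.15 * (seq_len(T) - 1L) %% 4,
               betaShape = rep(1.5, T),
               lambda = rep(5e-4, T),
               catalog = catalog,
               abundance = .caseAbundance(case, catalog),
               noiseSd = noiseSd, nReplicates = as.integer(nReplicates),
               mode = mode, xmin = xmin, weakMax = weakMax,
               seed = as.integer(seed))
  class(spec) <- "SimulationSpec"
  spec
}

# Noise-free bound/background draws shared by all replicates of a spec.
.simulateBase <- function(spec) {
  set.seed(spec$seed)
  K <- spec$nRegions; T <- spec$nTFs
  B <- moduleMatrix(spec$catalog)
  C <- sample.int(nrow(B), K, replace = TRUE, prob = spec$abundance) - 1L
  bound <- B[C + 1L, , drop = FALSE] == 1
  X <- matrix(0, K, T); I <- matrix(0, K, T)
  for (t in seq_len(T)) {
    nb <- sum(bound[, t])
    xmax <- if (t %in% spec$weakTFs) spec$weakMax else 1e6
    if (nb > 0)
      X[bound[, t], t] <- rPowerLaw(nb, spec$gamma[t], spec$xmin, xmax)
    I[!bound[, t], t] <- round(rGammaMeanShape(K - nb, spec$alphaMean[t],
                                               spec$betaShape[t]))
  }
  input <- vapply(seq_len(T), function(t)
    round(rGammaMeanShape(K, spec$alphaMean[t], spec$betaShape[t])),
    numeric(K))
  d <- rep(NA_real_, K)
  if (spec$mode == "promoter") {
    lam <- mean(spec$lambda)
    isBound <- C > 0L
    d[isBound] <- sample(c(-1, 1), sum(isBound), replace = TRUE) *
      rexp(sum(isBound), rate = lam)
    d[!isBound] <- runif(sum(!isBound), -10000, 10000)
  }
  list(C = C, bound = bound, X = X, I = I, input = input, d = d)
}

.assembleCounts <- function(spec, base, noiseSeed) {
  set.seed(noiseSeed)
  K <- spec$nRegions; T <- spec$nTFs
  Y <- base$bound * base$X + (!base$bound) * base$I
  if (spec$noiseSd > 0)
    Y <- Y + matrix(round(rnorm(K * T, 0, spec$noiseSd)), K, T)
  Y <- pmax(Y, 0)
  colnames(Y) <- spec$tfNames
  starts <- (seq_len(K) - 1L) * 500L
  regions <- GRanges("chrS", IRanges(start = starts + 1L, width = 500L))
  mcols(regions)$region_id <- sprintf("chrS:%d-%d", starts, starts + 500L)
  mcols(regions)$region_class <-
    rep(if (spec$mode == "promoter") "promoter" else "enhancer", K)
  mcols(regions)$tss_distance <- base$d
  metadata(regions)$binSize <- 500L
  metadata(regions)$promoterSpan <- 20000L
  BindingCounts(Y, base$input, regions = regions, tfNames = spec$tfNames)
}

#' Simulate multi-TF ChIP-seq counts with known module assignments
#'
#' Draws a module per region from the truth abundances, bound counts from
#' the discrete Power-Law (truncated near the floor for weak TFs),
#' background and input counts from the per-TF Gamma, adds rounded
#' Gaussian read noise clipped at zero, and (in promoter mode) draws TSS
#' distances from the exponential/uniform mixture.
#'
#' @param spec a `SimulationSpec` from [simulationSpec()].
#' @return list with the [BindingCounts-class] `counts`, the truth module
#'   index vector `truth` (0 = background), the truth `catalog`, the
#'   noise-free bound counts `boundCounts` (0 where unbound) and the
#'   binary truth `binding` matrix.
#' @export
simulateCounts <- function(spec) {
  base <- .simulateBase(spec)
  bc <- .assembleCounts(spec, base, noiseSeed = spec$seed + 1L)
  storage.mode(base$bound) <- "integer"
  list(counts = bc, truth = base$C, catalog = spec$catalog,
       boundCounts = base$bound * base$X, binding = base$bound)
}

#' Noise replicates of one simulated dataset
#'
#' Keeps the module assignments and noise-free counts fixed and re-draws
#' the additive read noise `nReplicates` times.
#'
#' @param spec a `SimulationSpec`.
#' @return list as [simulateCounts()] plus `replicates`, a list of
#'   [BindingCounts-class] objects.
#' @export
simulateReplicates <- function(spec) {
  base <- .simulateBase(spec)
  reps <- lapply(seq_len(spec$nReplicates), function(r)
    .assembleCounts(spec, base, noiseSeed = spec$seed + r))
  storage.mode(base$bound) <- "integer"
  list(replicates = reps, truth = base$C, catalog = spec$catalog,
       boundCounts = base$bound * base$X, binding = base$bound)
}

#' Simulate activity labels and a matching TPM table
#'
#' Regions whose true module belongs to `activeModules` emit TPM > 1 in at
#' least two synthetic focal samples (positives); regions bound by other
#' modules are active in another context only (negatives); background
#' regions are inactive everywhere (unlabeled). Labels are flipped
#' (positive <-> negative) at `flipRate` before the TPM table is emitted, so
#' the table is always consistent with [labelRegions()].
#'
#' @param truth truth module indices from [simulateCounts()].
#' @param activeModules integer set of module indices deemed active in the
#'   focal context.
#' @param flipRate label-noise rate in [0, 0.5).
#' @param nFocalSamples,nOtherSamples synthetic sample counts (default 3).
#' @param seed RNG seed.
#' @return list with `labels` (factor), `tpm` (matrix), `focalSamples`
#'   (column names) and `truthLabels` (pre-flip).
#' @export
simulateLabels <- function(truth, activeModules, flipRate = 0,
                           nFocalSamples = 3L, nOtherSamples = 3L,
                           seed = 1L) {
  if (length(activeModules) == 0L) stop("activeModules must be non-empty")
  if (flipRate < 0 || flipRate >= 0.5) stop("flipRate must be in [0, 0.5)")
  set.seed(seed)
  K <- length(truth)
  lab <- rep("unlabeled", K)
  lab[truth %in% activeModules] <- "positive"
  lab[truth > 0L & !(truth %in% activeModules)] <- "negative"
  truthLabels <- factor(lab, levels = c("negative", "positive", "unlabeled"))
  labeled <- which(lab != "unlabeled")
  flip <- labeled[runif(length(labeled)) < flipRate]
  lab[flip] <- ifelse(lab[flip] == "positive", "negative", "positive")
  tpm <- matrix(runif(K * (nFocalSamples + nOtherSamples), 0, 0.8),
                K, nFocalSamples + nOtherSamples)
  colnames(tpm) <- c(paste0("focal_", seq_len(nFocalSamples)),
                     paste0("other_", seq_len(nOtherSamples)))
  pos <- lab == "positive"; neg <- lab == "negative"
  tpm[pos, seq_len(nFocalSamples)] <-
    runif(sum(pos) * nFocalSamples, 1.5, 8)
  tpm[neg, nFocalSamples + seq_len(nOtherSamples)] <-
    runif(sum(neg) * nOtherSamples, 1.5, 8)
  list(labels = factor(lab, levels = c("negative", "positive", "unlabeled")),
       tpm = tpm, focalSamples = paste0("focal_", seq_len(nFocalSamples)),
       truthLabels = truthLabels)
}

#' Score inferred binding events against the simulation truth
#'
#' Compares the per-(region, TF) binding events implied by the inferred
#' module assignments with the ground truth and reports precision, recall
#' and F-measure, overall and restricted to the weak-region subset (regions
#' whose truth includes at least one bound count inside `weakRange`).
#'
#' @param truth truth module indices (0 = background).
#' @param assignments inferred module sets from [assignModules()] (or an
#'   integer vector of single module indices).
#' @param catalog the [ModuleCatalog-class] shared by truth and inference.
#' @param boundCounts noise-free bound-count matrix from
#'   [simulateCounts()]; required for the weak subset.
#' @param weakRange inclusive count range defining a weak binding event
#'   (default c(10, 30)).
#' @return list with `overall` and (when `boundCounts` is given) `weak`,
#'   each holding precision, recall, F and the event counts.
#' @export
scoreBindingRecovery <- function(truth, assignments, catalog,
                                 boundCounts = NULL,
                                 weakRange = c(10, 30)) {
  truthB <- moduleBindingMatrix(truth, catalog)
  inferB <- moduleBindingMatrix(assignments, catalog)
  if (!all(dim(truthB) == dim(inferB)))
    stop("truth and inferred assignments cover different region sets")
  prf <- function(tB, iB) {
    tp <- sum(tB == 1L & iB == 1L)
    fp <- sum(tB == 0L & iB == 1L)
    fn <- sum(tB == 1L & iB == 0L)
    precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    list(precision = precision, recall = recall,
         F = fMeasure(precision, recall), tp = tp, fp = fp, fn = fn)
  }
  out <- list(overall = prf(truthB, inferB))
  if (!is.null(boundCounts)) {
    weak <- rowSums(truthB == 1L & boundCounts >= weakRange[1] &
                      boundCounts <= weakRange[2]) > 0
    out$weak <- prf(truthB[weak, , drop = FALSE],
                    inferB[weak, , drop = FALSE])
    out$nWeakRegions <- sum(weak)
  }
  out
}
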