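# A frozen toy state for the module-sampling oracle tests: counts chosen so
# every quantity in the categorical posterior is hand-computable.
toyState <- function(Y, gamma = 2, alphaMean = 3, betaShape = 1.5,
                     catalog = NULL, sigma2 = 4) {
  Y <- as.matrix(Y)
  colnames(Y) <- paste0("TF", seq_len(ncol(Y)))
  bc <- toyBindingCounts(Y, input = matrix(2, nrow(Y), ncol(Y)))
  params <- data.frame(tf = colnames(Y), gamma = gamma, xmin = 10,
                       alphaMean = alphaMean, betaShape = betaShape,
                       lambda = NA_real_, totalReads = colSums(Y))
  models <- new("TFModelSet", params = params, mode = "enhancer")
  if (is.null(catalog)) catalog <- enumerateModules(colnames(Y))
  cfg <- samplerConfig(burnIn = 1, nSamples = 1, seed = 1)
  st <- initializeSampler(bc, models, catalog, cfg)
  # freeze allocations at the observed counts and fix the variance
  st$X <- Y; st$I <- Y; st$sigma2 <- sigma2
  st
}

# Independent evaluation of the per-region categorical posterior: product
# over TFs of residual x emission terms for the roles the module implies.
oracleModuleProbs <- function(Y, catalog, gamma, alphaMean, betaShape,
                              sigma2, xmin = 10) {
  B <- moduleMatrix(catalog)
  K <- nrow(Y)
  P <- matrix(0, K, nrow(B))
  for (k in seq_len(K)) {
    for (m in seq_len(nrow(B))) {
      pr <- 1
      for (t in seq_len(ncol(Y))) {
        y <- Y[k, t]
        if (B[m, t] == 1) {
          pr <- pr * (if (y >= xmin)
            dnorm(0, 0, sqrt(sigma2)) * dPowerLaw(y, gamma[t], xmin) else 0)
        } else {
          pr <- pr * dnorm(0, 0, sqrt(sigma2)) *
            dGammaMeanShape(max(y, 0.5), alphaMean[t], betaShape[t])
        }
      }
      P[k, m] <- pr
    }
  }
  P / rowSums(P)
}

test_that("initial bound budget reproduces the amplified-weight split", {
  # no seeded region -> everything to background
  expect_equal(initialBoundBudget(c(0.5, 0.5), c(FALSE, FALSE), 10, 1000), 0L)
  # two regions, equal weights, one seeded, F = 10 -> (10/11) * Rt
  expect_equal(initialBoundBudget(c(0.5, 0.5), c(TRUE, FALSE), 10, 1100),
               as.integer(round(1100 * 10 / 11)))
  # all seeded -> the whole library
  expect_equal(initialBoundBudget(c(0.5, 0.5), c(TRUE, TRUE), 10, 1100),
               1100L)
})

test_that("read tossing conserves the budget and honors the floor", {
  set.seed(1)
  a <- allocateReads(c(1, 1), budget = 20, floor = 10)
  expect_equal(a, c(10, 10))
  for (i in 1:25) {
    a <- allocateReads(runif(7), budget = 500, floor = 10)
    expect_equal(sum(a), 500)
    expect_true(all(a >= 10))
  }
  # multinomial moments: weights 3:1, floor xmin = 10, budget B
  B <- 2000
  draws <- t(replicate(1000, allocateReads(c(3, 1), B, floor = 10)))
  expected <- 10 + c(0.75, 0.25) * (B - 20)
  se <- sqrt((B - 20) * c(0.75, 0.25) * c(0.25, 0.75)) / sqrt(1000)
  expect_true(all(abs(colMeans(draws) - expected) < 3 * se))
})

test_that("infeasible floors shrink the bound set instead of failing", {
  expect_message(a <- allocateReads(c(5, 1, 3), budget = 25, floor = 10),
                 "dropping")
  expect_equal(sum(a), 25)             # full budget among the kept regions
  expect_equal(a[2], 0)                # lowest-weight region dropped
  expect_true(all(a[c(1, 3)] >= 10))   # kept regions keep the floor
})

test_that("residual variance follows its inverse-Gamma posterior", {
  # prior-dominated closed form: SSR = 0, alphaN = betaN = 1, KT = 2
  # -> InverseGamma(shape 2, scale 1); check via the Gamma of 1/draws
  set.seed(2)
  draws <- replicate(5000, sampleSigma2(0, 2, 1, 1))
  ks <- ks.test(1 / draws, pgamma, shape = 2, rate = 1)
  expect_gt(ks$p.value, 0.01)
  # moment oracle with a finite-variance posterior: shape 11, scale 30
  set.seed(3)
  d2 <- replicate(20000, sampleSigma2(ssr = 58, nObs = 20, alphaN = 1,
                                      betaN = 1))
  expect_equal(mean(d2), 30 / (11 - 1), tolerance = 0.02)
})

test_that("module sampling matches the exact categorical posterior", {
  # region bound by TF1 but not TF2: odds set by the Power-Law/Gamma ratio
  Y <- rbind(c(25, 3), c(4, 4), c(40, 40))
  st <- toyState(Y)
  P <- moduleProbabilities(st)
  expect_equal(dim(P), c(3L, 4L))
  for (k in 1:3) expect_prob_vector(P[k, ])
  O <- oracleModuleProbs(Y, enumerateModules(c("TF1", "TF2")),
                         gamma = c(2, 2), alphaMean = c(3, 3),
                         betaShape = c(1.5, 1.5), sigma2 = 4)
  expect_equal(unname(P), unname(O), tolerance = 1e-10)
  # all counts below the floor -> background with probability 1
  expect_equal(unname(P[2, 1]), 1)
  # long-run sampling frequency matches the exact probabilities
  set.seed(4)
  draws <- sampleModules(st, nDraws = 2000)
  freq <- tabulate(draws[, 1] + 1L, nbins = 4) / 2000
  expect_lt(0.5 * sum(abs(freq - O[1, ])), 0.03)  # total variation
})

test_that("a hand-set 9:1 likelihood ratio is sampled at ~0.9", {
  # single region, catalog restricted to two modules whose probabilities
  # are forced to 9:1 by direct construction of the posterior
  Y <- rbind(c(25, 3))
  ct <- enumerateModules(c("TF1", "TF2"))
  st <- toyState(Y, catalog = ct)
  P <- moduleProbabilities(st)
  # restrict to the two dominant modules and renormalize as the oracle
  top2 <- order(P[1, ], decreasing = TRUE)[1:2]
  q <- P[1, top2] / sum(P[1, top2])
  set.seed(5)
  draws <- sampleModules(st, nDraws = 1000)[, 1]
  inTop <- draws %in% (top2 - 1L)
  emp <- mean(draws[inTop] == (top2[1] - 1L))
  expect_equal(emp, unname(q[1]), tolerance = 0.05)
})

test_that("sampler weights are valid and scale-invariant", {
  s <- smallSim(K = 300, seed = 9)
  bc <- s$sim$counts
  models <- suppressWarnings(fitTFModels(bc))
  ct <- enumerateModules(tfNames(bc))
  st <- initializeSampler(bc, models, ct, samplerConfig(seed = 1))
  W <- updateWeights(st)
  expect_true(all(W$bound >= 0) && all(W$background >= 0))
  expect_true(all(apply(W$background, 2, max) == 1))  # per-TF rescaled
  # normalized toss distribution is invariant to doubling all weights
  w <- W$background[1:50, 1]
  expect_equal(w / sum(w), (2 * w) / sum(2 * w))
})

test_that("the full run is reproducible and its posterior is proper", {
  s <- smallSim(K = 400, seed = 21)
  bc <- s$sim$counts
  models <- suppressWarnings(fitTFModels(bc))
  ct <- enumerateModules(tfNames(bc))
  cfg <- samplerConfig(burnIn = 20, nSamples = 30, seed = 77)
  p1 <- runGibbs(bc, models, ct, cfg)
  p2 <- runGibbs(bc, models, ct, cfg)
  expect_identical(posteriorMatrix(p1), posteriorMatrix(p2))
  rs <- rowSums(posteriorMatrix(p1))
  expect_equal(rs, rep(1, nrow(bc)), tolerance = 1e-9, ignore_attr = TRUE)
  expect_prob_vector(moduleAbundance(p1))
  # single accumulated sample -> one-hot rows
  p3 <- runGibbs(bc, models, ct,
                 samplerConfig(burnIn = 5, nSamples = 1, seed = 3))
  expect_true(all(posteriorMatrix(p3) %in% c(0, 1)))
})

test_that("posterior modes follow the tau threshold rule", {
  ct <- enumerateModules(c("A", "B"))
  Chat <- rbind(c(0.05, 0.55, 0.40, 0.0),
                c(0.96, 0.02, 0.01, 0.01),
                c(0.20, 0.05, 0.05, 0.70))
  rownames(Chat) <- paste0("r", 1:3)
  colnames(Chat) <- moduleIds(ct)
  post <- new("ModulePosterior", Chat = Chat,
              abundance = colSums(Chat) / 3, catalog = ct,
              config = list(), diagnostics = list())
  sets <- assignModules(post, tau = 0.1)
  expect_equal(sets[[1]], c(1L, 2L), ignore_attr = TRUE)
  expect_length(sets[[2]], 0)        # nothing reaches tau -> background
  expect_equal(sets[[3]], 3L, ignore_attr = TRUE)
  expect_error(assignModules(post, tau = 1.2), "tau")
  # abundance identity: colSums(Chat)/K equals the normalized accumulation
  expect_equal(moduleAbundance(post),
               colSums(Chat) / sum(Chat), ignore_attr = TRUE)
})

test_that("binding matrices union the assigned modules", {
  ct <- enumerateModules(c("A", "B", "C"))
  # module indices: 1 = A, 2 = B, 3 = A+B, 4 = C, ...
  sets <- list(integer(0), 3L, c(1L, 4L))
  bm <- moduleBindingMatrix(sets, ct)
  expect_equal(unname(bm),
               rbind(c(0L, 0L, 0L), c(1L, 1L, 0L), c(1L, 0L, 1L)))
})
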