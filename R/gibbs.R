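#' @importFrom stats rmultinom
NULL

.LOGZERO <- -1e30  # stands in for log(0) so matrix products stay finite

# Precomputed quantities shared by all sampler steps.
.samplerContext <- function(bc, models, catalog, config) {
  Y <- unname(counts(bc))
  storage.mode(Y) <- "double"
  tfs <- tfNames(bc)
  p <- tfParams(models)
  if (!all(tfs %in% p$tf))
    stop("models do not cover all TFs in the count matrix")
  p <- p[match(tfs, p$tf), , drop = FALSE]
  B <- moduleMatrix(catalog)
  if (!all(tfs %in% colnames(B)))
    stop("catalog does not cover all TFs in the count matrix")
  B <- B[, tfs, drop = FALSE]
  K <- nrow(Y); T <- ncol(Y)
  xmin <- config@xmin
  lZ <- vapply(p$gamma, .plLogNorm, numeric(1), xmin = xmin)
  d <- tssDistance(bc)
  if (config@mode == "promoter" && any(!is.na(d))) {
    if (any(is.na(p$lambda)))
      stop("promoter mode requires a fitted distance decay for every TF")
    ldb <- vapply(seq_len(T), function(t)
      ifelse(is.na(d), 0, log(p$lambda[t]) - p$lambda[t] * abs(d)),
      numeric(K))
    ldu <- ifelse(is.na(d), 0,
                  log(binSize(bc) / metadata(rowRanges(bc))$promoterSpan))
  } else {
    ldb <- matrix(0, K, T)
    ldu <- numeric(K)
  }
  Rt <- colSums(Y)
  if (any(Rt <= 0))
    stop("TF with zero total reads: ", paste(tfs[Rt <= 0], collapse = ", "))
  list(Y = Y, K = K, T = T, B = B, M1 = nrow(B), tfs = tfs,
       gamma = p$gamma, lZ = lZ, alphaMean = p$alphaMean,
       betaShape = p$betaShape, Rt = Rt, LDB = ldb, LDU = ldu,
       xmin = xmin, rawInput = unname(inputCounts(bc)))
}

# Eq-12 style log weights for the bound (LB) and background (LG) roles at
# every (region, TF) entry. Entries whose bound-role count sits below the
# Power-Law floor get .LOGZERO: such regions are background with
# probability one.
.logWeights <- function(X, I, Y, sigma2, ctx) {
  sdN <- sqrt(sigma2)
  LB <- matrix(.LOGZERO, ctx$K, ctx$T)
  LG <- matrix(0, ctx$K, ctx$T)
  for (t in seq_len(ctx$T)) {
    x <- X[, t]
    ok <- x >= ctx$xmin
    if (any(ok))
      LB[ok, t] <- dnorm(Y[ok, t] - x[ok], 0, sdN, log = TRUE) -
        ctx$gamma[t] * log(x[ok]) - ctx$lZ[t] + ctx$LDB[ok, t]
    i <- I[, t]
    LG[, t] <- dnorm(Y[, t] - i, 0, sdN, log = TRUE) +
      dGammaMeanShape(pmax(i, 0.5), ctx$alphaMean[t], ctx$betaShape[t],
                      log = TRUE) + ctx$LDU
  }
  list(LB = LB, LG = LG)
}

#' Initial bound-read budget from amplified weights
#'
#' Splits a TF's library between bound and background regions from the
#' initial all-background weights: the seeded bound regions have their
#' weights amplified by `F` and receive
#' `Rt * F * sum(w[seeded]) / (F * sum(w[seeded]) + sum(w[!seeded]))` reads.
#'
#' @param weights per-region initial weights (proportional to observed
#'   counts).
#' @param seeded logical vector marking the seeded bound regions.
#' @param F weight amplification fold.
#' @param Rt total reads of the TF.
#' @return integer read budget for the bound regions.
#' @export
initialBoundBudget <- function(weights, seeded, F, Rt) {
  num <- F * sum(weights[seeded])
  den <- num + sum(weights[!seeded])
  if (den == 0) return(0L)
  as.integer(round(Rt * num / den))
}

#' Toss reads to regions proportionally to their weights
#'
#' Implements sequential one-by-one read assignment as a single multinomial
#' draw (distributionally identical). With a positive `floor` every region
#' first receives `floor` reads and the remainder is shared
#' multinomially; if the budget cannot cover the floor, the lowest-weight
#' regions are dropped from the draw (allocation 0) with a message.
#'
#' @param weights nonnegative region weights (need not be normalized).
#' @param budget total reads to assign.
#' @param floor minimum reads per region (xmin for bound regions, 0 for
#'   background).
#' @return numeric vector of allocated counts summing exactly to `budget`
#'   (or to the largest feasible multiple of `floor` below it).
#' @export
allocateReads <- function(weights, budget, floor = 0) {
  n <- length(weights)
  out <- numeric(n)
  if (n == 0L || budget <= 0) return(out)
  budget <- round(budget)
  if (any(weights < 0)) stop("negative weights")
  if (sum(weights) == 0) weights <- rep(1, n)
  keep <- seq_len(n)
  if (floor > 0 && budget < floor * n) {
    nKeep <- max(floor(budget / floor), 0L)
    message("allocateReads: budget ", budget, " cannot floor ", n,
            " regions at ", floor, "; dropping ", n - nKeep,
            " lowest-weight regions")
    if (nKeep == 0L) return(out)
    keep <- order(weights, decreasing = TRUE)[seq_len(nKeep)]
  }
  rem <- budget - floor * length(keep)
  alloc <- rep(floor, length(keep))
  if (rem > 0)
    alloc <- alloc + as.numeric(rmultinom(1L, rem, prob = weights[keep]))
  out[keep] <- alloc
  out
}

#' Draw the residual variance from its inverse-Gamma posterior
#'
#' The Gaussian residual variance has conjugate posterior
#' InverseGamma(alphaN + n/2, betaN + SSR/2) where SSR is the summed squared
#' residual between observed and sampled counts over all n = K*T entries.
#'
#' @param ssr summed squared residuals.
#' @param nObs number of (region, TF) entries.
#' @param alphaN,betaN prior shape and scale.
#' @return one draw of sigma^2_N.
#' @export
sampleSigma2 <- function(ssr, nObs, alphaN = 1, betaN = 1) {
  1 / rgamma(1L, shape = alphaN + nObs / 2, rate = betaN + ssr / 2)
}

#' Initialize the module sampler
#'
#' Initial region weights are proportional to observed counts under an
#' all-background assumption; regions with counts above the seed cutoff are
#' seeded as bound with their weights amplified `F`-fold, the bound-read
#' budget follows [initialBoundBudget()], and reads are tossed to produce
#' the initial allocations. Module indices start at the catalog row exactly
#' matching each region's rough binding calls (background when no row
#' matches).
#'
#' @param bc a [BindingCounts-class].
#' @param models a [TFModelSet-class].
#' @param catalog a [ModuleCatalog-class].
#' @param config a [SamplerConfig-class].
#' @return sampler state: list with module indices `C` (0 = background),
#'   allocation matrices `X` and `I` (entries outside the current role hold
#'   the observed count as the evaluation proxy), `sigma2`, budgets `R_X`
#'   and the precomputed context.
#' @export
initializeSampler <- function(bc, models, catalog, config = samplerConfig()) {
  ctx <- .samplerContext(bc, models, catalog, config)
  Y <- ctx$Y
  p0 <- sweep(Y, 2L, ctx$Rt, "/")
  seeded <- Y > config@seedCountCutoff
  R_X <- vapply(seq_len(ctx$T), function(t)
    as.numeric(initialBoundBudget(p0[, t], seeded[, t], config@F,
                                  ctx$Rt[t])), numeric(1))
  calls <- roughBindingCalls(Y, ctx$rawInput)
  pat <- apply(calls, 1L, paste, collapse = "")
  rowPat <- apply(ctx$B, 1L, paste, collapse = "")
  C <- match(pat, rowPat, nomatch = 1L) - 1L
  X <- Y; I <- Y
  for (t in seq_len(ctx$T)) {
    s <- which(seeded[, t])
    if (length(s))
      X[s, t] <- allocateReads(p0[s, t], R_X[t], floor = ctx$xmin)
    g <- which(!seeded[, t])
    if (length(g))
      I[g, t] <- allocateReads(p0[g, t], ctx$Rt[t] - R_X[t], floor = 0)
  }
  bound <- ctx$B[C + 1L, , drop = FALSE] == 1
  X[!bound] <- Y[!bound]  # evaluation proxy outside the current role
  I[bound] <- Y[bound]
  Yp <- ifelse(bound, X, I)
  sigma2 <- max(mean((Y - Yp)^2), 1)
  structure(list(C = C, X = X, I = I, sigma2 = sigma2, R_X = R_X,
                 config = config, ctx = ctx),
            class = "tfmodSamplerState")
}

#' Region weights for read tossing
#'
#' Returns, for the current state, the relative bound-role and
#' background-role weights at every (region, TF) entry: the Gaussian
#' residual likelihood times the emission prior (Power-Law or Gamma) times
#' the TSS-distance factor, rescaled per TF so the largest weight is 1
#' (normalization cancels in the multinomial toss).
#'
#' @param state sampler state from [initializeSampler()].
#' @return list with matrices `bound` and `background`.
#' @export
updateWeights <- function(state) {
  ctx <- state$ctx
  W <- .logWeights(state$X, state$I, ctx$Y, state$sigma2, ctx)
  shiftExp <- function(m) {
    mx <- apply(m, 2L, max)
    exp(sweep(m, 2L, mx, "-"))
  }
  list(bound = shiftExp(W$LB), background = shiftExp(W$LG))
}

# Categorical log-probabilities over all catalog rows (Eq-14 numerators).
.moduleLogProb <- function(state) {
  ctx <- state$ctx
  W <- .logWeights(state$X, state$I, ctx$Y, state$sigma2, ctx)
  tB <- t(ctx$B)
  logP <- W$LB %*% tB + W$LG %*% (1 - tB)
  bad <- !is.finite(rowSums(logP))
  if (any(bad)) {
    warning(sum(bad), " regions had non-finite module log-probabilities; ",
            "forced to background")
    logP[bad, ] <- .LOGZERO
    logP[bad, 1L] <- 0
  }
  logP
}

#' Posterior module probabilities at the current state
#'
#' Normalizes the per-region categorical distribution over all catalog rows
#' (background first) with allocations and residual variance held fixed.
#'
#' @param state sampler state.
#' @return K x (M+1) probability matrix (rows sum to 1).
#' @export
moduleProbabilities <- function(state) {
  logP <- .moduleLogProb(state)
  mx <- apply(logP, 1L, max)
  P <- exp(logP - mx)
  P / rowSums(P)
}

#' Sample a module index for every region
#'
#' Draws from the per-region categorical distribution over catalog rows via
#' the Gumbel-max trick (an exact categorical draw); allocations and the
#' residual variance are taken from the state unchanged.
#'
#' @param state sampler state.
#' @param nDraws number of independent draws (rows of the result).
#' @return integer matrix `nDraws` x K of module indices (0 = background).
#' @export
sampleModules <- function(state, nDraws = 1L) {
  logP <- .moduleLogProb(state)
  K <- nrow(logP); M1 <- ncol(logP)
  out <- matrix(0L, nDraws, K)
  for (i in seq_len(nDraws)) {
    g <- matrix(-log(-log(runif(K * M1))), K, M1)
    out[i, ] <- max.col(logP + g, ties.method = "first") - 1L
  }
  out
}

# One full sweep: weights -> read tossing -> residual variance -> modules.
.gibbsIteration <- function(state) {
  ctx <- state$ctx
  Y <- ctx$Y
  bound <- ctx$B[state$C + 1L, , drop = FALSE] == 1
  W <- .logWeights(state$X, state$I, Y, state$sigma2, ctx)
  R_X <- colSums(Y * bound)
  X <- state$X; I <- state$I
  for (t in seq_len(ctx$T)) {
    bk <- which(bound[, t])
    if (length(bk)) {
      w <- exp(W$LB[bk, t] - max(W$LB[bk, t]))
      X[bk, t] <- allocateReads(w, R_X[t], floor = ctx$xmin)
      if (R_X[t] >= ctx$xmin * length(bk))
        stopifnot(sum(X[bk, t]) == round(R_X[t]))  # read conservation
    }
    gk <- which(!bound[, t])
    if (length(gk)) {
      w <- exp(W$LG[gk, t] - max(W$LG[gk, t]))
      I[gk, t] <- allocateReads(w, ctx$Rt[t] - R_X[t], floor = 0)
      stopifnot(sum(I[gk, t]) == round(ctx$Rt[t] - R_X[t]))
    }
  }
  Yp <- ifelse(bound, X, I)
  ssr <- sum((Y - Yp)^2)
  sigma2 <- sampleSigma2(ssr, ctx$K * ctx$T, state$config@alphaN,
                         state$config@betaN)
  state$X <- X; state$I <- I; state$sigma2 <- sigma2; state$R_X <- R_X
  C <- drop(sampleModules(state, nDraws = 1L))
  boundNew <- ctx$B[C + 1L, , drop = FALSE] == 1
  X[!boundNew] <- Y[!boundNew]
  I[boundNew] <- Y[boundNew]
  state$C <- C; state$X <- X; state$I <- I
  state
}

.gewekeZ <- function(trace) {
  n <- length(trace)
  if (n < 20L) return(NA_real_)
  a <- trace[seq_len(max(2L, floor(0.1 * n)))]
  b <- trace[seq.int(floor(0.5 * n) + 1L, n)]
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

#' Run the Gibbs sampler to a posterior module summary
#'
#' Executes initialization followed by `burnIn + nSamples * thinning`
#' sweeps of read tossing, residual-variance sampling and per-region module
#' sampling; post-burn-in module draws are accumulated into the posterior
#' frequency matrix C-hat. Fully reproducible given `config@seed`.
#'
#' @param bc a [BindingCounts-class].
#' @param models a [TFModelSet-class].
#' @param catalog a [ModuleCatalog-class].
#' @param config a [SamplerConfig-class].
#' @param verbose log progress every 100 sweeps.
#' @return a [ModulePosterior-class].
#' @export
runGibbs <- function(bc, models, catalog, config = samplerConfig(),
                     verbose = FALSE) {
  if (!is.na(config@seed)) set.seed(config@seed)
  state <- initializeSampler(bc, models, catalog, config)
  ctx <- state$ctx
  total <- config@burnIn + config@nSamples * config@thinning
  Chat <- matrix(0, ctx$K, ctx$M1)
  trace <- numeric(total)
  kept <- 0L
  for (it in seq_len(total)) {
    state <- .gibbsIteration(state)
    trace[it] <- state$sigma2
    if (it > config@burnIn &&
        (it - config@burnIn) %% config@thinning == 0L) {
      Chat[cbind(seq_len(ctx$K), state$C + 1L)] <-
        Chat[cbind(seq_len(ctx$K), state$C + 1L)] + 1
      kept <- kept + 1L
    }
    if (verbose && it %% 100L == 0L)
      message("sweep ", it, "/", total, "  sigma2 = ",
              signif(state$sigma2, 4))
  }
  Chat <- Chat / kept
  rownames(Chat) <- regionIds(bc)
  colnames(Chat) <- moduleIds(catalog)
  abundance <- colSums(Chat) / ctx$K
  names(abundance) <- moduleIds(catalog)
  post <- new("ModulePosterior", Chat = Chat, abundance = abundance,
              catalog = catalog,
              config = list(F = config@F, burnIn = config@burnIn,
                            nSamples = config@nSamples,
                            thinning = config@thinning,
                            seed = config@seed, alphaN = config@alphaN,
                            betaN = config@betaN,
                            seedCountCutoff = config@seedCountCutoff,
                            mode = config@mode, tau = config@tau,
                            xmin = config@xmin),
              diagnostics = list(
                sigma2Trace = trace,
                gewekeZ = .gewekeZ(trace[-seq_len(config@burnIn)]),
                finalBoundBudget = state$R_X))
  post
}

#' Assign posterior module modes to regions
#'
#' Every non-background module whose posterior sampling frequency reaches
#' `tau` is a mode of the region's module distribution; a region with no
#' mode is background.
#'
#' @param posterior a [ModulePosterior-class].
#' @param tau sampling-frequency threshold in (0,1) (default 0.1).
#' @return list (one element per region) of integer module indices
#'   (1..M; empty = background), with the module ids as an attribute.
#' @export
assignModules <- function(posterior, tau = 0.1) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0,1)")
  Chat <- posteriorMatrix(posterior)
  nonbg <- Chat[, -1L, drop = FALSE]
  sets <- lapply(seq_len(nrow(nonbg)), function(k)
    which(nonbg[k, ] >= tau))
  names(sets) <- rownames(Chat)
  attr(sets, "moduleIds") <- colnames(nonbg)
  sets
}

#' Per-(region, TF) binding indicator implied by module assignments
#'
#' @param assignments list of module index sets from [assignModules()] (or
#'   an integer vector of single module indices, 0 = background).
#' @param catalog the [ModuleCatalog-class] the indices refer to.
#' @return binary K x T matrix.
#' @export
moduleBindingMatrix <- function(assignments, catalog) {
  B <- moduleMatrix(catalog)
  Bm <- B[-1L, , drop = FALSE]
  if (!is.list(assignments))
    assignments <- lapply(assignments, function(m)
      if (m == 0L) integer(0) else m)
  out <- matrix(0L, length(assignments), ncol(B),
                dimnames = list(NULL, colnames(B)))
  for (k in seq_along(assignments)) {
    ms <- assignments[[k]]
    if (length(ms))
      out[k, ] <- as.integer(colSums(Bm[ms, , drop = FALSE]) > 0)
  }
  out
}
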