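#' @importFrom stats dgamma pgamma dnorm optim optimize rgamma runif var sd
#' @importFrom MASS fitdistr
NULL

# log normalizing constant of the discrete power law on {xmin, xmin+1, ...}
.plLogNorm <- function(gamma, xmin) {
  z <- pracma::zeta(gamma)
  if (xmin > 1L) z <- z - sum(seq_len(xmin - 1L)^(-gamma))
  log(z)
}

#' Discrete Power-Law probability mass function
#'
#' Zeta-normalized pmf p(x) = x^-gamma / sum_{y >= xmin} y^-gamma on the
#' integer support {xmin, xmin+1, ...}; zero below `xmin`.
#'
#' @param x integer counts.
#' @param gamma exponent (> 1).
#' @param xmin support floor (default 10).
#' @param log return log-probabilities.
#' @return numeric vector of (log-)probabilities.
#' @export
dPowerLaw <- function(x, gamma, xmin = 10, log = FALSE) {
  if (gamma <= 1) stop("gamma must be > 1")
  lz <- .plLogNorm(gamma, xmin)
  lp <- ifelse(x >= xmin, -gamma * base::log(x) - lz, -Inf)
  if (log) lp else exp(lp)
}

#' Draw from the discrete Power-Law
#'
#' Exact inversion on the enumerated support `xmin:xmax` (renormalized; the
#' default cap of 1e6 reads per 500-bp bin truncates a physically impossible
#' tail). Lower `xmax` yields the truncated variant used for weak binders.
#'
#' @param n number of draws.
#' @param gamma exponent (> 1).
#' @param xmin support floor.
#' @param xmax support cap (inclusive).
#' @return integer vector of draws.
#' @export
rPowerLaw <- function(n, gamma, xmin = 10, xmax = 1e6) {
  if (xmax < xmin) stop("infeasible truncation: xmax < xmin")
  support <- seq.int(xmin, xmax)
  w <- support^(-gamma)
  cdf <- cumsum(w) / sum(w)
  support[pmin(findInterval(runif(n), cdf) + 1L, length(support))]
}

#' Gamma density in mean/shape parameterization
#'
#' The background model uses a Gamma with mean `alphaMean` and shape
#' `betaShape` (rate = shape/mean).
#'
#' @param x nonnegative values.
#' @param alphaMean,betaShape mean and shape (> 0).
#' @param log return log-density.
#' @export
dGammaMeanShape <- function(x, alphaMean, betaShape, log = FALSE) {
  dgamma(x, shape = betaShape, rate = betaShape / alphaMean, log = log)
}

#' @rdname dGammaMeanShape
#' @param n number of draws.
#' @export
rGammaMeanShape <- function(n, alphaMean, betaShape) {
  rgamma(n, shape = betaShape, rate = betaShape / alphaMean)
}

#' Fit the discrete Power-Law exponent by maximum likelihood
#'
#' With `xmin` fixed, maximizes the zeta-normalized discrete likelihood over
#' gamma in (1, 8] by one-dimensional optimization.
#'
#' @param x integer counts, all >= `xmin`.
#' @param xmin support floor (default 10).
#' @return fitted exponent `gamma`.
#' @export
fitPowerLaw <- function(x, xmin = 10) {
  if (any(x < xmin))
    stop("all counts must be >= xmin (", xmin, "); found ", min(x))
  if (length(x) < 10L)
    stop("fewer than 10 qualifying counts; drop this TF from the analysis")
  slx <- sum(base::log(x)); n <- length(x)
  nll <- function(g) n * .plLogNorm(g, xmin) + g * slx
  optimize(nll, interval = c(1.0001, 8), tol = 1e-7)$minimum
}

.gammaMoM <- function(x) {
  m <- mean(x); v <- var(x)
  if (!is.finite(v) || v <= 0) return(c(mean = m, shape = 1e6))
  c(mean = m, shape = m^2 / v)
}

#' Fit the background Gamma model to input-control counts
#'
#' With `fitHighCounts = TRUE` (default) the Gamma is fitted by a
#' left-censored maximum likelihood: counts >= `threshold` enter with their
#' full density while counts below it contribute only their aggregate mass
#' `pgamma(threshold)`. All individual-level information therefore comes
#' from the high-count background regions that confound weak binding
#' events, while the censored mass keeps the fitted tail probability
#' anchored; counts below the Power-Law floor are always treated as
#' background regardless of this fit, so underestimation there is harmless.
#' With `fitHighCounts = FALSE` a plain MLE on the positive counts is used.
#'
#' @param x nonnegative input-control counts.
#' @param fitHighCounts emphasize the high-count tail (default TRUE).
#' @param threshold truncation threshold for the tail fit (default 10, the
#'   Power-Law floor).
#' @return list with `alphaMean`, `betaShape`, `n` (points used) and
#'   `method`.
#' @export
fitGamma <- function(x, fitHighCounts = TRUE, threshold = 10) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty input")
  if (all(x == 0)) stop("all input counts are zero")
  pos <- x[x > 0]
  if (length(pos) < 10L) stop("need at least 10 positive input counts")
  if (sd(pos) == 0) {
    warning("degenerate (constant) input counts; returning a point-mass-like fit")
    return(list(alphaMean = mean(pos), betaShape = 1e6, n = length(pos),
                method = "degenerate"))
  }
  start <- .gammaMoM(pos)
  if (fitHighCounts) {
    xt <- x[x >= threshold]
    nBelow <- sum(x < threshold)
    if (length(xt) >= 10L && sd(xt) > 0) {
      nll <- function(par) {
        sh <- exp(par[1]); rt <- exp(par[2])
        -sum(dgamma(xt, shape = sh, rate = rt, log = TRUE)) -
          nBelow * pgamma(threshold, shape = sh, rate = rt, log.p = TRUE)
      }
      p0 <- c(log(start["shape"]), log(start["shape"] / start["mean"]))
      opt <- tryCatch(optim(p0, nll, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-10)),
                      error = function(e) NULL)
      if (!is.null(opt) && opt$convergence == 0) {
        sh <- exp(opt$par[1]); rt <- exp(opt$par[2])
        return(list(alphaMean = sh / rt, betaShape = sh, n = length(xt),
                    method = "censored_mle"))
      }
      warning("censored Gamma fit did not converge; falling back to full MLE")
    } else {
      warning("fewer than 10 counts >= ", threshold,
              "; falling back to full MLE on positive counts")
    }
  }
  fit <- tryCatch(
    fitdistr(pos, "gamma",
             start = list(shape = unname(start["shape"]),
                          rate = unname(start["shape"] / start["mean"])),
             lower = c(1e-8, 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gamma MLE failed; using method-of-moments estimates")
    return(list(alphaMean = unname(start["mean"]),
                betaShape = unname(start["shape"]), n = length(pos),
                method = "moments"))
  }
  sh <- unname(fit$estimate["shape"]); rt <- unname(fit$estimate["rate"])
  list(alphaMean = sh / rt, betaShape = sh, n = length(pos), method = "mle")
}

#' Fit the TSS-distance exponential decay rate
#'
#' Closed-form exponential MLE lambda = n / sum(|d|), promoter mode only.
#'
#' @param distances |d_k| of rough-bound promoter regions (bp).
#' @param mode analysis mode; `"enhancer"` is an error because the distance
#'   factor is dropped there.
#' @return decay rate per bp.
#' @export
fitDecay <- function(distances, mode = "promoter") {
  if (mode == "enhancer")
    stop("distance decay is not applicable in enhancer mode")
  distances <- abs(distances[!is.na(distances)])
  if (length(distances) == 0L) stop("no distances supplied")
  if (length(distances) < 10L)
    warning("fewer than 10 distances; decay estimate will be unstable")
  length(distances) / sum(distances)
}

#' Bound and background emission likelihoods for one TF
#'
#' The bound likelihood is the discrete Power-Law pmf when y >= xmin and
#' exactly 0 below the floor (such regions are background with probability
#' one); the background likelihood is the Gamma density evaluated at
#' max(y, 0.5) so zero counts have finite density.
#'
#' @param y nonnegative counts.
#' @param model a list / one-row data.frame with `gamma`, `xmin`,
#'   `alphaMean`, `betaShape`.
#' @return matrix with columns `bound` and `background`.
#' @export
emissionLikelihoods <- function(y, model) {
  xmin <- model$xmin
  pb <- ifelse(y >= xmin, dPowerLaw(pmax(y, xmin), model$gamma, xmin), 0)
  pg <- dGammaMeanShape(pmax(y, 0.5), model$alphaMean, model$betaShape)
  cbind(bound = pb, background = pg)
}

#' TSS-distance likelihood factor
#'
#' In promoter mode a bound region contributes lambda * exp(-lambda |d|) and
#' a background region the uniform mass binSize / promoterSpan; in enhancer
#' mode regulatory effects are independent of position and the factor is 1.
#' Undefined distances (NA) also contribute 1.
#'
#' @param d signed distance(s) to the nearest TSS (bp).
#' @param bound logical, bound or background role.
#' @param mode `"promoter"` or `"enhancer"`.
#' @param lambda per-TF decay rate (1/bp).
#' @param binSize,promoterSpan geometry of the uniform background mass.
#' @return likelihood value(s).
#' @export
distanceLikelihood <- function(d, bound, mode = c("promoter", "enhancer"),
                               lambda = NULL, binSize = 500,
                               promoterSpan = 20000) {
  mode <- match.arg(mode)
  if (mode == "enhancer") return(rep(1, length(d)))
  out <- rep(binSize / promoterSpan, length(d))
  if (any(bound)) {
    if (is.null(lambda)) stop("lambda required for bound promoter regions")
    out[bound] <- lambda * exp(-lambda * abs(d[bound]))
  }
  out[is.na(d)] <- 1
  out
}

#' Fit all per-TF emission models from a BindingCounts object
#'
#' For each TF the Power-Law exponent is fitted to regions with counts > 10
#' and a > 2-fold increase over the matched input (the rough binding set);
#' the background Gamma is fitted to the TF's input profile; in promoter
#' mode the distance decay is fitted to |d_k| of the rough binding set.
#'
#' @param bc a [BindingCounts-class] object.
#' @param mode `"enhancer"` (default) or `"promoter"`.
#' @param xmin Power-Law support floor.
#' @param fitHighCounts,gammaThreshold passed to [fitGamma()].
#' @return a [TFModelSet-class].
#' @export
fitTFModels <- function(bc, mode = c("enhancer", "promoter"), xmin = 10,
                        fitHighCounts = TRUE, gammaThreshold = 10) {
  mode <- match.arg(mode)
  Y <- counts(bc); ic <- inputCounts(bc)
  calls <- roughBindingCalls(bc)
  d <- tssDistance(bc)
  rows <- lapply(seq_len(ncol(Y)), function(t) {
    yt <- Y[, t]
    qual <- yt[calls[, t] == 1]
    if (length(qual) < 10L)
      stop("TF ", colnames(Y)[t], ": fewer than 10 rough-bound regions; ",
           "drop this TF from the analysis")
    g <- fitPowerLaw(qual, xmin = xmin)
    gm <- fitGamma(ic[, t], fitHighCounts = fitHighCounts,
                   threshold = gammaThreshold)
    lam <- NA_real_
    if (mode == "promoter") {
      dd <- d[calls[, t] == 1]
      lam <- fitDecay(dd, mode = "promoter")
    }
    Rt <- sum(yt)
    if (Rt <= 0) stop("TF ", colnames(Y)[t], " has zero total reads")
    data.frame(tf = colnames(Y)[t], gamma = g, xmin = xmin,
               alphaMean = gm$alphaMean, betaShape = gm$betaShape,
               lambda = lam, totalReads = Rt, stringsAsFactors = FALSE)
  })
  params <- do.call(rbind, rows)
  rownames(params) <- NULL
  new("TFModelSet", params = params, mode = mode)
}

#' Serialize / restore fitted TF models as JSON
#'
#' @param models a [TFModelSet-class].
#' @param path JSON file path.
#' @export
writeTFModels <- function(models, path) {
  jsonlite::write_json(list(mode = models@mode, params = models@params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTFModels
#' @export
readTFModels <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- as.data.frame(obj$params)
  if (is.null(p$lambda)) p$lambda <- NA_real_  # all-NA columns drop in JSON
  for (cn in c("gamma", "xmin", "alphaMean", "betaShape", "lambda",
               "totalReads"))
    p[[cn]] <- as.numeric(p[[cn]])
  new("TFModelSet", params = p, mode = obj$mode)
}
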