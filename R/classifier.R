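#' @importFrom stats plogis predict coef
NULL

#' Label regions from activity measurements
#'
#' A region is `positive` when its TPM exceeds `threshold` in at least
#' `minSamples` samples of the focal context, `negative` when it is not
#' positive here but is active in another context, and `unlabeled`
#' otherwise.
#'
#' @param tpm region x sample activity matrix (e.g. CAGE TPM).
#' @param focalSamples column names or indices of the focal-context samples
#'   (at least 2).
#' @param threshold TPM threshold (default 1).
#' @param minSamples minimum focal samples above threshold (default 2).
#' @param crossActive logical vector flagging regions active in another
#'   context; when `NULL` it is derived from the non-focal columns with the
#'   same rule.
#' @return factor with levels `negative`, `positive`, `unlabeled`.
#' @export
labelRegions <- function(tpm, focalSamples, threshold = 1, minSamples = 2,
                         crossActive = NULL) {
  tpm <- as.matrix(tpm)
  if (is.character(focalSamples))
    focalSamples <- match(focalSamples, colnames(tpm))
  if (anyNA(focalSamples)) stop("unknown focal sample names")
  if (length(focalSamples) < 2L)
    stop("need at least 2 focal-context samples")
  focal <- tpm[, focalSamples, drop = FALSE]
  pos <- rowSums(focal > threshold) >= minSamples
  if (is.null(crossActive)) {
    others <- tpm[, -focalSamples, drop = FALSE]
    if (ncol(others) == 0L)
      stop("crossActive flags or non-focal columns required for negatives")
    crossActive <- rowSums(others > threshold) >= minSamples
  }
  lab <- rep("unlabeled", nrow(tpm))
  lab[pos] <- "positive"
  lab[!pos & crossActive] <- "negative"
  factor(lab, levels = c("negative", "positive", "unlabeled"))
}

#' Penalized binomial objective of the activity classifier
#'
#' Mean negative log-likelihood of the logistic model plus the elastic-net
#' penalty `lambda * ((1 - alpha)/2 * sum(beta^2) + alpha * sum(|beta|))`;
#' the intercept is unpenalized.
#'
#' @param beta0,beta intercept and module weights.
#' @param x feature matrix (posterior module probabilities).
#' @param z binary labels (0/1).
#' @param lambda,alpha penalty strength and mixing.
#' @return objective value.
#' @export
elasticNetObjective <- function(beta0, beta, x, z, lambda, alpha) {
  eta <- beta0 + drop(as.matrix(x) %*% beta)
  nll <- mean(-z * eta + log1p(exp(eta)))
  nll + lambda * ((1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta)))
}

.labelsToBinary <- function(labels) {
  labels <- as.character(labels)
  keep <- labels %in% c("positive", "negative")
  list(keep = keep, z = as.integer(labels[keep] == "positive"))
}

#' Fit the elastic-net activity classifier
#'
#' Trains the penalized binomial model on posterior module probabilities of
#' the labeled regions. When `lambda` is `NULL` it is chosen by 5-fold
#' cross-validation over a 50-value log-spaced grid with the 1-SE rule
#' (folds are deterministic given `seed`). Features are left on their
#' natural [0,1] probability scale (no standardization).
#'
#' @param features K' x M matrix of posterior module probabilities
#'   (labeled regions only, or aligned with `labels`).
#' @param labels factor from [labelRegions()] (unlabeled rows are dropped)
#'   or a 0/1 vector.
#' @param alpha L1/L2 mixing in [0,1] (default 0.5).
#' @param lambda penalty; `NULL` selects by cross-validation.
#' @param seed RNG seed for the fold assignment.
#' @return an [ActivityModel-class].
#' @export
fitElasticNet <- function(features, labels, alpha = 0.5, lambda = NULL,
                          seed = 1L) {
  features <- as.matrix(features)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    keep <- rep(TRUE, length(labels)); z <- as.integer(labels)
  } else {
    lb <- .labelsToBinary(labels); keep <- lb$keep; z <- lb$z
  }
  x <- features[keep, , drop = FALSE]
  if (length(unique(z)) < 2L)
    stop("both activity classes must be present for training")
  if (is.null(lambda)) {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(5L), length(z)))
    cv <- glmnet::cv.glmnet(x, z, family = "binomial", alpha = alpha,
                            nlambda = 50L, foldid = foldid,
                            standardize = FALSE)
    lambda <- cv$lambda.1se
  }
  fit <- glmnet::glmnet(x, z, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-16, maxit = 1e7)
  cf <- as.matrix(coef(fit))
  beta <- cf[-1L, 1L]
  names(beta) <- colnames(x)
  new("ActivityModel", beta0 = unname(cf[1L, 1L]), beta = beta,
      lambda = lambda, alpha = alpha, fit = fit)
}

#' Predict regulatory activity scores
#'
#' Logistic score sigma(beta0 + sum_m chat_km * beta_m) for every region;
#' the score ranking drives top-fraction selections.
#'
#' @param features K x M posterior module probabilities; columns must match
#'   the training catalog.
#' @param model an [ActivityModel-class].
#' @return numeric score in (0,1) per region.
#' @export
predictActivity <- function(features, model) {
  features <- as.matrix(features)
  if (!identical(colnames(features), names(model@beta)))
    stop("feature columns do not match the training module catalog")
  plogis(model@beta0 + drop(features %*% model@beta))
}

#' Harmonic-mean F-measure
#'
#' @param precision,recall in [0,1].
#' @return 2 / (1/precision + 1/recall); 0 when either is 0.
#' @export
fMeasure <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Repeated stratified holdout evaluation of activity prediction
#'
#' Repeats a stratified train/test split of the labeled regions, refits the
#' classifier on the training split and scores the held-out regions with the
#' F-measure at a 0.5 score cutoff.
#'
#' @param features K' x M posterior module probabilities.
#' @param labels labels aligned with the rows (unlabeled dropped).
#' @param trainFraction fraction of labeled regions used for training
#'   (default 0.8).
#' @param repeats number of random splits (default 100).
#' @param alpha,lambda elastic-net settings (lambda `NULL` = per-split CV).
#' @param seed RNG seed.
#' @param cutoff score cutoff calling a prediction positive (default 0.5).
#' @return numeric vector of per-split F-measures.
#' @export
holdoutEvaluate <- function(features, labels, trainFraction = 0.8,
                            repeats = 100L, alpha = 0.5, lambda = NULL,
                            seed = 1L, cutoff = 0.5) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0,1)")
  features <- as.matrix(features)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    x <- features; z <- as.integer(labels)
  } else {
    lb <- .labelsToBinary(labels)
    x <- features[lb$keep, , drop = FALSE]
    z <- lb$z
  }
  idxPos <- which(z == 1L); idxNeg <- which(z == 0L)
  if (length(idxPos) < 2L || length(idxNeg) < 2L)
    stop("need at least two regions of each class")
  set.seed(seed)
  vapply(seq_len(repeats), function(r) {
    trPos <- sample(idxPos, max(1L, round(trainFraction * length(idxPos))))
    trNeg <- sample(idxNeg, max(1L, round(trainFraction * length(idxNeg))))
    tr <- c(trPos, trNeg)
    te <- setdiff(seq_along(z), tr)
    if (length(unique(z[te])) < 2L) return(NA_real_)
    mdl <- fitElasticNet(x[tr, , drop = FALSE], z[tr], alpha = alpha,
                         lambda = lambda, seed = seed + r)
    sc <- predictActivity(x[te, , drop = FALSE], mdl)
    pred <- as.integer(sc > cutoff)
    tp <- sum(pred == 1L & z[te] == 1L)
    prec <- if (sum(pred == 1L) == 0L) 0 else tp / sum(pred == 1L)
    rec <- if (sum(z[te] == 1L) == 0L) 0 else tp / sum(z[te] == 1L)
    fMeasure(prec, rec)
  }, numeric(1))
}
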