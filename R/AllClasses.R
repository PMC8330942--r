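#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' Container for binned multi-TF ChIP-seq read counts
#'
#' `BindingCounts` extends `RangedSummarizedExperiment` with two assays:
#' `counts`, the K x T matrix of observed ChIP-seq read counts per 500-bp bin
#' and TF, and `input`, the matched input-control counts (a shared control is
#' recycled across TFs). Row ranges carry the region identifier, the signed
#' distance of the bin center to the nearest TSS (`tss_distance`, NA until
#' annotated) and the region class (`promoter`, `enhancer` or `unannotated`).
#'
#' @export
setClass("BindingCounts", contains = "RangedSummarizedExperiment")

setValidity("BindingCounts", function(object) {
  a <- assays(object)
  if (!all(c("counts", "input") %in% names(a)))
    return("assays must contain 'counts' and 'input'")
  Y <- a$counts; ic <- a$input
  if (!all(dim(Y) == dim(ic)))
    return("'counts' and 'input' must have identical dimensions")
  if (nrow(Y) < 1L || ncol(Y) < 1L)
    return("need at least one region and one TF")
  if (any(Y < 0) || any(ic < 0))
    return("read counts must be nonnegative")
  if (anyDuplicated(colnames(Y)))
    return("TF names must be unique")
  rr <- rowRanges(object)
  need <- c("region_id", "region_class", "tss_distance")
  if (!all(need %in% names(mcols(rr))))
    return("rowRanges must carry region_id, region_class, tss_distance")
  if (anyDuplicated(mcols(rr)$region_id))
    return("region_ids must be unique")
  TRUE
})

#' Construct a BindingCounts object
#'
#' @param counts K x T matrix of observed TF read counts (columns named by TF).
#' @param input matched input-control counts: K x T matrix or a single K-vector
#'   shared by all TFs.
#' @param regions `GRanges` of the binned regions (as returned by
#'   [loadRegions()]); when `NULL` a synthetic coordinate frame of consecutive
#'   `binSize`-bp bins on one contig is fabricated.
#' @param tfNames character vector of TF names (defaults to `colnames(counts)`).
#' @param binSize,promoterSpan bin width and promoter window (bp) recorded in
#'   the object metadata.
#' @return a [BindingCounts-class] object.
#' @export
BindingCounts <- function(counts, input, regions = NULL,
                          tfNames = colnames(counts),
                          binSize = 500L, promoterSpan = 20000L) {
  counts <- as.matrix(counts)
  if (is.null(tfNames)) tfNames <- paste0("TF", seq_len(ncol(counts)))
  colnames(counts) <- tfNames
  input <- as.matrix(input)
  if (ncol(input) == 1L && ncol(counts) > 1L)
    input <- input[, rep(1L, ncol(counts)), drop = FALSE]
  colnames(input) <- tfNames
  K <- nrow(counts)
  if (is.null(regions)) {
    starts <- (seq_len(K) - 1L) * binSize
    regions <- GRanges("regionSet",
                       IRanges(start = starts + 1L, width = binSize))
    mcols(regions)$region_id <- sprintf("bin_%06d", seq_len(K))
    mcols(regions)$region_class <- rep("unannotated", K)
    mcols(regions)$tss_distance <- rep(NA_real_, K)
  }
  if (length(regions) != K)
    stop("'regions' length does not match the number of count rows")
  md <- metadata(regions)
  metadata(regions)$binSize <- if (is.null(md$binSize)) binSize else md$binSize
  if (is.null(md$promoterSpan)) metadata(regions)$promoterSpan <- promoterSpan
  se <- SummarizedExperiment(
    assays = SimpleList(counts = counts, input = input),
    rowRanges = regions)
  rownames(se) <- mcols(regions)$region_id
  new("BindingCounts", se)
}

#' Catalog of candidate TF modules
#'
#' Holds the (M+1) x T binary matrix B of candidate modules; row 1 is the
#' all-zero background row (module index 0). Rows are named by the TFs they
#' combine (`"TF1+TF3"`), the background row `"background"`.
#'
#' @slot B binary matrix, background row first.
#' @slot provenance `"exhaustive"`, `"top_k"` or `"truth"`.
#' @export
setClass("ModuleCatalog",
         representation(B = "matrix", provenance = "character"))

setValidity("ModuleCatalog", function(object) {
  B <- object@B
  if (nrow(B) < 1L) return("catalog needs at least the background row")
  if (any(B != 0 & B != 1)) return("B must be binary")
  if (any(B[1L, ] != 0)) return("row 1 must be the all-zero background row")
  if (anyDuplicated(apply(B, 1L, paste, collapse = "")))
    return("duplicate module rows")
  if (nrow(B) > 1L && any(rowSums(B[-1L, , drop = FALSE]) < 1))
    return("non-background rows must bind at least one TF")
  if (is.null(colnames(B))) return("B must have TF column names")
  TRUE
})

.moduleIdsFromB <- function(B) {
  ids <- apply(B, 1L, function(b) {
    if (!any(b == 1)) "background" else
      paste(colnames(B)[b == 1], collapse = "+")
  })
  unname(ids)
}

#' @rdname ModuleCatalog-class
#' @param B binary module matrix (background row optional; added if missing).
#' @param tfNames TF names for the columns of `B`.
#' @param provenance how the catalog was built.
#' @export
ModuleCatalog <- function(B, tfNames = colnames(B),
                          provenance = "exhaustive") {
  B <- as.matrix(B)
  if (is.null(tfNames)) tfNames <- paste0("TF", seq_len(ncol(B)))
  colnames(B) <- tfNames
  if (nrow(B) == 0L || any(B[1L, ] != 0))
    B <- rbind(matrix(0, 1L, ncol(B), dimnames = list(NULL, tfNames)), B)
  rownames(B) <- .moduleIdsFromB(B)
  new("ModuleCatalog", B = B, provenance = provenance)
}

#' Per-TF emission model parameters
#'
#' One row per TF: the discrete Power-Law exponent `gamma` with support floor
#' `xmin` for bound-region counts, the background Gamma in its mean
#' (`alphaMean`) / shape (`betaShape`) parameterization, the TSS-distance
#' exponential decay `lambda` (NA in enhancer mode) and the library total
#' `totalReads`.
#'
#' @slot params data.frame of per-TF parameters.
#' @slot mode `"promoter"` or `"enhancer"`.
#' @export
setClass("TFModelSet",
         representation(params = "data.frame", mode = "character"))

setValidity("TFModelSet", function(object) {
  p <- object@params
  need <- c("tf", "gamma", "xmin", "alphaMean", "betaShape", "lambda",
            "totalReads")
  if (!all(need %in% names(p))) return("missing parameter columns")
  if (any(p$gamma <= 1)) return("gamma must be > 1")
  if (any(p$alphaMean <= 0) || any(p$betaShape <= 0))
    return("Gamma mean and shape must be positive")
  if (any(p$xmin < 1)) return("xmin must be >= 1")
  if (any(!is.na(p$lambda) & p$lambda <= 0))
    return("lambda must be positive when fitted")
  if (!object@mode %in% c("promoter", "enhancer"))
    return("mode must be 'promoter' or 'enhancer'")
  TRUE
})

#' Gibbs sampler configuration
#'
#' @slot F weight amplification fold for seeded bound regions at
#'   initialization (dimensionless).
#' @slot burnIn,nSamples,thinning iteration schedule.
#' @slot seed RNG seed applied at the start of a run (NA = leave RNG alone).
#' @slot alphaN,betaN inverse-Gamma prior on the residual variance.
#' @slot seedCountCutoff observed-count threshold seeding the initial
#'   bound set.
#' @slot mode `"promoter"` or `"enhancer"` (controls the distance factor).
#' @slot tau posterior sampling-frequency threshold defining module modes.
#' @slot xmin Power-Law support floor; counts below it are background with
#'   probability one.
#' @export
setClass("SamplerConfig",
         representation(F = "numeric", burnIn = "integer",
                        nSamples = "integer", thinning = "integer",
                        seed = "numeric", alphaN = "numeric",
                        betaN = "numeric", seedCountCutoff = "numeric",
                        mode = "character", tau = "numeric",
                        xmin = "numeric"))

setValidity("SamplerConfig", function(object) {
  if (object@F <= 1) return("F must be > 1")
  if (object@burnIn < 1L || object@nSamples < 1L || object@thinning < 1L)
    return("burnIn, nSamples and thinning must be >= 1")
  if (!object@mode %in% c("promoter", "enhancer"))
    return("mode must be 'promoter' or 'enhancer'")
  if (object@tau <= 0 || object@tau >= 1) return("tau must be in (0,1)")
  if (object@alphaN <= 0 || object@betaN <= 0)
    return("alphaN and betaN must be positive")
  TRUE
})

#' @rdname SamplerConfig-class
#' @param F,burnIn,nSamples,thinning,seed,alphaN,betaN,seedCountCutoff,mode,tau,xmin
#'   see the class slots.
#' @export
samplerConfig <- function(F = 10, burnIn = 200L, nSamples = 500L,
                          thinning = 1L, seed = NA_real_, alphaN = 1,
                          betaN = 1, seedCountCutoff = 50,
                          mode = c("enhancer", "promoter"), tau = 0.1,
                          xmin = 10) {
  mode <- match.arg(mode)
  new("SamplerConfig", F = F, burnIn = as.integer(burnIn),
      nSamples = as.integer(nSamples), thinning = as.integer(thinning),
      seed = as.numeric(seed), alphaN = alphaN, betaN = betaN,
      seedCountCutoff = seedCountCutoff, mode = mode, tau = tau,
      xmin = xmin)
}

#' Posterior summary of the module sampler
#'
#' @slot Chat K x (M+1) matrix of posterior sampling frequencies; rows are
#'   probability vectors over the catalog (background column first).
#' @slot abundance per-module fraction of accumulated samples across regions.
#' @slot catalog the [ModuleCatalog-class] sampled over.
#' @slot config run configuration echoed as a list.
#' @slot diagnostics residual-variance trace and a Geweke-style z score.
#' @export
setClass("ModulePosterior",
         representation(Chat = "matrix", abundance = "numeric",
                        catalog = "ModuleCatalog", config = "list",
                        diagnostics = "list"))

setValidity("ModulePosterior", function(object) {
  rs <- rowSums(object@Chat)
  if (any(abs(rs - 1) > 1e-9)) return("Chat rows must sum to 1")
  if (abs(sum(object@abundance) - 1) > 1e-9)
    return("abundance must sum to 1")
  if (ncol(object@Chat) != nrow(object@catalog@B))
    return("Chat columns must match catalog rows")
  TRUE
})

#' Elastic-net activity classifier
#'
#' @slot beta0 intercept.
#' @slot beta per-module weights (named by module id).
#' @slot lambda,alpha penalty strength and L1/L2 mixing of the elastic net.
#' @slot fit the underlying glmnet fit (kept for prediction paths).
#' @export
setClass("ActivityModel",
         representation(beta0 = "numeric", beta = "numeric",
                        lambda = "numeric", alpha = "numeric", fit = "ANY"))

setValidity("ActivityModel", function(object) {
  if (!all(is.finite(object@beta)) || !is.finite(object@beta0))
    return("weights must be finite")
  if (object@alpha < 0 || object@alpha > 1)
    return("alpha must be in [0,1]")
  if (object@lambda < 0) return("lambda must be nonnegative")
  TRUE
})
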