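#' Rough per-TF binding calls
#'
#' A (region, TF) pair is called bound when the observed count exceeds 10 and
#' exceeds twice the matched input count (an input of zero is replaced by a
#' 0.5 pseudo-count for the ratio).
#'
#' @param x a [BindingCounts-class], or a count matrix (then `input` must be
#'   given).
#' @param input input-control matrix aligned with `x`.
#' @param minCount strict count threshold (default 10).
#' @param foldChange strict fold-change threshold over input (default 2).
#' @return binary K x T matrix of calls.
#' @export
roughBindingCalls <- function(x, input = NULL, minCount = 10,
                              foldChange = 2) {
  if (is(x, "BindingCounts")) {
    input <- inputCounts(x)
    x <- counts(x)
  }
  if (is.null(input)) stop("input counts required")
  inp <- pmax(input, 0.5)
  calls <- (x > minCount) & (x > foldChange * inp)
  storage.mode(calls) <- "integer"
  calls
}

#' Enumerate all TF combinations as candidate modules
#'
#' Exhaustive catalog of all 2^T - 1 nonempty TF combinations plus the
#' background row; feasible only for small TF panels, guarded by a capacity
#' cap (default 2^T <= 256, i.e. up to 8 TFs).
#'
#' @param tfNames character vector of TF names (or an integer T).
#' @param cap maximum number of combinations 2^T allowed.
#' @return a [ModuleCatalog-class] with provenance `"exhaustive"`.
#' @export
enumerateModules <- function(tfNames, cap = 256L) {
  if (is.numeric(tfNames) && length(tfNames) == 1L)
    tfNames <- paste0("TF", seq_len(tfNames))
  T <- length(tfNames)
  if (2^T > cap)
    stop("2^", T, " = ", 2^T, " exceeds the exhaustive cap (", cap,
         "); use topKModules() on rough binding calls instead")
  M <- 2^T - 1L
  B <- matrix(0L, nrow = M, ncol = T, dimnames = list(NULL, tfNames))
  for (m in seq_len(M))
    B[m, ] <- as.integer(bitwAnd(m, bitwShiftL(1L, seq_len(T) - 1L)) > 0L)
  ModuleCatalog(B, tfNames = tfNames, provenance = "exhaustive")
}

#' Frequency-ranked candidate module search
#'
#' Tallies each region's exact rough-call pattern (restricted to patterns
#' with at least two TFs, since a module requires co-binding) and keeps the
#' `k` patterns covering the most regions; ties are broken by lexicographic
#' pattern order. Single-TF binding remains representable through the
#' exhaustive catalog for small panels.
#'
#' @param calls binary K x T rough-call matrix from [roughBindingCalls()].
#' @param k number of candidate modules to keep (default 100).
#' @param minTFs minimum TFs per pattern (default 2).
#' @return a [ModuleCatalog-class] with provenance `"top_k"`.
#' @export
topKModules <- function(calls, k = 100L, minTFs = 2L) {
  if (k < 1L) stop("k must be >= 1")
  calls <- as.matrix(calls)
  tfNames <- colnames(calls)
  if (is.null(tfNames)) tfNames <- paste0("TF", seq_len(ncol(calls)))
  keep <- rowSums(calls) >= minTFs
  if (!any(keep))
    stop("no region shows a rough-call pattern with >= ", minTFs, " TFs")
  pats <- apply(calls[keep, , drop = FALSE], 1L, paste, collapse = "")
  tab <- table(pats)
  ord <- order(-as.integer(tab), names(tab))
  pats <- names(tab)[ord]
  if (length(pats) < k)
    warning("only ", length(pats), " distinct patterns available (k = ",
            k, "); returning all")
  pats <- utils::head(pats, k)
  B <- t(vapply(strsplit(pats, ""), function(b) as.integer(b == "1"),
                integer(ncol(calls))))
  colnames(B) <- tfNames
  ModuleCatalog(B, tfNames = tfNames, provenance = "top_k")
}

#' Write / read a module catalog as TSV
#'
#' Layout: `module_id` column followed by one binary column per TF.
#'
#' @param catalog a [ModuleCatalog-class].
#' @param path TSV file path.
#' @export
writeModuleCatalog <- function(catalog, path) {
  B <- moduleMatrix(catalog)
  df <- data.frame(module_id = rownames(B), B, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeModuleCatalog
#' @export
readModuleCatalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  B <- as.matrix(df[, -1L, drop = FALSE])
  rownames(B) <- NULL
  bg <- which(rowSums(B) == 0)
  prov <- "top_k"
  if (length(bg)) B <- B[-bg, , drop = FALSE]
  ModuleCatalog(B, provenance = prov)
}
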