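#' @importFrom BiocGenerics counts
NULL

#' @describeIn BindingCounts-class observed TF read-count matrix.
#' @param object a `BindingCounts`.
#' @export
setMethod("counts", "BindingCounts", function(object) {
  assay(object, "counts")
})

#' @export
setGeneric("inputCounts", function(object) standardGeneric("inputCounts"))

#' @describeIn BindingCounts-class matched input-control count matrix.
#' @export
setMethod("inputCounts", "BindingCounts", function(object) {
  assay(object, "input")
})

#' @export
setGeneric("tfNames", function(object) standardGeneric("tfNames"))

#' @describeIn BindingCounts-class TF names (assay columns).
#' @export
setMethod("tfNames", "BindingCounts", function(object) colnames(object))

#' @describeIn ModuleCatalog-class TF names (catalog columns).
#' @export
setMethod("tfNames", "ModuleCatalog", function(object) colnames(object@B))

#' @describeIn TFModelSet-class TF names.
#' @export
setMethod("tfNames", "TFModelSet", function(object) object@params$tf)

#' @export
setGeneric("regionIds", function(object) standardGeneric("regionIds"))

#' @describeIn BindingCounts-class unique region identifiers.
#' @export
setMethod("regionIds", "BindingCounts", function(object) {
  mcols(rowRanges(object))$region_id
})

#' @export
setGeneric("regionClass", function(object) standardGeneric("regionClass"))

#' @describeIn BindingCounts-class region class per bin.
#' @export
setMethod("regionClass", "BindingCounts", function(object) {
  mcols(rowRanges(object))$region_class
})

#' @export
setGeneric("tssDistance", function(object) standardGeneric("tssDistance"))

#' @describeIn BindingCounts-class signed bin-center distance to the nearest
#'   TSS (NA until annotated).
#' @export
setMethod("tssDistance", "BindingCounts", function(object) {
  mcols(rowRanges(object))$tss_distance
})

#' @export
setGeneric("binSize", function(object) standardGeneric("binSize"))

#' @describeIn BindingCounts-class bin width in bp.
#' @export
setMethod("binSize", "BindingCounts", function(object) {
  bs <- metadata(rowRanges(object))$binSize
  if (is.null(bs)) 500L else bs
})

#' @export
setGeneric("moduleMatrix", function(object) standardGeneric("moduleMatrix"))

#' @describeIn ModuleCatalog-class the binary module matrix, background row
#'   first.
#' @param object a `ModuleCatalog`.
#' @export
setMethod("moduleMatrix", "ModuleCatalog", function(object) object@B)

#' @export
setGeneric("nModules", function(object) standardGeneric("nModules"))

#' @describeIn ModuleCatalog-class number of non-background modules M.
#' @export
setMethod("nModules", "ModuleCatalog", function(object) nrow(object@B) - 1L)

#' @export
setGeneric("moduleIds", function(object) standardGeneric("moduleIds"))

#' @describeIn ModuleCatalog-class module identifiers, background first.
#' @export
setMethod("moduleIds", "ModuleCatalog", function(object) rownames(object@B))

#' @export
setGeneric("tfParams", function(object) standardGeneric("tfParams"))

#' @describeIn TFModelSet-class per-TF parameter table.
#' @param object a `TFModelSet`.
#' @export
setMethod("tfParams", "TFModelSet", function(object) object@params)

#' @export
setGeneric("posteriorMatrix", function(object) standardGeneric("posteriorMatrix"))

#' @describeIn ModulePosterior-class the K x (M+1) posterior frequency matrix.
#' @param object a `ModulePosterior`.
#' @export
setMethod("posteriorMatrix", "ModulePosterior", function(object) object@Chat)

#' @export
setGeneric("moduleAbundance", function(object) standardGeneric("moduleAbundance"))

#' @describeIn ModulePosterior-class per-module abundance (fraction of
#'   accumulated samples, background included).
#' @export
setMethod("moduleAbundance", "ModulePosterior", function(object) {
  object@abundance
})

setMethod("show", "BindingCounts", function(object) {
  cat("BindingCounts:", nrow(object), "regions x", ncol(object), "TFs\n")
  cat("  TFs:", paste(tfNames(object), collapse = ", "), "\n")
  cat("  bin size:", binSize(object), "bp;",
      sum(regionClass(object) == "promoter"), "promoter bins\n")
})

setMethod("show", "ModuleCatalog", function(object) {
  cat("ModuleCatalog:", nModules(object), "candidate modules +",
      "background (", object@provenance, ") over",
      ncol(object@B), "TFs\n")
})

setMethod("show", "TFModelSet", function(object) {
  cat("TFModelSet (", object@mode, " mode):\n", sep = "")
  print(object@params, row.names = FALSE)
})

setMethod("show", "ModulePosterior", function(object) {
  ab <- sort(object@abundance, decreasing = TRUE)
  cat("ModulePosterior:", nrow(object@Chat), "regions x",
      ncol(object@Chat), "modules (incl. background)\n")
  cat("  top modules by abundance:\n")
  top <- utils::head(ab, 5L)
  for (i in seq_along(top))
    cat(sprintf("    %-30s %.3f\n", names(top)[i], top[i]))
})

setMethod("show", "ActivityModel", function(object) {
  nz <- sum(object@beta != 0)
  cat("ActivityModel: elastic net (alpha =", object@alpha,
      ", lambda =", signif(object@lambda, 4), ");",
      nz, "of", length(object@beta), "module weights nonzero\n")
})
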