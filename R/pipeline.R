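#' @importFrom utils write.table read.delim packageVersion modifyList
NULL

#' Read a flat key=value run configuration file
#'
#' Lines are `key = value`; dots nest (`sampler.burnIn = 100`). `#` starts a
#' comment. Values are auto-converted to numeric/logical where possible and
#' comma-separated values become vectors.
#'
#' @param path configuration file.
#' @return nested configuration list for [runPipeline()].
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    conv <- suppressWarnings(as.numeric(vals))
    if (!anyNA(conv)) vals <- conv
    else if (all(vals %in% c("TRUE", "FALSE", "true", "false")))
      vals <- as.logical(toupper(vals))
    path_parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    cfg <- .assignNested(cfg, path_parts, vals)
  }
  cfg
}

.assignNested <- function(lst, parts, value) {
  if (length(parts) == 1L) {
    lst[[parts]] <- value
    return(lst)
  }
  if (is.null(lst[[parts[1]]])) lst[[parts[1]]] <- list()
  lst[[parts[1]]] <- .assignNested(lst[[parts[1]]], parts[-1], value)
  lst
}

.writeMatrixTsv <- function(m, path, idCol = "region_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- idCol
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.stage <- function(name, outDir, resume, files, fun, reload = NULL) {
  paths <- file.path(outDir, files)
  if (resume && all(file.exists(paths)) && !is.null(reload)) {
    message("[", name, "] resuming from ", paste(files, collapse = ", "))
    return(reload())
  }
  message("[", name, "] running")
  t0 <- Sys.time()
  res <- tryCatch(fun(), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message("[", name, "] done in ",
          round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1),
          " s")
  res
}

#' Run the full inference pipeline
#'
#' Orchestrates fit -> candidate-module search -> Gibbs sampling ->
#' (optional) activity classification and enrichment, writing every stage's
#' artifact plus a JSON run manifest into `outDir`. Input is either a
#' simulation preset (`config$simulate`) or count files
#' (`config$input$countsTsv` / `inputTsv`, optionally produced earlier by
#' [countReads()]).
#'
#' @param config nested configuration list (see [readRunConfig()]) or a
#'   path to a key=value configuration file. Recognized blocks:
#'   `outDir`, `seed`, `mode`, `resume`, `simulate(case, nRegions,
#'   activeModules)`, `input(countsTsv, inputTsv)`, `filter(minCount,
#'   minTFs, apply)`, `catalog(cap, topK)`, `sampler(F, burnIn, nSamples,
#'   thinning, tau)`, `classifier(alpha, trainFraction, repeats)`.
#' @return (invisibly) a list with the fitted models, catalog, posterior
#'   and, when applicable, recovery scores and classifier evaluation.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(config$outDir)) stop("config$outDir is required")
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  mode <- if (is.null(config$mode)) "enhancer" else config$mode
  resume <- isTRUE(config$resume)
  results <- list()

  # --- data stage -----------------------------------------------------
  sim <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    spec <- simulationSpec(case = if (is.null(sc$case)) 1 else sc$case,
                           nRegions = if (is.null(sc$nRegions)) 1e4
                                      else sc$nRegions,
                           seed = seed, mode = mode)
    sim <- simulateCounts(spec)
    bc <- sim$counts
    utils::write.table(
      data.frame(region_id = regionIds(bc), module = sim$truth),
      file.path(outDir, "truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    results$spec <- spec
  } else if (!is.null(config$input$countsTsv)) {
    bc <- readCountMatrix(config$input$countsTsv, config$input$inputTsv)
  } else {
    stop("config needs either a 'simulate' block or input$countsTsv")
  }

  # --- candidate filter ----------------------------------------------
  flt <- config$filter
  keep <- seq_len(nrow(bc))
  if (is.null(flt) || !identical(flt$apply, FALSE)) {
    keep <- filterCandidateRegions(
      bc, minCount = if (is.null(flt$minCount)) 10 else flt$minCount,
      minTFs = if (is.null(flt$minTFs)) 2 else flt$minTFs)
    message("candidate filter kept ", length(keep), " / ", nrow(bc),
            " regions")
  }
  bcK <- bc[keep, ]

  # --- model fit ------------------------------------------------------
  models <- .stage("fit", outDir, resume, "models.json", function() {
    m <- fitTFModels(bcK, mode = mode)
    writeTFModels(m, file.path(outDir, "models.json"))
    m
  }, reload = function() readTFModels(file.path(outDir, "models.json")))
  results$models <- models

  # --- module search --------------------------------------------------
  cap <- if (is.null(config$catalog$cap)) 256L else config$catalog$cap
  topK <- if (is.null(config$catalog$topK)) 100L else config$catalog$topK
  catalog <- .stage("search", outDir, resume, "catalog.tsv", function() {
    ct <- if (2^ncol(bcK) <= cap) enumerateModules(tfNames(bcK), cap = cap)
          else topKModules(roughBindingCalls(bcK), k = topK)
    writeModuleCatalog(ct, file.path(outDir, "catalog.tsv"))
    ct
  }, reload = function() readModuleCatalog(file.path(outDir, "catalog.tsv")))
  results$catalog <- catalog

  # --- Gibbs sampling -------------------------------------------------
  sp <- config$sampler
  cfg <- samplerConfig(
    F = if (is.null(sp$F)) 10 else sp$F,
    burnIn = if (is.null(sp$burnIn)) 200L else sp$burnIn,
    nSamples = if (is.null(sp$nSamples)) 500L else sp$nSamples,
    thinning = if (is.null(sp$thinning)) 1L else sp$thinning,
    tau = if (is.null(sp$tau)) 0.1 else sp$tau,
    seed = seed, mode = mode)
  posterior <- .stage("sample", outDir, resume,
                      c("chat.tsv", "abundance.tsv"), function() {
    post <- runGibbs(bcK, models, catalog, cfg)
    .writeMatrixTsv(posteriorMatrix(post), file.path(outDir, "chat.tsv"))
    ab <- moduleAbundance(post)
    write.table(data.frame(module_id = names(ab), abundance = ab),
                file.path(outDir, "abundance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    post
  }, reload = function() {
    tab <- read.delim(file.path(outDir, "chat.tsv"), check.names = FALSE)
    Chat <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(Chat) <- tab[[1L]]
    ab <- read.delim(file.path(outDir, "abundance.tsv"))
    new("ModulePosterior", Chat = Chat,
        abundance = stats::setNames(ab$abundance, ab$module_id),
        catalog = catalog, config = list(seed = seed, mode = mode,
                                         tau = cfg@tau),
        diagnostics = list(resumed = TRUE, gewekeZ = NA_real_))
  })
  results$posterior <- posterior
  assignments <- assignModules(posterior, tau = cfg@tau)

  # --- recovery scoring (simulation only) ------------------------------
  if (!is.null(sim)) {
    full <- replicate(nrow(bc), integer(0), simplify = FALSE)
    full[keep] <- assignments
    results$recovery <- scoreBindingRecovery(
      sim$truth, full, catalog, boundCounts = sim$boundCounts)
    message(sprintf("binding-event F-measure: %.4f (overall), %.4f (weak)",
                    results$recovery$overall$F, results$recovery$weak$F))
  }

  # --- activity classification (simulation labels) ---------------------
  cls <- config$classifier
  if (!is.null(sim) && !is.null(config$simulate$activeModules)) {
    act <- as.integer(config$simulate$activeModules)
    labs <- simulateLabels(sim$truth[keep], act,
                           flipRate = if (is.null(cls$flipRate)) 0.05
                                      else cls$flipRate,
                           seed = seed)
    feats <- posteriorMatrix(posterior)[, -1L, drop = FALSE]
    ev <- holdoutEvaluate(
      feats, labs$labels,
      trainFraction = if (is.null(cls$trainFraction)) 0.8
                      else cls$trainFraction,
      repeats = if (is.null(cls$repeats)) 20L else cls$repeats,
      alpha = if (is.null(cls$alpha)) 0.5 else cls$alpha,
      seed = seed)
    write.table(data.frame(repeat_id = seq_along(ev), f_measure = ev),
                file.path(outDir, "evaluation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    mdl <- fitElasticNet(feats, labs$labels,
                         alpha = if (is.null(cls$alpha)) 0.5 else cls$alpha,
                         seed = seed)
    sc <- predictActivity(feats, mdl)
    write.table(data.frame(region_id = rownames(feats), score = sc),
                file.path(outDir, "scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$classifier <- mdl
    results$evaluation <- ev
  }

  # --- manifest --------------------------------------------------------
  manifest <- list(
    package = "tfmodules",
    version = as.character(packageVersion("tfmodules")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, mode = mode,
    config = config[setdiff(names(config), "outDir")],
    sampler = posterior@config,
    models = tfParams(models),
    diagnostics = list(gewekeZ = posterior@diagnostics$gewekeZ),
    recovery = if (!is.null(results$recovery))
      list(overall = results$recovery$overall$F,
           weak = results$recovery$weak$F))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(results)
}
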