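#' Default pipeline configuration
#'
#' All stage parameters with their defaults, plus the simulation settings
#' used when `simulate = TRUE`. Thresholds must be positive; the validated
#' config is serialized verbatim into the run manifest.
#'
#' @param ... overrides of any default (unknown keys are an error).
#' @return A validated config list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1,
    simulate = TRUE,
    nGenes = 60, repliconLength = 120000,
    conditions = c("H20", "A20", "H10", "A10"),
    depth = 50, enrichment = 8, replicates = 2,
    lambdaBg = 2, bgFraction = 0.05,
    clusterGap = 300, pairSdMax = 15, enrichmentMin = 2,
    mergeWindow = 4, minDensity = 5, pseudocount = 1,
    replicateWindow = 4, windowHalfWidth = 0,
    binSize = 200,
    upstream = 299, downstream = 100, leaderlessMax = 10,
    promoterWidth = 50, maxMismatch = 1,
    nNull = 200, nC7 = 60, nC1 = 60, nReps = 4, dispersion = 0.05,
    foldChange = 4,
    fcMin = 1, fdrMax = 0.01, minContrasts = 1,
    kRange = 2:6, restarts = 10,
    genomePath = NULL, annotationPath = NULL, manifestPath = NULL,
    operonsPath = NULL)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  errs <- character()
  for (key in c("clusterGap", "pairSdMax", "enrichmentMin", "minDensity",
                "pseudocount", "depth", "enrichment", "fdrMax"))
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0)
      errs <- c(errs, paste0(key, " must be positive"))
  if (!cfg$simulate) {
    for (key in c("genomePath", "annotationPath", "manifestPath"))
      if (is.null(cfg[[key]]))
        errs <- c(errs, paste0(key, " required when simulate = FALSE"))
  }
  if (length(errs))
    stop("config validation failed:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

#' Run the full primary-transcriptome pipeline
#'
#' Orchestrates simulate -> normalize -> TSS calling -> merging ->
#' classification -> 5'-UTR / folding / promoter scans -> operon
#' assignment -> expression analysis, writing all products plus a
#' `summary.json` and a `manifest.json` into `outDir`. With
#' `config$simulate = TRUE` the inputs are generated, written to
#' `outDir/inputs` in standard formats (FASTA/GFF3/bedGraph) and read back
#' through the package's own readers; otherwise the configured paths are
#' read. The folding and promoter stages are optional: a failure there is
#' logged into the manifest and the run continues. Reruns with the same
#' config and seed are bit-identical for all deterministic outputs.
#'
#' @param config from [pipelineConfig()].
#' @param outDir output directory.
#' @return Invisibly, a list with the main in-memory results and output
#'   paths.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message("[primaryTx] ", ...)
  stageErrors <- list()

  if (isTRUE(config$simulate)) {
    log("simulating genome, annotation and 5'-end profiles")
    sim <- generateGenomeAnnotation(config$nGenes, config$repliconLength,
                                    seed = config$seed,
                                    enrichment = config$enrichment)
    profiles0 <- simulateEndProfiles(
      sim, conditions = config$conditions, depth = config$depth,
      enrichment = config$enrichment, replicates = config$replicates,
      lambdaBg = config$lambdaBg, bgFraction = config$bgFraction,
      seed = config$seed + 1)
    inDir <- file.path(outDir, "inputs")
    paths <- writeSimulatedData(sim, profiles0, inDir)
    genome <- readGenome(paths$genome)
    genes <- readAnnotation(paths$annotation, genome)
    operons <- utils::read.table(paths$operons, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    manifest <- paths$manifest
    truth <- sim$truth
  } else {
    genome <- readGenome(config$genomePath)
    genes <- readAnnotation(config$annotationPath, genome)
    manifest <- utils::read.table(config$manifestPath, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
    operons <- if (!is.null(config$operonsPath))
      utils::read.table(config$operonsPath, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    else data.frame(operonId = character(), geneId = character(),
                    order = integer())
    truth <- NULL
  }
  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
  profiles <- lapply(seq_len(nrow(manifest)), function(i) {
    readBedgraphPair(manifest$plusBedgraph[i], manifest$minusBedgraph[i],
                     libraryId = manifest$libraryId[i],
                     condition = manifest$condition[i],
                     replicate = manifest$replicate[i],
                     treatment = manifest$treatment[i],
                     seqlengths = seqlens)
  })
  names(profiles) <- manifest$libraryId

  tssCfg <- tssCallingConfig()
  for (key in names(tssCfg)) tssCfg[[key]] <- config[[key]]

  log("calling TSSs per condition")
  condSets <- list()
  for (cond in unique(manifest$condition)) {
    libs <- manifest[manifest$condition == cond, ]
    sf <- computeSizeFactors(binProfiles(profiles[libs$libraryId],
                                         config$binSize))
    plus <- profiles[libs$libraryId[libs$treatment == "RPP+"]]
    minus <- profiles[libs$libraryId[libs$treatment == "RPP-"]]
    ordRep <- order(vapply(plus, libReplicate, 0L))
    plus <- plus[ordRep]
    minus <- minus[order(vapply(minus, libReplicate, 0L))]
    condSets[[cond]] <- callConditionTss(plus, minus, sf, tssCfg)
  }
  log("merging ", length(condSets), " condition sets")
  total <- mergeTssSets(condSets, window = config$mergeWindow,
                        nConditions = length(condSets))
  classified <- classifyTss(total, genes, upstream = config$upstream,
                            downstream = config$downstream)
  tssPaths <- writeTssOutputs(classified, file.path(outDir, "run"))

  log("extracting 5'-UTRs")
  utrs <- extractUtrs(classified, genes, genome,
                      leaderlessMax = config$leaderlessMax)
  utils::write.table(utrs, file.path(outDir, "utrs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  codonUsage <- startCodonUsage(utrs)
  context <- tssContextProfile(classified, genome)

  mfe <- tryCatch({
    tab <- utrMfeTable(utrs)
    utils::write.table(tab, file.path(outDir, "mfe.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tab
  }, error = function(e) {
    stageErrors$fold <<- conditionMessage(e)
    warning("folding stage failed (continuing): ", conditionMessage(e))
    NULL
  })
  promoters <- tryCatch({
    tab <- scanAllPromoters(classified, genome, utrs,
                            width = config$promoterWidth,
                            maxMismatch = config$maxMismatch)
    utils::write.table(tab, file.path(outDir, "promoters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  }, error = function(e) {
    stageErrors$promoter <<- conditionMessage(e)
    warning("promoter stage failed (continuing): ", conditionMessage(e))
    NULL
  })
  operonMap <- if (nrow(operons))
    assignTssToOperons(classified, operons, genes) else NULL

  log("expression analysis")
  expr <- simulateCountMatrix(config$nNull, config$nC7, config$nC1,
                              conditions = config$conditions,
                              nReps = config$nReps,
                              dispersion = config$dispersion,
                              foldChange = config$foldChange,
                              seed = config$seed + 2)
  counts <- SummarizedExperiment::assay(expr$counts, "counts")
  cd <- SummarizedExperiment::colData(expr$counts)
  sfExpr <- computeSizeFactors(counts)
  ref <- config$conditions[1L]
  degResults <- list()
  for (cond in setdiff(config$conditions, ref)) {
    res <- testDifferentialExpression(
      counts, groupA = rownames(cd)[cd$condition == cond],
      groupB = rownames(cd)[cd$condition == ref], sizeFactors = sfExpr)
    res$padj <- adjustFdr(res$p)
    res$contrast <- paste0(cond, ":", ref)
    degResults[[cond]] <- res
  }
  degTab <- do.call(rbind, degResults)
  utils::write.table(degTab, file.path(outDir, "deg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  degGenes <- selectDeg(degResults, fcMin = config$fcMin,
                        fdrMax = config$fdrMax,
                        minContrasts = config$minContrasts)
  fcMat <- vapply(degResults, function(r)
    r$log2FC[match(degGenes, r$geneId)], numeric(length(degGenes)))
  clusters <- NULL
  if (length(degGenes) >= max(config$kRange)) {
    fcMat <- matrix(fcMat, nrow = length(degGenes),
                    dimnames = list(degGenes, names(degResults)))
    clusters <- kmeansCluster(fcMat, kRange = config$kRange,
                              restarts = config$restarts,
                              seed = config$seed + 3)
    utils::write.table(
      data.frame(geneId = names(clusters$labels),
                 cluster = unname(clusters$labels)),
      file.path(outDir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(clusters$sse, file.path(outDir, "sse.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  catCounts <- as.list(tssCategoryCounts(classified))
  leaderLens <- utrs$length[utrs$leaderStatus == "leader"]
  summary <- list(
    nTss = length(classified),
    categories = catCounts,
    scopes = as.list(table(tssTable(classified)$scope)),
    nPrimaryUtrs = nrow(utrs),
    nLeaderless = sum(utrs$leaderStatus == "leaderless"),
    medianUtrLength = if (length(leaderLens))
      stats::median(leaderLens) else NA,
    startCodonUsage = as.list(as.data.frame(codonUsage)),
    plusOneContext = as.list(context[, "+1"]),
    nDeg = length(degGenes),
    kSelected = if (!is.null(clusters)) clusters$k else NA)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifestJson <- list(
    package = "primaryTx",
    version = as.character(utils::packageVersion("primaryTx")),
    config = config[!vapply(config, is.null, TRUE)],
    stageErrors = stageErrors,
    outputs = list.files(outDir, recursive = TRUE))
  jsonlite::write_json(manifestJson, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(outDir = outDir, tss = classified, utrs = utrs,
                 mfe = mfe, promoters = promoters, operonMap = operonMap,
                 deg = degResults, degGenes = degGenes,
                 clusters = clusters, summary = summary, truth = truth,
                 codonUsage = codonUsage, context = context,
                 expr = expr))
}
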