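## End-to-end orchestration: structures -> topology reports -> registry ->
## architecture screen -> summary table, with every intermediate artifact
## serialized to the run directory.

#' Build a pipeline run configuration
#'
#' @param outDir run directory (created if absent).
#' @param seed integer seed driving every stochastic stage.
#' @param structures optional data.frame describing input structures:
#'   `path`, `chain` (NA = first chain), `protein_id`, `family_id`.
#' @param annotations optional domain table (data.frame or TSV path, see
#'   [readArchitectureTable()]).
#' @param hits optional homology table (data.frame or TSV path).
#' @param registry optional registry data.frame; when NULL it is built
#'   from the structure topology reports grouped by `family_id`.
#' @param nClosures,sphereRadiusFactor,callThreshold,stride,fpClosures
#'   topology settings (see [closureConfig()], [analyzeTopology()]).
#' @param evalueThreshold homology gate threshold (default 1e-3).
#' @param adjacencyMaxGap gene-arrangement adjacency cutoff (nt).
#' @param minConfidence optional mean-pLDDT gate for structure chains.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(outDir, seed = 1L, structures = NULL,
                      annotations = NULL, hits = NULL, registry = NULL,
                      nClosures = 100L, sphereRadiusFactor = 2.0,
                      callThreshold = 0.5, stride = 5L, fpClosures = 20L,
                      evalueThreshold = 1e-3, adjacencyMaxGap = 50L,
                      minConfidence = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  stopifnot(callThreshold > 0, callThreshold <= 1, evalueThreshold > 0)
  structure(list(outDir = outDir, seed = as.integer(seed),
                 structures = structures, annotations = annotations,
                 hits = hits, registry = registry,
                 nClosures = as.integer(nClosures),
                 sphereRadiusFactor = sphereRadiusFactor,
                 callThreshold = callThreshold, stride = as.integer(stride),
                 fpClosures = as.integer(fpClosures),
                 evalueThreshold = evalueThreshold,
                 adjacencyMaxGap = as.integer(adjacencyMaxGap),
                 minConfidence = minConfidence),
            class = "RunConfig")
}

reportToList <- function(rep) {
  list(chain = rep@chainLabel,
       label = rep@globalCall@label,
       support = rep@globalCall@support,
       det1 = rep@globalCall@det1, det2 = rep@globalCall@det2,
       composite = rep@composite, slipknotted = rep@slipknotted,
       cores = rep@cores)
}

#' Run the composite-knot discovery pipeline
#'
#' Stages: (1) per-structure topology analysis (global knot call,
#' fingerprint, cores, composite/slipknot flags); (2) entangled-domain
#' registry, built from the reports grouped by family unless supplied;
#' (3) architecture screen plus homology gate over the annotation table;
#' (4) a summary table with one row per candidate architecture
#' (architecture, number of proteins, example protein, knot type).
#' Every stage writes its artifact into the run directory
#' (`topology.json`, `registry.tsv`, `verdicts.tsv`, `summary.tsv`,
#' `config.json`); identical config and inputs give byte-identical
#' outputs.  Failures are isolated per structure and summarized.
#'
#' @param config a `"RunConfig"` from [runConfig()].
#' @return list with `reports`, `registry`, `verdicts`, `summary`,
#'   `failures`, invisibly also written to `config$outDir`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  cc <- closureConfig("sphere_random", nClosures = config$nClosures,
                      seed = config$seed,
                      sphereRadiusFactor = config$sphereRadiusFactor)
  reports <- list(); failures <- character(0)
  st <- config$structures
  if (!is.null(st)) {
    for (i in seq_len(nrow(st))) {
      id <- st$protein_id[i]
      res <- tryCatch({
        model <- readStructure(st$path[i])
        chain <- if (!is.null(st$chain) && !is.na(st$chain[i])) {
          ids <- vapply(model@chains, function(ch) ch@chainId, character(1))
          model@chains[[match(st$chain[i], ids)]]
        } else model@chains[[1]]
        pl <- chainToPolyline(chain, minConfidence = config$minConfidence)
        analyzeTopology(pl, cc, stride = config$stride,
                        fpClosures = config$fpClosures,
                        callThreshold = config$callThreshold,
                        chainLabel = id)
      }, error = function(e) conditionMessage(e))
      if (is(res, "TopologyReport")) reports[[id]] <- res
      else failures <- c(failures, sprintf("%s: %s", id, res))
    }
    jsonlite::write_json(lapply(reports, reportToList),
                         file.path(config$outDir, "topology.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }

  registry <- config$registry
  if (is.null(registry) && length(reports) && !is.null(st$family_id)) {
    fams <- split(names(reports),
                  st$family_id[match(names(reports), st$protein_id)])
    registry <- buildRegistry(lapply(fams, function(ids) reports[ids]))
  }
  if (!is.null(registry))
    utils::write.table(registry, file.path(config$outDir, "registry.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  verdicts <- NULL; summary <- NULL
  ann <- config$annotations
  if (is.character(ann)) ann <- readArchitectureTable(ann)
  hits <- config$hits
  if (is.character(hits)) hits <- readHomologyTable(hits)
  if (!is.null(ann) && !is.null(registry)) {
    verdicts <- screenArchitectures(ann, registry)
    if (!is.null(hits))
      verdicts <- homologyGate(verdicts, hits, config$evalueThreshold)
    utils::write.table(verdicts, file.path(config$outDir, "verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    kt <- NULL
    if (length(reports)) {
      kt <- vapply(reports, function(r) r@globalCall@label, character(1))
    }
    summary <- summarizeArchitectures(verdicts, kt)
    utils::write.table(summary, file.path(config$outDir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfgOut <- config[setdiff(names(config),
                           c("outDir", "structures", "annotations", "hits",
                             "registry"))]
  jsonlite::write_json(cfgOut, file.path(config$outDir, "config.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  if (length(failures))
    message("pipeline finished with ", length(failures), " failed structure(s)")
  invisible(list(reports = reports, registry = registry, verdicts = verdicts,
                 summary = summary, failures = failures))
}
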