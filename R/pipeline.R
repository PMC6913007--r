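## End-to-end orchestration: simulate -> filter -> mask -> benchmark, with
## a JSON manifest (config hash, seed, version) and a removal log for
## auditability. Rerunning with an identical config reproduces
## byte-identical FASTA/BED/TSV artifacts.

.writeTSV <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Assemble a pipeline configuration
#'
#' @param seed integer seed; flows into every stage.
#' @param sim named list of [simConfig()] arguments (seed is injected).
#' @param filter named list of [filterConfig()] arguments.
#' @param mask named list of [maskParams()] arguments.
#' @param targetClasses classes benchmarked individually.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(seed, sim = list(), filter = list(), mask = list(),
                      targetClasses = c("LTR", "TIR", "Helitron",
                                        "nonLTR")) {
  if (missing(seed)) stop("seed is mandatory")
  sim$seed <- as.integer(seed)
  cfg <- list(seed = as.integer(seed),
              sim = do.call(simConfig, sim),
              filter = do.call(filterConfig, filter),
              mask = do.call(maskParams, mask),
              targetClasses = targetClasses)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML document has top-level keys `seed` and optional `sim`,
#' `filter`, `mask`, `targetClasses` blocks whose entries are the
#' arguments of [simConfig()], [filterConfig()] and [maskParams()].
#'
#' @param path YAML file.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must provide a seed")
  known <- c("seed", "sim", "filter", "mask", "targetClasses")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  runConfig(seed = y$seed, sim = if (is.null(y$sim)) list() else y$sim,
            filter = if (is.null(y$filter)) list() else y$filter,
            mask = if (is.null(y$mask)) list() else y$mask,
            targetClasses = if (is.null(y$targetClasses))
              c("LTR", "TIR", "Helitron", "nonLTR") else y$targetClasses)
}

#' Run the full pipeline: simulate, filter, mask, benchmark
#'
#' Executes the four stages in order, each stage consuming the previous
#' stage's outputs, and writes all artifacts plus a JSON manifest into
#' `outDir`: `genome.fa`, `library.fa` (exemplars), `truth.bed`/`.gff3`,
#' `candidates.fa`/`.bed`, `stage0/` and `stage1/library.fa`,
#' `removals.tsv`, `mask.bed`/`.gff3`, `metrics.tsv`, `misclass.tsv`,
#' `manifest.json` and `run.log`.
#'
#' @param config a `RunConfig` ([runConfig()]), or the path of a YAML
#'   config ([readRunConfig()]).
#' @param outDir output directory (created if needed).
#' @param cds optional coding sequences for [cdsFilter()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the main in-memory results: `genome`,
#'   `truth`, `candidates`, `stage0`, `stage1`, `mask`, `metrics`,
#'   `misclass`, `manifest`.
#' @export
runPipeline <- function(config, outDir, cds = NULL, quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outDir, "stage0"), showWarnings = FALSE)
  dir.create(file.path(outDir, "stage1"), showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  logLines <- character(0)
  note <- function(...) {
    logLines <<- c(logLines, paste0(...))
    say(...)
  }

  note("simulate: seed ", config$seed)
  ex <- makeExemplars(config$sim)
  sim <- simulateGenome(ex, config$sim)
  cands <- makeNoisyCandidates(sim$genome, sim$truth, config$sim)
  writeLibraryFasta(sim$genome, file.path(outDir, "genome.fa"))
  writeLibraryFasta(ex, file.path(outDir, "library.fa"))
  writeAnnotation(sim$truth@annotation, file.path(outDir, "truth.bed"))
  writeAnnotation(sim$truth@annotation, file.path(outDir, "truth.gff3"))
  writeLibraryFasta(entries(cands), file.path(outDir, "candidates.fa"))
  a <- anchors(cands)
  anchored <- !is.na(a$seqId)
  if (any(anchored)) {
    info <- libInfo(entries(cands))
    cgr <- GRanges(a$seqId[anchored],
                   IRanges(a$start[anchored], a$end[anchored]),
                   Name = info$name[anchored],
                   teClass = info$class[anchored],
                   classification = info$classification[anchored],
                   identity = NA_real_, score = info$score[anchored])
    writeAnnotation(TEAnnotation(cgr), file.path(outDir, "candidates.bed"))
  }

  note("filter: ", length(cands), " raw candidates")
  s0 <- runStage0(cands, sim$genome, config$filter, config$mask)
  s1 <- runStage1(s0$candidates, sim$genome, config$filter, cds,
                  config$mask)
  info0 <- libInfo(entries(s0$candidates))
  for (cl in unique(info0$class))
    writeLibraryFasta(entries(s0$candidates)[info0$class == cl],
                      file.path(outDir, "stage0",
                                paste0(cl, ".stage0.fa")))
  writeLibraryFasta(s1$library, file.path(outDir, "stage1", "library.fa"))
  removals <- rbind(s0$removals, s1$removals)
  .writeTSV(removals, file.path(outDir, "removals.tsv"))
  tab <- table(removals$rule)
  note("filter: removed ", nrow(removals), " (",
       paste(names(tab), tab, sep = ":", collapse = " "), "); kept ",
       length(s1$library))

  note("mask: annotating the genome with the stage-1 library")
  msk <- maskGenome(sim$genome, s1$library, config$mask)
  writeAnnotation(msk, file.path(outDir, "mask.bed"))
  writeAnnotation(msk, file.path(outDir, "mask.gff3"))

  note("benchmark: against the simulated truth annotation")
  rows <- list()
  for (cl in config$targetClasses) {
    truthCl <- TEAnnotation(granges(sim$truth@annotation)[
      mcols(granges(sim$truth@annotation))$teClass == cl])
    testCl <- TEAnnotation(granges(msk)[mcols(granges(msk))$teClass == cl])
    cc <- confusionCounts(sim$truth@annotation, testCl, cl, sim$genome)
    rows[[cl]] <- cbind(data.frame(classes = cl),
                        as.data.frame(cc),
                        as.data.frame(computeMetrics(cc)))
  }
  ccAll <- confusionCounts(sim$truth@annotation, msk,
                           config$targetClasses, sim$genome)
  rows[["total"]] <- cbind(data.frame(classes = "total"),
                           as.data.frame(ccAll),
                           as.data.frame(computeMetrics(ccAll)))
  metrics <- do.call(rbind, rows)
  .writeTSV(metrics, file.path(outDir, "metrics.tsv"))
  mis <- misclassificationRate(msk, sim$truth@annotation)
  misDf <- data.frame(class = c(names(mis$perClass), "overall"),
                      misclassification = c(mis$perClass, mis$overall),
                      mode = mis$mode)
  .writeTSV(misDf, file.path(outDir, "misclass.tsv"))

  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(list(seed = config$seed,
                        sim = config$sim[setdiff(names(config$sim), "class")],
                        filter = unclass(config$filter),
                        mask = unclass(config$mask),
                        targetClasses = config$targetClasses), cfgPath)
  writeLines(logLines, file.path(outDir, "run.log"))
  manifest <- list(
    version = as.character(utils::packageVersion("TEforge")),
    seed = config$seed,
    configHash = unname(tools::md5sum(cfgPath)),
    artifacts = sort(setdiff(list.files(outDir, recursive = TRUE),
                             "manifest.json")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genome = sim$genome, truth = sim$truth,
                 candidates = cands, stage0 = s0, stage1 = s1, mask = msk,
                 metrics = metrics, misclass = mis, manifest = manifest))
}
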