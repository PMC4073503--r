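## Named per-stage RNG substreams derived from one pipeline seed, so stages
## can be rerun independently yet reproducibly. Values stay below 2^31.
.STAGE_OFFSETS <- c(map = 11L, cross = 23L, phenotype = 37L, ferment = 41L,
                    signals = 53L)

#' Derive a per-stage seed from the pipeline seed
#'
#' @param seed Integer pipeline seed.
#' @param stage One of "map", "cross", "phenotype", "ferment", "signals".
#' @return Integer seed for the stage's substream.
#' @export
stageSeed <- function(seed, stage) {
  off <- .STAGE_OFFSETS[[match.arg(stage, names(.STAGE_OFFSETS))]]
  as.integer((as.numeric(seed) %% 1000003) * 2011 + off) %% 2147483647L
}

## FNV-1a 32-bit hash of a character scalar; used for the manifest's
## parameter fingerprint.
.fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30  # keep in int range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Read / write a pipeline configuration
#'
#' YAML configuration holding the seed, simulation sizes, the planted QTL
#' model, scan parameters, the phenotyping checkpoint and the fermenter
#' volume. Round-trips losslessly through its on-disk form.
#'
#' @param path YAML file path.
#'
#' @return [readPipelineConfig()] returns the configuration list with
#'   elements \code{seed}, \code{simulation} ([SimulationConfig-class]),
#'   \code{model} ([QTLEffectModel-class]), \code{scan}
#'   ([ScanParameters-class]), \code{n_markers}, \code{genetic_rate},
#'   \code{checkpoint_h}, \code{volume_L}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  defaultPipelineConfig(
    seed = y$seed %||% 1L,
    nMarkers = y$n_markers %||% 6318L,
    geneticRate = y$genetic_rate %||% 0.35,
    simulation = do.call(SimulationConfig, c(list(seed = y$seed %||% 1L),
                                             y$simulation %||% list())),
    model = if (is.null(y$qtl)) defaultQTLModel() else QTLEffectModel(
      loci = do.call(rbind, lapply(y$qtl$loci, as.data.frame)),
      baseline = y$qtl$baseline %||% 70,
      targetH2 = y$qtl$target_H2 %||% 0.98,
      envSdParent = y$qtl$env_sd_parent %||% NA_real_),
    scan = do.call(ScanParameters, y$scan %||% list()),
    checkpoint_h = y$checkpoint_h %||% 89,
    volume_L = y$volume_L %||% 1.2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readPipelineConfig
#' @param seed Pipeline seed.
#' @param nMarkers,geneticRate Size and map rate of the synthetic marker map.
#' @param simulation A [SimulationConfig-class].
#' @param model A [QTLEffectModel-class].
#' @param scan A [ScanParameters-class].
#' @param checkpoint_h Phenotyping checkpoint (default 89 h).
#' @param volume_L Fermenter volume (default 1.2 L).
#' @export
defaultPipelineConfig <- function(seed = 1L, nMarkers = 6318L,
                                  geneticRate = 0.35,
                                  simulation = SimulationConfig(seed = seed),
                                  model = defaultQTLModel(),
                                  scan = ScanParameters(),
                                  checkpoint_h = 89, volume_L = 1.2) {
  list(seed = as.integer(seed), n_markers = as.integer(nMarkers),
       genetic_rate = geneticRate, simulation = simulation, model = model,
       scan = scan, checkpoint_h = checkpoint_h, volume_L = volume_L)
}

#' @rdname readPipelineConfig
#' @param config A configuration list as returned by
#'   [defaultPipelineConfig()].
#' @export
writePipelineConfig <- function(config, path) {
  sim <- config$simulation
  sc <- config$scan
  mod <- config$model
  y <- list(
    seed = config$seed,
    n_markers = config$n_markers,
    genetic_rate = config$genetic_rate,
    simulation = list(nSegregants = sim@nSegregants,
                      bulkSize = sim@bulkSize, nBlocks = sim@nBlocks,
                      probeNoiseSd = sim@probeNoiseSd,
                      nParentReplicates = sim@nParentReplicates),
    qtl = list(baseline = mod@baseline, target_H2 = mod@targetH2,
               env_sd_parent = if (is.na(mod@envSdParent)) NULL
                               else mod@envSdParent,
               loci = lapply(seq_len(nrow(mod@loci)), function(i)
                 as.list(mod@loci[i, ]))),
    scan = list(windowSize = sc@windowSize, probeAlpha = sc@probeAlpha,
                windowAlpha = sc@windowAlpha,
                parentalFraction = sc@parentalFraction, step = sc@step,
                mergeGap = sc@mergeGap),
    checkpoint_h = config$checkpoint_h,
    volume_L = config$volume_L)
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

#' Run the full pipeline
#'
#' Chains the stages with one seed fanned out into named per-stage
#' substreams: synthetic marker map, F2 cross, phenotype assignment,
#' population statistics (heritability, transgression), bulk selection,
#' pooled signal simulation, and the bulk-segregant scan. All artifacts,
#' a JSON stats report and a manifest (package version, seed, parameter
#' hash) are written to \code{outDir}. Reruns with the same configuration
#' produce identical outputs.
#'
#' @param config Configuration list from [defaultPipelineConfig()] or
#'   [readPipelineConfig()].
#' @param outDir Output directory (created if missing).
#' @param logLevel "info" (default) for progress messages, "quiet" for none.
#'
#' @return Invisibly, a list with the in-memory stage results
#'   (\code{population}, \code{phenotypes}, \code{stats}, \code{bulks},
#'   \code{scan}) and \code{outDir}.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir,
                        logLevel = c("info", "quiet")) {
  logLevel <- match.arg(logLevel)
  say <- function(...) if (logLevel == "info") message("[segscan] ", ...)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  runStage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed

  map <- runStage("map", yeastMarkerMap(config$n_markers,
                                        config$genetic_rate))
  say("marker map: ", nMarkers(map), " markers")
  writeMarkerMap(map, file.path(outDir, "marker_map.tsv"))

  pop <- runStage("cross", makeF2Population(map, config$simulation,
                                            seed = stageSeed(seed, "cross")))
  say("F2 population: ", ncol(genotypes(pop)), " segregants")
  writeGenotypes(pop, file.path(outDir, "genotypes.tsv"))

  phen <- runStage("phenotype",
                   assignPhenotypes(pop, config$model, config$simulation,
                                    seed = stageSeed(seed, "phenotype")))
  writePhenotypes(phen, file.path(outDir, "phenotypes.csv"))

  segv <- phen$co2_at_checkpoint[phen$group == "segregant"]
  pav <- phen$co2_at_checkpoint[phen$group == "parentA"]
  pbv <- phen$co2_at_checkpoint[phen$group == "parentB"]
  h2 <- runStage("stats", heritability(segv, pav, pbv))
  tg <- runStage("stats", transgression(segv, pav, pbv))
  stats <- list(
    n_segregants = length(segv),
    H2_percent = h2@H2Percent, var_seg = h2@varSeg, var_env = h2@varEnv,
    transgression_percent = tg@percent, n_high = tg@nHigh, n_low = tg@nLow,
    sigma_parental = tg@sigma)
  jsonlite::write_json(stats, file.path(outDir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  say(sprintf("H2 = %.1f%%, transgression %.1f%%", h2@H2Percent,
              tg@percent))

  bulks <- runStage("bulks", selectBulks(phen, config$simulation@bulkSize))
  jsonlite::write_json(bulks, file.path(outDir, "bulks.json"))

  adt <- runStage("signals",
                  simulateSignalTable(pop, bulks$low, bulks$high,
                                      config$simulation,
                                      seed = stageSeed(seed, "signals")))
  writeSignals(adt, file.path(outDir, "signals.tsv"))

  scan <- runStage("bsa", bsaScan(adt, config$scan))
  .writeTable(scan$windows, file.path(outDir, "windows.tsv"), sep = "\t")
  writeRegionsBED(scan$regions, file.path(outDir, "regions.bed"))
  writeRegionsTSV(scan$regions, file.path(outDir, "regions.tsv"))
  say(length(scan$regions), " region(s) called")

  cfgPath <- file.path(outDir, "config.yaml")
  writePipelineConfig(config, cfgPath)
  manifest <- list(
    package = "segscan",
    version = as.character(utils::packageVersion("segscan")),
    seed = seed,
    parameter_hash = .fnv1a(paste(readLines(cfgPath), collapse = "\n")),
    n_markers = nMarkers(map),
    n_segregants = ncol(genotypes(pop)),
    n_regions = length(scan$regions))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(population = pop, phenotypes = phen, stats = stats,
                 bulks = bulks, scan = scan, outDir = outDir))
}
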