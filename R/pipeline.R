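# End-to-end pipeline wiring with a machine-readable run manifest.

.validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file '%s' does not exist", config)
    config <- read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  if (is.null(config$outputDir)) stopf("config$outputDir is required")
  hasInput <- !is.null(config$input)
  hasSim <- !is.null(config$simulate)
  if (!hasInput && !hasSim)
    stopf("config must provide either $input (path + dialect) or $simulate")
  if (hasInput) {
    if (is.null(config$input$path) || !file.exists(config$input$path))
      stopf("input path '%s' does not exist", config$input$path)
    dialect <- config$input$dialect %||% "immunoseq"
    if (!dialect %in% c("immunoseq", "airr", "10x"))
      stopf("unknown dialect '%s' (expected immunoseq, airr or 10x)", dialect)
  }
  if (!is.null(config$labels) && !file.exists(config$labels))
    stopf("labels file '%s' does not exist", config$labels)
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the convergence analysis pipeline
#'
#' Executes quality control, convergence grouping and the configured
#' downstream stages (repertoire statistics, degeneracy spectrum, and
#' label enrichment with the matched-expansion comparator when a labels
#' file is supplied) on either an input repertoire file or a simulated
#' repertoire. Every run writes TSV results plus a machine-readable
#' \code{manifest.json} (config echo, package version, seed, input
#' checksums), and is byte-deterministic under a fixed seed. A stage
#' failure aborts with the stage name; partial outputs are moved under
#' \code{failed/}.
#'
#' @param config list or YAML file path with fields: \code{outputDir};
#'   either \code{input} (\code{path}, \code{dialect} in
#'   \code{"immunoseq"}/\code{"airr"}/\code{"10x"}) or \code{simulate}
#'   (arguments of \code{\link{simulationConfig}}); optional \code{qc}
#'   (\code{minLen}, \code{maxLen}); optional \code{labels} (TSV of
#'   labelled keys: columns \code{v_gene}, \code{cdr3_aa}); \code{seed}.
#' @return the output directory path, invisibly; side effect: result TSVs
#'   and \code{manifest.json}.
#' @export
runPipeline <- function(config) {
  config <- .validateRunConfig(config)
  outDir <- config$outputDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  stages <- character(0)
  inputChecksums <- character(0)
  runStage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      failed <- file.path(outDir, "failed")
      if (!dir.exists(failed)) dir.create(failed)
      done <- list.files(outDir, pattern = "\\.tsv$", full.names = TRUE)
      file.rename(done, file.path(failed, basename(done)))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    stages <<- c(stages, name)
    res
  }

  # input stage: read or simulate
  if (!is.null(config$input)) {
    dialect <- config$input$dialect %||% "immunoseq"
    rep <- runStage("read", {
      if (dialect == "10x")
        stopf("paired single-cell input goes through read10xContigs() + convergentGroups(); the bulk pipeline needs immunoseq or airr")
      readBulkRepertoire(config$input$path, dialect = dialect)
    })
    inputChecksums <- md5sum(config$input$path)
  } else {
    sim <- runStage("simulate", {
      simArgs <- config$simulate
      simArgs$seed <- simArgs$seed %||% config$seed
      cfg <- do.call(simulationConfig, simArgs)
      simulateRepertoire(cfg, sampleId = config$sampleId %||% "sim")
    })
    rep <- sim$repertoire
    writeReportTSV(sim$truth, file.path(outDir, "truth.tsv"))
  }

  policy <- qcPolicy(minLen = config$qc$minLen %||% 8L,
                     maxLen = config$qc$maxLen %||% 23L)
  rep <- runStage("qc", filterRepertoire(rep, policy))
  writeReportTSV(rep, file.path(outDir, "repertoire_qc.tsv"))

  groups <- runStage("convergence", convergentGroups(rep))
  writeReportTSV(groups, file.path(outDir, "convergent_groups.tsv"))
  writeReportTSV(degeneracySpectrum(groups),
                 file.path(outDir, "degeneracy_spectrum.tsv"))

  statsRow <- runStage("stats", repertoireStats(rep, groups))
  writeReportTSV(statsRow, file.path(outDir, "repertoire_stats.tsv"))

  if (!is.null(config$labels)) {
    enrich <- runStage("enrichment", {
      lab <- fread(config$labels, sep = "\t", header = TRUE,
                   data.table = FALSE)
      labKeys <- tcrKey(normalizeVGene(lab$v_gene), lab$cdr3_aa)
      universe <- groupTable(groups)$key
      labKeys <- intersect(labKeys, universe)
      conv <- convergentSet(groups)
      eC <- fisherEnrichment(conv, labKeys, universe)
      expd <- selectExpanded(groups, length(conv))
      eE <- fisherEnrichment(expd, labKeys, universe)
      data.frame(set = c("convergent", "expanded"),
                 odds_ratio = c(eC@oddsRatio, eE@oddsRatio),
                 log10_odds_ratio = c(eC@log10OddsRatio, eE@log10OddsRatio),
                 p_value = c(eC@pValue, eE@pValue),
                 corrected = c(eC@corrected, eE@corrected),
                 stringsAsFactors = FALSE)
    })
    writeReportTSV(enrich, file.path(outDir, "enrichment.tsv"))
    inputChecksums <- c(inputChecksums, md5sum(config$labels))
  }

  manifest <- list(
    package = "TCRconvergence",
    version = as.character(packageVersion("TCRconvergence")),
    seed = config$seed,
    stages = stages,
    config = config[setdiff(names(config), "outputDir")],
    input_checksums = as.list(inputChecksums))
  write_json(manifest, file.path(outDir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}
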