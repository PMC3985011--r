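#' @include pattern-fixture.R
NULL

#' Pipeline configuration
#'
#' Bundles and validates everything [runPipeline()] needs: either a
#' directory of cohort CSVs (as written by [writeCohort()]) or a
#' [cohortConfig()] generator block (exactly one of the two), the case
#' filter, the model-averaging settings and the congruence thresholds.
#'
#' @param inputDir directory holding \code{cases.csv}, \code{plasma.csv},
#'   \code{proteins.csv}, \code{histology.csv}; mutually exclusive with
#'   \code{generator}.
#' @param generator a [cohortConfig()]; mutually exclusive with
#'   \code{inputDir}.
#' @param groupFilter \code{"pooled"}, \code{"HF"} or \code{"HHF"}.
#' @param computeLDL forwarded to [preprocessCohort()].
#' @param bma list overriding \code{windowSize}, \code{retentionThreshold},
#'   \code{occamRatio}, \code{maxEnumerate}.
#' @param congruence list overriding \code{magnitudeFloor},
#'   \code{sizeRatioCap}, \code{strictSign}.
#' @param outputDir where [runPipeline()] writes its artifacts.
#' @return validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(inputDir = NULL, generator = NULL,
                           groupFilter = c("pooled", "HF", "HHF"),
                           computeLDL = TRUE,
                           bma = list(), congruence = list(),
                           outputDir = tempfile("atherobma-run-")) {
  groupFilter <- match.arg(groupFilter)
  if (is.null(inputDir) == is.null(generator))
    stop("exactly one of inputDir or generator must be given")
  if (!is.null(generator)) validateCohortConfig(generator)
  bma <- utils::modifyList(
    list(windowSize = NULL, retentionThreshold = 0.5, occamRatio = 20,
         maxEnumerate = 20), bma)
  congruence <- utils::modifyList(
    list(magnitudeFloor = 0.001, sizeRatioCap = 10, strictSign = TRUE),
    congruence)
  if (bma$retentionThreshold <= 0 || bma$retentionThreshold >= 1)
    stop("retentionThreshold must be in (0, 1)")
  if (bma$occamRatio < 1) stop("occamRatio must be >= 1")
  if (congruence$magnitudeFloor < 0) stop("magnitudeFloor must be >= 0")
  structure(list(inputDir = inputDir, generator = generator,
                 groupFilter = groupFilter, computeLDL = computeLDL,
                 bma = bma, congruence = congruence, outputDir = outputDir),
            class = "PipelineConfig")
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, preprocessing, the four per-index iterated-BMA
#' selection runs and the two-stage congruence filter, and writes every
#' artifact to the configured output directory: the cohort CSVs (when
#' generated), \code{processed_dataset.csv} and \code{variables.csv},
#' \code{bma_result_<index>.csv} and \code{models_<index>.csv} per index,
#' \code{ledger.csv}, \code{report.md}, \code{figure_data.csv}, and
#' \code{manifest.yaml} recording all settings, the generator seed and the
#' md5 checksum of each artifact.  Identical configuration (including the
#' generator seed) yields byte-identical artifacts.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the cohort, dataset, per-index results,
#'   selection table, ledger and output directory.
#' @examples
#' cfg <- pipelineConfig(generator = cohortConfig(nProteins = 10, seed = 1))
#' out <- runPipeline(cfg)
#' ledgerTable(out$ledger)
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)

  cohort <- stageTry("simulate/load",
    if (!is.null(config$generator)) generateCohort(config$generator)
    else readCohort(config$inputDir))
  if (!any(cohort@cases$group == "CNTL"))
    stop("[simulate/load] cohort has no CNTL group; ",
         "control normalization is undefined")
  if (!is.null(config$generator))
    writeCohort(cohort, file.path(config$outputDir, "cohort"))

  dataset <- stageTry("preprocess",
    preprocessCohort(cohort, computeLDL = config$computeLDL))
  writeProcessedDataset(dataset, config$outputDir)

  results <- stageTry("select",
    runAllIndexes(dataset, config$groupFilter, settings = config$bma))
  writeBMAResults(results, config$outputDir)

  table <- stageTry("congruence", buildSelectionTable(results))
  ledger <- stageTry("congruence",
    congruenceFilter(table,
                     magnitudeFloor = config$congruence$magnitudeFloor,
                     sizeRatioCap = config$congruence$sizeRatioCap,
                     strictSign = config$congruence$strictSign))
  writeLedger(ledger, config$outputDir)

  fig <- renderFigureData(results, ledger)
  utils::write.csv(fig, file.path(config$outputDir, "figure_data.csv"),
                   row.names = FALSE)

  files <- setdiff(list.files(config$outputDir, recursive = TRUE),
                   "manifest.yaml")
  manifest <- list(
    settings = list(groupFilter = config$groupFilter,
                    computeLDL = config$computeLDL,
                    bma = config$bma[!vapply(config$bma, is.null, TRUE)],
                    congruence = config$congruence),
    generator = if (!is.null(config$generator))
      unclass(config$generator) else NULL,
    inputDir = config$inputDir,
    checksums = as.list(tools::md5sum(file.path(config$outputDir, files)))
  )
  names(manifest$checksums) <- files
  yaml::write_yaml(manifest, file.path(config$outputDir, "manifest.yaml"))

  invisible(list(cohort = cohort, dataset = dataset, results = results,
                 table = table, ledger = ledger, dir = config$outputDir))
}

#' Plot-ready long-format coefficient table
#'
#' Flattens the per-index results into (index, variable, coefficient,
#' inclusion probability, retained-by-index, retained-by-ledger) rows for
#' coefficient-vs-index plots of the selected variables.
#'
#' @param results named list of four [BMAResult]s.
#' @param ledger optional [CongruenceLedger] to flag the final retained
#'   set.
#' @return data.frame in long format.
#' @export
renderFigureData <- function(results, ledger = NULL) {
  rows <- lapply(names(results), function(idx) {
    r <- results[[idx]]
    if (!length(inclusionProb(r))) return(NULL)
    data.frame(index = idx, variable = names(inclusionProb(r)),
               coefficient = unname(avgCoefficient(r)),
               inclusion_prob = unname(inclusionProb(r)),
               selected = names(inclusionProb(r)) %in% retainedVariables(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(index = character(0), variable = character(0),
                      coefficient = numeric(0), inclusion_prob = numeric(0),
                      selected = logical(0))
  if (!is.null(ledger)) {
    tb <- ledgerTable(ledger)
    out$retained <- out$variable %in% tb$variable[tb$status == "retained"]
  }
  out
}
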