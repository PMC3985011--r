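#' @include bma-ibma.R
NULL

#' Run iterated BMA selection on all four histology indexes
#'
#' One [ibmaSelect()] run per outcome index (mean and median intimal
#' thickness, mean and median lesional area) with an identical candidate
#' set and identical settings, as the per-index inputs of the downstream
#' congruence filter.
#'
#' @param dataset a [ProcessedDataset].
#' @param groupFilter \code{"pooled"}, \code{"HF"} or \code{"HHF"}.
#' @param settings list overriding \code{windowSize},
#'   \code{retentionThreshold}, \code{occamRatio}, \code{maxEnumerate}.
#' @return named list of four [BMAResult]s keyed by index name.
#' @examples
#' ds <- preprocessCohort(generateCohort(cohortConfig(seed = 1)))
#' res <- runAllIndexes(ds)
#' names(res)
#' @export
runAllIndexes <- function(dataset, groupFilter = c("pooled", "HF", "HHF"),
                          settings = list()) {
  groupFilter <- match.arg(groupFilter)
  s <- utils::modifyList(
    list(windowSize = NULL, retentionThreshold = 0.5, occamRatio = 20,
         maxEnumerate = 20), settings)
  res <- lapply(outcomeIndexNames(), function(idx) {
    prob <- buildProblem(dataset, idx, groupFilter)
    ibmaSelect(prob@y, prob@X, windowSize = s$windowSize,
               retentionThreshold = s$retentionThreshold,
               occamRatio = s$occamRatio, maxEnumerate = s$maxEnumerate)
  })
  stats::setNames(res, outcomeIndexNames())
}

#' Write per-index BMA results as CSV
#'
#' For each index writes \code{bma_result_<index>.csv} (variable,
#' inclusion_prob, avg_coefficient, retained flag) and
#' \code{models_<index>.csv} (mask string over the final variable set, k,
#' rss, bic, pmp).
#'
#' @param results named list of [BMAResult]s as from [runAllIndexes()].
#' @param directory output directory, created if missing.
#' @return the directory, invisibly.
#' @export
writeBMAResults <- function(results, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  for (idx in names(results)) {
    r <- results[[idx]]
    utils::write.csv(
      data.frame(variable = names(inclusionProb(r)),
                 inclusion_prob = inclusionProb(r),
                 avg_coefficient = avgCoefficient(r),
                 retained = names(inclusionProb(r)) %in% retainedVariables(r),
                 row.names = NULL),
      file.path(directory, paste0("bma_result_", idx, ".csv")),
      row.names = FALSE)
    utils::write.csv(modelTable(r),
      file.path(directory, paste0("models_", idx, ".csv")),
      row.names = FALSE)
  }
  invisible(directory)
}
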