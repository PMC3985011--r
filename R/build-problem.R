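#' @include preprocess.R
NULL

#' Build a single-outcome regression problem
#'
#' Restricts a [ProcessedDataset] to one outcome index and one case filter
#' and assembles the candidate matrix the model-averaging stage consumes.
#' Zero-variance predictor columns (constant across the filtered cases) are
#' dropped with a warning since they cannot enter any subset model.
#'
#' @param dataset a [ProcessedDataset].
#' @param outcome one of \code{"IT_mean"}, \code{"IT_median"},
#'   \code{"LA_mean"}, \code{"LA_median"}.
#' @param groupFilter \code{"pooled"} (all treated cases), \code{"HF"} or
#'   \code{"HHF"}.
#' @return a [RegressionProblem].
#' @examples
#' ds <- preprocessCohort(generateCohort(cohortConfig(seed = 1)))
#' buildProblem(ds, "IT_mean", "pooled")
#' @export
buildProblem <- function(dataset,
                         outcome = outcomeIndexNames(),
                         groupFilter = c("pooled", "HF", "HHF")) {
  stopifnot(methods::is(dataset, "ProcessedDataset"))
  outcome <- match.arg(outcome)
  groupFilter <- match.arg(groupFilter)
  keep <- if (groupFilter == "pooled") names(dataset@groups)
          else names(dataset@groups)[dataset@groups == groupFilter]
  if (length(keep) < 3)
    stop("group filter '", groupFilter, "' leaves ", length(keep),
         " cases; at least 3 are required for subset regression ",
         "(small-sample limit)")
  y <- dataset@outcomes[keep, outcome]
  X <- dataset@predictors[keep, , drop = FALSE]
  v <- apply(X, 2, stats::var)
  dropped <- colnames(X)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance predictor(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  methods::new("RegressionProblem", y = y, X = X, outcome = outcome,
               groupFilter = groupFilter, dropped = dropped)
}
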