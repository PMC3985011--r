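#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# RawCohort
# ---------------------------------------------------------------------------

#' Raw study-shaped cohort
#'
#' Container for a full cohort in the shape the analysis expects: per-case
#' diet-group labels, a long-format two-timepoint plasma panel, a case x
#' protein secretome abundance matrix, and segment-level coronary histology
#' records (intimal thickness IT in mm, lesional area LA in mm^2).
#'
#' @slot cases data.frame with columns \code{case_id}, \code{group}
#'   (one of \code{"CNTL"}, \code{"HF"}, \code{"HHF"}).
#' @slot plasma data.frame with columns \code{case_id}, \code{timepoint}
#'   (\code{"BAS"} or \code{"END"}), \code{analyte}, \code{value} (> 0,
#'   concentration units).
#' @slot proteins numeric matrix, one row per case (rownames = case ids),
#'   one column per protein; abundances are non-negative arbitrary counts.
#' @slot histology data.frame with columns \code{case_id}, \code{artery},
#'   \code{segment}, \code{it_mm}, \code{la_mm2}.
#'
#' @seealso [generateCohort()], [writeCohort()], [readCohort()],
#'   [preprocessCohort()]
#' @export
setClass("RawCohort",
  representation(
    cases     = "data.frame",
    plasma    = "data.frame",
    proteins  = "matrix",
    histology = "data.frame"
  )
)

setValidity("RawCohort", function(object) {
  msg <- character(0)
  cs <- object@cases
  if (!all(c("case_id", "group") %in% names(cs)))
    msg <- c(msg, "cases must have columns case_id, group")
  else {
    if (anyDuplicated(cs$case_id))
      msg <- c(msg, "duplicated case_id in cases")
    if (!all(cs$group %in% c("CNTL", "HF", "HHF")))
      msg <- c(msg, "group must be one of CNTL, HF, HHF")
  }
  pl <- object@plasma
  if (!all(c("case_id", "timepoint", "analyte", "value") %in% names(pl)))
    msg <- c(msg, "plasma must have columns case_id, timepoint, analyte, value")
  else if (nrow(pl)) {
    if (!all(pl$timepoint %in% c("BAS", "END")))
      msg <- c(msg, "plasma timepoint must be BAS or END")
    if (any(!is.finite(pl$value)) || any(pl$value <= 0))
      msg <- c(msg, "plasma values must be finite and > 0")
    # every case must carry both timepoints for every analyte
    tab <- table(pl$case_id, pl$analyte, pl$timepoint)
    if (nrow(tab) && any(tab != 1))
      msg <- c(msg, "every case needs exactly one value per analyte per timepoint")
    if (!setequal(rownames(tab), cs$case_id))
      msg <- c(msg, "plasma cases do not match the case table")
  }
  pr <- object@proteins
  if (nrow(pr)) {
    if (is.null(rownames(pr)) || !setequal(rownames(pr), cs$case_id))
      msg <- c(msg, "protein matrix rownames must be exactly the case ids")
    if (any(!is.finite(pr)) || any(pr < 0))
      msg <- c(msg, "protein abundances must be finite and >= 0")
  }
  hs <- object@histology
  if (!all(c("case_id", "artery", "segment", "it_mm", "la_mm2") %in% names(hs)))
    msg <- c(msg, "histology must have columns case_id, artery, segment, it_mm, la_mm2")
  else if (nrow(hs)) {
    if (any(hs$it_mm < 0) || any(hs$la_mm2 < 0))
      msg <- c(msg, "IT and LA must be non-negative")
    key <- paste(hs$case_id, hs$artery, hs$segment)
    if (anyDuplicated(key))
      msg <- c(msg, "segment index must be unique within (case, artery)")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("cohortCases", "RawCohort", function(object) object@cases)

#' @rdname accessors
#' @export
setMethod("cohortPlasma", "RawCohort", function(object) object@plasma)

#' @rdname accessors
#' @export
setMethod("cohortProteins", "RawCohort", function(object) object@proteins)

#' @rdname accessors
#' @export
setMethod("cohortHistology", "RawCohort", function(object) object@histology)

setMethod("show", "RawCohort", function(object) {
  grp <- table(factor(object@cases$group, c("CNTL", "HF", "HHF")))
  cat("RawCohort with", nrow(object@cases), "cases (",
      paste(names(grp), grp, sep = ":", collapse = " "), ")\n")
  cat("  plasma:   ", length(unique(object@plasma$analyte)),
      "analytes x 2 timepoints\n")
  cat("  proteins: ", ncol(object@proteins), "secreted proteins\n")
  cat("  histology:", nrow(object@histology), "segment records\n")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# ProcessedDataset
# ---------------------------------------------------------------------------

#' Regression-ready processed dataset
#'
#' Control-normalized, log-scale outcome and predictor tables over the
#' diet-treated (HF, HHF) cases.  Every entry is
#' \code{ln(value / mean over CNTL cases)}, so a treated value equal to the
#' control average maps to 0 and all variables are dimensionless.
#'
#' @slot outcomes numeric matrix, treated cases x the four histomorphometric
#'   indexes \code{IT_mean}, \code{IT_median}, \code{LA_mean},
#'   \code{LA_median}.
#' @slot predictors numeric matrix, treated cases x candidate variable.
#' @slot catalog data.frame with columns \code{name}, \code{provenance}
#'   (\code{"circulatory"} or \code{"secreted"}), \code{timepoint}
#'   (\code{"BAS"}, \code{"END"} or \code{"n/a"}).
#' @slot groups named character vector, treated case id -> group.
#' @slot controlMeans list of the per-variable CNTL means used for
#'   normalization (kept so the transform can be inverted).
#'
#' @seealso [preprocessCohort()], [buildProblem()]
#' @export
setClass("ProcessedDataset",
  representation(
    outcomes     = "matrix",
    predictors   = "matrix",
    catalog      = "data.frame",
    groups       = "character",
    controlMeans = "list"
  )
)

outcomeIndexNames <- function() c("IT_mean", "IT_median", "LA_mean", "LA_median")

setValidity("ProcessedDataset", function(object) {
  msg <- character(0)
  if (!identical(colnames(object@outcomes), outcomeIndexNames()))
    msg <- c(msg, "outcomes must have columns IT_mean, IT_median, LA_mean, LA_median")
  if (!identical(rownames(object@outcomes), rownames(object@predictors)))
    msg <- c(msg, "outcome and predictor rows must cover the same cases")
  if (!identical(sort(names(object@groups)), sort(rownames(object@outcomes))))
    msg <- c(msg, "groups must be named by the treated case ids")
  if (length(object@groups) && !all(object@groups %in% c("HF", "HHF")))
    msg <- c(msg, "processed rows must cover treated (HF, HHF) cases only")
  if (!identical(object@catalog$name, colnames(object@predictors)))
    msg <- c(msg, "catalog rows must match predictor columns in order")
  if (any(!is.finite(object@predictors)) || any(!is.finite(object@outcomes)))
    msg <- c(msg, "all processed values must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("outcomeMatrix", "ProcessedDataset", function(object) object@outcomes)

#' @rdname accessors
#' @export
setMethod("predictorMatrix", "ProcessedDataset", function(object) object@predictors)

#' @rdname accessors
#' @export
setMethod("variableCatalog", "ProcessedDataset", function(object) object@catalog)

setMethod("show", "ProcessedDataset", function(object) {
  cat("ProcessedDataset:", nrow(object@outcomes), "treated cases,",
      ncol(object@predictors), "candidate variables\n")
  prov <- table(object@catalog$provenance)
  cat("  provenance:", paste(names(prov), prov, sep = ":", collapse = " "), "\n")
  cat("  scale: control-normalized natural log (dimensionless)\n")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# RegressionProblem
# ---------------------------------------------------------------------------

#' One outcome / candidate-set regression problem
#'
#' A single outcome index (control-normalized log scale) over a filtered case
#' set, with its candidate predictor matrix.  Produced by [buildProblem()].
#'
#' @slot y numeric outcome vector (named by case id).
#' @slot X numeric matrix, cases x candidate variables.
#' @slot outcome which of the four indexes \code{y} is.
#' @slot groupFilter \code{"pooled"}, \code{"HF"} or \code{"HHF"}.
#' @slot dropped character vector of zero-variance variables removed.
#'
#' @export
setClass("RegressionProblem",
  representation(
    y           = "numeric",
    X           = "matrix",
    outcome     = "character",
    groupFilter = "character",
    dropped     = "character"
  )
)

setValidity("RegressionProblem", function(object) {
  msg <- character(0)
  if (length(object@y) != nrow(object@X))
    msg <- c(msg, "length(y) must equal nrow(X)")
  if (ncol(object@X)) {
    v <- apply(object@X, 2, stats::var)
    if (any(v == 0))
      msg <- c(msg, "X must not contain zero-variance columns")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegressionProblem", function(object) {
  cat("RegressionProblem:", object@outcome, "~", ncol(object@X),
      "candidates over", length(object@y), "cases (", object@groupFilter, ")\n")
  if (length(object@dropped))
    cat("  dropped zero-variance:", paste(object@dropped, collapse = ", "), "\n")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# BMAResult
# ---------------------------------------------------------------------------

#' Bayesian model averaging result
#'
#' Result of [enumerateBMA()] or [ibmaSelect()]: the retained subset models
#' with BIC-approximate posterior model probabilities, per-variable posterior
#' inclusion probabilities and model-averaged coefficients.
#'
#' For [enumerateBMA()] the slots describe the single enumeration:
#' \code{inclusionProb[v]} is the summed posterior probability of the
#' post-Occam's-window models containing \code{v}, and
#' \code{avgCoefficient[v]} the probability-weighted slope (0 where
#' excluded).  For [ibmaSelect()] both vectors cover every candidate
#' variable: final-enumeration values for the surviving active set, and the
#' values from the window in which a variable was last examined for the
#' variables that were swapped out along the way.
#'
#' @slot variables candidate variable names (columns of the final X).
#' @slot models data.frame of the models surviving Occam's window:
#'   \code{mask} ("0"/"1" string over \code{variables}), \code{k} (number of
#'   predictors), \code{rss}, \code{bic}, \code{pmp}.
#' @slot coefficients numeric matrix models x (intercept + variables); NA
#'   marks a variable excluded from that model.
#' @slot inclusionProb named numeric, P(effect != 0 | data) per variable.
#' @slot avgCoefficient named numeric model-averaged slope per variable.
#' @slot retained variables whose inclusion probability exceeds the
#'   retention threshold in the final enumeration.
#' @slot settings list echoing \code{occamRatio}, \code{windowSize},
#'   \code{retentionThreshold} and the fitting floor.
#'
#' @export
setClass("BMAResult",
  representation(
    variables      = "character",
    models         = "data.frame",
    coefficients   = "matrix",
    inclusionProb  = "numeric",
    avgCoefficient = "numeric",
    retained       = "character",
    settings       = "list"
  )
)

setValidity("BMAResult", function(object) {
  msg <- character(0)
  if (nrow(object@models)) {
    if (abs(sum(object@models$pmp) - 1) > 1e-12)
      msg <- c(msg, "posterior model probabilities must sum to 1")
    if (any(object@models$rss < 0))
      msg <- c(msg, "rss must be non-negative")
  }
  if (!all(object@retained %in% names(object@inclusionProb)))
    msg <- c(msg, "retained variables must appear in inclusionProb")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("inclusionProb", "BMAResult", function(object) object@inclusionProb)

#' @rdname accessors
#' @export
setMethod("avgCoefficient", "BMAResult", function(object) object@avgCoefficient)

#' @rdname accessors
#' @export
setMethod("retainedVariables", "BMAResult", function(object) object@retained)

#' @rdname accessors
#' @export
setMethod("modelTable", "BMAResult", function(object) object@models)

setMethod("show", "BMAResult", function(object) {
  cat("BMAResult:", nrow(object@models), "models over",
      length(object@variables), "variables\n")
  top <- sort(object@inclusionProb, decreasing = TRUE)
  top <- top[seq_len(min(5, length(top)))]
  cat("  top inclusion:",
      paste(sprintf("%s=%.2f", names(top), top), collapse = ", "), "\n")
  cat("  retained:", if (length(object@retained))
    paste(object@retained, collapse = ", ") else "(none)", "\n")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# SelectionTable
# ---------------------------------------------------------------------------

#' Per-index selection table
#'
#' For every candidate variable and each of the four histology indexes:
#' whether the variable was retained by the per-index model run, and its
#' model-averaged coefficient there.
#'
#' @slot selected logical matrix, variables x the four indexes.
#' @slot coefficients numeric matrix, same shape; coefficient on the
#'   control-normalized log scale (NA where never examined).
#'
#' @seealso [buildSelectionTable()], [congruenceFilter()]
#' @export
setClass("SelectionTable",
  representation(selected = "matrix", coefficients = "matrix")
)

setValidity("SelectionTable", function(object) {
  msg <- character(0)
  if (!identical(colnames(object@selected), outcomeIndexNames()))
    msg <- c(msg, "columns must be IT_mean, IT_median, LA_mean, LA_median")
  if (!identical(dimnames(object@selected), dimnames(object@coefficients)))
    msg <- c(msg, "selected and coefficients must share dimnames")
  if (!is.logical(object@selected))
    msg <- c(msg, "selected must be logical")
  bad <- object@selected & !is.finite(object@coefficients)
  if (any(bad))
    msg <- c(msg, "a selected cell must carry a finite coefficient")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("selectedFlags", "SelectionTable", function(object) object@selected)

#' @rdname accessors
#' @export
setMethod("selectionCoefficients", "SelectionTable",
          function(object) object@coefficients)

setMethod("show", "SelectionTable", function(object) {
  cat("SelectionTable:", nrow(object@selected), "variables x 4 indexes;",
      sum(object@selected), "selected cells\n")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# CongruenceLedger
# ---------------------------------------------------------------------------

#' Two-stage congruence verdict ledger
#'
#' Final per-variable verdict of the congruence post-processing:
#' \code{retained}, \code{discarded_stage1} (not selected for at least one IT
#' and one LA index), \code{discarded_sign} (supporting coefficients of
#' incongruent sign), or \code{discarded_magnitude} (all supporting
#' coefficients below the magnitude floor).
#'
#' @slot table data.frame with columns \code{variable}, \code{status},
#'   \code{direction} (\code{"positive"}, \code{"negative"} or \code{"n/a"}),
#'   \code{supporting} (";"-joined supporting index names),
#'   \code{max_abs_coef}.
#' @slot selection the [SelectionTable] the ledger was derived from.
#' @slot settings list echoing \code{magnitudeFloor}, \code{sizeRatioCap},
#'   \code{strictSign}.
#'
#' @seealso [congruenceFilter()], [summarizeLedger()]
#' @export
setClass("CongruenceLedger",
  representation(
    table     = "data.frame",
    selection = "SelectionTable",
    settings  = "list"
  )
)

setValidity("CongruenceLedger", function(object) {
  msg <- character(0)
  tb <- object@table
  need <- c("variable", "status", "direction", "supporting", "max_abs_coef")
  if (!all(need %in% names(tb)))
    msg <- c(msg, paste("table must have columns", paste(need, collapse = ", ")))
  else if (nrow(tb)) {
    ok <- c("retained", "discarded_stage1", "discarded_sign",
            "discarded_magnitude")
    if (!all(tb$status %in% ok))
      msg <- c(msg, "unknown status value")
    ret <- tb[tb$status == "retained", , drop = FALSE]
    if (nrow(ret)) {
      sup <- strsplit(ret$supporting, ";", fixed = TRUE)
      hasBoth <- vapply(sup, function(s)
        any(startsWith(s, "IT_")) && any(startsWith(s, "LA_")), logical(1))
      if (!all(hasBoth))
        msg <- c(msg, "retained variables need >= 1 IT and >= 1 LA supporting index")
      if (!all(ret$direction %in% c("positive", "negative")))
        msg <- c(msg, "retained variables must carry a direction")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("ledgerTable", "CongruenceLedger", function(object) object@table)

setMethod("show", "CongruenceLedger", function(object) {
  tb <- object@table
  cat("CongruenceLedger:", nrow(tb), "variables;",
      sum(tb$status == "retained"), "retained\n")
  if (any(tb$status == "retained")) {
    ret <- tb[tb$status == "retained", ]
    sgn <- ifelse(ret$direction == "positive", "+", "-")
    cat("  retained:", paste0(ret$variable, " (", sgn, ")", collapse = ", "), "\n")
  }
  invisible(NULL)
})
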