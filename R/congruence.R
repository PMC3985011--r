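#' @include run-indexes.R
NULL

#' Build the per-index selection table
#'
#' Collects the four per-index model runs into one table: a variable is
#' "selected" for an index iff it is in that result's retained set, and its
#' model-averaged coefficient there is recorded (NA where the run never
#' examined the variable).
#'
#' @param results named list of [BMAResult]s covering exactly the four
#'   indexes \code{IT_mean}, \code{IT_median}, \code{LA_mean},
#'   \code{LA_median}.
#' @return a [SelectionTable].
#' @export
buildSelectionTable <- function(results) {
  need <- outcomeIndexNames()
  if (!all(need %in% names(results)))
    stop("missing index result(s): ",
         paste(setdiff(need, names(results)), collapse = ", "))
  results <- results[need]
  vars <- unique(unlist(lapply(results, function(r) names(inclusionProb(r)))))
  if (is.null(vars)) vars <- character(0)
  sel <- matrix(FALSE, length(vars), 4, dimnames = list(vars, need))
  coef <- matrix(NA_real_, length(vars), 4, dimnames = list(vars, need))
  for (idx in need) {
    r <- results[[idx]]
    sel[retainedVariables(r), idx] <- TRUE
    coef[names(avgCoefficient(r)), idx] <- avgCoefficient(r)
  }
  methods::new("SelectionTable", selected = sel, coefficients = coef)
}

#' Stage 1: congruence of selection across histology index families
#'
#' A variable passes only if it was selected for at least one intimal
#' thickness index AND at least one lesional area index; variables with
#' only-IT or only-LA (or no) support are marked \code{discarded_stage1}.
#'
#' @param table a [SelectionTable].
#' @return data.frame with columns \code{variable}, \code{pass},
#'   \code{supporting} (";"-joined selected index names).
#' @export
applyIndexCongruence <- function(table) {
  stopifnot(methods::is(table, "SelectionTable"))
  sel <- selectedFlags(table)
  if (!nrow(sel))
    return(data.frame(variable = character(0), pass = logical(0),
                      supporting = character(0), stringsAsFactors = FALSE))
  supporting <- apply(sel, 1, function(s)
    paste(colnames(sel)[s], collapse = ";"))
  pass <- (sel[, "IT_mean"] | sel[, "IT_median"]) &
          (sel[, "LA_mean"] | sel[, "LA_median"])
  data.frame(variable = rownames(sel), pass = unname(pass),
             supporting = unname(supporting), stringsAsFactors = FALSE)
}

#' Stage 2: congruence of the supporting regression coefficients
#'
#' Among stage-1 survivors, a variable is retained iff its supporting
#' coefficients (at the indexes that selected it) agree in sign and at
#' least one reaches the magnitude floor (default 0.001 on the
#' control-normalized log scale the model was fitted on — the floor is
#' scale-dependent, see the vignette).  Sign disagreement is classed
#' \code{discarded_sign}; with \code{strictSign = TRUE} (default) any
#' opposite-sign pair discards, with \code{strictSign = FALSE} only
#' opposite-sign pairs of comparable size (max/min absolute ratio at most
#' \code{sizeRatioCap}) discard, and otherwise the direction of the
#' dominant coefficient is used.  Variables whose supporting coefficients
#' all fall below the floor are \code{discarded_magnitude}.  Coefficients
#' exactly zero carry no sign information; a variable with only zero
#' support is discarded on magnitude.
#'
#' @param stage1 the data.frame returned by [applyIndexCongruence()].
#' @param table the [SelectionTable] the stage-1 verdicts came from.
#' @param magnitudeFloor minimum absolute coefficient (default 0.001).
#' @param sizeRatioCap "comparable size" bound for the relaxed sign rule
#'   (default 10).
#' @param strictSign treat any sign disagreement as incongruent (default).
#' @return a [CongruenceLedger].
#' @export
applyCoefficientCongruence <- function(stage1, table, magnitudeFloor = 0.001,
                                       sizeRatioCap = 10, strictSign = TRUE) {
  stopifnot(methods::is(table, "SelectionTable"))
  sel <- selectedFlags(table)
  coefs <- selectionCoefficients(table)
  emptyRow <- data.frame(variable = character(0), status = character(0),
                         direction = character(0), supporting = character(0),
                         max_abs_coef = numeric(0), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(stage1)), function(i) {
    v <- stage1$variable[i]
    sup <- colnames(sel)[sel[v, ]]
    cf <- coefs[v, sup]
    maxAbs <- if (length(cf)) max(abs(cf)) else 0
    row <- function(status, direction)
      data.frame(variable = v, status = status, direction = direction,
                 supporting = paste(sup, collapse = ";"),
                 max_abs_coef = maxAbs, stringsAsFactors = FALSE)
    if (!stage1$pass[i])
      return(row("discarded_stage1", "n/a"))
    sgn <- unique(sign(cf[cf != 0]))
    if (!length(sgn))
      return(row("discarded_magnitude", "n/a"))
    if (length(sgn) > 1) {
      nz <- abs(cf[cf != 0])
      comparable <- max(nz) / min(nz) <= sizeRatioCap
      if (strictSign || comparable)
        return(row("discarded_sign", "n/a"))
      sgn <- sign(cf[which.max(abs(cf))])   # relaxed: dominant sign wins
    }
    if (maxAbs < magnitudeFloor)
      return(row("discarded_magnitude", "n/a"))
    row("retained", if (sgn > 0) "positive" else "negative")
  })
  methods::new("CongruenceLedger",
    table = if (length(rows)) do.call(rbind, rows) else emptyRow,
    selection = table,
    settings = list(magnitudeFloor = magnitudeFloor,
                    sizeRatioCap = sizeRatioCap, strictSign = strictSign))
}

#' Two-stage congruence filter
#'
#' Convenience wrapper chaining [applyIndexCongruence()] and
#' [applyCoefficientCongruence()].
#'
#' @inheritParams applyCoefficientCongruence
#' @param table a [SelectionTable].
#' @return a [CongruenceLedger].
#' @examples
#' tab <- demoSelectionPattern()
#' congruenceFilter(tab)
#' @export
congruenceFilter <- function(table, magnitudeFloor = 0.001,
                             sizeRatioCap = 10, strictSign = TRUE) {
  applyCoefficientCongruence(applyIndexCongruence(table), table,
                             magnitudeFloor = magnitudeFloor,
                             sizeRatioCap = sizeRatioCap,
                             strictSign = strictSign)
}

#' Summarize a congruence ledger into report rows
#'
#' Orders the ledger retained-first, then by the strongest supporting
#' coefficient magnitude, keeping the discard reason for the rest.
#'
#' @param ledger a [CongruenceLedger].
#' @return data.frame of report rows.
#' @export
summarizeLedger <- function(ledger) {
  stopifnot(methods::is(ledger, "CongruenceLedger"))
  tb <- ledgerTable(ledger)
  if (!nrow(tb)) return(tb)
  tb[order(tb$status != "retained", -tb$max_abs_coef, tb$variable), ,
     drop = FALSE]
}

#' Write the ledger and a human-readable report
#'
#' Emits \code{ledger.csv} (variable, status, direction, supporting
#' indexes, strongest coefficient) and \code{report.md}, a markdown table
#' mirroring the selection-table / final-ledger presentation.
#'
#' @param ledger a [CongruenceLedger].
#' @param directory output directory, created if missing.
#' @return the directory, invisibly.
#' @export
writeLedger <- function(ledger, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  tb <- summarizeLedger(ledger)
  utils::write.csv(tb, file.path(directory, "ledger.csv"), row.names = FALSE)
  lines <- c("# Congruence ledger", "",
             sprintf("%d variables examined, %d retained.", nrow(tb),
                     sum(tb$status == "retained")), "",
             "| variable | status | direction | supporting | max |coef| |",
             "|---|---|---|---|---|",
             sprintf("| %s | %s | %s | %s | %.4g |", tb$variable, tb$status,
                     tb$direction, tb$supporting, tb$max_abs_coef))
  writeLines(lines, file.path(directory, "report.md"))
  invisible(directory)
}
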