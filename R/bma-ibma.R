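#' @include bma-enumerate.R
NULL

#' Iterated BMA variable selection
#'
#' Variable selection for small-n / large-p problems by repeatedly calling
#' exhaustive model averaging on a moving window of candidates.  Variables
#' are processed in the fixed [rankVariables()] order (decreasing univariate
#' R-squared).  The first \code{windowSize} variables form the active set;
#' after each [enumerateBMA()] call, variables whose posterior inclusion
#' probability exceeds \code{retentionThreshold} stay active and the rest
#' are replaced by the next-ranked unexamined variables.  When every active
#' variable survives while unexamined variables remain, the lowest-inclusion
#' survivors are swapped out until one slot is free, so the walk always
#' terminates.  Once all variables have been examined, a final enumeration
#' over the surviving active set produces the returned result;
#' \code{retained} are the variables exceeding the threshold there.
#'
#' When \code{p <= windowSize} the procedure reduces to a single
#' [enumerateBMA()] call and returns its result unchanged.
#'
#' The returned \code{inclusionProb} and \code{avgCoefficient} cover every
#' candidate variable: final-enumeration values for the survivors, and the
#' values from the window where a variable was last examined for the rest
#' (a variable never appearing in a surviving model there has coefficient
#' exactly zero).
#'
#' @param y outcome vector.
#' @param X candidate matrix with named columns.
#' @param windowSize active-set size; default
#'   \code{min(8, n - 3, maxEnumerate)}.  Must be \code{< n - 1}; at
#'   \code{n = 4} the cap forces \code{windowSize = 1} and the procedure
#'   degenerates to univariate screening (a message notes the cap).
#' @param retentionThreshold inclusion-probability threshold in (0, 1).
#' @param occamRatio Occam's window width.
#' @param maxEnumerate per-window enumeration cap.
#' @return a [BMAResult].
#' @examples
#' set.seed(2)
#' X <- matrix(rnorm(40 * 12), 40, 12,
#'             dimnames = list(NULL, sprintf("v%02d", 1:12)))
#' y <- X[, "v01"] - X[, "v02"] + rnorm(40, 0, 0.4)
#' retainedVariables(ibmaSelect(y, X, windowSize = 5))
#' @export
ibmaSelect <- function(y, X, windowSize = NULL, retentionThreshold = 0.5,
                       occamRatio = 20, maxEnumerate = 20) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (retentionThreshold <= 0 || retentionThreshold >= 1)
    stop("retentionThreshold must be in (0, 1)")
  if (is.null(windowSize)) {
    windowSize <- min(8L, n - 3L, maxEnumerate)
    if (windowSize < min(8L, maxEnumerate))
      message("window size capped at n - 3 = ", windowSize,
              " by the small sample (n = ", n, ")")
  }
  if (windowSize < 1) stop("windowSize must be >= 1")
  if (windowSize >= n - 1)
    stop("windowSize = ", windowSize, " must be below n - 1 = ", n - 1,
         " (small-sample cap)")
  if (windowSize > maxEnumerate)
    stop("windowSize must not exceed the enumeration cap")

  settings <- list(windowSize = windowSize,
                   retentionThreshold = retentionThreshold,
                   occamRatio = occamRatio)
  if (p <= windowSize) {
    # single-window degeneracy: identical to exhaustive enumeration
    res <- enumerateBMA(y, X, occamRatio, retentionThreshold, maxEnumerate)
    res@settings <- utils::modifyList(res@settings, settings)
    return(res)
  }

  ranked <- rankVariables(y, X)
  active <- ranked[seq_len(windowSize)]
  pending <- ranked[-seq_len(windowSize)]
  lastIncl <- stats::setNames(rep(0, p), colnames(X))
  lastCoef <- stats::setNames(rep(0, p), colnames(X))

  repeat {
    res <- enumerateBMA(y, X[, active, drop = FALSE], occamRatio,
                        retentionThreshold, maxEnumerate)
    lastIncl[active] <- inclusionProb(res)[active]
    lastCoef[active] <- avgCoefficient(res)[active]
    survivors <- active[inclusionProb(res)[active] > retentionThreshold]
    if (!length(pending)) break
    free <- windowSize - length(survivors)
    if (free < 1) {
      # all survived: swap out the weakest to keep examining new variables
      drop <- survivors[order(inclusionProb(res)[survivors])][1]
      survivors <- setdiff(survivors, drop)
      free <- 1L
    }
    entering <- pending[seq_len(min(free, length(pending)))]
    pending <- setdiff(pending, entering)
    active <- ranked[ranked %in% c(survivors, entering)]
  }

  final <- if (length(survivors)) {
    if (setequal(survivors, active)) res
    else enumerateBMA(y, X[, survivors, drop = FALSE], occamRatio,
                      retentionThreshold, maxEnumerate)
  } else emptyBMAResult(y, settings)
  if (length(survivors)) {
    lastIncl[final@variables] <- inclusionProb(final)
    lastCoef[final@variables] <- avgCoefficient(final)
  }

  methods::new("BMAResult",
    variables = colnames(X), models = final@models,
    coefficients = final@coefficients,
    inclusionProb = lastIncl, avgCoefficient = lastCoef,
    retained = final@variables[inclusionProb(final) > retentionThreshold],
    settings = c(settings, list(rssFloor = rssFloorFor(y))))
}
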