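#' @include build-problem.R
NULL

# Default residual-sum-of-squares floor: keeps the BIC finite on (near-)
# perfect fits without perturbing any realistic model comparison.
rssFloorFor <- function(y) {
  f <- 1e-12 * stats::var(y) * length(y)
  max(f, .Machine$double.xmin)
}

#' Ordinary least squares on one predictor subset
#'
#' Fits the intercept-plus-subset linear model by pivoted QR and evaluates
#' its Bayesian information criterion
#' \code{BIC = n * ln(max(RSS, floor) / n) + (k + 1) * ln(n)} with \code{k}
#' the number of included predictors (the intercept contributes the
#' \code{+ 1}).  The RSS floor (default \code{1e-12 * var(y) * n}) keeps the
#' criterion finite when a subset fits perfectly.  Rank-deficient subsets
#' are rejected by name rather than silently pseudo-inverted, since the
#' pseudo-inverse would reorder posterior model probabilities
#' irreproducibly.
#'
#' @param y numeric outcome vector.
#' @param X numeric matrix, cases x candidate variables.
#' @param mask logical (or 0/1) inclusion vector over \code{ncol(X)}.
#' @param rssFloor optional override of the RSS floor.
#' @return list with \code{mask}, \code{coefficients} (intercept first,
#'   then the included variables), \code{rss}, \code{k}, \code{bic}.
#' @examples
#' set.seed(1); X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
#' y <- 2 * X[, 1] + rnorm(20, 0, .1)
#' fitSubset(y, X, c(TRUE, FALSE))$coefficients
#' @export
fitSubset <- function(y, X, mask, rssFloor = NULL) {
  mask <- as.logical(mask)
  n <- length(y)
  k <- sum(mask)
  if (k > n - 2)
    stop("subset with ", k, " predictors exceeds the n - 2 = ", n - 2,
         " cap for n = ", n, " cases")
  if (is.null(rssFloor)) rssFloor <- rssFloorFor(y)
  Z <- cbind(`(Intercept)` = rep(1, n), X[, mask, drop = FALSE])
  fit <- stats::.lm.fit(Z, y)
  if (fit$rank < ncol(Z)) {
    coefNA <- rep(NA_real_, ncol(Z))
    coefNA[fit$pivot[seq_len(fit$rank)]] <- 0
    stop("collinear subset; aliased variable(s): ",
         paste(colnames(Z)[is.na(coefNA)], collapse = ", "))
  }
  coef <- numeric(ncol(Z))
  coef[fit$pivot] <- fit$coefficients[seq_len(ncol(Z))]
  names(coef) <- colnames(Z)
  rss <- sum(fit$residuals^2)
  bic <- n * log(max(rss, rssFloor) / n) + (k + 1) * log(n)
  list(mask = mask, coefficients = coef, rss = rss, k = k, bic = bic)
}
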