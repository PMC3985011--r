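#' @include bma-fit.R
NULL

#' Occam's window over a set of fitted subset models
#'
#' Discards models whose posterior probability falls below \code{1/ratio}
#' of the best model's, i.e. keeps exactly the models with
#' \code{pmp_best / pmp <= ratio}, and renormalizes the survivors' posterior
#' probabilities to sum to one.  The best model is always retained;
#' \code{ratio = Inf} keeps everything, \code{ratio = 1} only the model(s)
#' tied for best.
#'
#' @param models data.frame with (at least) a \code{pmp} column of posterior
#'   model probabilities.
#' @param ratio Occam's window width, >= 1.
#' @return the filtered data.frame with renormalized \code{pmp}; the
#'   attribute \code{"kept"} carries the retained row indices of the input.
#' @examples
#' m <- data.frame(pmp = c(0.6, 0.35, 0.05))
#' occamWindow(m, 10)$pmp   # the 0.05 model is dropped
#' @export
occamWindow <- function(models, ratio) {
  if (!nrow(models)) stop("no models to filter")
  if (is.na(ratio) || ratio < 1) stop("Occam's window ratio must be >= 1")
  keep <- which(max(models$pmp) / models$pmp <= ratio)
  out <- models[keep, , drop = FALSE]
  out$pmp <- out$pmp / sum(out$pmp)
  attr(out, "kept") <- keep
  out
}

#' Rank candidate variables by univariate goodness of fit
#'
#' Orders variables by decreasing univariate R-squared against the outcome
#' (the squared Pearson correlation), the fixed examination order the
#' iterated variable-selection loop walks through.  Ties are broken
#' lexicographically by variable name.
#'
#' @param y outcome vector.
#' @param X candidate matrix with column names.
#' @return character vector of variable names, best first.
#' @export
rankVariables <- function(y, X) {
  r2 <- suppressWarnings(as.vector(stats::cor(y, X))^2)
  r2[!is.finite(r2)] <- 0
  nm <- colnames(X)
  nm[order(-r2, nm, method = "radix")]
}

emptyBMAResult <- function(y, settings = list()) {
  n <- length(y)
  rss <- sum((y - mean(y))^2)
  bic <- n * log(max(rss, rssFloorFor(y)) / n) + log(n)
  methods::new("BMAResult",
    variables = character(0),
    models = data.frame(mask = "", k = 0L, rss = rss, bic = bic, pmp = 1,
                        stringsAsFactors = FALSE),
    coefficients = matrix(mean(y), 1, 1,
                          dimnames = list(NULL, "(Intercept)")),
    inclusionProb = stats::setNames(numeric(0), character(0)),
    avgCoefficient = stats::setNames(numeric(0), character(0)),
    retained = character(0), settings = settings)
}

#' Exhaustive BIC-approximate Bayesian model averaging
#'
#' Fits every subset of the candidate variables (all \code{2^p} models,
#' subject to the \code{k <= n - 2} cap), converts BIC values to
#' approximate posterior model probabilities under a uniform model prior,
#' \code{pmp_k} proportional to \code{exp(-(BIC_k - BIC_min)/2)}, applies
#' [occamWindow()], and averages: a variable's posterior inclusion
#' probability is the summed probability of the surviving models containing
#' it, and its model-averaged coefficient the probability-weighted slope
#' with weight zero where it is excluded (the shrinkage that sets
#' never-included variables exactly to zero).
#'
#' @param y outcome vector.
#' @param X candidate matrix (named columns); \code{ncol(X)} must not
#'   exceed \code{maxEnumerate} — use [ibmaSelect()] beyond that.
#' @param occamRatio Occam's window width (default 20; \code{Inf} keeps all
#'   models).
#' @param retentionThreshold inclusion-probability threshold defining the
#'   \code{retained} set (default 0.5).
#' @param maxEnumerate enumeration cap on \code{ncol(X)} (default 20).
#' @param rssFloor optional RSS floor forwarded to [fitSubset()].
#' @return a [BMAResult].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- X[, "a"] + rnorm(30, 0, 0.5)
#' inclusionProb(enumerateBMA(y, X))
#' @export
enumerateBMA <- function(y, X, occamRatio = 20, retentionThreshold = 0.5,
                         maxEnumerate = 20, rssFloor = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- length(y)
  settings <- list(occamRatio = occamRatio,
                   retentionThreshold = retentionThreshold)
  if (p == 0) return(emptyBMAResult(y, settings))
  if (p > maxEnumerate)
    stop("p = ", p, " exceeds the enumeration cap (", maxEnumerate,
         "); use ibmaSelect() for iterated variable selection")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(p))
  if (is.null(rssFloor)) rssFloor <- rssFloorFor(y)

  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p),
                                 KEEP.OUT.ATTRS = FALSE))
  sizes <- rowSums(masks)
  feasible <- sizes <= n - 2
  if (!all(feasible))
    warning(sum(!feasible), " subset(s) with k > n - 2 skipped")
  masks <- masks[feasible, , drop = FALSE]

  m <- nrow(masks)
  bic <- rss <- numeric(m)
  ks <- integer(m)
  coefMat <- matrix(NA_real_, m, p + 1,
                    dimnames = list(NULL, c("(Intercept)", colnames(X))))
  for (i in seq_len(m)) {
    f <- fitSubset(y, X, masks[i, ], rssFloor = rssFloor)
    bic[i] <- f$bic; rss[i] <- f$rss; ks[i] <- f$k
    coefMat[i, c(TRUE, masks[i, ])] <- f$coefficients
  }
  w <- exp(-(bic - min(bic)) / 2)
  models <- data.frame(
    mask = apply(masks, 1, function(mk) paste0(as.integer(mk), collapse = "")),
    k = ks, rss = rss, bic = bic, pmp = w / sum(w),
    stringsAsFactors = FALSE)

  kept <- occamWindow(models, occamRatio)
  masks <- masks[attr(kept, "kept"), , drop = FALSE]
  coefMat <- coefMat[attr(kept, "kept"), , drop = FALSE]
  attr(kept, "kept") <- NULL

  incl <- as.vector(kept$pmp %*% masks)
  slopes <- coefMat[, -1, drop = FALSE]
  slopes[is.na(slopes)] <- 0
  avg <- as.vector(kept$pmp %*% slopes)
  names(incl) <- names(avg) <- colnames(X)

  methods::new("BMAResult",
    variables = colnames(X), models = kept, coefficients = coefMat,
    inclusionProb = incl, avgCoefficient = avg,
    retained = colnames(X)[incl > retentionThreshold],
    settings = c(settings, list(rssFloor = rssFloor)))
}
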