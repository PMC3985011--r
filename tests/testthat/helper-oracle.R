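# Independent brute-force model-averaging oracle: enumerates every subset
# by bit arithmetic and solves each least-squares problem by the normal
# equations, sharing no code with the package's QR-based path.
bruteForceBMA <- function(y, X) {
  p <- ncol(X)
  n <- length(y)
  floorRss <- 1e-12 * stats::var(y) * n
  bits <- 2^(seq_len(p) - 1)
  models <- lapply(0:(2^p - 1), function(id) {
    mask <- bitwAnd(id, bits) > 0
    Z <- cbind(1, X[, mask, drop = FALSE])
    beta <- solve(crossprod(Z), crossprod(Z, y))
    rss <- sum((y - Z %*% beta)^2)
    bic <- n * log(max(rss, floorRss) / n) + (sum(mask) + 1) * log(n)
    slopes <- numeric(p)
    slopes[mask] <- beta[-1]
    list(mask = mask, slopes = slopes, bic = bic)
  })
  bic <- vapply(models, `[[`, numeric(1), "bic")
  w <- exp(-(bic - min(bic)) / 2)
  w <- w / sum(w)
  maskMat <- t(vapply(models, `[[`, logical(p), "mask"))
  slopeMat <- t(vapply(models, `[[`, numeric(p), "slopes"))
  list(incl = stats::setNames(as.vector(w %*% maskMat), colnames(X)),
       avg = stats::setNames(as.vector(w %*% slopeMat), colnames(X)))
}

# Seeded regression fixture: X standard normal, y = X beta + noise.
makeRegData <- function(seed, n, p, beta = numeric(p), noiseSd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("v%02d", seq_len(p))))
  list(X = X, y = as.vector(X %*% beta) + rnorm(n, 0, noiseSd))
}

# Hand-built selection table over arbitrary cells.
makeSelectionTable <- function(cells) {
  idx <- c("IT_mean", "IT_median", "LA_mean", "LA_median")
  vars <- unique(cells$variable)
  sel <- matrix(FALSE, length(vars), 4, dimnames = list(vars, idx))
  coef <- matrix(NA_real_, length(vars), 4, dimnames = list(vars, idx))
  for (i in seq_len(nrow(cells))) {
    sel[cells$variable[i], cells$index[i]] <- TRUE
    coef[cells$variable[i], cells$index[i]] <- cells$coefficient[i]
  }
  methods::new("SelectionTable", selected = sel, coefficients = coef)
}
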