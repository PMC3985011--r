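test_that("exhaustive enumeration matches the brute-force oracle", {
  d <- makeRegData(7, 30, 5, beta = c(1, -0.8, 0, 0, 0), noiseSd = 0.5)
  res <- enumerateBMA(d$y, d$X, occamRatio = Inf)
  oracle <- bruteForceBMA(d$y, d$X)
  expect_equal(inclusionProb(res), oracle$incl, tolerance = 1e-10)
  expect_equal(avgCoefficient(res), oracle$avg, tolerance = 1e-10)
  expect_equal(sum(modelTable(res)$pmp), 1, tolerance = 1e-12)
  expect_equal(nrow(modelTable(res)), 2^5)
})

test_that("posterior model probabilities always renormalize to one", {
  for (s in 1:5) {
    d <- makeRegData(100 + s, 25, 4, beta = c(s / 5, 0, 0, 0))
    res <- enumerateBMA(d$y, d$X, occamRatio = 20)
    expect_equal(sum(modelTable(res)$pmp), 1, tolerance = 1e-12)
  }
})

test_that("Occam's window keeps the right models", {
  m <- data.frame(pmp = c(0.6, 0.35, 0.05))
  expect_equal(nrow(occamWindow(m, 20)), 3)   # 0.6/0.05 = 12 <= 20
  w10 <- occamWindow(m, 10)                   # 12 > 10 drops the 0.05 model
  expect_equal(nrow(w10), 2)
  expect_equal(w10$pmp, c(0.6, 0.35) / 0.95)
  expect_equal(nrow(occamWindow(m, 1)), 1)    # only the best survives
  expect_equal(occamWindow(m, 1)$pmp, 1)
  expect_equal(nrow(occamWindow(m, Inf)), 3)  # no-op boundary
  expect_error(occamWindow(m[0, , drop = FALSE], 10), "no models")
  expect_error(occamWindow(m, 0.5), ">= 1")
})

test_that("a single pure-noise predictor is not included at large n", {
  set.seed(31)
  X <- matrix(rnorm(100), dimnames = list(NULL, "noise"))
  y <- rnorm(100)
  expect_lt(inclusionProb(enumerateBMA(y, X))[["noise"]], 0.5)
})

test_that("variable ranking is a univariate R-squared sort with name ties", {
  d <- makeRegData(12, 40, 4, beta = c(0, 2, 0, 0), noiseSd = 0.3)
  X <- cbind(d$X, exact = d$y)   # a predictor equal to y ranks first
  expect_equal(rankVariables(d$y, X)[1], "exact")
  # two identical columns: lexicographic tie-break
  tied <- cbind(b = d$X[, 2], a = d$X[, 2])
  expect_equal(rankVariables(d$y, tied), c("a", "b"))
  # order equals an independently computed squared-correlation sort
  r2 <- apply(d$X, 2, function(col) cor(d$y, col)^2)
  expect_equal(rankVariables(d$y, d$X),
               names(sort(-r2)))
})

test_that("averaging identity and shrinkage contract hold", {
  d <- makeRegData(17, 30, 4, beta = c(1.2, 0, 0, 0), noiseSd = 0.5)
  res <- enumerateBMA(d$y, d$X, occamRatio = 20)
  mt <- modelTable(res)
  masks <- do.call(rbind, lapply(strsplit(mt$mask, ""), function(x) x == "1"))
  for (j in seq_along(res@variables)) {
    v <- res@variables[j]
    inModels <- masks[, j]
    condAvg <- if (any(inModels)) {
      sum(mt$pmp[inModels] * res@coefficients[inModels, v]) /
        sum(mt$pmp[inModels])
    } else 0
    expect_equal(avgCoefficient(res)[[v]],
                 inclusionProb(res)[[v]] * condAvg, tolerance = 1e-12)
  }
  # a tight window excludes the weak variables from every retained model;
  # their averaged coefficient must then be exactly zero
  tight <- enumerateBMA(d$y, d$X, occamRatio = 1)
  gone <- setdiff(tight@variables,
                  unlist(lapply(strsplit(modelTable(tight)$mask, ""),
                                function(m) tight@variables[m == "1"])))
  expect_gt(length(gone), 0)
  expect_identical(unname(avgCoefficient(tight)[gone]),
                   rep(0, length(gone)))
  expect_identical(unname(inclusionProb(tight)[gone]),
                   rep(0, length(gone)))
})

test_that("inclusion probability responds monotonically to effect size", {
  set.seed(23)
  n <- 30
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  noise <- rnorm(n, 0, 0.5)
  incl <- vapply(seq(0, 1, by = 0.2), function(b) {
    y <- b * X[, "a"] + noise
    inclusionProb(enumerateBMA(y, X, occamRatio = Inf))[["a"]]
  }, numeric(1))
  expect_true(all(diff(incl) >= -1e-12))
})

test_that("the enumeration cap redirects to iterated selection", {
  d <- makeRegData(3, 40, 6)
  expect_error(enumerateBMA(d$y, d$X, maxEnumerate = 5), "ibmaSelect")
})
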