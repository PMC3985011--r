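test_that("Friedewald LDL follows the mass-concentration formula", {
  expect_equal(friedewaldLDL(200, 50, 100), 130)
  expect_equal(friedewaldLDL(100, 40, 0), 60)
  expect_warning(ldl <- friedewaldLDL(50, 60, 100), "negative")
  expect_true(is.na(ldl))
  expect_warning(friedewaldLDL(300, 50, 450), "unreliable")
  expect_error(friedewaldLDL(-1, 50, 100), "non-negative")
})

test_that("total-protein normalization equalizes row totals", {
  m <- rbind(case1 = c(40, 60), case2 = c(100, 200))
  out <- normalizeTotalProtein(m)
  expect_equal(unname(rowSums(out)), c(200, 200))
  expect_equal(unname(out["case1", ]), c(80, 120))           # x2
  expect_equal(unname(out["case2", ]), c(100, 200) * 2 / 3)  # x(2/3)
  # proportions within a case preserved
  expect_equal(unname(out["case2", 1] / out["case2", 2]), 100 / 200)
  # idempotence / fixed point
  expect_equal(normalizeTotalProtein(out), out, tolerance = 1e-12)
  # single case: grand mean equals its own total
  one <- m[1, , drop = FALSE]
  expect_equal(normalizeTotalProtein(one), one)
  bad <- rbind(ok = c(1, 2), empty = c(0, 0))
  expect_error(normalizeTotalProtein(bad), "empty")
})

test_that("histology aggregation pools segments per case", {
  h <- data.frame(case_id = "a", artery = "LAD", segment = 1:5,
                  it_mm = c(0.6, 0.1, 0.1, 0.1, 0.1),
                  la_mm2 = c(2.4, 0.4, 0.4, 0.4, 0.4))
  agg <- aggregateHistology(h)
  expect_equal(agg$it_mean, 0.2)
  expect_equal(agg$it_median, 0.1)
  expect_equal(agg$it_median / agg$it_mean, 0.5)  # localized divergence
  # single record: mean = median = input
  one <- aggregateHistology(data.frame(case_id = "b", artery = "RCA",
                                       segment = 1, it_mm = 0.3, la_mm2 = 1.2))
  expect_equal(unlist(one[-1]), c(it_mean = 0.3, it_median = 0.3,
                                  la_mean = 1.2, la_median = 1.2))
  # even-count midpoint convention
  two <- aggregateHistology(data.frame(case_id = "c", artery = "LAD",
                                       segment = 1:2, it_mm = c(0.2, 0.4),
                                       la_mm2 = c(1, 2)))
  expect_equal(two$it_median, 0.3)
  # permutation invariance in segment order; arteries pooled
  h2 <- h[sample(5), ]; h2$artery <- c("LAD", "LCX", "RCA", "LM", "LAD")
  h2$segment <- 1:5
  expect_equal(aggregateHistology(h2)[-1], agg[-1])
  expect_error(aggregateHistology(h, "missing"), "missing")
})

test_that("control-normalized log transform behaves and inverts", {
  cm <- c(x = 5, y = 2)
  vals <- cbind(x = c(5, 50), y = c(2, 1))
  out <- controlNormalizeLog(vals, cm)
  expect_equal(unname(out[1, "x"]), 0)              # value = control mean
  expect_equal(unname(out[2, "x"]), log(10), tolerance = 1e-12)
  expect_equal(exp(out) %*% diag(cm), unname(vals), tolerance = 1e-10,
               ignore_attr = TRUE)                   # invertibility
  expect_error(controlNormalizeLog(vals, c(x = 5, y = 0)), "y")

  # zero entries floored at half the smallest positive value, with warning
  withZero <- cbind(x = c(0, 4, 8))
  expect_warning(fl <- controlNormalizeLog(withZero, c(x = 4)), "floored")
  expect_equal(unname(fl[1, "x"]), log((4 / 2) / 4))
  expect_true(all(is.finite(fl)))
})

test_that("preprocessing yields a treated-only, finite, tagged dataset", {
  ch <- generateCohort(cohortConfig(seed = 3))
  ds <- preprocessCohort(ch)
  cases <- cohortCases(ch)
  expect_setequal(rownames(outcomeMatrix(ds)),
                  cases$case_id[cases$group != "CNTL"])
  expect_true(all(is.finite(predictorMatrix(ds))))
  cat <- variableCatalog(ds)
  expect_setequal(unique(cat$provenance), c("circulatory", "secreted"))
  # both timepoints offered as distinct candidates, LDL derived
  expect_true(all(c("TNFa_BAS", "TNFa_END", "LDL_BAS", "LDL_END") %in%
                  cat$name))
  expect_true(all(cat$timepoint[cat$provenance == "secreted"] == "n/a"))
  expect_error(preprocessCohort(
    methods::new("RawCohort",
      cases = cases[cases$group != "CNTL", ],
      plasma = cohortPlasma(ch)[cohortPlasma(ch)$case_id %in%
                                cases$case_id[cases$group != "CNTL"], ],
      proteins = cohortProteins(ch)[cases$group != "CNTL", ],
      histology = cohortHistology(ch))), "CNTL")
})

test_that("regression problems are filtered, cleaned and size-guarded", {
  ds <- preprocessCohort(generateCohort(cohortConfig(seed = 3)))
  pooled <- buildProblem(ds, "IT_mean", "pooled")
  expect_length(pooled@y, 10)         # 4 HF + 6 HHF treated cases
  hf <- buildProblem(ds, "LA_median", "HF")
  expect_length(hf@y, 4)
  # a constant predictor is dropped with a warning and p shrinks by one
  ds2 <- ds
  ds2@predictors[, "PROT01"] <- 0.5
  expect_warning(pr <- buildProblem(ds2, "IT_mean", "pooled"), "PROT01")
  expect_equal(ncol(pr@X), ncol(predictorMatrix(ds)) - 1)
  # fewer than 3 cases in the filter is refused
  dsSmall <- preprocessCohort(generateCohort(cohortConfig(nHhf = 2, seed = 4)))
  expect_error(buildProblem(dsSmall, "IT_mean", "HHF"), "at least 3")
})
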