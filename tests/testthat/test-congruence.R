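test_that("selection tables collect retained flags and coefficients", {
  ds <- preprocessCohort(generateCohort(cohortConfig(seed = 6)))
  res <- suppressMessages(runAllIndexes(ds))
  tab <- buildSelectionTable(res)
  expect_identical(colnames(selectedFlags(tab)),
                   c("IT_mean", "IT_median", "LA_mean", "LA_median"))
  for (idx in names(res)) {
    expect_setequal(rownames(selectedFlags(tab))[selectedFlags(tab)[, idx]],
                    retainedVariables(res[[idx]]))
    # selected cells carry the run's model-averaged coefficient
    sel <- selectedFlags(tab)[, idx]
    expect_equal(unname(selectionCoefficients(tab)[sel, idx]),
                 unname(avgCoefficient(res[[idx]])[names(which(sel))]))
  }
  expect_error(buildSelectionTable(res[1:3]), "missing index")
  # a never-retained variable still has a row
  expect_equal(nrow(selectedFlags(tab)), ncol(predictorMatrix(ds)))
})

test_that("stage 1 requires support from both index families", {
  cells <- data.frame(
    variable = c("itOnly", "itOnly", "laOnly", "both", "both", "all",
                 "all", "all", "all"),
    index = c("IT_mean", "IT_median", "LA_median", "IT_mean", "LA_mean",
              "IT_mean", "IT_median", "LA_mean", "LA_median"),
    coefficient = c(0.3, 0.2, 0.4, 0.4, 0.3, 0.1, 0.1, 0.1, 0.1))
  s1 <- applyIndexCongruence(makeSelectionTable(cells))
  pass <- setNames(s1$pass, s1$variable)
  expect_false(pass[["itOnly"]])
  expect_false(pass[["laOnly"]])
  expect_true(pass[["both"]])
  expect_true(pass[["all"]])
})

test_that("stage 2 sorts sign, magnitude and direction correctly", {
  cells <- data.frame(
    variable = c("pos", "pos", "neg", "neg", "flip", "flip",
                 "tiny", "tiny", "itOnly", "skew", "skew"),
    index = c("IT_mean", "LA_mean", "IT_median", "LA_median",
              "IT_mean", "LA_mean", "IT_mean", "LA_median",
              "IT_mean", "IT_mean", "LA_mean"),
    coefficient = c(0.4, 0.3, -0.4, -0.3, 0.5, -0.5,
                    0.0005, 0.0007, 0.9, 0.5, -0.01))
  tab <- makeSelectionTable(cells)
  led <- congruenceFilter(tab)
  tb <- ledgerTable(led)
  st <- setNames(tb$status, tb$variable)
  dr <- setNames(tb$direction, tb$variable)
  expect_equal(st[["pos"]], "retained");  expect_equal(dr[["pos"]], "positive")
  expect_equal(st[["neg"]], "retained");  expect_equal(dr[["neg"]], "negative")
  expect_equal(st[["flip"]], "discarded_sign")
  expect_equal(st[["tiny"]], "discarded_magnitude")
  expect_equal(st[["itOnly"]], "discarded_stage1")
  # strict default: opposite signs discard even at very different size
  expect_equal(st[["skew"]], "discarded_sign")
  # relaxed reading: dominant sign wins when sizes are not comparable
  relaxed <- ledgerTable(congruenceFilter(tab, strictSign = FALSE))
  rl <- setNames(relaxed$status, relaxed$variable)
  expect_equal(rl[["skew"]], "retained")
  expect_equal(relaxed$direction[relaxed$variable == "skew"], "positive")
  expect_equal(rl[["flip"]], "discarded_sign")  # comparable sizes still do
  # stage ordering: stage-1 rejects are never re-examined by stage 2
  expect_equal(st[["itOnly"]], "discarded_stage1")
  # determinism: the ledger is a pure function of table and thresholds
  expect_identical(ledgerTable(congruenceFilter(tab)), tb)
})

test_that("the bundled selection pattern reproduces the expected ledger", {
  led <- congruenceFilter(demoSelectionPattern())
  tb <- ledgerTable(led)
  ret <- tb[tb$status == "retained", ]
  expect_setequal(ret$variable[ret$direction == "positive"],
                  c("oxLDL", "HDL", "TNFa", "CATA", "CATD", "BGH3", "S10AA"))
  expect_identical(ret$variable[ret$direction == "negative"], "FABPH")
  expect_equal(tb$status[tb$variable == "IL6 BAS"], "discarded_stage1")
  expect_equal(tb$status[tb$variable == "ICAM-1 BAS"], "discarded_stage1")
  # retained variables always span both families with one common sign
  expect_true(validObject(led))
})

test_that("ledger summaries order retained-first by coefficient strength", {
  led <- congruenceFilter(demoSelectionPattern())
  rep <- summarizeLedger(led)
  expect_equal(unique(rep$status == "retained"), c(TRUE, FALSE))
  ret <- rep[rep$status == "retained", ]
  expect_true(all(diff(ret$max_abs_coef) <= 0))
  d <- file.path(tempdir(), "ledger-out")
  writeLedger(led, d)
  expect_true(file.exists(file.path(d, "ledger.csv")))
  expect_true(any(grepl("retained", readLines(file.path(d, "report.md")))))
  # degenerate outcomes: empty table summarizes without error
  emptyTab <- makeSelectionTable(data.frame(variable = character(0),
                                            index = character(0),
                                            coefficient = numeric(0)))
  expect_equal(nrow(ledgerTable(congruenceFilter(emptyTab))), 0)
})
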