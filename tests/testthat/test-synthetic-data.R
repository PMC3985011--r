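test_that("generated cohorts honour the shape contract", {
  cfg <- cohortConfig(nCntl = 3, nHf = 4, nHhf = 6, nProteins = 40, seed = 11)
  ch <- generateCohort(cfg)
  expect_equal(nrow(cohortCases(ch)), 13)
  expect_equal(as.vector(table(cohortCases(ch)$group)[c("CNTL", "HF", "HHF")]),
               c(3, 4, 6))
  # 7 measured analytes x 2 timepoints per case (LDL is derived downstream)
  expect_equal(nrow(cohortPlasma(ch)), 13 * 2 * 7)
  expect_equal(dim(cohortProteins(ch)), c(13, 40))
  expect_equal(nrow(cohortHistology(ch)), 13 * cfg$segments_per_case)
  expect_true(validObject(ch))
})

test_that("the cohort is a deterministic function of config and seed", {
  cfg <- cohortConfig(seed = 42)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generateCohort(cohortConfig(seed = 43))))

  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  writeCohort(a, d1); writeCohort(b, d2)
  for (f in c("cases.csv", "plasma.csv", "proteins.csv", "histology.csv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})

test_that("a noise-free single planted effect shows up exactly in log burden", {
  cfg <- cohortConfig(nProteins = 5, noiseSd = 0,
                      trueEffectMap = c(PROT01 = 1),
                      burdenIntercept = -4, seed = 5)
  ch <- generateCohort(cfg)
  idx <- aggregateHistology(cohortHistology(ch))
  rownames(idx) <- idx$case_id
  trt <- cohortCases(ch)$case_id[cohortCases(ch)$group != "CNTL"]
  lhs <- log(idx[trt, "it_mean"]) - log(cfg$baseline_intima_mm) + 4
  expect_equal(lhs, unname(log(cohortProteins(ch)[trt, "PROT01"])),
               tolerance = 1e-10)
  # controls sit exactly at the baseline intima when noise is zero
  ctl <- setdiff(idx$case_id, trt)
  expect_equal(idx[ctl, "it_mean"], rep(cfg$baseline_intima_mm, length(ctl)),
               tolerance = 1e-12)
})

test_that("noise-free planted effects are identifiable by OLS on the true set", {
  eff <- c(PROT01 = 1, PROT02 = 0.8, PROT03 = -0.8)
  cfg <- cohortConfig(nCntl = 4, nHf = 10, nHhf = 10, nProteins = 10,
                      noiseSd = 0, trueEffectMap = eff, seed = 9)
  ch <- generateCohort(cfg)
  # true predictor set: log raw abundances of the planted proteins
  trt <- cohortCases(ch)$case_id[cohortCases(ch)$group != "CNTL"]
  lx <- log(cohortProteins(ch)[trt, names(eff)])
  idx <- aggregateHistology(cohortHistology(ch))
  y <- log(idx$it_mean[match(trt, idx$case_id)])
  fit <- lm(y ~ lx)
  expect_equal(unname(coef(fit)[-1]), unname(eff), tolerance = 1e-8)
})

test_that("lesion profiles hit their target mean and separate by pattern", {
  prof <- generateLesionProfile(log(0.2), "localized", 9, seed = 1)
  expect_equal(mean(prof$it_mm), 0.2, tolerance = 1e-12)
  expect_equal(nrow(prof), 9)
  expect_true(all(prof$it_mm >= 0 & prof$la_mm2 >= 0))
  expect_error(generateLesionProfile(log(0.2), "localized", 2), "nSegments")

  # constant diffuse profile: zero jitter forces mean = median
  flat <- generateLesionProfile(log(0.3), "diffuse", 8, seed = 2, jitter = 0)
  expect_equal(median(flat$it_mm), mean(flat$it_mm), tolerance = 1e-12)

  # Monte-Carlo pattern contract: localized median/mean ratio below diffuse
  ratios <- vapply(1:500, function(s) {
    loc <- generateLesionProfile(log(0.2), "localized", 10, seed = s)
    dif <- generateLesionProfile(log(0.2), "diffuse", 10, seed = s + 1000)
    c(median(loc$it_mm) / mean(loc$it_mm),
      median(dif$it_mm) / mean(dif$it_mm))
  }, numeric(2))
  expect_lt(mean(ratios[1, ]), mean(ratios[2, ]))
  expect_lt(mean(ratios[1, ]), 0.65)   # localized: median well below mean
  expect_gt(mean(ratios[2, ]), 0.9)    # diffuse: median ~ mean
})

test_that("cohorts round-trip through the CSV files", {
  ch <- generateCohort(cohortConfig(nProteins = 7, seed = 21))
  d <- file.path(tempdir(), "roundtrip")
  writeCohort(ch, d)
  back <- readCohort(d)
  expect_identical(cohortCases(back), cohortCases(ch))
  expect_equal(cohortProteins(back), cohortProteins(ch), tolerance = 1e-12)
  expect_equal(cohortPlasma(back)$value, cohortPlasma(ch)$value,
               tolerance = 1e-12)
  expect_equal(cohortHistology(back)$it_mm, cohortHistology(ch)$it_mm,
               tolerance = 1e-12)

  # degenerate input: empty histology writes a header-only file
  empty <- ch
  empty@histology <- cohortHistology(ch)[0, ]
  d2 <- file.path(tempdir(), "roundtrip-empty")
  writeCohort(empty, d2)
  expect_equal(length(readLines(file.path(d2, "histology.csv"))), 1)
  expect_equal(nrow(cohortHistology(readCohort(d2))), 0)
})

test_that("invalid generator configurations are rejected", {
  expect_error(cohortConfig(nCntl = 0), "counts|CNTL")
  expect_error(cohortConfig(noiseSd = -1), "noise_sd")
  expect_error(cohortConfig(baselineIntimaMm = 0), "baseline_intima_mm")
  expect_error(cohortConfig(trueEffectMap = c(NOPE = 1)), "unknown variables")
  expect_error(cohortConfig(segmentsPerCase = 2), "segments_per_case")
})
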