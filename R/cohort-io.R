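#' @include generate-cohort.R
NULL

#' Write / read a cohort as plain CSV files
#'
#' `writeCohort()` persists a [RawCohort] as four UTF-8 CSV files with "."
#' decimal separator: \code{cases.csv} (case_id, group), \code{plasma.csv}
#' (case_id, timepoint, analyte, value), \code{proteins.csv} (case_id plus
#' one column per protein) and \code{histology.csv} (case_id, artery,
#' segment, it_mm, la_mm2).  `readCohort()` reads them back; numeric values
#' are written with 15 significant digits so the round trip reproduces the
#' cohort to within floating-point printing precision.
#'
#' @param cohort a [RawCohort].
#' @param directory target/source directory; created if missing.
#' @return `writeCohort()` the directory (invisibly); `readCohort()` a
#'   [RawCohort].
#' @examples
#' d <- file.path(tempdir(), "demo-cohort")
#' ch <- generateCohort(cohortConfig(seed = 3))
#' writeCohort(ch, d)
#' ch2 <- readCohort(d)
#' all.equal(cohortProteins(ch), cohortProteins(ch2))
#' @export
writeCohort <- function(cohort, directory) {
  stopifnot(methods::is(cohort, "RawCohort"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  wr <- function(df, file) {
    path <- file.path(directory, file)
    ok <- try(utils::write.csv(df, path, row.names = FALSE,
                               fileEncoding = "UTF-8"), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("failed to write ", path, ": ", attr(ok, "condition")$message)
  }
  wr(cohort@cases, "cases.csv")
  wr(cohort@plasma, "plasma.csv")
  prot <- data.frame(case_id = rownames(cohort@proteins),
                     cohort@proteins, check.names = FALSE,
                     stringsAsFactors = FALSE)
  wr(prot, "proteins.csv")
  wr(cohort@histology, "histology.csv")
  invisible(directory)
}

#' @rdname writeCohort
#' @export
readCohort <- function(directory) {
  rd <- function(file, colClasses = NA) {
    path <- file.path(directory, file)
    if (!file.exists(path)) stop("missing cohort file: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = colClasses)
  }
  cases <- rd("cases.csv")
  plasma <- rd("plasma.csv")
  protDf <- rd("proteins.csv")
  proteins <- as.matrix(protDf[, -1, drop = FALSE])
  rownames(proteins) <- protDf$case_id
  histology <- rd("histology.csv")
  if (!nrow(histology))   # header-only file: keep typed empty columns
    histology <- data.frame(case_id = character(0), artery = character(0),
                            segment = integer(0), it_mm = numeric(0),
                            la_mm2 = numeric(0))
  methods::new("RawCohort", cases = cases, plasma = plasma,
               proteins = proteins, histology = histology)
}
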