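#' @include cohort-io.R
NULL

#' Friedewald LDL calculation
#'
#' Computes low-density lipoprotein cholesterol from a standard lipid panel
#' under the mass-concentration (mg/dL) convention:
#' \code{LDL = TC - HDL - TG/5}.  The estimate is unreliable above 400 mg/dL
#' triglycerides (a warning is raised) and a negative result is returned as
#' \code{NA} with a warning rather than silently propagated.
#'
#' @param tc,hdl,tg total cholesterol, HDL cholesterol, triglycerides
#'   (mg/dL); vectors are recycled as usual.
#' @return numeric vector of LDL concentrations (mg/dL), \code{NA} where the
#'   formula yields a negative value.
#' @examples
#' friedewaldLDL(200, 50, 100)  # 130
#' @export
friedewaldLDL <- function(tc, hdl, tg) {
  if (any(c(tc, hdl, tg) < 0, na.rm = TRUE))
    stop("concentrations must be non-negative")
  if (any(tg > 400, na.rm = TRUE))
    warning("triglycerides > 400 mg/dL: Friedewald LDL unreliable")
  ldl <- tc - hdl - tg / 5
  neg <- !is.na(ldl) & ldl < 0
  if (any(neg)) {
    warning(sum(neg), " negative Friedewald LDL value(s) set to NA")
    ldl[neg] <- NA_real_
  }
  ldl
}

#' Total-protein normalization of an abundance matrix
#'
#' Rescales each case's protein profile so all row totals equal the grand
#' mean of the original row totals, compensating for differing amounts of
#' secreting artery tissue while preserving within-case proportions.  The
#' operation is idempotent.
#'
#' @param mat numeric matrix, cases x proteins, entries >= 0.
#' @return matrix of the same shape with equal row totals.
#' @examples
#' m <- rbind(a = c(40, 60), b = c(100, 200))
#' rowSums(normalizeTotalProtein(m))  # both 200
#' @export
normalizeTotalProtein <- function(mat) {
  if (any(mat < 0)) stop("abundances must be >= 0")
  totals <- rowSums(mat)
  zero <- totals == 0
  if (any(zero))
    stop("zero total protein for case(s): ",
         paste(rownames(mat)[zero], collapse = ", "))
  mat * (mean(totals) / totals)
}

#' Aggregate segment histology into per-case indexes
#'
#' Pools every lesion cross-section of a case across all sampled arteries
#' and computes the four histomorphometric outcome indexes: mean and median
#' intimal thickness (mm) and mean and median lesional area (mm^2).  Medians
#' use the midpoint convention for even counts.
#'
#' @param records data.frame of histology records (\code{case_id},
#'   \code{artery}, \code{segment}, \code{it_mm}, \code{la_mm2}).
#' @param caseId optional single case id; default aggregates every case
#'   present.
#' @return data.frame with columns \code{case_id}, \code{it_mean},
#'   \code{it_median}, \code{la_mean}, \code{la_median}.
#' @examples
#' h <- data.frame(case_id = "a", artery = "LAD", segment = 1:5,
#'                 it_mm = c(0.6, 0.1, 0.1, 0.1, 0.1),
#'                 la_mm2 = c(2.4, 0.4, 0.4, 0.4, 0.4))
#' aggregateHistology(h)   # it_mean 0.2, it_median 0.1
#' @export
aggregateHistology <- function(records, caseId = NULL) {
  ids <- if (is.null(caseId)) unique(records$case_id) else caseId
  rows <- lapply(ids, function(id) {
    rec <- records[records$case_id == id, , drop = FALSE]
    if (!nrow(rec))
      stop("no histology records for case ", id)
    data.frame(case_id = id,
               it_mean = mean(rec$it_mm), it_median = stats::median(rec$it_mm),
               la_mean = mean(rec$la_mm2), la_median = stats::median(rec$la_mm2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Control-normalized logarithmic transform
#'
#' The analysis scale for every dependent and independent variable: treated
#' values are divided by the average of the standard-diet CNTL cases and
#' natural-logged, \code{ln(value / control_mean)}, making all variables
#' dimensionless and a treated value equal to the control average map to 0.
#'
#' Zeros (possible for protein abundances) are floored at half the smallest
#' positive value of the same variable before the log, with a warning; the
#' transform is exactly invertible wherever no floor was applied.
#'
#' @param values numeric matrix, cases x variables (>= 0).
#' @param controlMeans named numeric vector of per-variable CNTL means;
#'   must be strictly positive and cover \code{colnames(values)}.
#' @param floorZeros floor zero entries (default) or raise an error on them.
#' @return matrix of the same shape on the control-normalized log scale.
#' @examples
#' controlNormalizeLog(cbind(x = c(5, 50)), c(x = 5))  # 0 and log(10)
#' @export
controlNormalizeLog <- function(values, controlMeans, floorZeros = TRUE) {
  values <- as.matrix(values)
  vars <- colnames(values)
  if (is.null(vars) || !all(vars %in% names(controlMeans)))
    stop("controlMeans must cover every column of values")
  cm <- controlMeans[vars]
  bad <- !is.finite(cm) | cm <= 0
  if (any(bad))
    stop("nonpositive control mean for variable(s): ",
         paste(vars[bad], collapse = ", "))
  if (any(values < 0)) stop("values must be >= 0")
  if (any(values == 0)) {
    if (!floorZeros) stop("zero values present and floorZeros = FALSE")
    floored <- character(0)
    for (j in seq_along(vars)) {
      z <- values[, j] == 0
      if (any(z)) {
        pos <- values[values[, j] > 0, j]
        if (!length(pos))
          stop("variable ", vars[j], " is identically zero")
        values[z, j] <- min(pos) / 2
        floored <- c(floored, vars[j])
      }
    }
    warning("zero values floored at half the smallest positive value for: ",
            paste(unique(floored), collapse = ", "))
  }
  sweep(log(values), 2, log(cm), "-")
}

#' Preprocess a raw cohort into the regression-ready dataset
#'
#' Runs the full preprocessing chain: derives Friedewald LDL from the lipid
#' panel (optional), applies total-protein normalization to the secretome
#' matrix, aggregates segment histology into the four per-case outcome
#' indexes, and places every outcome and candidate variable of the
#' diet-treated (HF, HHF) cases on the control-normalized natural-log scale.
#' Baseline and end-diet plasma measurements enter as distinct candidate
#' variables (\code{TNFa_BAS}, \code{TNFa_END}, ...), each normalized by the
#' CNTL mean at its own timepoint.
#'
#' @param cohort a [RawCohort].
#' @param computeLDL derive LDL via [friedewaldLDL()] and add it to the
#'   candidate panel (default TRUE).
#' @return a [ProcessedDataset].
#' @examples
#' ds <- preprocessCohort(generateCohort(cohortConfig(seed = 1)))
#' ds
#' @export
preprocessCohort <- function(cohort, computeLDL = TRUE) {
  stopifnot(methods::is(cohort, "RawCohort"))
  cases <- cohort@cases
  ctl <- cases$case_id[cases$group == "CNTL"]
  trt <- cases$case_id[cases$group != "CNTL"]
  if (!length(ctl))
    stop("no CNTL cases: control normalization is undefined")
  if (!length(trt))
    stop("no treated (HF/HHF) cases to analyze")

  # --- plasma wide, one column per analyte x timepoint -------------------
  pl <- cohort@plasma
  analytes <- sort(unique(pl$analyte))
  plasmaWide <- matrix(NA_real_, nrow(cases), 2 * length(analytes),
                       dimnames = list(cases$case_id,
                         paste0(rep(analytes, each = 2), "_", c("BAS", "END"))))
  for (a in analytes) for (tp in c("BAS", "END")) {
    sub <- pl[pl$analyte == a & pl$timepoint == tp, ]
    plasmaWide[sub$case_id, paste0(a, "_", tp)] <- sub$value
  }
  if (computeLDL && all(c("TC", "HDL", "TG") %in% analytes)) {
    for (tp in c("BAS", "END")) {
      ldl <- friedewaldLDL(plasmaWide[, paste0("TC_", tp)],
                           plasmaWide[, paste0("HDL_", tp)],
                           plasmaWide[, paste0("TG_", tp)])
      if (anyNA(ldl)) {
        pos <- ldl[!is.na(ldl) & ldl > 0]
        if (!length(pos)) {
          warning("dropping LDL_", tp, ": no positive Friedewald values")
          next
        }
        warning("invalid Friedewald LDL_", tp,
                " floored at half the smallest positive value")
        ldl[is.na(ldl)] <- min(pos) / 2
      }
      plasmaWide <- cbind(plasmaWide, ldl)
      colnames(plasmaWide)[ncol(plasmaWide)] <- paste0("LDL_", tp)
    }
  }

  # --- secretome ---------------------------------------------------------
  prot <- normalizeTotalProtein(cohort@proteins[cases$case_id, , drop = FALSE])

  # --- histology outcome indexes ----------------------------------------
  idx <- aggregateHistology(cohort@histology)
  rownames(idx) <- idx$case_id
  outMat <- as.matrix(idx[cases$case_id,
                          c("it_mean", "it_median", "la_mean", "la_median")])
  colnames(outMat) <- outcomeIndexNames()

  # --- control-normalized log scale -------------------------------------
  cmPlasma <- colMeans(plasmaWide[ctl, , drop = FALSE])
  cmProt <- colMeans(prot[ctl, , drop = FALSE])
  cmOut <- colMeans(outMat[ctl, , drop = FALSE])
  predictors <- cbind(
    controlNormalizeLog(plasmaWide[trt, , drop = FALSE], cmPlasma),
    controlNormalizeLog(prot[trt, , drop = FALSE], cmProt)
  )
  outcomes <- controlNormalizeLog(outMat[trt, , drop = FALSE], cmOut)

  catalog <- data.frame(
    name = colnames(predictors),
    provenance = c(rep("circulatory", ncol(plasmaWide)),
                   rep("secreted", ncol(prot))),
    timepoint = c(sub("^.*_", "", colnames(plasmaWide)),
                  rep("n/a", ncol(prot))),
    stringsAsFactors = FALSE
  )
  groups <- stats::setNames(cases$group[match(trt, cases$case_id)], trt)

  methods::new("ProcessedDataset",
    outcomes = outcomes, predictors = predictors, catalog = catalog,
    groups = groups,
    controlMeans = list(plasma = cmPlasma, proteins = cmProt,
                        outcomes = cmOut))
}

#' Write a processed dataset and its variable catalog
#'
#' Emits \code{processed_dataset.csv} (case_id, group, the four outcome
#' indexes, then one column per candidate variable, all on the
#' control-normalized log scale) and \code{variables.csv} (name, provenance,
#' timepoint).
#'
#' @param dataset a [ProcessedDataset].
#' @param directory output directory, created if missing.
#' @return the directory, invisibly.
#' @export
writeProcessedDataset <- function(dataset, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  df <- data.frame(case_id = rownames(dataset@outcomes),
                   group = dataset@groups[rownames(dataset@outcomes)],
                   dataset@outcomes, dataset@predictors,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, file.path(directory, "processed_dataset.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset@catalog, file.path(directory, "variables.csv"),
                   row.names = FALSE)
  invisible(directory)
}
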