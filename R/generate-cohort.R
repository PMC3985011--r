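#' @include lesion-profile.R
NULL

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a seed-reproducible synthetic cohort
#'
#' Draws a full [RawCohort] under the statistical structure described in
#' [cohortConfig()]: lognormal plasma analytes at baseline and end of diet
#' (with group-specific fold changes for the diet-treated groups and a
#' structural total cholesterol \code{TC = HDL + LDL + TG/5}), a lognormal
#' case x protein secretome matrix, and segment-level histology whose
#' per-case log lesion burden is the planted sparse linear model
#' \code{intercept + sum_j effect_j log(x_j) + N(0, noise_sd)}.
#'
#' The cohort is a deterministic function of the configuration (including
#' its seed): two calls with the same config are identical.
#'
#' @param config a [cohortConfig()] object.
#' @return a [RawCohort].
#' @examples
#' ch <- generateCohort(cohortConfig(seed = 1))
#' ch
#' @export
generateCohort <- function(config) {
  validateCohortConfig(config)
  withSeed(config$seed, .generateCohortImpl(config))
}

.generateCohortImpl <- function(cfg) {
  groups <- c(rep("CNTL", cfg$n_cntl), rep("HF", cfg$n_hf),
              rep("HHF", cfg$n_hhf))
  ids <- character(length(groups))
  for (g in unique(groups))
    ids[groups == g] <- sprintf("%s%02d", g, seq_len(sum(groups == g)))
  treated <- groups != "CNTL"
  nCase <- length(ids)

  # --- plasma: draw HDL, TG, LDL, oxLDL, IL6, TNFa, ICAM1; derive TC ------
  base <- .plasmaBaselines()
  drawn <- names(base)
  bas <- sapply(drawn, function(a)
    base[[a]] * exp(stats::rnorm(nCase, 0, cfg$plasma_logsd)))
  rownames(bas) <- ids
  folds <- rep(1, length(drawn)); names(folds) <- drawn
  hit <- intersect(names(cfg$diet_fold_changes), drawn)
  folds[hit] <- cfg$diet_fold_changes[hit]
  fold <- outer(ifelse(treated, 1, 0), log(folds))   # treated rows get log-fold
  end <- bas * exp(fold + stats::rnorm(nCase * length(drawn), 0,
                                       cfg$plasma_logsd / 2))
  addTC <- function(m) cbind(m, TC = m[, "HDL"] + m[, "LDL"] + m[, "TG"] / 5)
  bas <- addTC(bas); end <- addTC(end)

  keepAnalytes <- .plasmaAnalytes()                  # TC kept, LDL left derived
  plasma <- rbind(
    data.frame(case_id = rep(ids, length(keepAnalytes)), timepoint = "BAS",
               analyte = rep(keepAnalytes, each = nCase),
               value = as.vector(bas[, keepAnalytes])),
    data.frame(case_id = rep(ids, length(keepAnalytes)), timepoint = "END",
               analyte = rep(keepAnalytes, each = nCase),
               value = as.vector(end[, keepAnalytes]))
  )

  # --- secretome --------------------------------------------------------
  protNames <- .proteinNames(cfg$n_proteins)
  proteins <- matrix(
    stats::rlnorm(nCase * cfg$n_proteins, cfg$abundance_logmean,
                  cfg$abundance_logsd),
    nrow = nCase, dimnames = list(ids, protNames))

  # --- planted burden model ---------------------------------------------
  valueOf <- function(v) {
    if (v %in% protNames) return(proteins[, v])
    a <- sub("_(BAS|END)$", "", v)
    tp <- sub("^.*_", "", v)
    if (tp == "BAS") bas[, a] else end[, a]
  }
  eff <- cfg$true_effect_map
  contrib <- if (length(eff)) {
    rowSums(sapply(names(eff), function(v) eff[[v]] * log(valueOf(v))))
  } else rep(0, nCase)
  intercept <- cfg$burden_intercept
  if (is.null(intercept)) {
    # centre planted contribution at its treated-group expectation, then
    # shift so treated lesions average ~4x baseline intima
    expLog <- vapply(names(eff), function(v) {
      if (v %in% protNames) return(cfg$abundance_logmean)
      a <- sub("_(BAS|END)$", "", v)
      tp <- sub("^.*_", "", v)
      f <- if (tp == "END" && a %in% names(folds)) log(folds[[a]]) else 0
      if (a == "TC") {
        b <- .plasmaBaselines()
        log(b[["HDL"]] + b[["LDL"]] + b[["TG"]] / 5) + f
      } else log(.plasmaBaselines()[[a]]) + f
    }, numeric(1))
    intercept <- log(4) - if (length(eff)) sum(eff * expLog) else 0
  }
  burden <- ifelse(treated, intercept + contrib, 0) +
    stats::rnorm(nCase, 0, cfg$noise_sd)
  logMeanIT <- log(cfg$baseline_intima_mm) + burden

  # --- histology --------------------------------------------------------
  histology <- do.call(rbind, lapply(seq_len(nCase), function(i)
    generateLesionProfile(
      caseBurden = logMeanIT[i],
      pattern = cfg$lesion_pattern[[groups[i]]],
      nSegments = cfg$segments_per_case,
      caseId = ids[i], jitter = cfg$profile_jitter,
      laPerIt = cfg$la_per_it)))

  methods::new("RawCohort",
    cases = data.frame(case_id = ids, group = groups,
                       stringsAsFactors = FALSE),
    plasma = plasma, proteins = proteins, histology = histology)
}
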