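#' @include AllClasses.R
NULL

# Measured plasma analytes and their baseline geometric-median
# concentrations.  TC is derived structurally (TC = HDL + LDL + TG/5) so the
# Friedewald calculation downstream recovers the generated LDL exactly.
.plasmaAnalytes <- function() c("TC", "HDL", "TG", "oxLDL", "IL6", "TNFa", "ICAM1")

.plasmaBaselines <- function() {
  # mg/dL for lipids, U/L for oxLDL, pg/mL for cytokines, ng/mL for ICAM-1;
  # typical farm-pig values on standard diet
  c(HDL = 40, TG = 40, LDL = 35, oxLDL = 50, IL6 = 20, TNFa = 30, ICAM1 = 250)
}

.defaultDietFolds <- function() {
  # multiplicative end-diet shifts for high-cholesterol/high-fat groups
  c(LDL = 5, HDL = 1.2, TG = 1.5, oxLDL = 3, IL6 = 2, TNFa = 2, ICAM1 = 1.5)
}

.proteinNames <- function(n) sprintf("PROT%0*d", max(2L, nchar(n)), seq_len(n))

#' Synthetic cohort generator configuration
#'
#' Assembles and validates the configuration for [generateCohort()].  The
#' generator emulates a diet-induced swine coronary atherogenesis study:
#' CNTL cases on standard diet, HF and HHF cases on a high-cholesterol
#' high-fat diet for a shorter and a longer period, a two-timepoint plasma
#' panel (total cholesterol, HDL, triglycerides, oxLDL, IL-6, TNFa, ICAM-1;
#' LDL is left to the Friedewald calculation downstream), a lognormal
#' artery-secretome abundance matrix, and segment-level coronary histology
#' whose per-case log lesion burden follows a sparse linear model in the log
#' values of designated variables.
#'
#' Case-level true log lesion burden is
#' \code{intercept + sum_j effect_j * log(x_j) + N(0, noiseSd)}, where the
#' \code{x_j} are the raw generated values of the variables named in
#' \code{trueEffectMap} (plasma variables as \code{"<analyte>_BAS"} /
#' \code{"<analyte>_END"}, proteins by column name).  Per-case mean intimal
#' thickness is \code{baselineIntimaMm * exp(burden)}; CNTL cases carry
#' burden \code{N(0, noiseSd)} around the baseline so control normalization
#' is always defined.
#'
#' @param nCntl,nHf,nHhf case counts per diet group (defaults 3/4/6).
#' @param nProteins number of secreted proteins (default 40).
#' @param trueEffectMap named numeric vector of planted signed effects on the
#'   log-log scale; names must be generated variables.  Default plants a
#'   positive oxLDL end-diet effect, a positive baseline TNFa effect and
#'   three protein effects.  Use \code{numeric(0)} for an all-noise cohort.
#' @param noiseSd standard deviation of the Gaussian noise on log burden.
#' @param segmentsPerCase histology cross-sections per case (>= 3).
#' @param lesionPattern named character vector group -> \code{"localized"}
#'   or \code{"diffuse"}; the default gives HF cases localized lesions and
#'   HHF diffuse ones, so mean and median IT diverge for HF.
#' @param dietFoldChanges named numeric vector analyte -> multiplicative
#'   end-diet factor applied to HF and HHF cases.
#' @param abundanceLogmean,abundanceLogsd lognormal parameters of protein
#'   abundances (natural-log scale).
#' @param plasmaLogsd between-case lognormal sd of plasma analytes.
#' @param baselineIntimaMm strictly positive control intimal thickness (mm).
#' @param burdenIntercept intercept of the burden model, or \code{NULL}
#'   (default) to auto-centre the planted contribution and add \code{log(4)}
#'   so treated lesions average about four times the control intima.
#' @param profileJitter within-case lognormal jitter of segment IT values.
#' @param laPerIt lesional area per unit intimal thickness (mm); segment LA
#'   is \code{laPerIt * IT} times a small jitter.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#'
#' @return a validated list of class \code{"CohortConfig"}.
#' @seealso [generateCohort()]
#' @examples
#' cfg <- cohortConfig(seed = 7)
#' cfg$n_cntl
#' @export
cohortConfig <- function(nCntl = 3, nHf = 4, nHhf = 6,
                         nProteins = 40,
                         trueEffectMap = NULL,
                         noiseSd = 0.3,
                         segmentsPerCase = 10,
                         lesionPattern = c(CNTL = "diffuse", HF = "localized",
                                           HHF = "diffuse"),
                         dietFoldChanges = .defaultDietFolds(),
                         abundanceLogmean = 4, abundanceLogsd = 0.5,
                         plasmaLogsd = 0.2,
                         baselineIntimaMm = 0.05,
                         burdenIntercept = NULL,
                         profileJitter = 0.15,
                         laPerIt = 4,
                         seed = 1L) {
  if (is.null(trueEffectMap)) {
    prot <- .proteinNames(nProteins)
    trueEffectMap <- c(oxLDL_END = 1.0, TNFa_BAS = 0.6)
    np <- min(3L, nProteins)
    eff <- c(1.0, 0.8, -0.8)[seq_len(np)]
    names(eff) <- prot[seq_len(np)]
    trueEffectMap <- c(trueEffectMap, eff)
  }
  cfg <- list(
    n_cntl = as.integer(nCntl), n_hf = as.integer(nHf),
    n_hhf = as.integer(nHhf), n_proteins = as.integer(nProteins),
    true_effect_map = trueEffectMap, noise_sd = noiseSd,
    segments_per_case = as.integer(segmentsPerCase),
    lesion_pattern = lesionPattern,
    diet_fold_changes = dietFoldChanges,
    abundance_logmean = abundanceLogmean, abundance_logsd = abundanceLogsd,
    plasma_logsd = plasmaLogsd,
    baseline_intima_mm = baselineIntimaMm,
    burden_intercept = burdenIntercept,
    profile_jitter = profileJitter, la_per_it = laPerIt,
    seed = as.integer(seed)
  )
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  stopifnot(inherits(cfg, "CohortConfig"))
  counts <- c(cfg$n_cntl, cfg$n_hf, cfg$n_hhf, cfg$n_proteins,
              cfg$segments_per_case)
  if (any(counts < 1L))
    stop("all counts must be >= 1 (a CNTL group is required: control ",
         "normalization is undefined without it)")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$baseline_intima_mm <= 0)
    stop("baseline_intima_mm must be > 0 so CNTL means are nonzero")
  if (cfg$segments_per_case < 3)
    stop("segments_per_case must be >= 3")
  if (!all(c("CNTL", "HF", "HHF") %in% names(cfg$lesion_pattern)))
    stop("lesion_pattern must name CNTL, HF and HHF")
  if (!all(cfg$lesion_pattern %in% c("localized", "diffuse")))
    stop("lesion_pattern values must be 'localized' or 'diffuse'")
  known <- generatedVariableNames(cfg)
  bad <- setdiff(names(cfg$true_effect_map), known)
  if (length(bad))
    stop("true_effect_map names unknown variables: ",
         paste(bad, collapse = ", "))
  badf <- setdiff(names(cfg$diet_fold_changes),
                  c(.plasmaAnalytes(), "LDL"))
  if (length(badf))
    stop("diet_fold_changes names unknown analytes: ",
         paste(badf, collapse = ", "))
  invisible(cfg)
}

#' Names of the variables a configuration generates
#'
#' Plasma variables are tagged by timepoint (\code{"TC_BAS"},
#' \code{"TC_END"}, ...); the derived LDL is included because the
#' generator's structural total cholesterol makes the Friedewald LDL an
#' exact generated quantity.
#'
#' @param cfg a [cohortConfig()] object.
#' @return character vector of variable names usable in
#'   \code{trueEffectMap}.
#' @export
generatedVariableNames <- function(cfg) {
  an <- c(.plasmaAnalytes(), "LDL")
  c(paste0(rep(an, each = 2), "_", c("BAS", "END")),
    .proteinNames(cfg$n_proteins))
}

#' @export
print.CohortConfig <- function(x, ...) {
  cat("CohortConfig:", x$n_cntl, "CNTL +", x$n_hf, "HF +", x$n_hhf,
      "HHF cases;", x$n_proteins, "proteins;",
      length(x$true_effect_map), "planted effects; seed", x$seed, "\n")
  invisible(x)
}
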