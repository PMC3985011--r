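#' @include congruence.R
NULL

#' Bundled demonstration selection pattern
#'
#' A ready-made [SelectionTable] over circulating lipid/inflammatory
#' factors (oxLDL, HDL, TNFa, ICAM-1, IL-6) and artery-secreted proteins
#' (catalase CATA, cathepsin D CATD, TGF-beta-induced ig-h3 BGH3, S100-A10
#' S10AA, FABPH, G3P, CPNS1, ANXA4, PPCE), reproducing the per-index
#' selection pattern reported for a pooled high-cholesterol-diet swine
#' coronary atherogenesis cohort.  The selection cells follow the reported
#' pattern; the coefficient values are SYNTHETIC stand-ins (the underlying
#' per-index coefficients were never deposited), chosen so the two-stage
#' congruence filter exercises every verdict class: the eight reported
#' variables come out retained (FABPH with a negative direction, all others
#' positive), IL6 BAS and both ICAM-1 timepoints fall at stage 1, G3P,
#' ANXA4 and PPCE on sign incongruence, CPNS1 below the magnitude floor.
#'
#' The raw cells ship as \code{extdata/selection_pattern_synthetic.csv}
#' (variable, index, coefficient; one row per selected cell).
#'
#' @return a [SelectionTable].
#' @examples
#' ledgerTable(congruenceFilter(demoSelectionPattern()))
#' @export
demoSelectionPattern <- function() {
  path <- system.file("extdata", "selection_pattern_synthetic.csv",
                      package = "atheroBMA", mustWork = TRUE)
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  vars <- unique(cells$variable)
  idx <- outcomeIndexNames()
  sel <- matrix(FALSE, length(vars), 4, dimnames = list(vars, idx))
  coef <- matrix(NA_real_, length(vars), 4, dimnames = list(vars, idx))
  for (i in seq_len(nrow(cells))) {
    sel[cells$variable[i], cells$index[i]] <- TRUE
    coef[cells$variable[i], cells$index[i]] <- cells$coefficient[i]
  }
  methods::new("SelectionTable", selected = sel, coefficients = coef)
}
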