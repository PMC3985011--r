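#' @include cohort-config.R
NULL

#' Generate a per-case lesion IT/LA segment profile
#'
#' Draws a coronary lesion profile over \code{nSegments} consecutive
#' cross-sections whose per-case mean intimal thickness equals
#' \code{exp(caseBurden)} exactly (the profile weights are renormalized to
#' mean one).  Two spatial patterns are supported, mirroring the two lesion
#' distributions seen along real coronary arteries:
#' \describe{
#'   \item{\code{"localized"}}{lesion mass concentrated in the proximal
#'     \code{max(1, floor(nSegments/3))} segments, the rest carrying
#'     \code{coldFraction} of the hot thickness.  The per-case median IT is
#'     then roughly half the mean.}
#'   \item{\code{"diffuse"}}{lesion mass spread uniformly (up to jitter), so
#'     median and mean IT nearly coincide.}
#' }
#' Segment lesional area is \code{laPerIt * IT} times a small lognormal
#' jitter.
#'
#' @param caseBurden log-scale severity; the target mean IT is
#'   \code{exp(caseBurden)} mm.
#' @param pattern \code{"localized"} or \code{"diffuse"}.
#' @param nSegments number of cross-sections (>= 3).
#' @param seed optional integer; when supplied the draw is seeded locally,
#'   otherwise the current RNG stream is used.
#' @param caseId,artery labels written into the records.
#' @param coldFraction thickness of unaffected segments relative to hot
#'   ones in the localized pattern.
#' @param jitter lognormal sd of within-profile segment variation.
#' @param laPerIt lesional area (mm^2) per mm of intimal thickness.
#'
#' @return data.frame of histology records: \code{case_id}, \code{artery},
#'   \code{segment}, \code{it_mm}, \code{la_mm2}.
#' @examples
#' prof <- generateLesionProfile(log(0.2), "localized", 9, seed = 1)
#' mean(prof$it_mm)            # 0.2 exactly
#' median(prof$it_mm) / mean(prof$it_mm)  # about one half
#' @export
generateLesionProfile <- function(caseBurden, pattern = c("localized", "diffuse"),
                                  nSegments, seed = NULL,
                                  caseId = "case", artery = "LAD",
                                  coldFraction = 0.25, jitter = 0.15,
                                  laPerIt = 4) {
  pattern <- match.arg(pattern)
  if (nSegments < 3) stop("nSegments must be >= 3")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  targetMean <- exp(caseBurden)
  base <- if (pattern == "localized") {
    nHot <- max(1L, nSegments %/% 3L)
    c(rep(1, nHot), rep(coldFraction, nSegments - nHot))
  } else {
    rep(1, nSegments)
  }
  w <- base * exp(stats::rnorm(nSegments, 0, jitter))
  w <- w / mean(w)                       # per-case mean IT is exact
  it <- targetMean * w
  la <- laPerIt * it * exp(stats::rnorm(nSegments, 0, jitter / 2))
  data.frame(
    case_id = caseId, artery = artery, segment = seq_len(nSegments),
    it_mm = it, la_mm2 = la, stringsAsFactors = FALSE
  )
}
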