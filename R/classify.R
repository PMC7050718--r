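#' Scenario category levels
#'
#' The mutually exclusive targeting categories a child can fall into under an
#' expanded MUAC-only admission policy, relative to the WHO case definitions.
#' @export
scenario_levels <- c("EXCLUDED_SAM", "UNDERESTIMATED_SAM", "IGNORED_RISK_SAM",
                     "CORRECTLY_DETECTED_SAM", "EXCLUDED_MAM", "INCLUDED_MAM",
                     "NOT_A_CASE")

#' Apply WHO acute-malnutrition case definitions
#'
#' Evaluates the standard MUAC- and WHZ-based case definitions for each child:
#' \itemize{
#'   \item SAM by MUAC: MUAC < 115 mm and/or oedema;
#'   \item MAM by MUAC: 115 mm <= MUAC < 125 mm and no oedema;
#'   \item SAM by WHZ: WHZ < -3; MAM by WHZ: -3 <= WHZ < -2;
#'   \item SAM by any criterion (`sam_all`): MUAC < 115 mm, WHZ < -3 or oedema;
#'   \item MAM by any criterion (`mam_all`): MAM by MUAC or by WHZ, *and not*
#'     SAM by any criterion — a child meeting both a SAM and a MAM criterion
#'     counts as SAM only, so SAM and MAM are disjoint and GAM = SAM + MAM.
#' }
#'
#' @param whz Numeric vector of weight-for-height z-scores.
#' @param muac_mm Numeric vector of MUAC in mm (positive).
#' @param oedema Logical vector.
#' @return Data frame of logical columns `sam_muac`, `mam_muac`, `sam_whz`,
#'   `mam_whz`, `oedema`, `sam_all`, `mam_all`, `gam`.
#' @export
classify_case <- function(whz, muac_mm, oedema) {
  n <- max(length(whz), length(muac_mm), length(oedema))
  whz <- rep_len(as.numeric(whz), n)
  muac_mm <- rep_len(as.numeric(muac_mm), n)
  oedema <- rep_len(as.logical(oedema), n)
  if (anyNA(whz) || anyNA(muac_mm) || anyNA(oedema)) {
    stop("classify_case: whz, muac_mm and oedema must all be defined",
         call. = FALSE)
  }
  if (any(muac_mm <= 0)) {
    stop("classify_case: muac_mm must be positive", call. = FALSE)
  }
  sam_muac <- muac_mm < 115 | oedema
  mam_muac <- muac_mm >= 115 & muac_mm < 125 & !oedema
  sam_whz <- whz < -3
  mam_whz <- whz >= -3 & whz < -2
  sam_all <- sam_muac | sam_whz | oedema
  mam_all <- (mam_muac | mam_whz) & !sam_all
  data.frame(sam_muac = sam_muac, mam_muac = mam_muac, sam_whz = sam_whz,
             mam_whz = mam_whz, oedema = oedema, sam_all = sam_all,
             mam_all = mam_all, gam = sam_all | mam_all)
}

#' Assign the expanded MUAC-only targeting scenario category
#'
#' Places each acutely malnourished child into exactly one category describing
#' its fate under a program that screens and admits on MUAC < 125 mm or oedema
#' alone:
#' \describe{
#'   \item{EXCLUDED_SAM}{WHZ < -3, MUAC >= 125 mm, no oedema — a severe case
#'     the program never sees.}
#'   \item{UNDERESTIMATED_SAM}{WHZ < -3, 115 <= MUAC < 125 mm, no oedema —
#'     admitted but managed as moderate.}
#'   \item{IGNORED_RISK_SAM}{WHZ < -3 together with MUAC < 115 mm or oedema —
#'     admitted as severe, but the concurrent weight-for-height deficit (a
#'     marker of elevated mortality risk) goes unmeasured.}
#'   \item{CORRECTLY_DETECTED_SAM}{MUAC < 115 mm and/or oedema with
#'     WHZ >= -3 — classified exactly as WHO guidance would.}
#'   \item{EXCLUDED_MAM / INCLUDED_MAM}{moderate cases with MUAC >= 125 mm
#'     (missed) vs 115 <= MUAC < 125 mm (enrolled).}
#'   \item{NOT_A_CASE}{neither SAM nor MAM by any criterion.}
#' }
#' The four SAM categories partition the SAM-by-any-criterion children and the
#' two MAM categories partition the MAM children.
#'
#' @inheritParams classify_case
#' @return Factor with levels [scenario_levels].
#' @export
assign_scenario_category <- function(whz, muac_mm, oedema) {
  profile <- classify_case(whz, muac_mm, oedema)
  n <- nrow(profile)
  whz <- rep_len(as.numeric(whz), n)
  muac_mm <- rep_len(as.numeric(muac_mm), n)
  oedema <- rep_len(as.logical(oedema), n)
  low_muac <- muac_mm < 115 | oedema
  cat <- rep("NOT_A_CASE", n)
  sam <- profile$sam_all
  cat[sam & low_muac & whz < -3] <- "IGNORED_RISK_SAM"
  cat[sam & low_muac & whz >= -3] <- "CORRECTLY_DETECTED_SAM"
  cat[sam & !low_muac & whz < -3 & muac_mm < 125] <- "UNDERESTIMATED_SAM"
  cat[sam & !low_muac & whz < -3 & muac_mm >= 125] <- "EXCLUDED_SAM"
  mam <- profile$mam_all
  cat[mam & muac_mm < 125] <- "INCLUDED_MAM"
  cat[mam & muac_mm >= 125] <- "EXCLUDED_MAM"
  factor(cat, levels = scenario_levels)
}

#' Expanded MUAC-only program enrolment
#'
#' Whether a child would be enrolled by a program admitting on
#' MUAC < 125 mm or oedema alone, and at which severity tier
#' (SEVERE: MUAC < 115 mm or oedema; MODERATE otherwise). The 125 mm boundary
#' itself is not enrolled, mirroring the half-open moderate interval
#' 115 <= MUAC < 125 mm.
#'
#' @inheritParams classify_case
#' @return Data frame with logical `enrolled` and factor `tier`
#'   (`SEVERE`/`MODERATE`, `NA` when not enrolled).
#' @export
in_muac_only_program <- function(muac_mm, oedema) {
  n <- max(length(muac_mm), length(oedema))
  muac_mm <- rep_len(as.numeric(muac_mm), n)
  oedema <- rep_len(as.logical(oedema), n)
  if (anyNA(muac_mm) || anyNA(oedema)) {
    stop("in_muac_only_program: muac_mm and oedema must be defined",
         call. = FALSE)
  }
  if (any(muac_mm <= 0)) {
    stop("in_muac_only_program: muac_mm must be positive", call. = FALSE)
  }
  enrolled <- muac_mm < 125 | oedema
  tier <- ifelse(!enrolled, NA_character_,
                 ifelse(muac_mm < 115 | oedema, "SEVERE", "MODERATE"))
  data.frame(enrolled = enrolled,
             tier = factor(tier, levels = c("SEVERE", "MODERATE")))
}

#' Classify cleaned survey records
#'
#' Convenience wrapper running [classify_case()], [assign_scenario_category()]
#' and [in_muac_only_program()] over a cleaned survey table. Children excluded
#' during cleaning receive `NA` in every classification column; they take no
#' part in any downstream tally.
#'
#' @param cleaned Output of [clean_records()].
#' @return `cleaned` with columns `sam_muac`, `mam_muac`, `sam_whz`,
#'   `mam_whz`, `sam_all`, `mam_all`, `gam`, `scenario_category`,
#'   `program_enrolled`, `program_tier` appended.
#' @export
classify_children <- function(cleaned) {
  stopifnot(all(c("whz", "exclusion_reason") %in% names(cleaned)))
  n <- nrow(cleaned)
  keep <- which(cleaned$exclusion_reason == "none")
  prof_cols <- c("sam_muac", "mam_muac", "sam_whz", "mam_whz", "sam_all",
                 "mam_all", "gam")
  for (col in prof_cols) cleaned[[col]] <- rep(NA, n)
  cleaned$scenario_category <- factor(rep(NA_character_, n),
                                      levels = scenario_levels)
  cleaned$program_enrolled <- rep(NA, n)
  cleaned$program_tier <- factor(rep(NA_character_, n),
                                 levels = c("SEVERE", "MODERATE"))
  if (length(keep) > 0) {
    prof <- classify_case(cleaned$whz[keep], cleaned$muac_mm[keep],
                          cleaned$oedema[keep])
    for (col in prof_cols) cleaned[[col]][keep] <- prof[[col]]
    cleaned$scenario_category[keep] <- assign_scenario_category(
      cleaned$whz[keep], cleaned$muac_mm[keep], cleaned$oedema[keep])
    prog <- in_muac_only_program(cleaned$muac_mm[keep], cleaned$oedema[keep])
    cleaned$program_enrolled[keep] <- prog$enrolled
    cleaned$program_tier[keep] <- prog$tier
  }
  cleaned
}
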