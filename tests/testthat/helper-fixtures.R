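# Small LMS grids and child rosters built in code for the unit tests.

# three-point single-sex grid with easy round numbers
tiny_reference <- function() {
  as_growth_reference(data.frame(
    sex = "f",
    height_cm = c(65.0, 65.1, 65.2),
    L = 1, M = c(7.0, 7.1, 7.2), S = 0.08))
}

# one-row constant-coefficient table: closed forms are hand-computable
flat_reference <- function(L = 1, M = 10, S = 0.1, sex = "f") {
  as_growth_reference(data.frame(
    sex = sex, height_cm = c(60, 120), L = L, M = M, S = S))
}

# a complete, in-range child record; override fields as needed
make_child <- function(..., n = 1) {
  # weight ~ -0.6 z at 85 cm on the synthetic reference: a healthy child
  base <- data.frame(survey_id = "S1", cluster_id = 1, age_months = 24,
                     sex = "f", weight_kg = 11.8, height_cm = 85,
                     muac_mm = 140, oedema = FALSE)
  base <- base[rep(1, n), , drop = FALSE]
  rownames(base) <- NULL
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# classified roster built directly from (whz, muac, oedema) triplets
classified_roster <- function(whz, muac, oedema = FALSE, sex = "f",
                              age = 24, survey_id = "S1") {
  n <- max(length(whz), length(muac), length(oedema))
  df <- make_child(n = n)
  df$survey_id <- survey_id
  df$age_months <- rep_len(age, n)
  df$sex <- rep_len(sex, n)
  df$muac_mm <- rep_len(muac, n)
  df$oedema <- rep_len(oedema, n)
  df$whz <- rep_len(whz, n)
  df$exclusion_reason <- factor("none", levels = c(
    "none", "missing_field", "age_out_of_range", "whz_flag"))
  classify_children(df)
}

# brute-force scenario truth table, transcribed clause by clause from the
# category definitions; deliberately independent of the package's decision
# order
scenario_oracle <- function(whz, muac, oedema) {
  mapply(function(z, m, oe) {
    sam <- (m < 115) || oe || (z < -3)
    mam <- !sam && ((m >= 115 && m < 125) || (z >= -3 && z < -2))
    if (z < -3 && m >= 125 && !oe) return("EXCLUDED_SAM")
    if (z < -3 && m >= 115 && m < 125 && !oe) return("UNDERESTIMATED_SAM")
    if ((z < -3 && m < 115) || (z < -3 && oe)) return("IGNORED_RISK_SAM")
    if ((m < 115 || oe) && z >= -3) return("CORRECTLY_DETECTED_SAM")
    if (mam && m >= 125) return("EXCLUDED_MAM")
    if (mam) return("INCLUDED_MAM")
    "NOT_A_CASE"
  }, whz, muac, oedema)
}
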