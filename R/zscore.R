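#' Weight-for-height z-scores by the LMS method
#'
#' Computes WHZ from weight and interpolated LMS coefficients:
#' \deqn{z = \frac{(w/M)^L - 1}{L\,S}}
#' (the limit \eqn{\log(w/M)/S} is used when \eqn{L = 0}). By default the WHO
#' "restricted" adjustment is applied beyond +/-3: for raw \eqn{z > 3},
#' \eqn{z = 3 + (w - SD3pos)/(SD3pos - SD2pos)}, and for raw \eqn{z < -3},
#' \eqn{z = -3 + (w - SD3neg)/(SD2neg - SD3neg)}, where
#' \eqn{SD_k = M (1 + L S k)^{1/L}}. This linearizes the scale beyond three
#' z-scores, anchored at the distance between the 2 and 3 SD curves, and is
#' continuous at \eqn{z = \pm 3}.
#'
#' @param weight_kg Numeric vector of weights (kg).
#' @param height_cm Numeric vector of heights (cm); must lie within the
#'   reference range.
#' @param sex Character vector (`"f"`/`"m"`).
#' @param table A `growth_reference` object.
#' @param restricted Apply the restricted adjustment beyond +/-3 (default
#'   `TRUE`, matching the WHO macro).
#' @return Numeric vector of z-scores.
#' @export
compute_whz <- function(weight_kg, height_cm, sex, table, restricted = TRUE) {
  n <- max(length(weight_kg), length(height_cm), length(sex))
  weight_kg <- rep_len(as.numeric(weight_kg), n)
  height_cm <- rep_len(as.numeric(height_cm), n)
  sex <- rep_len(as.character(sex), n)
  if (anyNA(weight_kg) || anyNA(height_cm) || anyNA(sex)) {
    stop("compute_whz: missing weight, height or sex", call. = FALSE)
  }
  if (any(weight_kg <= 0)) {
    stop("compute_whz: weight must be positive", call. = FALSE)
  }
  lms <- lms_at(table, height_cm, sex)
  z <- lms_z(weight_kg, lms$L, lms$M, lms$S)
  if (restricted) {
    hi <- which(z > 3)
    if (length(hi) > 0) {
      sd3 <- lms_x(3, lms$L[hi], lms$M[hi], lms$S[hi])
      sd2 <- lms_x(2, lms$L[hi], lms$M[hi], lms$S[hi])
      z[hi] <- 3 + (weight_kg[hi] - sd3) / (sd3 - sd2)
    }
    lo <- which(z < -3)
    if (length(lo) > 0) {
      sd3n <- lms_x(-3, lms$L[lo], lms$M[lo], lms$S[lo])
      sd2n <- lms_x(-2, lms$L[lo], lms$M[lo], lms$S[lo])
      z[lo] <- -3 + (weight_kg[lo] - sd3n) / (sd2n - sd3n)
    }
  }
  z
}

# raw LMS z for measurement x against coefficients (L, M, S)
lms_z <- function(x, L, M, S) {
  n <- max(length(x), length(L))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  out <- ((x / M)^L - 1) / (L * S)
  deg <- abs(L) < 1e-12  # Box-Cox limit at L = 0
  out[deg] <- log(x[deg] / M[deg]) / S[deg]
  out
}

# inverse LMS: the measurement lying exactly z SD from the median
lms_x <- function(z, L, M, S) {
  n <- max(length(z), length(L))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  out <- M * (1 + L * S * z)^(1 / L)
  deg <- abs(L) < 1e-12
  out[deg] <- M[deg] * exp(S[deg] * z[deg])
  out
}

#' Invert a weight-for-height z-score to a weight
#'
#' The exact inverse of [compute_whz()]: for \eqn{|z| \le 3},
#' \eqn{w = M (1 + L S z)^{1/L}}; beyond +/-3 the piecewise-linear inverse of
#' the restricted adjustment is used, so `compute_whz(invert_whz(z)) == z` to
#' numerical precision. Used by the survey simulator to emit weights that
#' reproduce a prescribed WHZ.
#'
#' @inheritParams compute_whz
#' @param z Numeric vector of target z-scores.
#' @return Numeric vector of weights (kg).
#' @export
invert_whz <- function(z, height_cm, sex, table, restricted = TRUE) {
  n <- max(length(z), length(height_cm), length(sex))
  z <- rep_len(as.numeric(z), n)
  height_cm <- rep_len(as.numeric(height_cm), n)
  sex <- rep_len(as.character(sex), n)
  lms <- lms_at(table, height_cm, sex)
  zc <- if (restricted) pmin(pmax(z, -3), 3) else z
  arg <- 1 + lms$L * lms$S * zc
  if (any(abs(lms$L) >= 1e-12 & arg <= 0)) {
    stop("invert_whz: z out of the LMS domain (1 + L*S*z <= 0)", call. = FALSE)
  }
  w <- lms_x(zc, lms$L, lms$M, lms$S)
  if (restricted) {
    hi <- which(z > 3)
    if (length(hi) > 0) {
      sd3 <- lms_x(3, lms$L[hi], lms$M[hi], lms$S[hi])
      sd2 <- lms_x(2, lms$L[hi], lms$M[hi], lms$S[hi])
      w[hi] <- sd3 + (z[hi] - 3) * (sd3 - sd2)
    }
    lo <- which(z < -3)
    if (length(lo) > 0) {
      sd3n <- lms_x(-3, lms$L[lo], lms$M[lo], lms$S[lo])
      sd2n <- lms_x(-2, lms$L[lo], lms$M[lo], lms$S[lo])
      w[lo] <- sd3n + (z[lo] + 3) * (sd2n - sd3n)
    }
  }
  w
}

#' Clean survey records and compute WHZ
#'
#' Applies the standard survey exclusions in fixed precedence order and
#' computes WHZ for the remaining children:
#' \enumerate{
#'   \item `missing_field` — age, sex, weight, height or MUAC missing
#'     (oedema too, unless `missing_oedema_policy = "assume_no"`);
#'   \item `age_out_of_range` — age outside 6.0 <= age < 60.0 months;
#'   \item `whz_flag` — computed WHZ outside the flagging bounds
#'     (fixed +/-5 around zero for the default `"who_fixed"` dialect;
#'     survey-mean +/-3 for `"smart_mean"`), or a height outside the
#'     reference grid, which is treated as an equally implausible measurement;
#'   \item `none` — retained for analysis.
#' }
#' One output row per input row, order preserved; nothing is dropped.
#'
#' @param records Data frame in the survey schema: `survey_id`, `cluster_id`,
#'   `age_months`, `sex`, `weight_kg`, `height_cm`, `muac_mm`, `oedema`
#'   (logical; `NA` = missing).
#' @param table A `growth_reference` object.
#' @param restricted Passed to [compute_whz()].
#' @param flag_dialect `"who_fixed"` (default) or `"smart_mean"`.
#' @param flag_sd Half-width of the flagging band (default 5 for
#'   `"who_fixed"`, 3 for `"smart_mean"`).
#' @param missing_oedema_policy `"exclude"` (default; missing oedema is a
#'   missing field) or `"assume_no"`.
#' @return The input data frame with added columns `whz` (numeric, `NA` when
#'   undefined) and `exclusion_reason` (factor with levels `none`,
#'   `missing_field`, `age_out_of_range`, `whz_flag`).
#' @export
clean_records <- function(records, table, restricted = TRUE,
                          flag_dialect = c("who_fixed", "smart_mean"),
                          flag_sd = NULL,
                          missing_oedema_policy = c("exclude", "assume_no")) {
  flag_dialect <- match.arg(flag_dialect)
  missing_oedema_policy <- match.arg(missing_oedema_policy)
  if (is.null(flag_sd)) {
    flag_sd <- if (flag_dialect == "who_fixed") 5 else 3
  }
  records <- validate_child_records(records)
  n <- nrow(records)
  reason <- rep("none", n)
  whz <- rep(NA_real_, n)

  miss <- is.na(records$age_months) | is.na(records$sex) |
    is.na(records$weight_kg) | is.na(records$height_cm) |
    is.na(records$muac_mm)
  if (missing_oedema_policy == "exclude") {
    miss <- miss | is.na(records$oedema)
  }
  reason[miss] <- "missing_field"

  age_bad <- !miss &
    (records$age_months < 6.0 | records$age_months >= 60.0)
  reason[age_bad] <- "age_out_of_range"

  eligible <- which(!miss & !age_bad)
  if (length(eligible) > 0) {
    # out-of-grid heights are flagged rather than erroring: cleaning never
    # rejects a record outright
    in_range <- height_in_range(table, records$height_cm[eligible],
                                records$sex[eligible])
    comp <- eligible[in_range]
    if (length(comp) > 0) {
      whz[comp] <- compute_whz(records$weight_kg[comp],
                               records$height_cm[comp],
                               records$sex[comp], table,
                               restricted = restricted)
    }
    reason[eligible[!in_range]] <- "whz_flag"
    if (flag_dialect == "who_fixed") {
      flagged <- comp[abs(whz[comp]) > flag_sd]
    } else {
      ctr <- stats::ave(whz[comp], records$survey_id[comp],
                        FUN = function(x) mean(x, na.rm = TRUE))
      flagged <- comp[abs(whz[comp] - ctr) > flag_sd]
    }
    reason[flagged] <- "whz_flag"
  }

  records$whz <- whz
  records$exclusion_reason <- factor(
    reason, levels = c("none", "missing_field", "age_out_of_range", "whz_flag"))
  records
}

# TRUE where height falls inside the tabulated grid for that sex
height_in_range <- function(table, height_cm, sex) {
  ok <- rep(FALSE, length(height_cm))
  for (sx in unique(sex)) {
    ref <- table[table$sex == sx, , drop = FALSE]
    idx <- which(sex == sx)
    if (nrow(ref) == 0) next
    ok[idx] <- height_cm[idx] >= ref$height_cm[1] &
      height_cm[idx] <= ref$height_cm[nrow(ref)]
  }
  ok
}

# coerce and sanity-check the survey schema; positive physical quantities
validate_child_records <- function(records) {
  required <- c("survey_id", "cluster_id", "age_months", "sex", "weight_kg",
                "height_cm", "muac_mm", "oedema")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("survey records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("age_months", "weight_kg", "height_cm", "muac_mm")) {
    records[[col]] <- as.numeric(records[[col]])
    bad <- which(!is.na(records[[col]]) & records[[col]] <= 0)
    if (length(bad) > 0) {
      stop("record ", bad[1], ": non-positive ", col, call. = FALSE)
    }
  }
  records$sex <- as.character(records$sex)
  records$sex[records$sex == ""] <- NA_character_
  bad_sex <- which(!is.na(records$sex) & !records$sex %in% c("f", "m"))
  if (length(bad_sex) > 0) {
    stop("record ", bad_sex[1], ": sex must be 'f', 'm' or missing",
         call. = FALSE)
  }
  records$oedema <- as.logical(records$oedema)
  records
}
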