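#' Load a sex-specific LMS growth-reference table
#'
#' Reads a reference table of LMS coefficients (Box-Cox power `L`, median `M`,
#' coefficient of variation `S`) indexed by sex and height, as used to compute
#' weight-for-height z-scores against the WHO 2006 child growth standards.
#' The table is validated: heights must be strictly increasing within each sex
#' and `M` and `S` strictly positive. Lookups outside the tabulated height
#' range are rejected, never extrapolated.
#'
#' @param source Path to a CSV file (or a connection) with columns
#'   `sex` (`"f"`/`"m"`), `height_cm`, `L`, `M`, `S`.
#' @return A `growth_reference` object: a data frame with the five columns
#'   above, ordered by sex then height.
#' @seealso [lms_at()], [compute_whz()], [synthetic_lms_table()]
#' @export
load_reference_table <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  required <- c("sex", "height_cm", "L", "M", "S")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("reference table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_growth_reference(df[required])
}

#' Construct and validate a growth-reference object
#'
#' @param df Data frame with columns `sex`, `height_cm`, `L`, `M`, `S`.
#' @return A validated `growth_reference` data frame.
#' @export
as_growth_reference <- function(df) {
  df$sex <- as.character(df$sex)
  bad_sex <- which(!df$sex %in% c("f", "m"))
  if (length(bad_sex) > 0) {
    stop("reference table row ", bad_sex[1], ": sex must be 'f' or 'm', got '",
         df$sex[bad_sex[1]], "'", call. = FALSE)
  }
  for (col in c("height_cm", "L", "M", "S")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]])) {
      stop("reference table row ", which(is.na(df[[col]]))[1],
           ": non-numeric or missing ", col, call. = FALSE)
    }
  }
  bad_m <- which(df$M <= 0)
  if (length(bad_m) > 0) {
    stop("reference table row ", bad_m[1], ": M must be > 0", call. = FALSE)
  }
  bad_s <- which(df$S <= 0)
  if (length(bad_s) > 0) {
    stop("reference table row ", bad_s[1], ": S must be > 0", call. = FALSE)
  }
  df <- df[order(match(df$sex, c("f", "m"))), , drop = FALSE]
  for (sx in unique(df$sex)) {
    h <- df$height_cm[df$sex == sx]
    if (any(diff(h) <= 0)) {
      i <- which(diff(h) <= 0)[1]
      stop("reference table (sex '", sx, "'): heights not strictly ",
           "increasing at ", h[i], " -> ", h[i + 1], call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("growth_reference", "data.frame")
  df
}

#' @export
print.growth_reference <- function(x, ...) {
  rng <- tapply(x$height_cm, x$sex, range)
  cat("<growth_reference> ", nrow(x), " rows\n", sep = "")
  for (sx in names(rng)) {
    cat("  sex ", sx, ": height ", rng[[sx]][1], "-", rng[[sx]][2], " cm\n",
        sep = "")
  }
  invisible(x)
}

#' Interpolate LMS coefficients at given heights
#'
#' Returns exact row values at tabulated grid points and linear interpolation
#' of `L`, `M` and `S` between adjacent grid points otherwise. Heights outside
#' the tabulated range raise an error (no extrapolation).
#'
#' @param table A `growth_reference` object.
#' @param height_cm Numeric vector of heights (cm).
#' @param sex Character vector (`"f"`/`"m"`), recycled to the length of
#'   `height_cm`.
#' @return A data frame with columns `L`, `M`, `S`, one row per input height.
#' @export
lms_at <- function(table, height_cm, sex) {
  stopifnot(inherits(table, "growth_reference"))
  n <- max(length(height_cm), length(sex))
  height_cm <- rep_len(as.numeric(height_cm), n)
  sex <- rep_len(as.character(sex), n)
  out <- data.frame(L = rep(NA_real_, n), M = NA_real_, S = NA_real_)
  for (sx in unique(sex)) {
    ref <- table[table$sex == sx, , drop = FALSE]
    if (nrow(ref) == 0) {
      stop("no reference rows for sex '", sx, "'", call. = FALSE)
    }
    idx <- which(sex == sx)
    h <- height_cm[idx]
    oor <- !is.na(h) & (h < ref$height_cm[1] | h > ref$height_cm[nrow(ref)])
    if (any(oor)) {
      stop("height ", h[which(oor)[1]], " cm outside reference range [",
           ref$height_cm[1], ", ", ref$height_cm[nrow(ref)], "] for sex '",
           sx, "'", call. = FALSE)
    }
    for (col in c("L", "M", "S")) {
      out[[col]][idx] <- stats::approx(ref$height_cm, ref[[col]], xout = h,
                                       method = "linear", ties = "ordered")$y
    }
  }
  out
}

#' Generate a synthetic LMS reference table
#'
#' Builds a smooth, WHO-like (but entirely synthetic) sex-specific LMS grid
#' for testing and simulation: the median weight `M` grows quadratically with
#' height (boys ~3% heavier), the Box-Cox power `L` is mildly negative and the
#' coefficient of variation `S` is constant. The real WHO 2006 coefficient
#' files are not bundled; users supply them where real-data fidelity matters.
#'
#' @param heights Numeric vector of grid heights in cm (default 45-130 by 0.5).
#' @return A `growth_reference` object covering both sexes.
#' @export
synthetic_lms_table <- function(heights = seq(45, 130, by = 0.5)) {
  m_base <- 2.4 + 0.205 * (heights - 45) + 0.00115 * (heights - 45)^2
  grid <- rbind(
    data.frame(sex = "f", height_cm = heights, L = -0.35, M = m_base,
               S = 0.085),
    data.frame(sex = "m", height_cm = heights, L = -0.32, M = m_base * 1.03,
               S = 0.082)
  )
  as_growth_reference(grid)
}
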