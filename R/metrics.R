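CATEGORY_COUNTS <- c("excluded_sam", "underestimated_sam", "ignored_risk_sam",
                     "correctly_detected_sam", "excluded_mam", "included_mam",
                     "not_a_case")
CASE_COUNTS <- c("sam_all", "mam_all", "gam", "sam_muac", "mam_muac",
                 "sam_whz", "mam_whz", "program_enrolled")
DEMO_CATEGORIES <- CATEGORY_COUNTS[1:6]
DEMO_COUNTS <- c(outer(DEMO_CATEGORIES, c("female", "under24m"), paste,
                       sep = "_"))
TALLY_COUNT_COLS <- c("n_children", CATEGORY_COUNTS, CASE_COUNTS, DEMO_COUNTS)

# lowercase tally column name for a scenario level
category_column <- function(level) tolower(level)

#' Tally scenario categories and demographics for one group
#'
#' Counts children by case definition, scenario category and demographic
#' stratum (female; aged 6-23 months) for one grouping unit (usually a
#' survey). Children with a non-`none` exclusion reason are omitted from every
#' count, including `n_children`.
#'
#' @param classified Output of [classify_children()].
#' @param group_id Identifier for the tallied unit.
#' @return A one-row `tally_table` data frame holding raw counts only;
#'   proportions are computed later, after aggregation, by
#'   [targeting_metrics()] and [demographic_summary()].
#' @export
tally <- function(classified, group_id) {
  keep <- classified[!is.na(classified$exclusion_reason) &
                       classified$exclusion_reason == "none", , drop = FALSE]
  row <- data.frame(group_id = as.character(group_id), n_surveys = 1L,
                    n_children = nrow(keep))
  cat_n <- table(factor(keep$scenario_category, levels = scenario_levels))
  for (lv in scenario_levels) {
    row[[category_column(lv)]] <- as.numeric(cat_n[[lv]])
  }
  for (col in c("sam_all", "mam_all", "gam", "sam_muac", "mam_muac",
                "sam_whz", "mam_whz")) {
    row[[col]] <- sum(keep[[col]])
  }
  row$program_enrolled <- sum(keep$program_enrolled)
  female <- keep$sex == "f"
  under24 <- keep$age_months < 24
  for (lv in DEMO_CATEGORIES) {
    in_cat <- category_column(keep$scenario_category) == lv
    row[[paste0(lv, "_female")]] <- sum(in_cat & female)
    row[[paste0(lv, "_under24m")]] <- sum(in_cat & under24)
  }
  class(row) <- c("tally_table", "data.frame")
  row
}

#' Aggregate survey tallies by country, region or overall
#'
#' Element-wise sums of counts within each group — never averages of
#' proportions. Proportions and ratios are derived afterwards from the summed
#' counts, which is what makes small and large surveys contribute in
#' proportion to their caseload.
#'
#' @param tallies A `tally_table` (one row per survey, or per lower-level
#'   group), e.g. several [tally()] results bound with `rbind`.
#' @param grouping Data frame mapping `survey_id` to `country` and `region`;
#'   required for `level = "country"` or `"region"`.
#' @param level `"country"`, `"region"` or `"overall"`.
#' @param overall_id Group label used when `level = "overall"`.
#' @return A `tally_table` with one row per group.
#' @export
aggregate_tallies <- function(tallies, grouping = NULL,
                              level = c("country", "region", "overall"),
                              overall_id = "overall") {
  level <- match.arg(level)
  tallies <- as.data.frame(tallies)
  if (level == "overall") {
    keys <- rep(overall_id, nrow(tallies))
  } else {
    if (is.null(grouping)) {
      stop("aggregate_tallies: a grouping table is required for level '",
           level, "'", call. = FALSE)
    }
    idx <- match(tallies$group_id, as.character(grouping$survey_id))
    if (anyNA(idx)) {
      stop("aggregate_tallies: group(s) missing from grouping table: ",
           paste(unique(tallies$group_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    keys <- as.character(grouping[[level]][idx])
  }
  pieces <- lapply(split(tallies, keys), function(block) {
    out <- data.frame(group_id = NA_character_,
                      n_surveys = sum(block$n_surveys))
    for (col in TALLY_COUNT_COLS) {
      vals <- block[[col]]
      out[[col]] <- if (all(is.na(vals))) NA_real_ else sum(vals, na.rm = TRUE)
    }
    out
  })
  res <- do.call(rbind, pieces)
  res$group_id <- names(pieces)
  rownames(res) <- NULL
  res <- res[c("group_id", "n_surveys", TALLY_COUNT_COLS)]
  class(res) <- c("tally_table", "data.frame")
  res
}

#' Program-targeting metrics from a count tally
#'
#' Derives, per group, the distribution of severe cases over the four
#' targeting categories, the proportion of moderate cases the program misses,
#' the case-mix of the program caseload and the RUTF allocation-increase
#' ratio:
#' \itemize{
#'   \item each SAM category percentage = 100 x category count / SAM cases;
#'   \item `excluded_mam_pct` = 100 x excluded-MAM count / MAM cases;
#'   \item program caseload = children enrolled on MUAC/oedema criteria
#'     (severe-by-MUAC plus moderate-by-MUAC counts);
#'   \item `mam_in_program_pct` = 100 x included-MAM count / program caseload;
#'   \item `rutf_allocation_increase` = program caseload / SAM cases — the
#'     factor by which the RUTF-receiving population grows when the
#'     therapeutic-food target moves from all SAM cases to everyone enrolled.
#' }
#' Metrics with a zero denominator are `NA` (absent), never 0.
#'
#' @param tallies A `tally_table`.
#' @return Data frame, one row per group, with unrounded percentage and ratio
#'   columns alongside `n_surveys` and `n_children`.
#' @export
targeting_metrics <- function(tallies) {
  t <- as.data.frame(tallies)
  pct <- function(num, den) ifelse(is.na(den) | den == 0, NA_real_,
                                   100 * num / den)
  out <- data.frame(group_id = t$group_id, n_surveys = t$n_surveys,
                    n_children = t$n_children)
  out$sam_all_pct <- pct(t$sam_all, t$n_children)
  out$mam_all_pct <- pct(t$mam_all, t$n_children)
  out$gam_pct <- pct(t$gam, t$n_children)
  for (col in c("excluded_sam", "underestimated_sam", "ignored_risk_sam",
                "correctly_detected_sam")) {
    out[[paste0(col, "_pct")]] <- pct(t[[col]], t$sam_all)
  }
  out$excluded_mam_pct <- pct(t$excluded_mam, t$mam_all)
  program <- t$program_enrolled
  out$mam_in_program_pct <- pct(t$included_mam, program)
  out$rutf_allocation_increase <- ifelse(
    is.na(t$sam_all) | t$sam_all == 0, NA_real_, program / t$sam_all)
  out
}

#' Demographic composition of each targeting category
#'
#' Percentage of females and of younger children (6-23 months) within each of
#' the six SAM/MAM targeting categories, from aggregated counts. Categories
#' with zero members yield `NA`.
#'
#' @param tallies A `tally_table`.
#' @return Data frame, one row per group, columns
#'   `<category>_female_pct` and `<category>_under24m_pct`.
#' @export
demographic_summary <- function(tallies) {
  t <- as.data.frame(tallies)
  out <- data.frame(group_id = t$group_id)
  for (lv in DEMO_CATEGORIES) {
    den <- t[[lv]]
    for (stratum in c("female", "under24m")) {
      num <- t[[paste0(lv, "_", stratum)]]
      out[[paste0(lv, "_", stratum, "_pct")]] <- ifelse(
        is.na(den) | den == 0, NA_real_, 100 * num / den)
    }
  }
  out
}

#' Rebuild a count tally from published percentages
#'
#' Turns a reported summary row (total children surveyed plus printed
#' percentages) back into a count table so that published aggregate rows can
#' be fed through the same count-first aggregation code path as raw surveys.
#' Counts are chained products — e.g. the excluded-SAM count is
#' `n_children x sam_all_pct/100 x excluded_sam_pct/100` — and may be
#' fractional, reflecting the rounding of the printed inputs.
#'
#' @param group_id Group label for the resulting row.
#' @param n_children Total children behind the published row.
#' @param proportions Named numeric vector or list of percentages in `[0,
#'   100]`: `sam_all_pct`, `mam_all_pct`, `excluded_sam_pct`,
#'   `underestimated_sam_pct`, `ignored_risk_sam_pct`,
#'   `correctly_detected_sam_pct`, `excluded_mam_pct`, and optionally
#'   demographic percentages named `<category>_female_pct` /
#'   `<category>_under24m_pct`.
#' @param n_surveys Number of surveys behind the row (default 1).
#' @return A one-row `tally_table` with real-valued counts. Counts that cannot
#'   be recovered from percentages alone (WHZ-only case counts) are `NA`.
#' @export
reconstruct_counts <- function(group_id, n_children, proportions,
                               n_surveys = 1L) {
  p <- as.list(proportions)
  need <- c("sam_all_pct", "mam_all_pct", "excluded_sam_pct",
            "underestimated_sam_pct", "ignored_risk_sam_pct",
            "correctly_detected_sam_pct", "excluded_mam_pct")
  missing_p <- setdiff(need, names(p))
  if (length(missing_p) > 0) {
    stop("reconstruct_counts: missing proportion(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(p[need])
  if (any(vals < 0 | vals > 100)) {
    stop("reconstruct_counts: percentages must lie in [0, 100]",
         call. = FALSE)
  }
  sam_split <- sum(vals[c("excluded_sam_pct", "underestimated_sam_pct",
                          "ignored_risk_sam_pct",
                          "correctly_detected_sam_pct")])
  if (abs(sam_split - 100) > 2 && vals[["sam_all_pct"]] > 0) {
    warning("reconstruct_counts: the four SAM category percentages sum to ",
            round(sam_split, 2), ", not 100", call. = FALSE)
  }
  row <- data.frame(group_id = as.character(group_id),
                    n_surveys = as.integer(n_surveys),
                    n_children = as.numeric(n_children))
  sam_all <- n_children * vals[["sam_all_pct"]] / 100
  mam_all <- n_children * vals[["mam_all_pct"]] / 100
  row$excluded_sam <- sam_all * vals[["excluded_sam_pct"]] / 100
  row$underestimated_sam <- sam_all * vals[["underestimated_sam_pct"]] / 100
  row$ignored_risk_sam <- sam_all * vals[["ignored_risk_sam_pct"]] / 100
  row$correctly_detected_sam <- sam_all *
    vals[["correctly_detected_sam_pct"]] / 100
  row$excluded_mam <- mam_all * vals[["excluded_mam_pct"]] / 100
  row$included_mam <- mam_all - row$excluded_mam
  row$not_a_case <- n_children - sam_all - mam_all
  row$sam_all <- sam_all
  row$mam_all <- mam_all
  row$gam <- sam_all + mam_all
  # children enrolled on MUAC/oedema: the severe tier is exactly the ignored-
  # risk + correctly-detected categories, the moderate tier the
  # underestimated-SAM + included-MAM categories
  row$sam_muac <- row$ignored_risk_sam + row$correctly_detected_sam
  row$mam_muac <- row$underestimated_sam + row$included_mam
  row$sam_whz <- NA_real_
  row$mam_whz <- NA_real_
  row$program_enrolled <- row$sam_muac + row$mam_muac
  for (lv in DEMO_CATEGORIES) {
    for (stratum in c("female", "under24m")) {
      key <- paste0(lv, "_", stratum, "_pct")
      row[[paste0(lv, "_", stratum)]] <-
        if (key %in% names(p)) row[[lv]] * p[[key]] / 100 else NA_real_
    }
  }
  row <- row[c("group_id", "n_surveys", TALLY_COUNT_COLS)]
  class(row) <- c("tally_table", "data.frame")
  row
}

#' Rounded targeting report
#'
#' Joins [targeting_metrics()] and [demographic_summary()] into the standard
#' report layout, rounding percentages to one decimal and the allocation
#' ratio to two, the customary precision for survey summary tables. Use the
#' unrounded component functions for further computation.
#'
#' @param tallies A `tally_table`.
#' @param digits_pct,digits_ratio Rounding precision.
#' @return Data frame, one row per group.
#' @export
targeting_report <- function(tallies, digits_pct = 1, digits_ratio = 2) {
  m <- targeting_metrics(tallies)
  d <- demographic_summary(tallies)
  rep <- merge(m, d, by = "group_id", sort = FALSE)
  pct_cols <- grep("_pct$", names(rep), value = TRUE)
  rep[pct_cols] <- lapply(rep[pct_cols], round, digits = digits_pct)
  rep$rutf_allocation_increase <- round(rep$rutf_allocation_increase,
                                        digits_ratio)
  names(rep)[names(rep) == "group_id"] <- "group"
  rep
}
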