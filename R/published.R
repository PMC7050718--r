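#' Published regional summary rows
#'
#' Regional aggregate rows (six regions, 550 surveys, ~400,000 children
#' 6-59 months) from a published multi-country compilation of humanitarian
#' nutrition surveys, shipped with the package: per-region child counts,
#' SAM/MAM prevalence, the distribution of SAM cases over the four targeting
#' categories, excluded-MAM proportion, program case-mix and RUTF
#' allocation-increase ratio, plus the demographic composition (percent
#' female, percent aged 6-23 months) of each category. The child-level
#' microdata behind these rows are restricted; the printed aggregates are the
#' finest publicly available resolution.
#'
#' @param which `"regional"` or `"overall"`; `demographics = TRUE` returns
#'   the companion demographic table.
#' @param demographics Logical.
#' @return Data frame of published percentages and counts.
#' @export
published_summary <- function(which = c("regional", "overall"),
                              demographics = FALSE) {
  which <- match.arg(which)
  stem <- if (demographics) "survey_compilation_demo_" else
    "survey_compilation_"
  path <- system.file("extdata", paste0(stem, which, ".csv"),
                      package = "muactarget", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reconstruct the overall aggregate row from regional summary rows
#'
#' Converts each published regional row back into a count table with
#' [reconstruct_counts()] (counts = N children x chained printed
#' percentages), pools the counts with [aggregate_tallies()], and recomputes
#' every proportion and ratio from the pooled counts — the same count-first
#' semantics used for raw surveys. Because the printed regional percentages
#' carry one-decimal rounding, reconstructed overall values match published
#' overall values to printed precision, with the derived ratio metrics
#' carrying about one unit in the last printed digit of propagated input
#' rounding.
#'
#' @param regional Data frame in the layout of
#'   `published_summary("regional")`; defaults to the shipped rows.
#' @param demographics Companion demographic rows
#'   (`published_summary("regional", demographics = TRUE)`).
#' @return One-row data frame: merged [targeting_metrics()] and
#'   [demographic_summary()] of the pooled counts (unrounded).
#' @export
reconstruct_overall_row <- function(regional = published_summary("regional"),
                                    demographics =
                                      published_summary("regional",
                                                        demographics = TRUE)) {
  rows <- lapply(seq_len(nrow(regional)), function(i) {
    props <- as.list(regional[i, !(names(regional) %in%
                                     c("region", "n_surveys", "n_children"))])
    if (!is.null(demographics)) {
      d <- demographics[demographics$region == regional$region[i], ,
                        drop = FALSE]
      if (nrow(d) == 1) props <- c(props, as.list(d[-1]))
    }
    reconstruct_counts(regional$region[i], regional$n_children[i], props,
                       n_surveys = regional$n_surveys[i])
  })
  tallies <- do.call(rbind, rows)
  class(tallies) <- c("tally_table", "data.frame")
  pooled <- aggregate_tallies(tallies, level = "overall")
  merge(targeting_metrics(pooled), demographic_summary(pooled),
        by = "group_id")
}
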