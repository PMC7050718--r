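SURVEY_HEADER <- c("survey_id", "cluster_id", "age_months", "sex",
                   "weight_kg", "height_cm", "muac_mm", "oedema")

#' Read a child-level survey CSV
#'
#' Expects exactly the columns `survey_id, cluster_id, age_months, sex,
#' weight_kg, height_cm, muac_mm, oedema`; empty cells are missing values,
#' `sex` is `f`/`m` and `oedema` is `y`/`n`.
#'
#' @param path CSV path or connection.
#' @return Data frame of typed child records (`oedema` logical).
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  extra <- setdiff(names(df), SURVEY_HEADER)
  missing_cols <- setdiff(SURVEY_HEADER, names(df))
  if (length(extra) > 0 || length(missing_cols) > 0) {
    stop("survey CSV must have exactly the header: ",
         paste(SURVEY_HEADER, collapse = ","),
         if (length(extra) > 0)
           paste0("; unexpected: ", paste(extra, collapse = ", ")),
         if (length(missing_cols) > 0)
           paste0("; missing: ", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  df <- df[SURVEY_HEADER]
  for (col in c("age_months", "weight_kg", "height_cm", "muac_mm")) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad) > 0) {
      stop("survey CSV row ", bad[1], ": malformed ", col, " value '",
           raw[bad[1]], "'", call. = FALSE)
    }
    df[[col]] <- val
  }
  df$sex[df$sex == ""] <- NA_character_
  oe <- df$oedema
  bad_oe <- which(!oe %in% c("y", "n", "", NA))
  if (length(bad_oe) > 0) {
    stop("survey CSV row ", bad_oe[1], ": oedema must be 'y', 'n' or empty",
         call. = FALSE)
  }
  df$oedema <- ifelse(oe %in% c("", NA), NA, oe == "y")
  validate_child_records(df)
}

#' Write child records in the survey CSV schema
#'
#' Inverse of [read_survey_csv()]: logical oedema becomes `y`/`n`, missing
#' values become empty cells. Extra columns (e.g. simulation truth) are
#' dropped.
#'
#' @param records Data frame of child records.
#' @param path Output CSV path.
#' @export
write_survey_csv <- function(records, path) {
  out <- records[SURVEY_HEADER]
  out$oedema <- ifelse(is.na(out$oedema), "", ifelse(out$oedema, "y", "n"))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a survey-to-country-to-region grouping table
#'
#' @param path CSV with columns `survey_id,country,region`.
#' @return Data frame with character columns.
#' @export
read_grouping_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("survey_id", "country", "region")
  if (!all(need %in% names(df))) {
    stop("grouping CSV must have the header: survey_id,country,region",
         call. = FALSE)
  }
  df[need]
}

#' Write a report table as CSV with an unrounded JSON mirror
#'
#' @param rows Report data frame (typically [targeting_report()] output for
#'   the CSV and the matching unrounded rows for the JSON).
#' @param path Output CSV path.
#' @param json_rows Optional unrounded data frame mirrored to
#'   `sub("\\\\.csv$", ".json", path)`.
#' @export
write_report <- function(rows, path, json_rows = NULL) {
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  if (!is.null(json_rows)) {
    jsonlite::write_json(json_rows, sub("\\.csv$", ".json", path),
                         dataframe = "rows", na = "null", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' @param survey Survey CSV path or a data frame of child records.
#' @param reference Reference-table CSV path or a `growth_reference`.
#' @param grouping Grouping CSV path or data frame (`survey_id`, `country`,
#'   `region`); optional — without it only survey-level and overall reports
#'   are produced.
#' @param out_dir Directory for report files; created if absent.
#' @param restricted_adjustment,flag_dialect,missing_oedema_policy Passed to
#'   [clean_records()].
#' @param digits_pct,digits_ratio Report rounding.
#' @param verbose Log progress and exclusion counts to stderr.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(survey, reference, grouping = NULL,
                            out_dir = NULL, restricted_adjustment = TRUE,
                            flag_dialect = "who_fixed",
                            missing_oedema_policy = "exclude",
                            digits_pct = 1, digits_ratio = 2,
                            verbose = TRUE) {
  cfg <- list(survey = survey, reference = reference, grouping = grouping,
              out_dir = out_dir,
              restricted_adjustment = isTRUE(restricted_adjustment),
              flag_dialect = match.arg(flag_dialect,
                                       c("who_fixed", "smart_mean")),
              missing_oedema_policy = match.arg(missing_oedema_policy,
                                                c("exclude", "assume_no")),
              digits_pct = digits_pct, digits_ratio = digits_ratio,
              verbose = isTRUE(verbose))
  for (f in c("survey", "reference", "grouping")) {
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("pipeline_config: ", f, " file not found: ", cfg[[f]],
           call. = FALSE)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML fields mirror the arguments of [pipeline_config()]; relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || !is.character(p)) return(p)
    if (file.exists(p)) p else file.path(base, p)
  }
  do.call(pipeline_config, c(
    list(survey = resolve(y$survey), reference = resolve(y$reference),
         grouping = resolve(y$grouping), out_dir = y$out_dir),
    y[intersect(names(y), c("restricted_adjustment", "flag_dialect",
                            "missing_oedema_policy", "digits_pct",
                            "digits_ratio", "verbose"))]))
}

#' Run the full targeting-analysis pipeline
#'
#' Clean -> classify -> tally per survey -> aggregate (country, region,
#' overall) -> metrics. Verifies that no record is silently lost (input
#' count = retained + sum of exclusions) and, when `out_dir` is set, writes
#' `report_survey.csv`, `report_country.csv`, `report_region.csv` and
#' `report_overall.csv`, each with an unrounded `.json` mirror, plus
#' `cleaned.csv` carrying per-child WHZ, exclusion reason and classification
#' columns. Identical inputs and configuration yield identical outputs.
#'
#' @param config A [pipeline_config()] (or YAML path, read via
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with `classified` (child-level table), `tallies`
#'   (per-survey counts), `aggregates` (list of tally tables by level) and
#'   `reports` (list of rounded report data frames).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (config$verbose) message("[pipeline] ", ...)

  records <- if (is.character(config$survey)) {
    read_survey_csv(config$survey)
  } else {
    validate_child_records(as.data.frame(config$survey))
  }
  table <- if (is.character(config$reference)) {
    load_reference_table(config$reference)
  } else {
    config$reference
  }
  grouping <- if (is.character(config$grouping)) {
    read_grouping_csv(config$grouping)
  } else {
    config$grouping
  }
  log_msg("read ", nrow(records), " child records from ",
          length(unique(records$survey_id)), " survey(s)")

  cleaned <- clean_records(records, table,
                           restricted = config$restricted_adjustment,
                           flag_dialect = config$flag_dialect,
                           missing_oedema_policy =
                             config$missing_oedema_policy)
  excl <- table(cleaned$exclusion_reason)
  if (sum(excl) != nrow(records)) {
    stop("run_pipeline: record accounting failed (", sum(excl), " != ",
         nrow(records), ")", call. = FALSE)
  }
  log_msg("retained ", excl[["none"]], "; excluded ",
          excl[["missing_field"]], " missing-field, ",
          excl[["age_out_of_range"]], " age-out-of-range, ",
          excl[["whz_flag"]], " WHZ-flagged")

  classified <- classify_children(cleaned)
  per_survey <- split(classified, classified$survey_id)
  tallies <- do.call(rbind, lapply(names(per_survey), function(sid) {
    tally(per_survey[[sid]], sid)
  }))
  class(tallies) <- c("tally_table", "data.frame")

  aggregates <- list(survey = tallies)
  if (!is.null(grouping)) {
    aggregates$country <- aggregate_tallies(tallies, grouping, "country")
    aggregates$region <- aggregate_tallies(tallies, grouping, "region")
  }
  aggregates$overall <- aggregate_tallies(tallies, level = "overall")

  reports <- lapply(aggregates, targeting_report,
                    digits_pct = config$digits_pct,
                    digits_ratio = config$digits_ratio)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(classified, file.path(config$out_dir, "cleaned.csv"),
                     row.names = FALSE, na = "")
    for (lvl in names(reports)) {
      unrounded <- merge(targeting_metrics(aggregates[[lvl]]),
                         demographic_summary(aggregates[[lvl]]),
                         by = "group_id", sort = FALSE)
      write_report(reports[[lvl]],
                   file.path(config$out_dir,
                             paste0("report_", lvl, ".csv")),
                   json_rows = unrounded)
    }
    log_msg("reports written to ", config$out_dir)
  }
  invisible(list(classified = classified, tallies = tallies,
                 aggregates = aggregates, reports = reports))
}
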