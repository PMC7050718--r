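# one child per SAM category, in the spec order
four_sam_roster <- function(survey_id = "S1") {
  classified_roster(whz = c(-3.5, -3.5, -3.5, -2.5),
                    muac = c(130, 120, 110, 110), survey_id = survey_id)
}

test_that("tally counts categories, cases and demographics", {
  t <- tally(four_sam_roster(), "S1")
  expect_equal(t$sam_all, 4)
  expect_equal(t$excluded_sam, 1)
  expect_equal(t$underestimated_sam, 1)
  expect_equal(t$ignored_risk_sam, 1)
  expect_equal(t$correctly_detected_sam, 1)
  expect_equal(t$mam_all, 0)
  expect_equal(t$program_enrolled, 3)
  expect_equal(t$program_enrolled, t$sam_muac + t$mam_muac)

  empty <- tally(four_sam_roster()[0, ], "E")
  expect_equal(empty$n_children, 0)
  expect_true(all(empty[muactarget:::TALLY_COUNT_COLS] == 0))

  demo <- tally(classified_roster(whz = -1, muac = 120, sex = "f", age = 18,
                                  survey_id = "S1")[rep(1, 2), ], "S1")
  expect_equal(demo$included_mam, 2)
  expect_equal(demo$included_mam_female, 2)
  expect_equal(demo$included_mam_under24m, 2)
})

test_that("tally omits excluded children from every count", {
  tab <- synthetic_lms_table()
  recs <- rbind(make_child(muac_mm = 110), make_child(weight_kg = NA))
  cl <- classify_children(clean_records(recs, tab))
  t <- tally(cl, "S1")
  expect_equal(t$n_children, 1)
  expect_equal(t$sam_all, 1)
})

test_that("metrics reproduce the hand-counted nine-child roster", {
  # 1 excluded + 1 underestimated + 1 ignored-risk + 1 correctly-detected SAM
  # and 5 included MAM: program = 3 SAM members + 5 MAM = 8
  roster <- classified_roster(
    whz = c(-3.5, -3.5, -3.5, -2.5, rep(-1, 5)),
    muac = c(130, 120, 110, 110, rep(120, 5)))
  m <- targeting_metrics(tally(roster, "S1"))
  expect_equal(m$rutf_allocation_increase, 2.0)
  expect_equal(m$mam_in_program_pct, 62.5)
  expect_equal(m$excluded_sam_pct, 25)
  expect_equal(m$underestimated_sam_pct, 25)
})

test_that("equal SAM categories give 25% each and sum to 100", {
  m <- targeting_metrics(tally(four_sam_roster(), "S1"))
  pcts <- c(m$excluded_sam_pct, m$underestimated_sam_pct,
            m$ignored_risk_sam_pct, m$correctly_detected_sam_pct)
  expect_equal(pcts, rep(25, 4))
  expect_equal(sum(pcts), 100)
})

test_that("zero denominators yield absent metrics, never zero", {
  m <- targeting_metrics(tally(four_sam_roster(), "S1"))
  expect_true(is.na(m$excluded_mam_pct))  # mam_all = 0
  none <- targeting_metrics(tally(classified_roster(0, 140), "S1"))
  expect_true(is.na(none$rutf_allocation_increase))
  expect_true(is.na(none$excluded_sam_pct))
})

test_that("aggregation sums counts and never averages proportions", {
  t1 <- tally(four_sam_roster("A"), "A")
  t2 <- tally(classified_roster(whz = rep(-3.5, 4), muac = rep(130, 4),
                                survey_id = "B"), "B")
  grouping <- data.frame(survey_id = c("A", "B"), country = "X",
                         region = "R1")
  both <- rbind(t1, t2)
  class(both) <- c("tally_table", "data.frame")
  agg <- aggregate_tallies(both, grouping, "country")
  expect_equal(agg$sam_all, 8)
  expect_equal(agg$excluded_sam, 5)
  expect_equal(agg$n_surveys, 2)
  # pooled percentage is count-weighted: 5/8, not mean(25%, 100%)
  m <- targeting_metrics(agg)
  expect_equal(m$excluded_sam_pct, 62.5)
  expect_error(aggregate_tallies(both, grouping[1, ], "country"),
               "missing from grouping")
})

test_that("aggregation commutes with pooled tallying", {
  tab <- synthetic_lms_table()
  cfg <- simulation_config(n_clusters = 15, children_per_cluster = 25,
                           p_missing = 0.03, reference_table = tab)
  surveys <- lapply(1:3, function(i) {
    cfg$seed <- 100 + i
    generate_survey(cfg, survey_id = paste0("S", i))
  })
  classified <- lapply(surveys, function(s) {
    classify_children(clean_records(s, tab))
  })
  per_survey <- do.call(rbind, lapply(seq_along(classified), function(i) {
    tally(classified[[i]], paste0("S", i))
  }))
  class(per_survey) <- c("tally_table", "data.frame")
  pooled_via_agg <- aggregate_tallies(per_survey, level = "overall")
  pooled_direct <- tally(do.call(rbind, classified), "overall")
  for (col in muactarget:::TALLY_COUNT_COLS) {
    expect_equal(pooled_via_agg[[col]], pooled_direct[[col]], info = col)
  }
})

test_that("metrics are invariant to scaling all counts", {
  t <- tally(classified_roster(
    whz = c(-3.5, -3.5, -2.5, rep(-1, 4), rep(-2.5, 2)),
    muac = c(130, 110, 110, rep(120, 4), rep(130, 2))), "S1")
  t3 <- t
  for (col in muactarget:::TALLY_COUNT_COLS) t3[[col]] <- 3 * t[[col]]
  m1 <- targeting_metrics(t)
  m3 <- targeting_metrics(t3)
  for (col in setdiff(names(m1), c("group_id", "n_surveys", "n_children"))) {
    expect_equal(m1[[col]], m3[[col]], info = col)
  }
})

test_that("program case-mix complement identity holds exactly", {
  t <- tally(classified_roster(
    whz = c(-3.5, -3.5, -3.5, -2.5, rep(-1, 5)),
    muac = c(130, 120, 110, 110, rep(120, 5))), "S1")
  m <- targeting_metrics(t)
  sam_in_program <- t$underestimated_sam + t$ignored_risk_sam +
    t$correctly_detected_sam
  expect_equal(t$program_enrolled * (1 - m$mam_in_program_pct / 100),
               sam_in_program)
})

test_that("demographic summary divides by the category count", {
  roster <- classified_roster(whz = rep(-1, 10), muac = rep(120, 10),
                              sex = c(rep("f", 10)),
                              age = c(rep(12, 3), rep(40, 7)))
  d <- demographic_summary(tally(roster, "S1"))
  expect_equal(d$included_mam_female_pct, 100)
  expect_equal(d$included_mam_under24m_pct, 30)
  expect_true(is.na(d$excluded_sam_female_pct))
})

test_that("reconstruct_counts turns printed percentages into counts", {
  t <- reconstruct_counts("G", 1000, list(
    sam_all_pct = 4, mam_all_pct = 0, excluded_sam_pct = 25,
    underestimated_sam_pct = 25, ignored_risk_sam_pct = 25,
    correctly_detected_sam_pct = 25, excluded_mam_pct = 0))
  expect_equal(t$excluded_sam, 10)
  expect_equal(t$sam_all, 40)
  # fractional counts are intentional for published-row fixtures
  t2 <- reconstruct_counts("EAP", 8671, list(
    sam_all_pct = 3.0, mam_all_pct = 13.1, excluded_sam_pct = 27.1,
    underestimated_sam_pct = 25.6, ignored_risk_sam_pct = 17.9,
    correctly_detected_sam_pct = 29.4, excluded_mam_pct = 58.2))
  expect_equal(t2$sam_all, 260.13)
  zero <- reconstruct_counts("Z", 500, list(
    sam_all_pct = 0, mam_all_pct = 0, excluded_sam_pct = 0,
    underestimated_sam_pct = 0, ignored_risk_sam_pct = 0,
    correctly_detected_sam_pct = 0, excluded_mam_pct = 0))
  expect_true(all(zero[c("sam_all", "mam_all", "excluded_sam")] == 0))
  expect_warning(reconstruct_counts("W", 100, list(
    sam_all_pct = 5, mam_all_pct = 0, excluded_sam_pct = 50,
    underestimated_sam_pct = 10, ignored_risk_sam_pct = 10,
    correctly_detected_sam_pct = 10, excluded_mam_pct = 0)),
    "sum to")
  expect_error(reconstruct_counts("B", 100, list(sam_all_pct = 120)),
               "missing proportion|\\[0, 100\\]")
})

test_that("targeting_report rounds to the reporting precision", {
  roster <- classified_roster(
    whz = c(-3.5, -3.5, -3.5, -2.5, rep(-1, 5), 0),
    muac = c(130, 120, 110, 110, rep(120, 5), 140))
  rep <- targeting_report(tally(roster, "S1"))
  expect_equal(rep$excluded_sam_pct, 25.0)
  expect_equal(rep$rutf_allocation_increase, 2.0)
  expect_equal(rep$group, "S1")
})
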