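test_that("the same seed reproduces the survey exactly", {
  cfg <- simulation_config(n_clusters = 8, children_per_cluster = 12,
                           seed = 99, reference_table = synthetic_lms_table())
  expect_identical(generate_survey(cfg), generate_survey(cfg))
  cfg2 <- cfg
  cfg2$seed <- 100L
  expect_false(identical(generate_survey(cfg), generate_survey(cfg2)))
})

test_that("config validation rejects impossible parameters", {
  expect_error(simulation_config(n_clusters = 0), ">= 1")
  expect_error(simulation_config(rho = 1.2), "rho")
  expect_error(simulation_config(p_oedema = -0.1), "\\[0, 1\\]")
  expect_error(simulation_config(sigma_whz = -1), ">= 0")
  expect_error(simulation_config(reference_table = data.frame()),
               "growth_reference")
})

test_that("a well-nourished configuration yields no cases", {
  cfg <- simulation_config(n_clusters = 10, children_per_cluster = 50,
                           mu_whz = 0, sigma_whz = 0.3, muac_beta0 = 160,
                           muac_sigma = 3, p_oedema = 0, p_missing = 0,
                           cluster_sd = 0, seed = 5)
  sv <- generate_survey(cfg)
  cat <- assign_scenario_category(sv$whz_sim, sv$muac_mm, sv$oedema)
  expect_true(all(cat == "NOT_A_CASE"))
})

test_that("rho = 1 makes the two deficits comonotone", {
  cfg <- simulation_config(n_clusters = 10, children_per_cluster = 100,
                           rho = 1, p_missing = 0, cluster_sd = 0, seed = 11)
  sv <- generate_survey(cfg)
  latent <- (sv$muac_mm - cfg$muac_beta0 - cfg$muac_beta_age * sv$age_months -
               cfg$muac_beta_male * (sv$sex == "m")) / cfg$muac_sigma
  keep <- sv$muac_mm > 80  # the floor censors the extreme left tail
  expect_equal(suppressWarnings(
    cor(sv$whz_sim[keep], latent[keep], method = "spearman")), 1)
})

test_that("simulated records honour the survey schema and ranges", {
  cfg <- simulation_config(n_clusters = 12, children_per_cluster = 20,
                           p_missing = 0, seed = 3,
                           reference_table = synthetic_lms_table())
  sv <- generate_survey(cfg)
  expect_equal(nrow(sv), 240)
  expect_true(all(sv$age_months >= 6 & sv$age_months < 60))
  expect_true(all(sv$sex %in% c("f", "m")))
  expect_true(all(sv$muac_mm >= 80))
  expect_equal(length(unique(sv$cluster_id)), 12)
})

test_that("emitted weight and height reproduce the simulated WHZ", {
  tab <- synthetic_lms_table()
  cfg <- simulation_config(n_clusters = 10, children_per_cluster = 40,
                           p_missing = 0, seed = 21, reference_table = tab)
  sv <- generate_survey(cfg)
  cleaned <- clean_records(sv, tab)
  keep <- cleaned$exclusion_reason == "none"
  expect_equal(cleaned$whz[keep], sv$whz_sim[keep], tolerance = 1e-6)
})

test_that("analytic category probabilities are a proper distribution", {
  for (rho in c(-0.4, 0, 0.6, 0.95)) {
    cfg <- simulation_config(rho = rho, p_missing = 0, cluster_sd = 0)
    pr <- expected_category_probabilities(cfg, fixed_age = 24,
                                          fixed_sex = "f")
    expect_equal(sum(pr), 1, tolerance = 1e-10)
    expect_true(all(pr >= 0))
  }
  bad <- simulation_config(p_missing = 0.1, cluster_sd = 0)
  expect_error(expected_category_probabilities(bad, 24, "f"),
               "requires p_missing")
})

test_that("universal oedema forces SAM, split by the severe WHZ tail", {
  cfg <- simulation_config(p_oedema = 1, p_missing = 0, cluster_sd = 0)
  pr <- expected_category_probabilities(cfg, 24, "f")
  p_sev <- pnorm(-3, cfg$mu_whz, cfg$sigma_whz)
  expect_equal(unname(pr["IGNORED_RISK_SAM"] +
                        pr["CORRECTLY_DETECTED_SAM"]), 1)
  expect_equal(unname(pr["IGNORED_RISK_SAM"]), p_sev, tolerance = 1e-9)
})

test_that("at rho = 0 rectangle probabilities factor into univariate tails", {
  cfg <- simulation_config(rho = 0, p_oedema = 0, p_missing = 0,
                           cluster_sd = 0)
  age <- 30
  base <- cfg$muac_beta0 + cfg$muac_beta_age * age
  pr <- expected_category_probabilities(cfg, age, "f")
  p_whz_sev <- pnorm(-3, cfg$mu_whz, cfg$sigma_whz)
  p_muac_ok <- 1 - pnorm(125, base, cfg$muac_sigma)
  expect_equal(unname(pr["EXCLUDED_SAM"]), p_whz_sev * p_muac_ok,
               tolerance = 1e-9)
  p_mam_whz <- pnorm(-2, cfg$mu_whz, cfg$sigma_whz) - p_whz_sev
  expect_equal(unname(pr["EXCLUDED_MAM"]), p_mam_whz * p_muac_ok,
               tolerance = 1e-9)
})

test_that("empirical category proportions match the analytic oracle", {
  # age/sex effects switched off so one oracle covers all children
  cfg <- simulation_config(n_clusters = 100, children_per_cluster = 150,
                           muac_beta0 = 145, muac_beta_age = 0,
                           muac_beta_male = 0, p_missing = 0, cluster_sd = 0,
                           seed = 17, reference_table = synthetic_lms_table())
  sv <- generate_survey(cfg)
  cl <- classify_children(clean_records(sv, cfg$reference_table))
  keep <- cl$exclusion_reason == "none"
  emp <- table(factor(cl$scenario_category[keep],
                      levels = scenario_levels)) / sum(keep)
  want <- expected_category_probabilities(cfg, 24, "f")
  n <- sum(keep)
  for (lv in scenario_levels) {
    se <- sqrt(want[[lv]] * (1 - want[[lv]]) / n)
    expect_lt(abs(emp[[lv]] - want[[lv]]), 3 * se + 1e-12, label = lv)
  }
})

test_that("weaker WHZ-MUAC correlation increases exclusion", {
  excluded_frac <- sapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    cfg <- simulation_config(n_clusters = 200, children_per_cluster = 250,
                             rho = rho, p_missing = 0, cluster_sd = 0,
                             seed = 31)
    sv <- generate_survey(cfg)
    cat <- assign_scenario_category(sv$whz_sim, sv$muac_mm, sv$oedema)
    mean(cat %in% c("EXCLUDED_SAM", "EXCLUDED_MAM"))
  })
  expect_true(all(diff(excluded_frac) < 0))
})

test_that("missingness erases fields at the configured rate", {
  cfg <- simulation_config(n_clusters = 50, children_per_cluster = 100,
                           p_missing = 0.2, seed = 13)
  sv <- generate_survey(cfg)
  for (col in c("age_months", "sex", "muac_mm", "oedema")) {
    # 3 binomial SEs at n = 5000
    expect_lt(abs(mean(is.na(sv[[col]])) - 0.2), 0.017)
  }
  expect_false(anyNA(sv$whz_sim))  # simulation truth is never erased
})
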