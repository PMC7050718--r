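#' Configuration for the two-stage cluster-survey simulator
#'
#' Bundles and validates the parameters of the synthetic survey generator.
#' The defaults are the package's "table1-like" preset: a field-survey-like
#' population with SAM-by-any-criterion prevalence near 3.7% and MAM near
#' 13%, partial overlap between weight-for-height and MUAC deficits, MUAC
#' increasing with age and slightly higher in boys, rare oedema, modest
#' cluster-level heterogeneity and sparse missingness.
#'
#' @param n_clusters Number of clusters (default 30).
#' @param children_per_cluster Children sampled per cluster (default 20).
#' @param mu_whz,sigma_whz Mean and SD of the WHZ distribution (z units).
#' @param mu_muacz,sigma_muacz Mean and SD of the latent MUAC deviation
#'   (z units).
#' @param rho Correlation between the WHZ and latent MUAC deviations,
#'   in `[-1, 1]`; lower values mean less overlap between the two deficits.
#' @param muac_beta0 MUAC intercept (mm).
#' @param muac_beta_age MUAC slope per month of age (mm/month).
#' @param muac_beta_male Additive MUAC shift for boys (mm).
#' @param muac_sigma Residual MUAC scale (mm per latent z unit).
#' @param p_oedema Probability of nutritional oedema (independent of
#'   anthropometry).
#' @param p_missing Per-field probability that a recorded value is missing.
#' @param cluster_sd SD of the shared cluster-level shift added to both
#'   latent means (z units).
#' @param seed Integer seed; the whole survey is reproducible from it.
#' @param age_distribution `"uniform"` on `[6, 60)` months, or `"piecewise"`
#'   (45% of mass on 6-23.99 months, echoing the younger-skewed age pyramids
#'   of high-burden settings).
#' @param reference_table Optional `growth_reference`; when supplied the
#'   generator emits height (from a fixed stylized age-height curve) and a
#'   weight chosen so that the emitted pair reproduces the simulated WHZ.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_clusters = 30, children_per_cluster = 20,
                              mu_whz = -0.65, sigma_whz = 1.18,
                              mu_muacz = 0, sigma_muacz = 1, rho = 0.75,
                              muac_beta0 = 129.5, muac_beta_age = 0.35,
                              muac_beta_male = 3, muac_sigma = 11.5,
                              p_oedema = 0.003, p_missing = 0.01,
                              cluster_sd = 0.2, seed = 1L,
                              age_distribution = c("uniform", "piecewise"),
                              reference_table = NULL) {
  age_distribution <- match.arg(age_distribution)
  cfg <- list(n_clusters = as.integer(n_clusters),
              children_per_cluster = as.integer(children_per_cluster),
              mu_whz = mu_whz, sigma_whz = sigma_whz, mu_muacz = mu_muacz,
              sigma_muacz = sigma_muacz, rho = rho, muac_beta0 = muac_beta0,
              muac_beta_age = muac_beta_age, muac_beta_male = muac_beta_male,
              muac_sigma = muac_sigma, p_oedema = p_oedema,
              p_missing = p_missing, cluster_sd = cluster_sd,
              seed = as.integer(seed), age_distribution = age_distribution,
              reference_table = reference_table)
  if (cfg$n_clusters < 1 || cfg$children_per_cluster < 1) {
    stop("simulation_config: counts must be >= 1", call. = FALSE)
  }
  if (cfg$sigma_whz < 0 || cfg$sigma_muacz < 0 || cfg$muac_sigma < 0 ||
      cfg$cluster_sd < 0) {
    stop("simulation_config: standard deviations must be >= 0", call. = FALSE)
  }
  if (abs(cfg$rho) > 1) {
    stop("simulation_config: |rho| must be <= 1", call. = FALSE)
  }
  for (p in c("p_oedema", "p_missing")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop("simulation_config: ", p, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(reference_table) &&
      !inherits(reference_table, "growth_reference")) {
    stop("simulation_config: reference_table must be a growth_reference",
         call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

# stylized median height-for-age curve (cm) keeping simulated 6-59-month
# children inside the synthetic reference grid
height_for_age <- function(age_months) 68 + 0.72 * age_months

#' Simulate a two-stage cluster survey of children 6-59 months
#'
#' Draws `n_clusters` clusters, each with a shared Gaussian shift applied to
#' both latent means (environmental heterogeneity), then
#' `children_per_cluster` children per cluster with:
#' age from the configured distribution on `[6, 60)`; sex by fair coin;
#' `(WHZ, MUAC deviation)` bivariate normal with correlation `rho`;
#' MUAC (mm) from a linear age/sex model plus the scaled latent deviation,
#' floored at 80 mm; oedema Bernoulli, independent of anthropometry; and each
#' recorded field erased independently with probability `p_missing`. When a
#' reference table is configured, height and weight are emitted such that the
#' weight-for-height computation recovers the simulated WHZ.
#'
#' @param config A [simulation_config()].
#' @param survey_id Survey identifier written into every record.
#' @return Data frame in the survey schema (`survey_id`, `cluster_id`,
#'   `age_months`, `sex`, `weight_kg`, `height_cm`, `muac_mm`, `oedema`) plus
#'   a `whz_sim` column carrying the simulated true WHZ (never erased; for
#'   validation only).
#' @export
generate_survey <- function(config, survey_id = "S1") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_per <- config$children_per_cluster
  n <- config$n_clusters * n_per
  cluster_id <- rep(seq_len(config$n_clusters), each = n_per)
  shift <- rep(stats::rnorm(config$n_clusters, 0, config$cluster_sd),
               each = n_per)
  age <- if (config$age_distribution == "uniform") {
    stats::runif(n, 6, 60)
  } else {
    young <- stats::runif(n) < 0.45
    ifelse(young, stats::runif(n, 6, 24), stats::runif(n, 24, 60))
  }
  sex <- ifelse(stats::runif(n) < 0.5, "f", "m")
  z1 <- stats::rnorm(n)
  z2 <- config$rho * z1 + sqrt(1 - config$rho^2) * stats::rnorm(n)
  whz <- config$mu_whz + shift + config$sigma_whz * z1
  muac_z <- config$mu_muacz + shift + config$sigma_muacz * z2
  muac <- config$muac_beta0 + config$muac_beta_age * age +
    config$muac_beta_male * (sex == "m") + config$muac_sigma * muac_z
  muac <- pmax(muac, 80)
  oedema <- stats::runif(n) < config$p_oedema
  if (!is.null(config$reference_table)) {
    height <- height_for_age(age)
    weight <- invert_whz(whz, height, sex, config$reference_table)
  } else {
    height <- rep(NA_real_, n)
    weight <- rep(NA_real_, n)
  }
  out <- data.frame(survey_id = survey_id, cluster_id = cluster_id,
                    age_months = age, sex = sex, weight_kg = weight,
                    height_cm = height, muac_mm = muac, oedema = oedema,
                    whz_sim = whz)
  if (config$p_missing > 0) {
    for (col in c("age_months", "sex", "weight_kg", "height_cm", "muac_mm",
                  "oedema")) {
      erase <- stats::runif(n) < config$p_missing
      out[[col]][erase] <- NA
    }
  }
  out
}

#' Analytic expected scenario-category probabilities
#'
#' Exact category probabilities implied by the simulator's joint model for a
#' child of fixed age and sex, with no cluster heterogeneity or missingness:
#' the WHZ thresholds (-3, -2) and the MUAC thresholds (115, 125 mm, mapped
#' back to the latent scale through the linear age/sex model) cut the
#' bivariate normal into nine rectangles whose probabilities (computed with
#' `mvtnorm::pmvnorm`) are routed to categories by the classification rules,
#' then mixed with the independent oedema probability (oedema forces SAM:
#' ignored-risk when WHZ < -3, correctly-detected otherwise). Serves as the
#' oracle for Monte-Carlo parameter-recovery checks of the full pipeline.
#'
#' @param config A [simulation_config()] with `p_missing = 0` and
#'   `cluster_sd = 0`.
#' @param fixed_age Age in months.
#' @param fixed_sex `"f"` or `"m"`.
#' @return Named numeric vector over [scenario_levels]; sums to 1.
#' @export
expected_category_probabilities <- function(config, fixed_age, fixed_sex) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$p_missing != 0 || config$cluster_sd != 0) {
    stop("expected_category_probabilities: requires p_missing = 0 and ",
         "cluster_sd = 0", call. = FALSE)
  }
  base <- config$muac_beta0 + config$muac_beta_age * fixed_age +
    config$muac_beta_male * (fixed_sex == "m")
  t115 <- (115 - base) / config$muac_sigma
  t125 <- (125 - base) / config$muac_sigma
  whz_cut <- c(-Inf, -3, -2, Inf)
  muac_cut <- c(-Inf, t115, t125, Inf)
  cell <- matrix(0, 3, 3)  # rows: whz bin; cols: muac bin
  for (i in 1:3) {
    for (j in 1:3) {
      cell[i, j] <- bvn_rect(
        lower = c(whz_cut[i], muac_cut[j]),
        upper = c(whz_cut[i + 1], muac_cut[j + 1]),
        mean = c(config$mu_whz, config$mu_muacz),
        sd = c(config$sigma_whz, config$sigma_muacz), rho = config$rho)
    }
  }
  p_oe <- config$p_oedema
  p_whz_lt3 <- sum(cell[1, ])
  pr <- stats::setNames(numeric(length(scenario_levels)), scenario_levels)
  pr["IGNORED_RISK_SAM"] <- p_oe * p_whz_lt3 + (1 - p_oe) * cell[1, 1]
  pr["CORRECTLY_DETECTED_SAM"] <- p_oe * (1 - p_whz_lt3) +
    (1 - p_oe) * (cell[2, 1] + cell[3, 1])
  pr["UNDERESTIMATED_SAM"] <- (1 - p_oe) * cell[1, 2]
  pr["EXCLUDED_SAM"] <- (1 - p_oe) * cell[1, 3]
  pr["INCLUDED_MAM"] <- (1 - p_oe) * (cell[2, 2] + cell[3, 2])
  pr["EXCLUDED_MAM"] <- (1 - p_oe) * cell[2, 3]
  pr["NOT_A_CASE"] <- (1 - p_oe) * cell[3, 3]
  pr / sum(pr)
}

# rectangle probability of a bivariate normal; comonotone/antimonotone
# limits handled by collapsing onto the first coordinate
bvn_rect <- function(lower, upper, mean, sd, rho) {
  if (abs(rho) > 0.9999) {
    # x2 is a deterministic monotone map of x1: intersect the two intervals
    # on the x1 scale
    s <- sign(rho)
    to_x1 <- function(x2) mean[1] + s * sd[1] * (x2 - mean[2]) / sd[2]
    b1 <- sort(c(to_x1(lower[2]), to_x1(upper[2])))
    lo <- max(lower[1], b1[1])
    hi <- min(upper[1], b1[2])
    if (hi <= lo) return(0)
    return(stats::pnorm(hi, mean[1], sd[1]) - stats::pnorm(lo, mean[1], sd[1]))
  }
  sigma <- matrix(c(sd[1]^2, rho * sd[1] * sd[2],
                    rho * sd[1] * sd[2], sd[2]^2), 2, 2)
  as.numeric(mvtnorm::pmvnorm(lower = lower, upper = upper, mean = mean,
                              sigma = sigma,
                              algorithm = mvtnorm::GenzBretz(abseps = 1e-10)))
}
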