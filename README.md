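# muactarget

Community management of acute malnutrition currently identifies children
6–59 months as cases by *either* of two independent anthropometric criteria —
weight-for-height z-score (WHZ, against the WHO 2006 growth standards) or
mid-upper arm circumference (MUAC) — plus nutritional oedema. A widely piloted
simplification, the **"expanded MUAC-only" program**, drops WHZ entirely:
every child with MUAC < 125 mm or oedema is enrolled, severity is tiered at
MUAC 115 mm, and both moderate (MAM) and severe (SAM) cases receive
ready-to-use therapeutic food (RUTF). Because the WHZ- and MUAC-defined case
populations overlap only partially, this policy re-targets treatment:
some severe cases are never detected, some are managed as moderate, and the
RUTF-receiving population changes size and composition.

`muactarget` is an R package for nutrition-survey analysts and program
planners that quantifies these consequences from standard cross-sectional
cluster-survey data. It implements:

- **WHZ computation** by the LMS method, `z = ((W/M)^L − 1)/(L·S)` with
  sex-specific coefficients interpolated on height, including the WHO
  "restricted" adjustment that linearizes the scale beyond ±3 SD
  (anchored on the ±2/±3 SD curves), ±5 z-score flagging, and the standard
  exclusions (missing fields, age outside 6.0–59.99 months);
- **WHO case definitions**: SAM = MUAC < 115 mm ∨ WHZ < −3 ∨ oedema;
  MAM = (115 ≤ MUAC < 125 ∨ −3 ≤ WHZ < −2) ∧ ¬SAM; GAM = SAM ∪ MAM;
- a mutually exclusive **targeting taxonomy** under MUAC-only admission:
  *Excluded SAM* (WHZ < −3, MUAC ≥ 125, no oedema), *Underestimated SAM*
  (WHZ < −3, 115 ≤ MUAC < 125, treated as MAM), *Ignored-Risk SAM*
  (WHZ < −3 with MUAC < 115 or oedema — admitted, but the concurrent
  weight-for-height deficit goes unmeasured), *Correctly Detected SAM*,
  and *Excluded* / *Included MAM*;
- **count-first aggregation**: child counts are pooled across surveys,
  countries and regions before any proportion is formed, then turned into
  the targeting metrics, including the **RUTF allocation increase** =
  (children with MUAC < 125 mm or oedema) / (children meeting any SAM
  criterion), and the age/sex composition of every category;
- a **two-stage cluster-survey simulator** with a controllable joint
  (WHZ, MUAC) distribution and an exact bivariate-normal category-probability
  oracle, so the whole pipeline is testable although real survey microdata
  of this kind are typically restricted.

## Worked example

Simulate a district survey (the default preset emulates a high-burden
population with ~3.7% SAM), run the full pipeline, and read the overall
report:

```r
library(muactarget)

ref    <- synthetic_lms_table()   # users substitute real WHO LMS tables
cfg    <- simulation_config(n_clusters = 35, children_per_cluster = 18,
                            seed = 2024, reference_table = ref)
survey <- generate_survey(cfg, survey_id = "DISTRICT_A")
res    <- run_pipeline(pipeline_config(survey = survey, reference = ref))
#> [pipeline] read 630 child records from 1 survey(s)
#> [pipeline] retained 586; excluded 44 missing-field, 0 age-out-of-range, 0 WHZ-flagged

res$reports$overall[, c("sam_all_pct", "excluded_sam_pct",
                        "underestimated_sam_pct", "ignored_risk_sam_pct",
                        "correctly_detected_sam_pct",
                        "rutf_allocation_increase")]
#>  sam_all_pct excluded_sam_pct underestimated_sam_pct ignored_risk_sam_pct
#>          2.6             13.3                   26.7                 26.7
#>  correctly_detected_sam_pct rutf_allocation_increase
#>                        33.3                     3.33
```

Reading: 2.6% of the 586 analyzable children are SAM by any criterion. Under
MUAC-only admission, 13.3% of those severe cases would never be detected,
26.7% would be admitted but managed as moderate cases, and a further 26.7%
would be treated without their severe weight-for-height deficit being known;
the population receiving RUTF would grow 3.33-fold, because all
moderate-by-MUAC children join the therapeutic-food target. (One simulated
district is noisy — pooled multi-survey runs give stabler splits.)

With many surveys, add a `grouping` CSV (`survey_id,country,region`) to get
country- and region-level reports, written as rounded CSV plus unrounded
JSON mirrors by `run_pipeline()` when `out_dir` is set.

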