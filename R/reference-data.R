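#' Published OAI reference-cohort T2 summary statistics
#'
#' Group-level summary statistics (mean, SD, group size) of layer-specific
#' femorotibial cartilage T2 from a published OAI-based early-osteoarthritis
#' study of three right-knee groups: `riskROA` (no radiographic OA, but OA
#' risk factors and a contralateral knee with a definite osteophyte),
#' `earlyROA` (definite osteophyte, no joint space narrowing) and `healthy`
#' (OAI non-exposed reference cohort). These printed summaries are shipped as
#' *inputs*: they parameterize the synthetic cohort generator and the
#' summary-statistic reproduction of the study's group contrasts.
#'
#' @param level `"avg"` for values averaged over the four femorotibial
#'   plates (the primary analysis), or `"plate"` for per-plate baseline
#'   values.
#' @return A data frame. For `level = "avg"`: one row per group x layer with
#'   columns `group`, `layer`, `n`, `baseline_mean`, `baseline_sd`,
#'   `n_followup`, `change_mean`, `change_sd` (T2 in ms; change is year-1
#'   minus baseline). For `level = "plate"`: `group`, `plate`, `layer`,
#'   `baseline_mean`, `baseline_sd`.
#' @seealso [oai_demographics()], [oai_cohort_spec()]
#' @export
oai_t2_reference <- function(level = c("avg", "plate")) {
  level <- match.arg(level)
  if (level == "avg") {
    return(data.frame(
      group = rep(c("riskROA", "earlyROA", "healthy"), each = 2),
      layer = rep(c("deep", "superficial"), 3),
      n = rep(c(28L, 32L, 89L), each = 2),
      baseline_mean = c(37.3, 48.1, 37.3, 48.0, 35.8, 45.4),
      baseline_sd = c(1.8, 3.1, 2.5, 3.5, 1.8, 2.3),
      n_followup = rep(c(26L, 24L, 89L), each = 2),
      change_mean = c(0.0, -0.4, -0.2, -0.1, 0.8, 0.5),
      change_sd = c(1.7, 1.8, 1.1, 1.5, 1.3, 1.4),
      stringsAsFactors = FALSE
    ))
  }
  plates <- c("MT", "cMF", "LT", "cLF")
  data.frame(
    group = rep(c("riskROA", "earlyROA", "healthy"), each = 8),
    plate = rep(rep(plates, each = 2), 3),
    layer = rep(c("deep", "superficial"), 12),
    baseline_mean = c(
      34.0, 43.6, 41.8, 52.8, 32.0, 45.5, 41.2, 50.5,   # riskROA
      33.3, 43.4, 42.5, 53.4, 32.5, 44.5, 40.8, 50.7,   # earlyROA
      33.0, 41.6, 39.3, 49.6, 31.0, 42.4, 39.7, 48.1),  # healthy
    baseline_sd = c(
      1.8, 2.5, 3.8, 5.8, 1.4, 3.6, 2.8, 4.1,
      1.8, 2.9, 5.9, 6.0, 2.1, 4.3, 3.2, 4.0,
      1.9, 2.9, 3.4, 3.8, 1.9, 2.6, 2.8, 2.9),
    stringsAsFactors = FALSE
  )
}

#' Published OAI reference-cohort demographics
#'
#' Baseline demographics of the three groups (see [oai_t2_reference()]):
#' group sizes, age, body-mass index and sex composition. Used to give the
#' synthetic cohort the covariate structure of the source cohort, including
#' the age/BMI imbalance between the healthy reference group and the two
#' risk-factor-exposed groups.
#'
#' @return A data frame with one row per group: `group`, `n`, `n_followup`,
#'   `age_mean`, `age_sd` (years), `bmi_mean`, `bmi_sd` (kg/m^2),
#'   `female_fraction`.
#' @export
oai_demographics <- function() {
  data.frame(
    group = c("riskROA", "earlyROA", "healthy"),
    n = c(28L, 32L, 89L),
    n_followup = c(26L, 24L, 89L),
    age_mean = c(61.1, 60.2, 55.0),
    age_sd = c(9.4, 10.0, 7.5),
    bmi_mean = c(28.0, 27.6, 24.4),
    bmi_sd = c(5.0, 4.6, 3.1),
    female_fraction = c(0.500, 0.563, 0.596),
    stringsAsFactors = FALSE
  )
}
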