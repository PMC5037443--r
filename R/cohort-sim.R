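#' Specify a synthetic subject cohort
#'
#' Describes a three-group cohort (riskROA, earlyROA, healthy) with
#' group-level distributions of age, BMI, sex, and per-layer baseline T2 and
#' one-year T2 change. [generate_synthetic_cohort()] draws subject-level
#' records from these distributions.
#'
#' @param groups Named list, one element per group. Each element is a list
#'   with fields `n`, `n_followup` (subjects with a year-1 visit,
#'   `<= n`), `age_mean`, `age_sd`, `bmi_mean`, `bmi_sd`,
#'   `female_fraction`, and `t2`: a named list with elements `superficial`
#'   and `deep`, each `c(baseline_mean, baseline_sd, change_mean,
#'   change_sd)`.
#' @param covariate_effects Linear coefficients of the covariates on T2 (all
#'   layers), `c(age = , sex = , bmi = )` in ms per year, ms for female sex,
#'   and ms per kg/m^2. Default all zero (T2 independent of covariates).
#'   Age and BMI are centered at `age_ref`/`bmi_ref` before the effect is
#'   applied, so group T2 means are shifted by the effect of the group's
#'   covariate imbalance relative to the reference point.
#' @param age_ref,bmi_ref Centering constants for the covariate effects.
#' @param baseline_change_cor Correlation between a subject's baseline T2
#'   deviation and their one-year change (default 0: change drawn
#'   independently of baseline).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @seealso [oai_cohort_spec()] for the specification matching the published
#'   reference cohort.
#' @export
cohort_spec <- function(groups, covariate_effects = c(age = 0, sex = 0, bmi = 0),
                        age_ref = 55, bmi_ref = 25,
                        baseline_change_cor = 0, seed = 1L) {
  stop_if_not(is.list(groups) && length(groups) >= 1 &&
                !is.null(names(groups)), "groups must be a named list")
  for (g in names(groups)) {
    gr <- groups[[g]]
    stop_if_not(is.numeric(gr$n) && gr$n >= 2,
                "group '%s': n must be >= 2 (downstream variance undefined)", g)
    stop_if_not(gr$n_followup <= gr$n && gr$n_followup >= 0,
                "group '%s': n_followup must be in [0, n]", g)
    stop_if_not(gr$age_sd >= 0 && gr$bmi_sd >= 0,
                "group '%s': SDs must be nonnegative", g)
    stop_if_not(gr$female_fraction >= 0 && gr$female_fraction <= 1,
                "group '%s': female_fraction must be in [0,1]", g)
    for (lay in c("superficial", "deep")) {
      v <- gr$t2[[lay]]
      stop_if_not(length(v) == 4 && v[2] >= 0 && v[4] >= 0,
                  "group '%s' layer '%s': t2 must be (baseline_mean, baseline_sd, change_mean, change_sd) with SDs >= 0",
                  g, lay)
    }
  }
  stop_if_not(all(c("age", "sex", "bmi") %in% names(covariate_effects)),
              "covariate_effects must name age, sex and bmi")
  stop_if_not(abs(baseline_change_cor) <= 1,
              "baseline_change_cor must be in [-1,1]")
  structure(list(groups = groups,
                 covariate_effects = covariate_effects,
                 age_ref = age_ref, bmi_ref = bmi_ref,
                 baseline_change_cor = baseline_change_cor,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Cohort specification matching the published reference cohort
#'
#' Builds a [cohort_spec()] whose group sizes, demographics and per-layer T2
#' distributions are the published summary statistics returned by
#' [oai_t2_reference()] and [oai_demographics()] (riskROA n = 28, earlyROA
#' n = 32, healthy n = 89). These defaults are the study conditions; they
#' are not tuning knobs.
#'
#' @inheritParams cohort_spec
#' @return A `cohort_spec`.
#' @examples
#' cohort <- generate_synthetic_cohort(oai_cohort_spec(seed = 7))
#' table(cohort$group[cohort$visit == "baseline" & cohort$layer == "deep"])
#' @export
oai_cohort_spec <- function(covariate_effects = c(age = 0, sex = 0, bmi = 0),
                            age_ref = 55, bmi_ref = 25,
                            baseline_change_cor = 0, seed = 1L) {
  dem <- oai_demographics()
  t2 <- oai_t2_reference("avg")
  groups <- lapply(seq_len(nrow(dem)), function(i) {
    g <- dem$group[i]
    lay <- function(l) {
      r <- t2[t2$group == g & t2$layer == l, ]
      c(r$baseline_mean, r$baseline_sd, r$change_mean, r$change_sd)
    }
    list(n = dem$n[i], n_followup = dem$n_followup[i],
         age_mean = dem$age_mean[i], age_sd = dem$age_sd[i],
         bmi_mean = dem$bmi_mean[i], bmi_sd = dem$bmi_sd[i],
         female_fraction = dem$female_fraction[i],
         t2 = list(superficial = lay("superficial"), deep = lay("deep")))
  })
  names(groups) <- dem$group
  cohort_spec(groups, covariate_effects = covariate_effects,
              age_ref = age_ref, bmi_ref = bmi_ref,
              baseline_change_cor = baseline_change_cor, seed = seed)
}

#' Generate a synthetic subject cohort
#'
#' Draws one record per subject, visit and cartilage layer from the
#' distributions in a [cohort_spec()]. Baseline T2 is normal with the group
#' x layer mean/SD; the year-1 value adds an independently drawn normal
#' change (optionally correlated with the baseline deviation); covariate
#' effects of age, sex and BMI are added linearly to both visits. Only the
#' first `n_followup` subjects of each group receive year-1 rows, so
#' follow-up subjects are a subset of baseline subjects.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame (the cohort table) with columns `subject_id`,
#'   `group`, `age`, `sex` (`"male"`/`"female"`), `bmi`, `visit`
#'   (`"baseline"`/`"year1"`), `plate` (`"Avg"`), `layer`, `t2_ms`.
#' @export
generate_synthetic_cohort <- function(spec) {
  stop_if_not(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  eff <- spec$covariate_effects
  with_seed(spec$seed, {
    out <- lapply(names(spec$groups), function(g) {
      gr <- spec$groups[[g]]
      n <- gr$n
      age <- stats::rnorm(n, gr$age_mean, gr$age_sd)
      bmi <- stats::rnorm(n, gr$bmi_mean, gr$bmi_sd)
      female <- stats::runif(n) < gr$female_fraction
      shift <- eff[["age"]] * (age - spec$age_ref) +
        eff[["sex"]] * as.numeric(female) +
        eff[["bmi"]] * (bmi - spec$bmi_ref)
      id <- sprintf("%s_%03d", g, seq_len(n))
      per_layer <- lapply(c("superficial", "deep"), function(lay) {
        p <- gr$t2[[lay]]
        z_base <- stats::rnorm(n)
        base <- p[1] + p[2] * z_base + shift
        rho <- spec$baseline_change_cor
        z_chg <- rho * z_base + sqrt(1 - rho^2) * stats::rnorm(n)
        chg <- p[3] + p[4] * z_chg
        fu <- seq_len(n) <= gr$n_followup
        bl_rows <- data.frame(subject_id = id, group = g, age = age,
                              sex = ifelse(female, "female", "male"),
                              bmi = bmi, visit = "baseline", plate = "Avg",
                              layer = lay, t2_ms = base,
                              stringsAsFactors = FALSE)
        if (!any(fu)) return(bl_rows)
        y1_rows <- bl_rows[fu, ]
        y1_rows$visit <- "year1"
        y1_rows$t2_ms <- (base + chg)[fu]
        rbind(bl_rows, y1_rows)
      })
      do.call(rbind, per_layer)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
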