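#' Cohen's d from group summary statistics
#'
#' Standardized mean difference `(mean_a - mean_b) / s_p` with the pooled
#' standard deviation
#' `s_p = sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a+n_b-2))`.
#' No small-sample (Hedges) correction is applied.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summary statistics.
#' @return The effect size (a single number).
#' @export
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stop_if_not(sd_a >= 0 && sd_b >= 0, "SDs must be nonnegative")
  stop_if_not(n_a >= 2 && n_b >= 2, "need n >= 2 per group")
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (sp == 0) {
    if (mean_a == mean_b) return(0)
    stop("effect size undefined: pooled SD is 0 with unequal means",
         call. = FALSE)
  }
  (mean_a - mean_b) / sp
}

comparison_result <- function(mean_diff, ci, p, d, n_a, n_b,
                              adjusted = FALSE, family_size = 6) {
  structure(list(mean_diff_ms = unname(mean_diff),
                 ci95 = as.numeric(ci), p_value = unname(p), cohens_d = d,
                 n_a = n_a, n_b = n_b, adjusted = adjusted,
                 significant_bonferroni = significance_flag(p, family_size)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> diff = %.2f ms, 95%% CI [%.2f, %.2f], p = %.3g, d = %.2f%s%s\n",
              x$mean_diff_ms, x$ci95[1], x$ci95[2], x$p_value,
              if (is.na(x$cohens_d)) NA else x$cohens_d,
              if (x$adjusted) " (adjusted)" else "",
              if (x$significant_bonferroni) " *" else ""))
  invisible(x)
}

#' Between-group comparison from summary statistics
#'
#' Pooled-variance (Student) two-sample inference computed directly from
#' group means, SDs and sizes: mean difference (A minus B), its 95%
#' confidence interval, the two-sided p-value, and Cohen's d. This lets
#' published "mean +/- SD (n)" cells be turned into the exact printed
#' contrasts without subject-level data. `welch = TRUE` uses the
#' Welch-Satterthwaite variance and degrees of freedom instead (effect size
#' still uses the pooled SD).
#'
#' @inheritParams cohens_d
#' @param conf Confidence level (default 0.95).
#' @param welch Use the Welch (unequal-variance) form.
#' @param family_size Bonferroni family size for the significance flag
#'   (default 6: 3 group pairs x 2 layers).
#' @return A list of class `comparison_result` with `mean_diff_ms`, `ci95`,
#'   `p_value`, `cohens_d`, `n_a`, `n_b`, `adjusted`,
#'   `significant_bonferroni`.
#' @examples
#' # healthy vs riskROA, superficial layer, from published summaries
#' comparison_from_summary(45.4, 2.3, 89, 48.1, 3.1, 28)
#' @export
comparison_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                    conf = 0.95, welch = FALSE,
                                    family_size = 6) {
  stop_if_not(sd_a >= 0 && sd_b >= 0, "SDs must be nonnegative")
  stop_if_not(n_a >= 2 && n_b >= 2, "need n >= 2 per group")
  diff <- mean_a - mean_b
  if (welch) {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  if (se == 0) {
    p <- if (diff == 0) 1 else 0
    ci <- c(diff, diff)
  } else {
    t_stat <- diff / se
    p <- 2 * stats::pt(-abs(t_stat), df)
    ci <- diff + c(-1, 1) * stats::qt(1 - (1 - conf) / 2, df) * se
  }
  d <- tryCatch(cohens_d(mean_a, sd_a, n_a, mean_b, sd_b, n_b),
                error = function(e) NA_real_)
  comparison_result(diff, ci, p, d, n_a, n_b, adjusted = FALSE,
                    family_size = family_size)
}

#' Crude between-group comparison from subject-level values
#'
#' Unpaired two-sided t-test of group A versus group B. The default is the
#' pooled-variance Student test; `welch = TRUE` switches to the Welch test.
#' Cohen's d uses the pooled SD of the two samples.
#'
#' @param values_a,values_b Numeric vectors of subject-level values
#'   (length >= 2 each).
#' @inheritParams comparison_from_summary
#' @return A `comparison_result` (see [comparison_from_summary()]).
#' @export
crude_group_difference <- function(values_a, values_b, conf = 0.95,
                                   welch = FALSE, family_size = 6) {
  stop_if_not(length(values_a) >= 2 && length(values_b) >= 2,
              "need at least 2 values per group")
  sda <- stats::sd(values_a); sdb <- stats::sd(values_b)
  if (sda == 0 && sdb == 0) {
    return(comparison_from_summary(mean(values_a), 0, length(values_a),
                                   mean(values_b), 0, length(values_b),
                                   conf = conf, welch = welch,
                                   family_size = family_size))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = !welch,
                      conf.level = conf)
  d <- tryCatch(cohens_d(mean(values_a), sda, length(values_a),
                         mean(values_b), sdb, length(values_b)),
                error = function(e) NA_real_)
  comparison_result(unname(diff(rev(tt$estimate))), tt$conf.int,
                    tt$p.value, d, length(values_a), length(values_b),
                    adjusted = FALSE, family_size = family_size)
}

#' Covariate-adjusted group difference (ANCOVA)
#'
#' Ordinary-least-squares model `t2 ~ group + age + sex + bmi` fitted to the
#' two requested groups at one visit, plate and layer. The adjusted group
#' difference is the model's group coefficient (first group minus second),
#' with its 95% confidence interval and p-value. Sex enters as a 0/1
#' indicator (female = 1); no interactions.
#'
#' @param cohort Cohort table (see [generate_synthetic_cohort()]).
#' @param plate,layer,visit Outcome selectors.
#' @param groups Length-2 character vector; the difference reported is
#'   `groups[1] - groups[2]`.
#' @param covariates Subset of `c("age", "sex", "bmi")`.
#' @param family_size Bonferroni family size for the significance flag.
#' @return A `comparison_result` with `adjusted = TRUE`.
#' @export
ancova_adjusted_difference <- function(cohort, plate = "Avg",
                                       layer = c("superficial", "deep"),
                                       groups = c("riskROA", "healthy"),
                                       visit = "baseline",
                                       covariates = c("age", "sex", "bmi"),
                                       family_size = 6) {
  layer <- match.arg(layer)
  stop_if_not(length(groups) == 2, "groups must name exactly two groups")
  stop_if_not(all(covariates %in% c("age", "sex", "bmi")),
              "covariates must be among age, sex, bmi")
  d <- cohort[cohort$plate == plate & cohort$layer == layer &
                cohort$visit == visit & cohort$group %in% groups, ]
  for (g in groups) {
    stop_if_not(sum(d$group == g) >= 2, "group '%s': fewer than 2 subjects", g)
  }
  stop_if_not(!anyDuplicated(d$subject_id),
              "duplicate subject rows for the selected outcome")
  stop_if_not(!anyNA(d[, covariates[covariates != "sex"]]) &&
                !anyNA(d$sex), "covariates must be complete")
  d$group <- factor(d$group, levels = rev(groups))  # coef = groups[1] - groups[2]
  d$sex01 <- as.numeric(d$sex == "female")
  terms <- c("group", sub("^sex$", "sex01", covariates))
  fml <- stats::reformulate(terms, response = "t2_ms")
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient ANCOVA design; collinear terms: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  co <- paste0("group", groups[1])
  est <- stats::coef(fit)[[co]]
  ci <- stats::confint(fit, co, level = 0.95)
  p <- summary(fit)$coefficients[co, "Pr(>|t|)"]
  n_a <- sum(d$group == groups[1]); n_b <- sum(d$group == groups[2])
  res <- comparison_result(est, as.numeric(ci), p, NA_real_, n_a, n_b,
                           adjusted = TRUE, family_size = family_size)
  res$model <- fit
  res
}

change_result <- function(mean_chg, sd_chg, n, conf = 0.95) {
  stop_if_not(n >= 2, "need at least 2 paired subjects")
  se <- sd_chg / sqrt(n)
  if (se == 0) {
    p <- if (mean_chg == 0) 1 else 0
    ci <- c(mean_chg, mean_chg)
  } else {
    t_stat <- mean_chg / se
    p <- 2 * stats::pt(-abs(t_stat), n - 1)
    ci <- mean_chg + c(-1, 1) * stats::qt(1 - (1 - conf) / 2, n - 1) * se
  }
  structure(list(mean_change_ms = mean_chg, sd_change_ms = sd_chg,
                 ci95 = ci, p_value = p, n = n),
            class = "change_result")
}

#' @export
print.change_result <- function(x, ...) {
  cat(sprintf("<change> %.2f +/- %.2f ms, 95%% CI [%.2f, %.2f], p = %.3g, n = %d\n",
              x$mean_change_ms, x$sd_change_ms, x$ci95[1], x$ci95[2],
              x$p_value, x$n))
  invisible(x)
}

#' Within-knee longitudinal change
#'
#' Paired, two-sided t-test of year-1 versus baseline T2 for one group,
#' plate and layer: per-subject change (year1 minus baseline), its mean,
#' SD, one-sample 95% confidence interval and p-value against zero. Only
#' subjects observed at both visits contribute.
#'
#' @inheritParams ancova_adjusted_difference
#' @param group Group label.
#' @return A list of class `change_result`: `mean_change_ms`,
#'   `sd_change_ms`, `ci95`, `p_value`, `n`.
#' @export
paired_change <- function(cohort, group, plate = "Avg",
                          layer = c("superficial", "deep")) {
  layer <- match.arg(layer)
  d <- cohort[cohort$group == group & cohort$plate == plate &
                cohort$layer == layer, ]
  bl <- d[d$visit == "baseline", ]
  y1 <- d[d$visit == "year1", ]
  both <- intersect(bl$subject_id, y1$subject_id)
  stop_if_not(length(both) >= 2,
              "group '%s': fewer than 2 subjects with both visits", group)
  chg <- y1$t2_ms[match(both, y1$subject_id)] -
    bl$t2_ms[match(both, bl$subject_id)]
  change_result(mean(chg), stats::sd(chg), length(both))
}

#' Longitudinal change inference from summary statistics
#'
#' One-sample t inference (95% CI, two-sided p against zero) for a mean
#' change given only its printed mean, SD and n.
#'
#' @param mean_change_ms,sd_change_ms,n Summary statistics of the
#'   per-subject change scores.
#' @return A `change_result` (see [paired_change()]).
#' @examples
#' change_from_summary(0.8, 1.3, 89)  # healthy deep layer
#' @export
change_from_summary <- function(mean_change_ms, sd_change_ms, n) {
  stop_if_not(sd_change_ms >= 0, "SD must be nonnegative")
  change_result(mean_change_ms, sd_change_ms, n)
}

#' Superficial-versus-deep change contrast
#'
#' Tests whether the one-year T2 change differs between the superficial and
#' the deep layer within one group: per subject, the contrast
#' (superficial change minus deep change) is formed and tested against zero
#' with a paired, two-sided t-test.
#'
#' @inheritParams paired_change
#' @return A `change_result` for the per-subject layer contrast.
#' @export
layer_change_contrast <- function(cohort, group, plate = "Avg") {
  per_layer <- lapply(c("superficial", "deep"), function(lay) {
    d <- cohort[cohort$group == group & cohort$plate == plate &
                  cohort$layer == lay, ]
    bl <- d[d$visit == "baseline", ]
    y1 <- d[d$visit == "year1", ]
    both <- intersect(bl$subject_id, y1$subject_id)
    list(ids = both,
         chg = y1$t2_ms[match(both, y1$subject_id)] -
           bl$t2_ms[match(both, bl$subject_id)])
  })
  ids <- per_layer[[1]]$ids
  stop_if_not(setequal(ids, per_layer[[2]]$ids) && length(ids) >= 2,
              "group '%s': both layers must be observed at both visits for the same subjects",
              group)
  contrast <- per_layer[[1]]$chg -
    per_layer[[2]]$chg[match(ids, per_layer[[2]]$ids)]
  change_result(mean(contrast), stats::sd(contrast), length(ids))
}

#' Bonferroni significance flag
#'
#' Strict comparison `p < 0.05 / family_size`. With the primary family of 6
#' parallel comparisons (3 group pairs x 2 layers) the threshold is
#' 0.05/6 = 0.00833.
#'
#' @param p P-value(s) in `[0,1]`.
#' @param family_size Number of parallel comparisons (>= 1).
#' @return Logical of the same length as `p`.
#' @export
significance_flag <- function(p, family_size = 6) {
  stop_if_not(all(family_size >= 1), "family_size must be >= 1")
  p < 0.05 / family_size
}
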