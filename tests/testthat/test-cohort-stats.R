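# Builds a minimal cohort table by hand for the longitudinal operations.
toy_cohort <- function(ids, group, base_sup, y1_sup, base_deep, y1_deep) {
  n <- length(ids)
  df <- function(visit, layer, vals, keep = rep(TRUE, n)) data.frame(
    subject_id = ids[keep], group = group, age = 60, sex = "female",
    bmi = 25, visit = visit, plate = "Avg", layer = layer,
    t2_ms = vals[keep], stringsAsFactors = FALSE)
  rbind(df("baseline", "superficial", base_sup),
        df("year1", "superficial", y1_sup, !is.na(y1_sup)),
        df("baseline", "deep", base_deep),
        df("year1", "deep", y1_deep, !is.na(y1_deep)))
}

test_that("identical samples give a null comparison", {
  r <- crude_group_difference(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$mean_diff_ms, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$cohens_d, 0)
})

test_that("the pooled t comparison matches its closed form", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- crude_group_difference(a, b)
  # hand-computed Student t: pooled SD 1, se = sqrt(2/3), df = 4
  se <- 1 * sqrt(1 / 3 + 1 / 3)
  t_stat <- -3 / se
  expect_equal(r$mean_diff_ms, -3)
  expect_equal(r$cohens_d, -3)
  expect_equal(r$p_value, 2 * pt(t_stat, 4), tolerance = 1e-12)
  expect_equal(r$ci95, -3 + c(-1, 1) * qt(0.975, 4) * se, tolerance = 1e-12)
})

test_that("summary-based and sample-based comparisons agree exactly", {
  set.seed(19)
  for (i in 1:10) {
    a <- rnorm(17, 45, 2.5); b <- rnorm(29, 47, 3)
    r1 <- crude_group_difference(a, b)
    r2 <- comparison_from_summary(mean(a), sd(a), 17, mean(b), sd(b), 29)
    expect_equal(r1$mean_diff_ms, r2$mean_diff_ms)
    expect_equal(r1$p_value, r2$p_value)
    expect_equal(r1$ci95, r2$ci95)
    expect_equal(r1$cohens_d, r2$cohens_d)
    # Welch variant too
    w1 <- crude_group_difference(a, b, welch = TRUE)
    w2 <- comparison_from_summary(mean(a), sd(a), 17, mean(b), sd(b), 29,
                                  welch = TRUE)
    expect_equal(w1$p_value, w2$p_value)
    expect_equal(w1$ci95, w2$ci95)
  }
})

test_that("Cohen's d follows the pooled-SD formula and its symmetries", {
  expect_equal(cohens_d(10, 2, 50, 8, 2, 50), 1)
  expect_equal(cohens_d(8, 2, 50, 10, 2, 50), -1)
  expect_equal(cohens_d(45, 2, 30, 45, 3, 60), 0)
  set.seed(7)
  for (i in 1:5) {
    m <- runif(2, 30, 50); s <- runif(2, 1, 4); n <- sample(10:90, 2)
    d1 <- cohens_d(m[1], s[1], n[1], m[2], s[2], n[2])
    expect_equal(cohens_d(m[2], s[2], n[2], m[1], s[1], n[1]), -d1)
    c0 <- 3.7
    expect_equal(cohens_d(c0 * m[1], c0 * s[1], n[1],
                          c0 * m[2], c0 * s[2], n[2]), d1)
  }
  expect_error(cohens_d(1, 0, 10, 2, 0, 10), "pooled SD")
})

test_that("ANCOVA equals the crude difference when covariates are orthogonal", {
  # identical covariate sets in both groups: group indicator orthogonal
  set.seed(23)
  n <- 20
  age <- rnorm(n, 60, 8); bmi <- rnorm(n, 26, 3)
  sex <- rep(c("male", "female"), 10)
  mk <- function(g, shift) data.frame(
    subject_id = paste0(g, 1:n), group = g, age = age, sex = sex, bmi = bmi,
    visit = "baseline", plate = "Avg", layer = "superficial",
    t2_ms = 45 + shift + rnorm(n, 0, 2), stringsAsFactors = FALSE)
  cohort <- rbind(mk("healthy", 0), mk("riskROA", 2.5))
  crude <- crude_group_difference(
    cohort$t2_ms[cohort$group == "riskROA"],
    cohort$t2_ms[cohort$group == "healthy"])
  adj <- ancova_adjusted_difference(cohort, "Avg", "superficial",
                                    c("riskROA", "healthy"))
  expect_equal(adj$mean_diff_ms, crude$mean_diff_ms, tolerance = 1e-10)
  expect_true(adj$adjusted)
})

test_that("ANCOVA removes injected age confounding", {
  # age raises T2; the riskROA group is older, biasing the crude contrast
  spec <- function(seed) oai_cohort_spec(
    covariate_effects = c(age = 0.2, sex = 0, bmi = 0), seed = seed)
  co <- generate_synthetic_cohort(spec(41))
  true_eff <- 48.1 - 45.4   # group-mean parameters, covariates held fixed
  crude <- crude_group_difference(
    co$t2_ms[co$group == "riskROA" & co$layer == "superficial" &
               co$visit == "baseline"],
    co$t2_ms[co$group == "healthy" & co$layer == "superficial" &
               co$visit == "baseline"])
  adj <- ancova_adjusted_difference(co, "Avg", "superficial",
                                    c("riskROA", "healthy"))
  # crude estimate absorbs the age effect of the 6-year group gap
  expect_gt(crude$mean_diff_ms - true_eff, 0.5)
  expect_lt(abs(adj$mean_diff_ms - true_eff),
            abs(crude$mean_diff_ms - true_eff))
})

test_that("rank-deficient ANCOVA designs are reported", {
  co <- generate_synthetic_cohort(oai_cohort_spec(seed = 2))
  co$bmi <- co$age   # perfectly collinear covariates
  expect_error(
    ancova_adjusted_difference(co, "Avg", "deep", c("riskROA", "healthy")),
    "collinear")
})

test_that("paired change matches its closed form", {
  ids <- paste0("s", 1:3)
  co <- toy_cohort(ids, "healthy",
                   base_sup = c(40, 41, 42), y1_sup = c(41, 43, 45),
                   base_deep = c(30, 31, 32), y1_deep = c(30, 31, 32))
  ch <- paired_change(co, "healthy", "Avg", "superficial")
  expect_equal(ch$mean_change_ms, 2)
  expect_equal(ch$sd_change_ms, 1)
  t_stat <- 2 / (1 / sqrt(3))
  expect_equal(t_stat, 3.464, tolerance = 1e-3)
  expect_equal(ch$p_value, 2 * pt(-t_stat, 2), tolerance = 1e-12)
  expect_equal(ch$ci95, 2 + c(-1, 1) * qt(0.975, 2) / sqrt(3),
               tolerance = 1e-12)
  # no change: p = 1
  ch0 <- paired_change(co, "healthy", "Avg", "deep")
  expect_equal(ch0$mean_change_ms, 0)
  expect_equal(ch0$p_value, 1)
  # only subjects with both visits contribute
  co2 <- toy_cohort(paste0("s", 1:4), "healthy",
                    base_sup = c(40, 41, 42, 99), y1_sup = c(41, 43, 45, NA),
                    base_deep = rep(30, 4), y1_deep = c(30, 30, 30, NA))
  expect_equal(paired_change(co2, "healthy", "Avg", "superficial")$n, 3)
})

test_that("change inference from printed summaries reproduces the CI", {
  ch <- change_from_summary(0.8, 1.3, 89)
  expect_equal(round(ch$ci95, 1), c(0.5, 1.1))
  expect_lt(ch$p_value, 0.001)
})

test_that("layer change contrast is antisymmetric in the layer labels", {
  ids <- paste0("s", 1:5)
  set.seed(3)
  co <- toy_cohort(ids, "healthy",
                   base_sup = rnorm(5, 45), y1_sup = rnorm(5, 46),
                   base_deep = rnorm(5, 35), y1_deep = rnorm(5, 35.4))
  lc <- layer_change_contrast(co, "healthy")
  swapped <- co
  swapped$layer <- ifelse(co$layer == "superficial", "deep", "superficial")
  lc2 <- layer_change_contrast(swapped, "healthy")
  expect_equal(lc2$mean_change_ms, -lc$mean_change_ms)
  expect_equal(lc2$p_value, lc$p_value)
  # identical layer changes: null contrast
  co0 <- toy_cohort(ids, "healthy",
                    base_sup = rep(45, 5), y1_sup = rep(46, 5),
                    base_deep = rep(35, 5), y1_deep = rep(36, 5))
  lc0 <- layer_change_contrast(co0, "healthy")
  expect_equal(lc0$mean_change_ms, 0)
  expect_equal(lc0$p_value, 1)
})

test_that("layer contrast power matches the analytic one-sample t power", {
  # generator with a true superficial-deep change difference of 0.3 ms and
  # contrast SD 1.35 at n = 89
  sdl <- 1.35 / sqrt(2)
  spec <- function(seed) cohort_spec(list(healthy = list(
    n = 89, n_followup = 89, age_mean = 55, age_sd = 7.5, bmi_mean = 24.4,
    bmi_sd = 3.1, female_fraction = 0.6,
    t2 = list(superficial = c(45.4, 2.3, 0.8, sdl),
              deep = c(35.8, 1.8, 0.5, sdl)))), seed = seed)
  hits <- vapply(1:500, function(s) {
    layer_change_contrast(generate_synthetic_cohort(spec(s)),
                          "healthy")$p_value < 0.05
  }, logical(1))
  analytic <- power.t.test(n = 89, delta = 0.3, sd = 1.35,
                           sig.level = 0.05, type = "one.sample")$power
  expect_lt(abs(mean(hits) - analytic), 0.05)
})

test_that("the Bonferroni flag uses a strict 0.05/m cut", {
  expect_true(significance_flag(0.006, 6))
  expect_false(significance_flag(0.011, 6))
  expect_false(significance_flag(0.05, 1))
  expect_true(significance_flag(0.00833, 6))   # 0.00833 < 0.05/6 = 0.008333...
})
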