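#' Pipeline configuration
#'
#' Collects every tunable setting of the analysis into one provenance-ready
#' object. Defaults are the pipeline's reference protocol: first-echo
#' exclusion on, R^2 elimination threshold 0.66, T2 bounds 1-1000 ms,
#' per-slice (2D) depth computation with ties at depth 0.5 assigned deep,
#' weight-bearing femoral fraction 0.6, pooled-variance t inference with a
#' Bonferroni family of 6 at alpha 0.05, and age/sex/BMI as ANCOVA
#' covariates.
#'
#' @param phantom A [phantom_spec()] for the imaging arm (or `NULL` to skip).
#' @param cohort A [cohort_spec()] for the statistics arm (or `NULL`).
#' @param exclude_first,r2_threshold,t2_bounds See [fit_settings()].
#' @param depth_method `"2d"` or `"3d"` (see [compute_normalized_depth()]).
#' @param roi_fraction Weight-bearing femoral ROI fraction, (0,1].
#' @param aggregate_weights `"equal"` or `"voxel"` (see
#'   [aggregate_femorotibial()]).
#' @param alpha,family_size Significance level and Bonferroni family.
#' @param welch Use Welch instead of pooled-variance t-tests.
#' @param covariates ANCOVA covariates.
#' @param seed Integer master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_spec(),
                            cohort = oai_cohort_spec(),
                            exclude_first = TRUE, r2_threshold = 0.66,
                            t2_bounds = c(1, 1000),
                            depth_method = c("2d", "3d"),
                            roi_fraction = 0.6,
                            aggregate_weights = c("equal", "voxel"),
                            alpha = 0.05, family_size = 6, welch = FALSE,
                            covariates = c("age", "sex", "bmi"),
                            seed = 1L) {
  depth_method <- match.arg(depth_method)
  aggregate_weights <- match.arg(aggregate_weights)
  stop_if_not(is.null(phantom) || inherits(phantom, "phantom_spec"),
              "phantom must be NULL or a phantom_spec")
  stop_if_not(is.null(cohort) || inherits(cohort, "cohort_spec"),
              "cohort must be NULL or a cohort_spec")
  structure(list(phantom = phantom, cohort = cohort,
                 fit = fit_settings(exclude_first, r2_threshold, t2_bounds),
                 depth_method = depth_method,
                 roi_fraction = roi_fraction,
                 aggregate_weights = aggregate_weights,
                 alpha = alpha, family_size = family_size, welch = welch,
                 covariates = covariates, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Validate pipeline inputs
#'
#' Structural checks before any computation: identical shapes across echo
#' volumes, strictly increasing echo times, plate masks with boundary
#' labels, and the cohort table schema/uniqueness invariants
#' ([validate_cohort()]).
#'
#' @param series Optional [mese_series()].
#' @param seg Optional [cartilage_segmentation()].
#' @param cohort Optional cohort data frame.
#' @return A data frame of violations (`check`, `message`); zero rows when
#'   everything is clean.
#' @export
validate_inputs <- function(series = NULL, seg = NULL, cohort = NULL) {
  v <- data.frame(check = character(0), message = character(0),
                  stringsAsFactors = FALSE)
  add <- function(check, msg) v <<- rbind(v, data.frame(
    check = check, message = msg, stringsAsFactors = FALSE))
  if (!is.null(series)) {
    dims <- lapply(series$volumes, dim)
    if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
      add("series", sprintf("echo volume shapes differ: %s",
                            paste(vapply(dims, paste, "", collapse = "x"),
                                  collapse = " vs ")))
    }
    if (is.unsorted(series$echo_times_ms, strictly = TRUE)) {
      add("series", "echo times are not strictly increasing")
    }
  }
  if (!is.null(seg)) {
    for (p in names(seg$plate_masks)) {
      m <- seg$plate_masks[[p]]
      if (!any(m)) add("seg", sprintf("plate '%s' mask is empty", p))
      else {
        if (!any(seg$bone_interface & m)) {
          add("seg", sprintf("plate '%s' has no bone-interface labels", p))
        }
        if (!any(seg$surface & m)) {
          add("seg", sprintf("plate '%s' has no surface labels", p))
        }
      }
    }
    if (!is.null(series) &&
        !identical(dim(seg$plate_masks[[1]]), dim(series$volumes[[1]]))) {
      add("seg", "segmentation and series shapes differ")
    }
  }
  if (!is.null(cohort)) v <- rbind(v, validate_cohort(cohort))
  v
}

#' Run the full analysis pipeline
#'
#' Orchestrates the four stages end to end: (1) synthesize (or accept) the
#' MESE phantom and subject cohort; (2) voxelwise T2 mapping with
#' first-echo exclusion and R^2 elimination; (3) laminar analysis — depth
#' normalization, superficial/deep split, weight-bearing femoral ROI,
#' plate and knee-level summaries; (4) cohort statistics — the six primary
#' baseline comparisons (crude and ANCOVA-adjusted), per-group paired
#' change tests, and the superficial-versus-deep change contrast. The run
#' is deterministic given the configuration (which embeds all seeds).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the laminar summary CSV,
#'   statistics CSV, a plain-text report, and the serialized configuration
#'   are written there.
#' @return A list of class `pipeline_result` with elements `t2map`,
#'   `laminar` (per-plate and knee-level summaries), `comparisons` (data
#'   frame of the 6 primary contrasts), `changes`, `layer_contrasts`,
#'   `provenance` (config, hash, package version, rejection counts).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stop_if_not(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  prov <- list(config = config, config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("cartT2")))

  t2map <- NULL; laminar <- NULL
  if (!is.null(config$phantom)) {
    phantom <- generate_phantom(config$phantom)
    viol <- validate_inputs(phantom$series, phantom$seg)
    stop_if_not(nrow(viol) == 0, "stage synth: invalid phantom:\n%s",
                paste(viol$message, collapse = "\n"))
    mask <- Reduce(`|`, phantom$seg$plate_masks)
    t2map <- build_t2_map(phantom$series, mask, config$fit)
    prov$n_rejected_r2 <- t2map$provenance$n_rejected_r2
    prov$n_mask <- t2map$provenance$n_mask

    summaries <- lapply(names(phantom$seg$plate_masks), function(p) {
      depth <- compute_normalized_depth(phantom$seg, p, config$depth_method)
      labels <- partition_layers(depth)
      roi <- if (p %in% c("cMF", "cLF")) {
        define_weightbearing_roi(phantom$seg, p, config$roi_fraction)
      } else NULL
      summarize_plate(t2map, labels, roi, p)
    })
    plate_summary <- do.call(rbind, summaries)
    knee_summary <- aggregate_femorotibial(plate_summary,
                                           config$aggregate_weights)
    laminar <- list(plate = plate_summary, knee = knee_summary,
                    phantom = phantom)
  }

  comparisons <- NULL; changes <- NULL; contrasts <- NULL
  if (!is.null(config$cohort)) {
    cohort <- generate_synthetic_cohort(config$cohort)
    viol <- validate_cohort(cohort)
    stop_if_not(nrow(viol) == 0, "stage synth: invalid cohort:\n%s",
                paste(viol$message, collapse = "\n"))
    pairs <- list(c("riskROA", "earlyROA"), c("riskROA", "healthy"),
                  c("earlyROA", "healthy"))
    pairs <- Filter(function(p) all(p %in% cohort$group), pairs)
    rows <- list()
    for (pr in pairs) {
      for (lay in c("superficial", "deep")) {
        a <- cohort$t2_ms[cohort$group == pr[1] & cohort$layer == lay &
                            cohort$visit == "baseline" & cohort$plate == "Avg"]
        b <- cohort$t2_ms[cohort$group == pr[2] & cohort$layer == lay &
                            cohort$visit == "baseline" & cohort$plate == "Avg"]
        crude <- crude_group_difference(a, b, welch = config$welch,
                                        family_size = config$family_size)
        adj <- ancova_adjusted_difference(cohort, "Avg", lay, pr,
                                          covariates = config$covariates,
                                          family_size = config$family_size)
        rows[[length(rows) + 1]] <- data.frame(
          group_a = pr[1], group_b = pr[2], plate = "Avg", layer = lay,
          diff_ms = crude$mean_diff_ms,
          ci_low = crude$ci95[1], ci_high = crude$ci95[2],
          p_crude = crude$p_value, p_adjusted = adj$p_value,
          adj_diff_ms = adj$mean_diff_ms, cohens_d = crude$cohens_d,
          significant = crude$significant_bonferroni,
          stringsAsFactors = FALSE)
      }
    }
    comparisons <- do.call(rbind, rows)

    chg_rows <- list(); ctr_rows <- list()
    for (g in unique(cohort$group)) {
      n_fu <- length(intersect(
        cohort$subject_id[cohort$group == g & cohort$visit == "baseline"],
        cohort$subject_id[cohort$group == g & cohort$visit == "year1"]))
      if (n_fu < 2) next
      for (lay in c("superficial", "deep")) {
        ch <- paired_change(cohort, g, "Avg", lay)
        chg_rows[[length(chg_rows) + 1]] <- data.frame(
          group = g, plate = "Avg", layer = lay,
          mean_change_ms = ch$mean_change_ms, sd_change_ms = ch$sd_change_ms,
          ci_low = ch$ci95[1], ci_high = ch$ci95[2], p = ch$p_value,
          n = ch$n, stringsAsFactors = FALSE)
      }
      lc <- layer_change_contrast(cohort, g, "Avg")
      ctr_rows[[length(ctr_rows) + 1]] <- data.frame(
        group = g, contrast_ms = lc$mean_change_ms, sd_ms = lc$sd_change_ms,
        ci_low = lc$ci95[1], ci_high = lc$ci95[2], p = lc$p_value, n = lc$n,
        stringsAsFactors = FALSE)
    }
    changes <- do.call(rbind, chg_rows)
    contrasts <- do.call(rbind, ctr_rows)
  }

  result <- structure(list(t2map = t2map, laminar = laminar,
                           comparisons = comparisons, changes = changes,
                           layer_contrasts = contrasts, provenance = prov),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$laminar)) {
    lam <- rbind(result$laminar$plate, result$laminar$knee)
    utils::write.csv(lam, file.path(out_dir, "laminar_summary.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$comparisons)) {
    utils::write.csv(result$comparisons,
                     file.path(out_dir, "group_comparisons.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$changes)) {
    utils::write.csv(result$changes,
                     file.path(out_dir, "longitudinal_change.csv"),
                     row.names = FALSE)
  }
  cfg <- result$provenance$config
  jsonlite::write_json(rapply(unclass(cfg), unclass, how = "replace"),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  rep <- file.path(out_dir, "report.txt")
  con <- file(rep, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("cartT2 pipeline report (config %s, package %s)",
            result$provenance$config_hash,
            result$provenance$package_version),
    ""), con)
  if (!is.null(result$laminar)) {
    writeLines("Plate x layer mean T2 (ms):", con)
    utils::capture.output(print(rbind(result$laminar$plate,
                                      result$laminar$knee),
                                row.names = FALSE), file = con)
    writeLines(sprintf("Voxels rejected by the R^2 filter: %s of %s",
                       format(result$provenance$n_rejected_r2),
                       format(result$provenance$n_mask)), con)
    writeLines("", con)
  }
  if (!is.null(result$comparisons)) {
    writeLines("Primary baseline comparisons (crude/adjusted):", con)
    utils::capture.output(print(result$comparisons, row.names = FALSE,
                                digits = 4), file = con)
  }
  invisible(rep)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$laminar)) {
    cat("  knee-level T2 (ms):\n")
    print(x$laminar$knee, row.names = FALSE)
  }
  if (!is.null(x$comparisons)) {
    cat(sprintf("  %d primary comparisons, %d significant (Bonferroni)\n",
                nrow(x$comparisons), sum(x$comparisons$significant)))
  }
  invisible(x)
}
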