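#' Fit settings for voxelwise T2 mapping
#'
#' @param exclude_first Drop the first echo before fitting (default `TRUE`);
#'   the first echo of a MESE train is contaminated by stimulated echoes and
#'   excluding it removes that bias from the mono-exponential fit.
#' @param r2_threshold Goodness-of-fit cutoff: voxels with R^2 below this
#'   value are eliminated (default 0.66). Strict inequality: a voxel with
#'   R^2 exactly at the threshold is kept.
#' @param t2_bounds Box bounds on T2 (ms) for the nonlinear fit; a fit
#'   landing on a bound is flagged non-converged.
#' @param s0_max_factor Upper bound on S0 as a multiple of the maximum
#'   observed intensity.
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(exclude_first = TRUE, r2_threshold = 0.66,
                         t2_bounds = c(1, 1000), s0_max_factor = 10) {
  stop_if_not(is_scalar_number(r2_threshold) &&
                r2_threshold >= 0 && r2_threshold <= 1,
              "r2_threshold must be in [0,1]")
  stop_if_not(length(t2_bounds) == 2 && t2_bounds[1] > 0 &&
                t2_bounds[2] > t2_bounds[1],
              "t2_bounds must be increasing and positive")
  structure(list(exclude_first = isTRUE(exclude_first),
                 r2_threshold = r2_threshold,
                 t2_bounds = as.numeric(t2_bounds),
                 s0_max_factor = s0_max_factor),
            class = "fit_settings")
}

#' Coefficient of determination of a fit
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the mean of the observed values. Returns `NA` when the observations
#' are constant (`SS_tot = 0`), since R^2 is undefined there.
#'
#' @param observed,fitted Numeric vectors of equal length >= 3.
#' @return A single number <= 1, or `NA_real_` when undefined.
#' @export
r_squared <- function(observed, fitted) {
  stop_if_not(length(observed) == length(fitted),
              "observed and fitted must have equal length")
  stop_if_not(length(observed) >= 3, "need at least 3 points for R^2")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((observed - fitted)^2) / ss_tot
}

# log-linear initializer: OLS of log(intensity) on TE over positive
# intensities; falls back to (max intensity, 40 ms) when < 3 are positive.
loglinear_init <- function(y, te) {
  pos <- y > 0
  if (sum(pos) < 3) return(c(s0 = max(y, 1e-6), t2 = 40))
  fit <- stats::lm.fit(cbind(1, te[pos]), log(y[pos]))
  slope <- fit$coefficients[2]
  t2 <- if (is.finite(slope) && slope < 0) -1 / slope else 40
  c(s0 = exp(fit$coefficients[1]), t2 = unname(t2))
}

#' Fit a mono-exponential decay to one voxel's echo train
#'
#' Nonlinear least squares of \eqn{S_0 \exp(-TE/T_2)} to the measured
#' intensities, by Levenberg-Marquardt with an analytic Jacobian,
#' initialized from the ordinary-least-squares line fit of log intensity
#' versus TE. With `exclude_first = TRUE` (the default) the first echo is
#' removed before fitting, so its value cannot influence the result.
#'
#' @param intensities Numeric vector, one intensity per echo.
#' @param echo_times_ms Strictly increasing echo times (ms), same length.
#' @param exclude_first Drop echo 1 before fitting.
#' @param settings A [fit_settings()] (supplies bounds; its
#'   `exclude_first` is overridden by the argument).
#' @return A list of class `fit_result`: `s0`, `t2_ms`, `r_squared`
#'   (computed over the echoes used in the fit), `converged`,
#'   `n_echoes_used`. A fit on a parameter bound or a degenerate input
#'   yields `converged = FALSE` rather than an error.
#' @examples
#' te <- seq(10, 70, by = 10)
#' fit_monoexponential(100 * exp(-te / 40), te)
#' @export
fit_monoexponential <- function(intensities, echo_times_ms,
                                exclude_first = TRUE,
                                settings = fit_settings()) {
  stop_if_not(length(intensities) == length(echo_times_ms),
              "intensities and echo_times_ms must have equal length")
  stop_if_not(!is.unsorted(echo_times_ms, strictly = TRUE),
              "echo_times_ms must be strictly increasing")
  use <- if (exclude_first) -1L else seq_along(intensities)
  y <- intensities[use]
  te <- echo_times_ms[use]
  if (length(y) < 3) {
    stop("fewer than 3 usable echoes after first-echo exclusion",
         call. = FALSE)
  }
  failed <- list(s0 = NA_real_, t2_ms = NA_real_, r_squared = NA_real_,
                 converged = FALSE, n_echoes_used = length(y))
  class(failed) <- "fit_result"
  if (all(!is.finite(y)) || all(y <= 0)) return(failed)

  lower <- c(0, settings$t2_bounds[1])
  upper <- c(settings$s0_max_factor * max(y), settings$t2_bounds[2])
  init <- pmin(pmax(loglinear_init(y, te), lower + 1e-9), upper - 1e-9)
  resid_fn <- function(p) y - p[1] * exp(-te / p[2])
  jac_fn <- function(p) {
    e <- exp(-te / p[2])
    -cbind(e, p[1] * te * e / p[2]^2)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                       fn = resid_fn, jac = jac_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  p <- fit$par
  eps <- 1e-8 * diff(settings$t2_bounds)
  on_bound <- p[2] <= settings$t2_bounds[1] + eps ||
    p[2] >= settings$t2_bounds[2] - eps
  converged <- fit$info %in% 1:4 && !on_bound
  structure(list(s0 = unname(p[1]), t2_ms = unname(p[2]),
                 r_squared = r_squared(y, p[1] * exp(-te / p[2])),
                 converged = converged, n_echoes_used = length(y)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> T2 = %.3f ms, S0 = %.3f, R^2 = %.4f, %s (%d echoes)\n",
              x$t2_ms, x$s0, x$r_squared,
              if (x$converged) "converged" else "NOT converged",
              x$n_echoes_used))
  invisible(x)
}

#' Compute a voxelwise T2 map
#'
#' Fits every voxel inside `mask` with [fit_monoexponential()], then applies
#' the R^2 quality filter ([apply_quality_filter()]). Invalid voxels carry
#' `NA`, never a silent zero. Voxels are fitted independently (no spatial
#' coupling), so the result does not depend on traversal order.
#'
#' @param series A [mese_series()].
#' @param mask Logical array matching the series dimensions.
#' @param settings A [fit_settings()].
#' @return A list of class `t2_map` with per-voxel arrays `t2_ms`, `s0`,
#'   `r_squared`, `converged`, `valid`, and a `provenance` list recording
#'   the fit settings and rejection counts.
#' @export
build_t2_map <- function(series, mask, settings = fit_settings()) {
  stop_if_not(inherits(series, "mese_series"), "series must be a mese_series")
  dims <- dim(series$volumes[[1]])
  stop_if_not(identical(dim(mask), dims), "mask shape must match series")
  n_after <- length(series$echo_times_ms) - as.integer(settings$exclude_first)
  stop_if_not(n_after >= 3,
              "need >= 3 echoes after first-echo exclusion, have %d", n_after)

  idx <- which(mask)
  t2 <- array(NA_real_, dims); s0 <- array(NA_real_, dims)
  r2 <- array(NA_real_, dims)
  conv <- array(FALSE, dims)
  if (length(idx) == 0) {
    warning("empty mask: returning an empty T2 map")
  } else {
    y_mat <- vapply(series$volumes, function(v) v[idx], numeric(length(idx)))
    if (is.null(dim(y_mat))) y_mat <- matrix(y_mat, nrow = 1)
    for (i in seq_along(idx)) {
      f <- fit_monoexponential(y_mat[i, ], series$echo_times_ms,
                               exclude_first = settings$exclude_first,
                               settings = settings)
      t2[idx[i]] <- f$t2_ms; s0[idx[i]] <- f$s0
      r2[idx[i]] <- f$r_squared; conv[idx[i]] <- f$converged
    }
  }
  map <- structure(list(
    t2_ms = t2, s0 = s0, r_squared = r2, converged = conv,
    valid = conv,
    provenance = list(settings = unclass(settings),
                      echo_times_ms = series$echo_times_ms,
                      n_mask = length(idx))
  ), class = "t2_map")
  apply_quality_filter(map, settings$r2_threshold)
}

#' Eliminate voxels with poor goodness of fit
#'
#' Marks as invalid every voxel whose fit R^2 falls strictly below the
#' threshold (voxels with `R^2 < threshold` are eliminated; a voxel exactly
#' at the threshold is kept). Validity can only shrink: the operation is
#' idempotent and composes with the convergence flags set by
#' [build_t2_map()].
#'
#' @param map A `t2_map`.
#' @param r2_threshold Threshold in `[0,1]`; 0 disables the filter.
#' @return The map with its `valid` array updated and the rejection count
#'   recorded in `provenance`.
#' @export
apply_quality_filter <- function(map, r2_threshold = 0.66) {
  stop_if_not(inherits(map, "t2_map"), "map must be a t2_map")
  stop_if_not(is_scalar_number(r2_threshold) &&
                r2_threshold >= 0 && r2_threshold <= 1,
              "r2_threshold must be in [0,1]")
  keep <- !is.na(map$r_squared) & map$r_squared >= r2_threshold
  before <- sum(map$valid)
  map$valid <- map$valid & keep
  map$provenance$r2_threshold <- r2_threshold
  map$provenance$n_rejected_r2 <- before - sum(map$valid)
  map
}

#' @export
print.t2_map <- function(x, ...) {
  n <- x$provenance$n_mask
  cat(sprintf("<t2_map> %d masked voxels, %d valid (%.1f%%), R^2 threshold %s\n",
              n, sum(x$valid),
              if (n > 0) 100 * sum(x$valid) / n else 0,
              format(x$provenance$r2_threshold)))
  invisible(x)
}
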