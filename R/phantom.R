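#' Simulate a multi-echo spin-echo (MESE) signal
#'
#' Generates per-echo magnitude intensities under the mono-exponential decay
#' model \eqn{S(TE) = S_0 \exp(-TE/T_2)}, optionally inflating the first echo
#' by a multiplicative factor to emulate stimulated-echo contamination, and
#' adding voxel noise.
#'
#' @param s0 Proton-density signal scale(s), positive. Scalar or vector (one
#'   value per voxel).
#' @param t2_ms T2 relaxation time(s) in ms, positive. Recycled against `s0`.
#' @param echo_times_ms Strictly increasing echo times in ms.
#' @param first_echo_bias_frac Fractional inflation of the first echo
#'   (e.g. 0.2 multiplies echo 1 by 1.2). Emulates stimulated echoes, which
#'   predominantly contaminate the first echo of a MESE train. Must be >= 0.
#' @param noise_sd Standard deviation of the additive noise, in intensity
#'   units. 0 gives noiseless signals.
#' @param noise_model `"gaussian"` (default; zero-mean additive) or
#'   `"rician"` (magnitude of a complex signal with Gaussian noise on both
#'   channels, the physical model for magnitude MRI).
#' @param seed Optional integer seed; the global RNG state is untouched.
#'
#' @return If `s0`/`t2_ms` are scalars, a numeric vector with one intensity
#'   per echo; otherwise a matrix with one row per voxel and one column per
#'   echo.
#' @examples
#' simulate_mese_signal(100, 40, seq(10, 70, by = 10))
#' @export
simulate_mese_signal <- function(s0, t2_ms, echo_times_ms,
                                 first_echo_bias_frac = 0, noise_sd = 0,
                                 noise_model = c("gaussian", "rician"),
                                 seed = NULL) {
  noise_model <- match.arg(noise_model)
  stop_if_not(all(is.finite(s0)) && all(s0 > 0),
              "s0 must be finite and positive")
  stop_if_not(all(is.finite(t2_ms)) && all(t2_ms > 0),
              "t2_ms must be finite and positive")
  stop_if_not(length(echo_times_ms) >= 1 && all(echo_times_ms > 0) &&
                !is.unsorted(echo_times_ms, strictly = TRUE),
              "echo_times_ms must be strictly increasing positive values")
  stop_if_not(is_scalar_number(first_echo_bias_frac) && first_echo_bias_frac >= 0,
              "first_echo_bias_frac must be a nonnegative number")
  stop_if_not(is_scalar_number(noise_sd) && noise_sd >= 0,
              "noise_sd must be a nonnegative number")

  n <- max(length(s0), length(t2_ms))
  s0 <- rep_len(s0, n)
  t2_ms <- rep_len(t2_ms, n)
  k <- length(echo_times_ms)

  clean <- outer(1 / t2_ms, echo_times_ms, function(inv_t2, te) exp(-te * inv_t2)) * s0
  clean[, 1] <- clean[, 1] * (1 + first_echo_bias_frac)

  sig <- with_seed(seed, {
    if (noise_sd == 0) {
      clean
    } else if (noise_model == "gaussian") {
      clean + matrix(stats::rnorm(n * k, sd = noise_sd), n, k)
    } else {
      re <- clean + matrix(stats::rnorm(n * k, sd = noise_sd), n, k)
      im <- matrix(stats::rnorm(n * k, sd = noise_sd), n, k)
      sqrt(re^2 + im^2)
    }
  })
  if (n == 1L) drop(sig) else sig
}

#' Specify a synthetic MESE cartilage phantom
#'
#' Describes a digital knee phantom made of up to four cartilage plates (the
#' medial/lateral tibia MT/LT as flat slabs, and the weight-bearing
#' medial/lateral femoral condyles cMF/cLF as curved shells), each with a
#' through-thickness T2 gradient, imaged by a simulated MESE acquisition.
#'
#' Acquisition defaults follow a standard 3T knee MESE protocol: echo times
#' 10-70 ms in 10 ms steps, TR 2700 ms, 0.3125 mm in-plane resolution and
#' 3.0 mm slice thickness.
#'
#' @param plate_shapes Named character vector mapping plate names (any of
#'   `"MT"`, `"LT"`, `"cMF"`, `"cLF"`) to `"slab"` or `"shell"`.
#' @param thickness_voxels Cartilage thickness in voxels per plate (integer
#'   >= 2, recycled; both layers must be nonempty).
#' @param t2_deep_ms,t2_superficial_ms Ground-truth T2 (ms) at the bone
#'   interface and articular surface, per plate (recycled).
#' @param t2_profile `"step"` (two-compartment: deep value for normalized
#'   depth <= 0.5, superficial above) or `"linear"` (linear in depth).
#' @param s0 Proton-density scale (intensity units).
#' @param noise_sd Additive noise SD (intensity units).
#' @param first_echo_bias_frac Stimulated-echo inflation of echo 1.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param extent_ap Anteroposterior extent of each plate, in voxels.
#' @param n_slices Number of sagittal slices per compartment (medial and
#'   lateral compartments occupy disjoint slice ranges).
#' @param voxel_spacing_mm Voxel spacing (in-plane row, in-plane column,
#'   slice), mm.
#' @param echo_times_ms Echo times, ms, strictly increasing.
#' @param tr_ms Repetition time, ms.
#' @param seed Integer seed for the noise generator.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(plate_shapes = c(MT = "slab", LT = "slab",
                                          cMF = "shell", cLF = "shell"),
                         thickness_voxels = 16,
                         t2_deep_ms = 35.8,
                         t2_superficial_ms = 45.4,
                         t2_profile = c("step", "linear"),
                         s0 = 100,
                         noise_sd = 0,
                         first_echo_bias_frac = 0,
                         noise_model = c("gaussian", "rician"),
                         extent_ap = 40,
                         n_slices = 3,
                         voxel_spacing_mm = c(0.3125, 0.3125, 3.0),
                         echo_times_ms = seq(10, 70, by = 10),
                         tr_ms = 2700,
                         seed = 1L) {
  t2_profile <- match.arg(t2_profile)
  noise_model <- match.arg(noise_model)
  plates <- names(plate_shapes)
  stop_if_not(length(plates) >= 1 && !anyDuplicated(plates) &&
                all(plates %in% c("MT", "LT", "cMF", "cLF")),
              "plate_shapes must be named with distinct plates among MT, LT, cMF, cLF")
  stop_if_not(all(plate_shapes %in% c("slab", "shell")),
              "plate shapes must be 'slab' or 'shell'")
  thickness_voxels <- rep_len(as.integer(thickness_voxels), length(plates))
  stop_if_not(all(thickness_voxels >= 2L),
              "thickness_voxels must be >= 2 so both layers are nonempty")
  t2_deep_ms <- rep_len(t2_deep_ms, length(plates))
  t2_superficial_ms <- rep_len(t2_superficial_ms, length(plates))
  stop_if_not(all(t2_deep_ms > 0) && all(t2_superficial_ms > 0),
              "ground-truth T2 values must be positive")
  stop_if_not(all(echo_times_ms > 0) &&
                !is.unsorted(echo_times_ms, strictly = TRUE),
              "echo_times_ms must be strictly increasing and positive")
  stop_if_not(is_scalar_number(s0) && s0 > 0, "s0 must be positive")
  stop_if_not(is_scalar_number(noise_sd) && noise_sd >= 0,
              "noise_sd must be nonnegative")
  stop_if_not(length(voxel_spacing_mm) == 3 && all(voxel_spacing_mm > 0),
              "voxel_spacing_mm must be 3 positive values")

  structure(list(
    plate_shapes = plate_shapes,
    thickness_voxels = stats::setNames(thickness_voxels, plates),
    t2_deep_ms = stats::setNames(t2_deep_ms, plates),
    t2_superficial_ms = stats::setNames(t2_superficial_ms, plates),
    t2_profile = t2_profile,
    s0 = s0, noise_sd = noise_sd,
    first_echo_bias_frac = first_echo_bias_frac,
    noise_model = noise_model,
    extent_ap = as.integer(extent_ap), n_slices = as.integer(n_slices),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    echo_times_ms = as.numeric(echo_times_ms),
    tr_ms = tr_ms, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' MESE image series container
#'
#' @param volumes List of 3D arrays, one per echo, identical dimensions.
#' @param echo_times_ms Strictly increasing echo times (ms), one per volume.
#' @param tr_ms Repetition time (ms).
#' @param voxel_spacing_mm Voxel spacing, 3 positive values (mm).
#' @return An object of class `mese_series`.
#' @export
mese_series <- function(volumes, echo_times_ms, tr_ms = 2700,
                        voxel_spacing_mm = c(0.3125, 0.3125, 3.0)) {
  stop_if_not(is.list(volumes) && length(volumes) == length(echo_times_ms),
              "need one volume per echo time")
  stop_if_not(!is.unsorted(echo_times_ms, strictly = TRUE) &&
                all(echo_times_ms > 0),
              "echo_times_ms must be strictly increasing positive values")
  dims <- lapply(volumes, dim)
  stop_if_not(all(vapply(dims, identical, logical(1), dims[[1]])),
              "all echo volumes must have identical dimensions")
  stop_if_not(is_scalar_number(tr_ms) && tr_ms > 0, "tr_ms must be positive")
  structure(list(volumes = volumes,
                 echo_times_ms = as.numeric(echo_times_ms),
                 tr_ms = tr_ms,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm)),
            class = "mese_series")
}

#' @export
print.mese_series <- function(x, ...) {
  cat(sprintf("<mese_series> %s voxels, %d echoes (TE %s ms), TR %g ms\n",
              paste(dim(x$volumes[[1]]), collapse = "x"),
              length(x$echo_times_ms),
              paste(x$echo_times_ms, collapse = ","), x$tr_ms))
  invisible(x)
}

#' Cartilage segmentation container
#'
#' Per-plate voxel masks plus boundary labels: `bone_interface` marks
#' cartilage voxels at the cartilage-bone interface, `surface` marks voxels
#' at the articular surface. Plate masks must be pairwise disjoint and each
#' boundary label must lie inside some plate mask.
#'
#' @param plate_masks Named list of logical 3D arrays (plates MT, LT, cMF,
#'   cLF or a subset).
#' @param bone_interface,surface Logical 3D arrays of the same dimensions.
#' @param voxel_spacing_mm Voxel spacing, mm.
#' @param notch Optional named integer vector giving, per femoral plate, the
#'   anteroposterior (column) index of the trochlear-notch landmark used by
#'   the weight-bearing ROI rule.
#' @return An object of class `cartilage_segmentation`.
#' @export
cartilage_segmentation <- function(plate_masks, bone_interface, surface,
                                   voxel_spacing_mm = c(0.3125, 0.3125, 3.0),
                                   notch = NULL) {
  stop_if_not(is.list(plate_masks) && length(plate_masks) >= 1 &&
                !is.null(names(plate_masks)),
              "plate_masks must be a named list")
  d <- dim(plate_masks[[1]])
  for (p in names(plate_masks)) {
    stop_if_not(identical(dim(plate_masks[[p]]), d),
                "plate mask '%s' has mismatched dimensions", p)
  }
  stop_if_not(identical(dim(bone_interface), d) && identical(dim(surface), d),
              "boundary label volumes must match plate mask dimensions")
  any_mask <- Reduce(`|`, plate_masks)
  overlap <- Reduce(`+`, lapply(plate_masks, as.integer))
  stop_if_not(max(overlap) <= 1L, "plate masks must be pairwise disjoint")
  stop_if_not(!any(bone_interface & !any_mask),
              "bone_interface labels must lie inside a plate mask")
  stop_if_not(!any(surface & !any_mask),
              "surface labels must lie inside a plate mask")
  structure(list(plate_masks = plate_masks,
                 bone_interface = bone_interface,
                 surface = surface,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 notch = notch),
            class = "cartilage_segmentation")
}

# Geometry of one plate on the (row, column) in-plane grid of `slices`
# sagittal slices. Returns logical mask/bone/surface arrays plus per-voxel
# normalized depth (0 at bone, 1 at surface) and discrete layer index.
build_plate_geometry <- function(shape, dims, slices, rows_avail, cols,
                                 thickness) {
  mask <- array(FALSE, dims); bone <- array(FALSE, dims)
  surf <- array(FALSE, dims)
  depth <- array(NA_real_, dims)
  if (shape == "slab") {
    bone_row <- max(rows_avail)
    rows <- seq(bone_row - thickness + 1L, bone_row)
    for (z in slices) {
      mask[rows, cols, z] <- TRUE
      bone[bone_row, cols, z] <- TRUE
      surf[min(rows), cols, z] <- TRUE
      for (i in seq_len(thickness)) {
        depth[bone_row - i + 1L, cols, z] <- (i - 1) / (thickness - 1)
      }
    }
  } else { # curved shell: downward-facing condyle, bone at the inner radius
    cy <- min(rows_avail)
    cx <- (min(cols) + max(cols)) / 2
    r_out <- max(rows_avail) - cy           # outermost ring radius
    r_in <- r_out - thickness + 1L
    stop_if_not(r_in >= 2, "shell plate does not fit: increase row extent")
    rr <- seq(min(rows_avail), max(rows_avail))
    for (z in slices) {
      for (r in rr) {
        for (cc in cols) {
          dy <- r - cy
          if (dy < 0) next                   # lower half-annulus only
          rad <- sqrt(dy^2 + (cc - cx)^2)
          ring <- round(rad - r_in)
          if (ring >= 0 && ring <= thickness - 1L) {
            mask[r, cc, z] <- TRUE
            # analytic radial depth: 0 at the inner (bone) radius, 1 at the
            # outer (surface) radius, clamped against half-voxel overhang
            depth[r, cc, z] <- min(1, max(0, (rad - r_in) / (thickness - 1)))
            if (ring == 0L) bone[r, cc, z] <- TRUE
            if (ring == thickness - 1L) surf[r, cc, z] <- TRUE
          }
        }
      }
    }
  }
  list(mask = mask, bone = bone, surface = surf, depth = depth)
}

#' Generate a synthetic MESE cartilage phantom
#'
#' Builds the digital phantom described by a [phantom_spec()]: a MESE image
#' series, a cartilage segmentation with bone-interface and surface labels,
#' and the voxelwise ground truth (true T2, normalized depth, layer).
#'
#' Tibial plates are flat slabs with the bone interface at the bottom row;
#' femoral plates are downward-facing half-annular shells with the bone
#' interface at the inner radius (towards the condyle center) and the
#' articular surface at the outer radius (towards the tibia). Medial plates
#' (MT, cMF) and lateral plates (LT, cLF) occupy disjoint sagittal slice
#' ranges.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `cartilage_phantom` with elements `series`
#'   ([mese_series()]), `seg` ([cartilage_segmentation()]) and `truth`
#'   (list of arrays `true_t2_ms`, `true_depth`, `true_layer`).
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0, n_slices = 1))
#' range(ph$truth$true_t2_ms, na.rm = TRUE)
#' @export
generate_phantom <- function(spec) {
  stop_if_not(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  plates <- names(spec$plate_shapes)
  thick <- spec$thickness_voxels
  # grid: femoral shell on top rows, tibial slab at the bottom, gap between
  max_shell <- if (any(spec$plate_shapes == "shell"))
    max(thick[spec$plate_shapes == "shell"]) else 0L
  max_slab <- if (any(spec$plate_shapes == "slab"))
    max(thick[spec$plate_shapes == "slab"]) else 0L
  shell_rows <- max_shell + ceiling(spec$extent_ap / 2) + 2L
  nrow_grid <- shell_rows + 4L + max_slab + 2L
  ncol_grid <- spec$extent_ap + 8L
  medial <- intersect(plates, c("MT", "cMF"))
  lateral <- intersect(plates, c("LT", "cLF"))
  nz <- spec$n_slices * ((length(medial) > 0) + (length(lateral) > 0))
  dims <- c(nrow_grid, ncol_grid, nz)
  cols <- seq(5L, 4L + spec$extent_ap)

  masks <- list(); depth <- array(NA_real_, dims)
  bone <- array(FALSE, dims); surf <- array(FALSE, dims)
  slice_of <- function(p) {
    if (p %in% medial) seq_len(spec$n_slices)
    else spec$n_slices * (length(medial) > 0) + seq_len(spec$n_slices)
  }
  for (p in plates) {
    # femoral plates occupy the upper grid region, tibial plates the lower
    rows_avail <- if (p %in% c("cMF", "cLF")) {
      seq_len(shell_rows)
    } else {
      seq(shell_rows + 5L, nrow_grid - 2L)
    }
    g <- build_plate_geometry(spec$plate_shapes[[p]], dims, slice_of(p),
                              rows_avail, cols, thick[[p]])
    masks[[p]] <- g$mask
    bone <- bone | g$bone
    surf <- surf | g$surface
    depth[g$mask] <- g$depth[g$mask]
  }

  true_t2 <- array(NA_real_, dims)
  for (p in plates) {
    m <- masks[[p]]
    d <- depth[m]
    true_t2[m] <- if (spec$t2_profile == "linear") {
      spec$t2_deep_ms[[p]] +
        d * (spec$t2_superficial_ms[[p]] - spec$t2_deep_ms[[p]])
    } else {
      ifelse(d > 0.5, spec$t2_superficial_ms[[p]], spec$t2_deep_ms[[p]])
    }
  }
  layer <- array(NA_character_, dims)
  any_mask <- Reduce(`|`, masks)
  layer[any_mask] <- ifelse(depth[any_mask] > 0.5, "superficial", "deep")

  # image synthesis: cartilage follows the decay model, background is noise
  idx <- which(any_mask)
  k <- length(spec$echo_times_ms)
  sig <- simulate_mese_signal(spec$s0, true_t2[idx], spec$echo_times_ms,
                              first_echo_bias_frac = spec$first_echo_bias_frac,
                              noise_sd = spec$noise_sd,
                              noise_model = spec$noise_model,
                              seed = spec$seed)
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1)
  bgn <- with_seed(spec$seed + 1L, {
    if (spec$noise_sd > 0) {
      matrix(stats::rnorm((prod(dims) - length(idx)) * k, sd = spec$noise_sd),
             ncol = k)
    } else matrix(0, prod(dims) - length(idx), k)
  })
  vols <- vector("list", k)
  for (e in seq_len(k)) {
    v <- array(0, dims)
    v[idx] <- sig[, e]
    v[-idx] <- bgn[, e]
    vols[[e]] <- v
  }

  notch <- stats::setNames(rep(min(cols), length(plates)), plates)
  notch <- notch[spec$plate_shapes[plates] == "shell"]
  if (length(notch) == 0) notch <- NULL

  structure(list(
    series = mese_series(vols, spec$echo_times_ms, spec$tr_ms,
                         spec$voxel_spacing_mm),
    seg = cartilage_segmentation(masks, bone, surf, spec$voxel_spacing_mm,
                                 notch = notch),
    truth = list(true_t2_ms = true_t2, true_depth = depth, true_layer = layer),
    spec = spec
  ), class = "cartilage_phantom")
}
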