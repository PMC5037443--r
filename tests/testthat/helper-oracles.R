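# Independent oracles and small fixture builders used across the suite.

# Exhaustive grid search for the mono-exponential least-squares problem:
# coarse grid over (S0, T2), then one refinement pass around the best cell.
# Returns the best parameters and their SSE. Independent of the package's
# Levenberg-Marquardt path.
grid_fit_oracle <- function(y, te, s0_range = c(50, 150),
                            t2_range = c(10, 100), n_coarse = 60,
                            n_fine = 60) {
  sse <- function(s0, t2) sum((y - s0 * exp(-te / t2))^2)
  best <- c(NA, NA, Inf)
  s0s <- seq(s0_range[1], s0_range[2], length.out = n_coarse)
  t2s <- seq(t2_range[1], t2_range[2], length.out = n_coarse)
  for (s0 in s0s) for (t2 in t2s) {
    v <- sse(s0, t2)
    if (v < best[3]) best <- c(s0, t2, v)
  }
  ds <- diff(s0s[1:2]); dt <- diff(t2s[1:2])
  for (pass in 1:4) {
    # widen by a few cells: the SSE valley is diagonal in (S0, T2), so the
    # best coarse cell can sit slightly off the global minimum
    s0s <- seq(best[1] - 3 * ds, best[1] + 3 * ds, length.out = n_fine)
    t2s <- seq(max(best[2] - 3 * dt, 1e-3), best[2] + 3 * dt,
               length.out = n_fine)
    for (s0 in s0s) for (t2 in t2s) {
      v <- sse(s0, t2)
      if (v < best[3]) best <- c(s0, t2, v)
    }
    ds <- diff(s0s[1:2]); dt <- diff(t2s[1:2])
  }
  list(s0 = best[1], t2 = best[2], sse = best[3])
}

# All-pairs brute-force depth oracle: per sagittal slice, the Euclidean
# distance from each plate voxel center to the nearest bone-interface and
# surface voxel center, combined as d_bone / (d_bone + d_surface).
brute_depth_oracle <- function(seg, plate) {
  mask <- seg$plate_masks[[plate]]
  bone <- seg$bone_interface & mask
  surf <- seg$surface & mask
  depth <- array(NA_real_, dim(mask))
  for (z in seq_len(dim(mask)[3])) {
    m <- which(mask[, , z], arr.ind = TRUE)
    if (nrow(m) == 0) next
    b <- which(bone[, , z], arr.ind = TRUE)
    s <- which(surf[, , z], arr.ind = TRUE)
    for (i in seq_len(nrow(m))) {
      db <- sqrt(min((m[i, 1] - b[, 1])^2 + (m[i, 2] - b[, 2])^2))
      ds <- sqrt(min((m[i, 1] - s[, 1])^2 + (m[i, 2] - s[, 2])^2))
      depth[m[i, 1], m[i, 2], z] <-
        if (db + ds == 0) 0.5 else db / (db + ds)
    }
  }
  depth
}

# Single 1-voxel-wide cartilage column of given thickness, bone interface at
# the bottom row: collinear geometry with known depths i/(thickness-1).
column_seg <- function(thickness = 10, spacing = c(0.3125, 0.3125, 3.0)) {
  dims <- c(thickness + 4L, 3L, 1L)
  mask <- array(FALSE, dims)
  bone <- array(FALSE, dims)
  surf <- array(FALSE, dims)
  rows <- seq(3L, 2L + thickness)
  mask[rows, 2, 1] <- TRUE
  bone[max(rows), 2, 1] <- TRUE
  surf[min(rows), 2, 1] <- TRUE
  cartilage_segmentation(list(MT = mask), bone, surf, spacing)
}

# Hand-built t2_map over an arbitrary array of values/r2/validity.
toy_t2_map <- function(t2, r2 = NULL, valid = NULL) {
  if (is.null(r2)) { r2 <- t2; r2[] <- 1 }
  if (is.null(valid)) valid <- !is.na(t2)
  structure(list(t2_ms = t2, s0 = t2, r_squared = r2,
                 converged = valid, valid = valid,
                 provenance = list(n_mask = sum(!is.na(t2)))),
            class = "t2_map")
}

# Small phantom whose slices fit within 40x40 (for the all-pairs oracle).
small_phantom <- function(...) {
  generate_phantom(phantom_spec(extent_ap = 20, thickness_voxels = 8,
                                n_slices = 1, ...))
}
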