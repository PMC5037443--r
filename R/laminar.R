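#' Normalized cartilage depth from boundary distance transforms
#'
#' For every voxel of one cartilage plate, computes the normalized depth
#' `d_bone / (d_bone + d_surface)`, where `d_bone` and `d_surface` are the
#' Euclidean distances from the voxel center to the nearest bone-interface
#' and articular-surface voxel of that plate. Depth is 0 at the bone
#' interface and 1 at the articular surface.
#'
#' The default method evaluates the two distance transforms per sagittal
#' slice (2D, exact Euclidean via `EBImage::distmap`): slice thickness is
#' roughly ten times the in-plane resolution in standard knee MESE
#' protocols, so in-plane distances dominate, and the ratio is invariant to
#' the (isotropic) in-plane pixel size. `method = "3d"` instead measures
#' distances in millimetres to boundary voxels in all slices, honoring
#' anisotropic spacing, by exhaustive nearest-boundary search.
#'
#' Voxels that are both bone interface and surface (single-voxel-thick
#' columns) get depth 0.5; their count is reported in a message.
#'
#' @param seg A [cartilage_segmentation()].
#' @param plate Plate name present in `seg$plate_masks`.
#' @param method `"2d"` (per sagittal slice, default) or `"3d"`.
#' @return A list of class `depth_field`: `depth` (array, `NA` outside the
#'   plate), `plate`, `method`.
#' @export
compute_normalized_depth <- function(seg, plate, method = c("2d", "3d")) {
  method <- match.arg(method)
  stop_if_not(inherits(seg, "cartilage_segmentation"),
              "seg must be a cartilage_segmentation")
  stop_if_not(plate %in% names(seg$plate_masks),
              "unknown plate '%s'", plate)
  mask <- seg$plate_masks[[plate]]
  bone <- seg$bone_interface & mask
  surf <- seg$surface & mask
  stop_if_not(any(mask), "plate '%s': empty mask", plate)
  stop_if_not(any(bone), "plate '%s': no bone-interface labels", plate)
  stop_if_not(any(surf), "plate '%s': no surface labels", plate)

  dims <- dim(mask)
  db <- array(NA_real_, dims)
  ds <- array(NA_real_, dims)
  if (method == "2d") {
    for (z in seq_len(dims[3])) {
      m <- mask[, , z]
      if (!any(m)) next
      b <- bone[, , z]; s <- surf[, , z]
      stop_if_not(any(b) && any(s),
                  "plate '%s', slice %d: missing boundary labels", plate, z)
      dbz <- EBImage::distmap(matrix(as.numeric(!b), dims[1], dims[2]))
      dsz <- EBImage::distmap(matrix(as.numeric(!s), dims[1], dims[2]))
      db[, , z][m] <- dbz[m]
      ds[, , z][m] <- dsz[m]
    }
  } else {
    sp <- seg$voxel_spacing_mm
    coords_mm <- function(w) {
      ij <- which(w, arr.ind = TRUE)
      sweep(ij, 2, sp, `*`)
    }
    vox <- coords_mm(mask); bc <- coords_mm(bone); sc <- coords_mm(surf)
    nearest <- function(pts, ref) {
      apply(pts, 1, function(p) {
        sqrt(min(colSums((t(ref) - p)^2)))
      })
    }
    db[mask] <- nearest(vox, bc)
    ds[mask] <- nearest(vox, sc)
  }
  tot <- db + ds
  depth <- array(NA_real_, dims)
  thin <- mask & !is.na(tot) & tot == 0
  if (any(thin)) {
    message(sprintf("plate '%s': %d single-voxel-thick column voxel(s) assigned depth 0.5",
                    plate, sum(thin)))
    depth[thin] <- 0.5
  }
  ok <- mask & !thin
  depth[ok] <- db[ok] / tot[ok]
  structure(list(depth = depth, plate = plate, method = method),
            class = "depth_field")
}

#' Split cartilage into superficial and deep 50% layers
#'
#' Labels each plate voxel by thresholding normalized depth at 0.5:
#' superficial where depth > 0.5, deep where depth <= 0.5 (ties go to the
#' deep layer). Every voxel with a defined depth receives exactly one
#' label.
#'
#' @param depth A `depth_field` from [compute_normalized_depth()].
#' @return A character array with values `"superficial"`/`"deep"` on plate
#'   voxels and `NA` elsewhere.
#' @export
partition_layers <- function(depth) {
  stop_if_not(inherits(depth, "depth_field"), "depth must be a depth_field")
  d <- depth$depth
  lab <- array(NA_character_, dim(d))
  on <- !is.na(d)
  lab[on] <- ifelse(d[on] > 0.5, "superficial", "deep")
  lab
}

#' Weight-bearing femoral region of interest
#'
#' Restricts a femoral condyle candidate mask to its central, weight-bearing
#' part: per sagittal slice, the contiguous anteroposterior (column) span
#' starting at the trochlear-notch landmark and extending `fraction` of the
#' condyle's anteroposterior extent. `fraction = 1` keeps the whole
#' candidate mask. The exact extent of the weight-bearing region is a
#' convention external to this package, so the fraction is an explicit,
#' provenance-tracked parameter (default 0.6).
#'
#' @param seg A [cartilage_segmentation()].
#' @param femur_plate Femoral plate name (`"cMF"` or `"cLF"`).
#' @param fraction Fraction of the anteroposterior extent to keep, in (0,1].
#' @param notch Anteroposterior (column) index of the trochlear-notch
#'   landmark. Default: taken from `seg$notch`, else the anterior-most
#'   column of the candidate mask per slice.
#' @return Logical array flagging retained voxels.
#' @export
define_weightbearing_roi <- function(seg, femur_plate, fraction = 0.6,
                                     notch = NULL) {
  stop_if_not(inherits(seg, "cartilage_segmentation"),
              "seg must be a cartilage_segmentation")
  stop_if_not(femur_plate %in% names(seg$plate_masks),
              "unknown plate '%s'", femur_plate)
  stop_if_not(is_scalar_number(fraction) && fraction > 0 && fraction <= 1,
              "fraction must be in (0, 1]")
  mask <- seg$plate_masks[[femur_plate]]
  stop_if_not(any(mask), "plate '%s': empty candidate mask", femur_plate)
  if (is.null(notch) && !is.null(seg$notch) &&
      femur_plate %in% names(seg$notch)) {
    notch <- seg$notch[[femur_plate]]
  }
  roi <- array(FALSE, dim(mask))
  for (z in seq_len(dim(mask)[3])) {
    m <- mask[, , z]
    if (!any(m)) next
    cols_present <- which(apply(m, 2, any))
    nz <- if (is.null(notch)) min(cols_present) else notch
    stop_if_not(nz <= max(cols_present),
                "plate '%s', slice %d: notch landmark beyond the mask",
                femur_plate, z)
    extent <- max(cols_present) - nz + 1L
    keep_cols <- seq(nz, nz + ceiling(fraction * extent) - 1L)
    roi[, intersect(keep_cols, cols_present), z] <-
      m[, intersect(keep_cols, cols_present)]
  }
  roi
}

#' Per-plate, per-layer T2 summary
#'
#' Mean T2 over the valid voxels of one plate, split by layer and optionally
#' restricted to a region of interest. An empty valid set yields an
#' undefined mean (`NA`), not an error: it is a data state that downstream
#' stages must handle.
#'
#' @param t2map A `t2_map` from [build_t2_map()].
#' @param labels Layer label array from [partition_layers()] (defines the
#'   plate's voxels).
#' @param roi Optional logical array; `NULL` keeps all plate voxels.
#' @param plate Plate name recorded in the output.
#' @return A data frame with one row per layer: `plate`, `layer`,
#'   `mean_t2_ms`, `n_voxels_valid`, `n_voxels_total`.
#' @export
summarize_plate <- function(t2map, labels, roi = NULL, plate) {
  stop_if_not(inherits(t2map, "t2_map"), "t2map must be a t2_map")
  stop_if_not(identical(dim(labels), dim(t2map$t2_ms)),
              "labels shape must match the T2 map")
  if (is.null(roi)) roi <- array(TRUE, dim(labels))
  stop_if_not(identical(dim(roi), dim(labels)),
              "roi shape must match the T2 map")
  out <- lapply(c("deep", "superficial"), function(lay) {
    in_layer <- !is.na(labels) & labels == lay & roi
    sel <- in_layer & t2map$valid
    data.frame(plate = plate, layer = lay,
               mean_t2_ms = if (any(sel)) mean(t2map$t2_ms[sel]) else NA_real_,
               n_voxels_valid = sum(sel),
               n_voxels_total = sum(in_layer),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Knee-level femorotibial average
#'
#' Averages the four femorotibial plate means (MT, LT, cMF, cLF) per layer.
#' The default is the unweighted mean of plate means; `weights = "voxel"`
#' weights each plate by its number of valid voxels.
#'
#' @param summaries Data frame of plate summaries (rows from
#'   [summarize_plate()] for all four plates).
#' @param weights `"equal"` (default) or `"voxel"`.
#' @return A data frame with one row per layer: `plate = "Avg"`, `layer`,
#'   `mean_t2_ms`, and the summed voxel counts.
#' @export
aggregate_femorotibial <- function(summaries, weights = c("equal", "voxel")) {
  weights <- match.arg(weights)
  plates <- c("MT", "LT", "cMF", "cLF")
  out <- lapply(unique(summaries$layer), function(lay) {
    s <- summaries[summaries$layer == lay, ]
    missing <- setdiff(plates, s$plate)
    stop_if_not(length(missing) == 0,
                "missing plate summaries for layer '%s': %s",
                lay, paste(missing, collapse = ", "))
    s <- s[match(plates, s$plate), ]
    w <- if (weights == "equal") rep(1, 4) else s$n_voxels_valid
    m <- if (any(is.na(s$mean_t2_ms)) || sum(w) == 0) NA_real_
    else sum(s$mean_t2_ms * w) / sum(w)
    data.frame(plate = "Avg", layer = lay, mean_t2_ms = m,
               n_voxels_valid = sum(s$n_voxels_valid),
               n_voxels_total = sum(s$n_voxels_total),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
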