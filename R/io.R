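# Plate label codes used in NIfTI label volumes.
PLATE_CODES <- c(MT = 1L, LT = 2L, cMF = 3L, cLF = 4L)

#' Write a phantom (or acquired study) to disk
#'
#' Writes the MESE series as one NIfTI volume per echo
#' (`echo_<TE>ms.nii.gz`) plus a 4D stack (`mese_4d.nii.gz`), the
#' segmentation as label volumes (`plates.nii.gz` with codes MT=1, LT=2,
#' cMF=3, cLF=4; `bone_interface.nii.gz` and `surface.nii.gz` as 0/1), the
#' ground truth (when present) as NIfTI volumes plus a JSON sidecar with
#' acquisition metadata.
#'
#' @param phantom A `cartilage_phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_phantom <- function(phantom, dir) {
  stop_if_not(inherits(phantom, "cartilage_phantom"),
              "phantom must be a cartilage_phantom")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- phantom$series$voxel_spacing_mm
  wr <- function(arr, name) {
    path <- file.path(dir, name)
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = sp), path)
    path
  }
  files <- character(0)
  tes <- phantom$series$echo_times_ms
  for (e in seq_along(tes)) {
    files <- c(files, wr(phantom$series$volumes[[e]],
                         sprintf("echo_%02.0fms.nii.gz", tes[e])))
  }
  stack4d <- array(unlist(phantom$series$volumes),
                   dim = c(dim(phantom$series$volumes[[1]]), length(tes)))
  files <- c(files, wr(stack4d, "mese_4d.nii.gz"))
  labels <- array(0L, dim(phantom$seg$plate_masks[[1]]))
  for (p in names(phantom$seg$plate_masks)) {
    labels[phantom$seg$plate_masks[[p]]] <- PLATE_CODES[[p]]
  }
  files <- c(files, wr(labels, "plates.nii.gz"),
             wr(phantom$seg$bone_interface * 1L, "bone_interface.nii.gz"),
             wr(phantom$seg$surface * 1L, "surface.nii.gz"))
  if (!is.null(phantom$truth)) {
    tl <- array(0L, dim(labels))
    tl[!is.na(phantom$truth$true_layer) &
         phantom$truth$true_layer == "deep"] <- 1L
    tl[!is.na(phantom$truth$true_layer) &
         phantom$truth$true_layer == "superficial"] <- 2L
    t2a <- phantom$truth$true_t2_ms; t2a[is.na(t2a)] <- 0
    da <- phantom$truth$true_depth; da[is.na(da)] <- -1
    files <- c(files, wr(t2a, "true_t2_ms.nii.gz"),
               wr(da, "true_depth.nii.gz"), wr(tl, "true_layer.nii.gz"))
  }
  sidecar <- file.path(dir, "mese.json")
  jsonlite::write_json(list(echo_times_ms = tes,
                            tr_ms = phantom$series$tr_ms,
                            voxel_spacing_mm = sp,
                            plate_codes = as.list(PLATE_CODES),
                            true_layer_codes = list(deep = 1, superficial = 2)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(files, sidecar))
}

#' Read a MESE series and segmentation from disk
#'
#' Reads the layout written by [write_phantom()]: either the per-echo
#' volumes or the 4D stack, the `mese.json` sidecar, and the label volumes.
#'
#' @param dir Directory containing the files.
#' @return A list with `series` ([mese_series()]) and `seg`
#'   ([cartilage_segmentation()]).
#' @export
read_mese_study <- function(dir) {
  sidecar <- file.path(dir, "mese.json")
  stop_if_not(file.exists(sidecar), "missing sidecar %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tes <- meta$echo_times_ms
  f4d <- file.path(dir, "mese_4d.nii.gz")
  if (file.exists(f4d)) {
    stack4d <- as.array(RNifti::readNifti(f4d))
    stop_if_not(length(dim(stack4d)) == 4 && dim(stack4d)[4] == length(tes),
                "4D stack does not match the sidecar echo count")
    vols <- lapply(seq_along(tes), function(e) stack4d[, , , e])
  } else {
    vols <- lapply(tes, function(te) {
      p <- file.path(dir, sprintf("echo_%02.0fms.nii.gz", te))
      stop_if_not(file.exists(p), "missing echo volume %s", p)
      as.array(RNifti::readNifti(p))
    })
  }
  labels <- as.array(RNifti::readNifti(file.path(dir, "plates.nii.gz")))
  bone <- as.array(RNifti::readNifti(file.path(dir, "bone_interface.nii.gz"))) > 0
  surf <- as.array(RNifti::readNifti(file.path(dir, "surface.nii.gz"))) > 0
  present <- names(PLATE_CODES)[PLATE_CODES %in% unique(as.integer(labels))]
  masks <- lapply(present, function(p) labels == PLATE_CODES[[p]])
  names(masks) <- present
  list(series = mese_series(vols, tes, meta$tr_ms, meta$voxel_spacing_mm),
       seg = cartilage_segmentation(masks, bone, surf, meta$voxel_spacing_mm))
}

#' Read and validate a cohort table CSV
#'
#' Expects the schema `subject_id, group, age, sex, bmi, visit, plate,
#' layer, t2_ms`. Violations of the schema or of the uniqueness invariant
#' are raised as errors via [validate_cohort()].
#'
#' @param path CSV file path.
#' @return The validated cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  stop_if_not(file.exists(path), "cannot read cohort file %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  viol <- validate_cohort(df)
  stop_if_not(nrow(viol) == 0, "invalid cohort table:\n%s",
              paste(viol$message, collapse = "\n"))
  df
}

#' Write a cohort table CSV
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Validate a cohort table
#'
#' Checks the column schema, the allowed factor levels, uniqueness of
#' (subject, visit, plate, layer), single group membership per subject, and
#' that follow-up subjects are a subset of baseline subjects.
#'
#' @param cohort Data frame to check.
#' @return A data frame of violations (zero rows when clean) with columns
#'   `check` and `message` (row numbers included where applicable).
#' @export
validate_cohort <- function(cohort) {
  v <- list()
  add <- function(check, msg) v[[length(v) + 1]] <<-
    data.frame(check = check, message = msg, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex", "bmi", "visit", "plate",
            "layer", "t2_ms")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0) {
    add("schema", sprintf("missing columns: %s", paste(missing, collapse = ", ")))
    return(do.call(rbind, v))
  }
  if (!all(cohort$visit %in% c("baseline", "year1"))) {
    add("levels", "visit must be 'baseline' or 'year1'")
  }
  if (!all(cohort$layer %in% c("superficial", "deep"))) {
    add("levels", "layer must be 'superficial' or 'deep'")
  }
  if (!all(cohort$plate %in% c("MT", "LT", "cMF", "cLF", "Avg"))) {
    add("levels", "plate must be one of MT, LT, cMF, cLF, Avg")
  }
  if (!all(cohort$sex %in% c("male", "female"))) {
    add("levels", "sex must be 'male' or 'female'")
  }
  key <- paste(cohort$subject_id, cohort$visit, cohort$plate, cohort$layer)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    add("uniqueness",
        sprintf("duplicate (subject, visit, plate, layer) rows: %s",
                paste(utils::head(rows, 10), collapse = ", ")))
  }
  gper <- tapply(cohort$group, cohort$subject_id,
                 function(g) length(unique(g)))
  if (any(gper > 1)) {
    add("groups", sprintf("subjects in more than one group: %s",
                          paste(names(gper)[gper > 1], collapse = ", ")))
  }
  bl <- unique(cohort$subject_id[cohort$visit == "baseline"])
  y1 <- unique(cohort$subject_id[cohort$visit == "year1"])
  extra <- setdiff(y1, bl)
  if (length(extra) > 0) {
    add("visits", sprintf("follow-up subjects missing a baseline: %s",
                          paste(extra, collapse = ", ")))
  }
  if (length(v) == 0) {
    data.frame(check = character(0), message = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
}
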