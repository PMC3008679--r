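#' Read a NIfTI-1 volume
#'
#' @param path NIfTI file path.
#' @return numeric array (3D or 4D) with attributes `tr_seconds` (from the
#'   header's temporal pixdim, when 4D) and `voxel_size_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "voxel_size_mm") <- pd[1:3]
  if (length(dim(arr)) == 4) attr(arr, "tr_seconds") <- pd[4]
  arr
}

#' Write a NIfTI-1 volume
#'
#' Data are stored as float32 on disk (computation stays in double).
#'
#' @param data 3D or 4D numeric/logical array.
#' @param path destination path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm per-axis voxel size (mm).
#' @param tr_seconds repetition time, written to the 4th pixdim for 4D data.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, voxel_size_mm = c(3, 3, 3), tr_seconds = 2) {
  nd <- length(dim(data))
  stopifnot(nd %in% c(3, 4))
  pd <- if (nd == 4) c(voxel_size_mm, tr_seconds) else voxel_size_mm
  img <- RNifti::asNifti(array(as.numeric(data), dim = dim(data)))
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a 6-column rigid-body motion-parameter file
#'
#' Expects one whitespace-delimited row per volume with 3 translations
#' followed by 3 rotations (the SPM `rp_*.txt` layout). Because rotation
#' files circulate in both radians and degrees, the angular unit must be
#' declared — either through `unit` or through a JSON sidecar
#' (`<path>.json` with field `rotation_unit`). Radians are converted so the
#' returned trace always carries degrees.
#'
#' @param path motion file path.
#' @param unit `"degrees"` or `"radians"`; `NULL` to require a sidecar.
#' @return a [motion_trace()] (translations mm, rotations degrees).
#' @export
read_motion <- function(path, unit = NULL) {
  if (is.null(unit)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("rotation unit not declared: pass 'unit' or provide sidecar ", sidecar)
    }
    unit <- jsonlite::read_json(sidecar)$rotation_unit
  }
  unit <- match.arg(unit, c("degrees", "radians"))
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6) {
    stop("motion file must have 6 columns, found ", ncol(m))
  }
  rot <- m[, 4:6, drop = FALSE]
  if (unit == "radians") rot <- rot * 180 / pi
  motion_trace(m[, 1:3, drop = FALSE], rot)
}

#' Write a motion trace with a unit sidecar
#'
#' @param trace a [motion_trace()].
#' @param path destination text file; a `<path>.json` sidecar recording the
#'   rotation unit is written alongside.
#' @param unit angular unit to write (`"degrees"` or `"radians"`).
#' @return `path`, invisibly.
#' @export
write_motion <- function(trace, path, unit = c("degrees", "radians")) {
  unit <- match.arg(unit)
  stopifnot(inherits(trace, "motion_trace"))
  rot <- trace$rotations
  if (unit == "radians") rot <- rot * pi / 180
  utils::write.table(format(cbind(trace$translations, rot), digits = 10),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(rotation_unit = unit), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read / write the subject metadata table
#'
#' CSV with columns `subject_id`, `group`, the LSAS/HAMD/HAMA/STAI scores,
#' `sex`, `age`, `education`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_subjects <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_subjects
#' @param records subject data frame.
#' @export
write_subjects <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a synthetic cohort to standard on-disk formats
#'
#' Writes per-subject 4D NIfTI volumes and motion traces (with unit
#' sidecars), the shared ROI/brain/WM/CSF masks, and the subject CSV.
#'
#' @param cohort a [synthesize_cohort()] result.
#' @param dir output directory (created if missing).
#' @return invisible character vector of written files.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- cohort$config$tr_seconds
  files <- character(0)
  for (s in cohort$subjects) {
    f <- file.path(dir, paste0(s$subject_id, "_bold.nii.gz"))
    write_volume(s$volume, f, tr_seconds = tr)
    m <- file.path(dir, paste0("rp_", s$subject_id, ".txt"))
    write_motion(s$motion, m, unit = "degrees")
    files <- c(files, f, m, paste0(m, ".json"))
  }
  for (nm in names(cohort$masks$roi_masks)) {
    f <- file.path(dir, paste0("mask_", nm, ".nii.gz"))
    write_volume(cohort$masks$roi_masks[[nm]], f)
    files <- c(files, f)
  }
  for (nm in c("brain_mask", "wm_mask", "csf_mask")) {
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    write_volume(cohort$masks[[nm]], f)
    files <- c(files, f)
  }
  f <- file.path(dir, "subjects.csv")
  write_subjects(cohort$records, f)
  invisible(c(files, f))
}
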