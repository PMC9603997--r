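# On-disk layout: NIfTI-1 (.nii.gz, RAS+, mm) for images and label maps,
# a BIDS-PET-dialect JSON sidecar for frame timing (keys FrameTimesStart
# and FrameDuration, both in seconds), and TSV for all tables. Frame
# timing never lives in the NIfTI header.

gridAffine <- function(grid) {
  aff <- diag(c(grid@spacing, 1))
  aff[1:3, 4] <- grid@origin
  aff
}

asNiftiOnGrid <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(grid@spacing, rep(1, nd - 3))
  aff <- structure(gridAffine(grid), code = 2L)
  RNifti::`sform<-`(img, aff)
}

gridFromNifti <- function(img) {
  dm <- dim(img)
  aff <- RNifti::xform(img)
  GridSpec(dm[1:3], spacing = abs(diag(aff)[1:3]), origin = aff[1:3, 4])
}

#' Write / read a frame-timing JSON sidecar
#'
#' @param schedule a [FrameSchedule-class].
#' @param path file path of the JSON sidecar.
#' @return `readSidecar` returns a [FrameSchedule-class].
#' @export
writeSidecar <- function(schedule, path) {
  stopifnot(is(schedule, "FrameSchedule"))
  jsonlite::write_json(
    list(FrameTimesStart = schedule@starts, FrameDuration = schedule@durations),
    path, digits = NA)
  invisible(path)
}

#' @rdname writeSidecar
#' @export
readSidecar <- function(path) {
  if (!file.exists(path)) petStop("io", "sidecar not found: %s", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$FrameTimesStart) || is.null(js$FrameDuration))
    petStop("sidecar", "sidecar must contain FrameTimesStart and FrameDuration")
  tryCatch(FrameSchedule(js$FrameTimesStart, js$FrameDuration),
           error = function(e)
             petStop("schedule", "invalid frame schedule in %s: %s",
                     path, conditionMessage(e)))
}

#' Write a dynamic study to NIfTI plus sidecar
#'
#' @param study a [DynamicStudy-class].
#' @param imagePath output `.nii.gz` path.
#' @param sidecarPath output JSON sidecar path (default: image path with a
#'   `.json` extension).
#' @return Invisibly, the image path.
#' @export
writeDynamicStudy <- function(study, imagePath,
                              sidecarPath = sub("\\.nii(\\.gz)?$", ".json",
                                                imagePath)) {
  stopifnot(is(study, "DynamicStudy"))
  validObject(study)
  RNifti::writeNifti(asNiftiOnGrid(study@voxels, study@grid), imagePath)
  writeSidecar(study@schedule, sidecarPath)
  invisible(imagePath)
}

#' Read a dynamic study from NIfTI plus sidecar
#'
#' All metadata are validated: the sidecar frame count must match the
#' image's fourth dimension, the schedule must be contiguous, and the
#' subject metadata complete. Failures raise typed conditions
#' (`ponsPET_error_io`, `ponsPET_error_frames`, `ponsPET_error_schedule`);
#' a truncated or unreadable file is an I/O error, never silent NaNs.
#'
#' @param imagePath 4D NIfTI path (kBq/cm^3).
#' @param sidecarPath frame-timing JSON sidecar path.
#' @param subject a [SubjectMeta-class] (or a list with fields
#'   `subjectId`, `group`, `injectedDose`, `bodyWeight`).
#' @return A [DynamicStudy-class].
#' @export
readDynamicStudy <- function(imagePath, sidecarPath, subject) {
  if (!file.exists(imagePath)) petStop("io", "image not found: %s", imagePath)
  img <- tryCatch(RNifti::readNifti(imagePath),
                  error = function(e)
                    petStop("io", "failed to read %s: %s", imagePath,
                            conditionMessage(e)))
  if (length(dim(img)) != 4L)
    petStop("io", "%s is not a 4D image", imagePath)
  schedule <- readSidecar(sidecarPath)
  if (dim(img)[4] != nFrames(schedule))
    petStop("frames", "sidecar has %d frames but image has %d",
            nFrames(schedule), dim(img)[4])
  if (is.list(subject) && !isS4(subject))
    subject <- new("SubjectMeta", subjectId = subject$subjectId,
                   group = subject$group,
                   injectedDose = subject$injectedDose,
                   bodyWeight = subject$bodyWeight)
  arr <- array(as.numeric(img), dim(img))
  if (any(!is.finite(arr)))
    petStop("io", "%s contains non-finite voxel values", imagePath)
  new("DynamicStudy", voxels = arr, grid = gridFromNifti(img),
      schedule = schedule, subject = subject)
}

#' Write / read a label volume (NIfTI + JSON name map)
#'
#' @param labels a [LabelVolume-class].
#' @param path `.nii.gz` path for the integer label map.
#' @param namesPath JSON path for the region-name map (default: `path`
#'   with a `.json` extension).
#' @return `readLabelVolume` returns a [LabelVolume-class].
#' @export
writeLabelVolume <- function(labels, path,
                             namesPath = sub("\\.nii(\\.gz)?$", ".json",
                                             path)) {
  stopifnot(is(labels, "LabelVolume"))
  validObject(labels)
  RNifti::writeNifti(asNiftiOnGrid(labels@labels, labels@grid), path,
                     datatype = "int16")
  jsonlite::write_json(as.list(labels@regionNames), namesPath,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLabelVolume
#' @export
readLabelVolume <- function(path, namesPath = sub("\\.nii(\\.gz)?$", ".json",
                                                  path)) {
  if (!file.exists(path)) petStop("io", "label map not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    petStop("io", "failed to read %s: %s", path,
                            conditionMessage(e)))
  nm <- unlist(jsonlite::read_json(namesPath, simplifyVector = TRUE))
  arr <- array(as.integer(img), dim(img)[1:3])
  new("LabelVolume", labels = arr, grid = gridFromNifti(img),
      regionNames = structure(as.integer(nm), names = names(nm)))
}

#' Build and write the per-frame TAC table
#'
#' One row per (subject, region, frame) with columns `subject_id`,
#' `region`, `frame_index`, `mid_time_s`, `mean_kBq_cm3` and `suv`.
#'
#' @param tacs list of [TimeActivityCurve-class] in kBq/cm^3.
#' @param dose,weight injected dose (kBq) and body weight (g), used for
#'   the SUV column.
#' @return `tacTable` returns the data.frame; `writeTacTable` writes it as
#'   TSV and returns the path invisibly.
#' @export
tacTable <- function(tacs, dose, weight) {
  do.call(rbind, lapply(tacs, function(tac) {
    stopifnot(is(tac, "TimeActivityCurve"))
    if (tac@unit != "kBq/cm3")
      petStop("units", "TAC table rows must be built from kBq/cm3 curves")
    data.frame(subject_id = tac@subjectId, region = tac@region,
               frame_index = seq_along(tac@midTimes),
               mid_time_s = tac@midTimes * 60,
               mean_kBq_cm3 = tac@values,
               suv = suvTransform(tac@values, dose, weight),
               stringsAsFactors = FALSE)
  }))
}

#' @rdname tacTable
#' @param path output TSV path.
#' @export
writeTacTable <- function(tacs, path, dose, weight) {
  writeResultsTable(tacTable(tacs, dose, weight), path)
}

#' Write / read a tidy results table as TSV
#'
#' Plain tab-separated text with a header row; numeric values are written
#' at full precision.
#'
#' @param df a data.frame.
#' @param path output TSV path.
#' @return `readResultsTable` returns the data.frame.
#' @export
writeResultsTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  if (!file.exists(path)) petStop("io", "table not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write the subject-metadata table
#'
#' Columns: subject_id, group, dose_kBq, weight_g, seed.
#'
#' @param studies list of [SimulatedStudy-class].
#' @param seeds per-subject seeds (same order).
#' @param path output TSV path.
#' @export
writeSubjectsTable <- function(studies, seeds, path) {
  df <- do.call(rbind, lapply(studies, function(s) {
    sub <- s@study@subject
    data.frame(subject_id = sub@subjectId, group = sub@group,
               dose_kBq = sub@injectedDose, weight_g = sub@bodyWeight,
               stringsAsFactors = FALSE)
  }))
  df$seed <- seeds
  writeResultsTable(df, path)
}
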