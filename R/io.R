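#' Write / read a session recording
#'
#' Recordings are stored as a delimited text table (one row per sample:
#' `time_s`, `y`, `r`, `theta`) plus a JSON sidecar holding the sampling
#' rate, muscle, trial markers, events and contraction blocks. Ground-truth
#' fields of synthetic recordings are not serialized.
#'
#' @param recording an `llr_recording`.
#' @param path path of the sample table; the sidecar is written next to it
#'   as `<path>.json`.
#' @param digits signal print precision.
#' @export
write_recording <- function(recording, path, digits = 8) {
  n <- length(recording$y)
  df <- data.frame(
    time_s = sprintf("%.6f", (seq_len(n) - 1) / recording$fs),
    y = sprintf(paste0("%.", digits, "g"), recording$y),
    r = sprintf(paste0("%.", digits, "g"), recording$r),
    theta = sprintf(paste0("%.", digits, "g"), recording$theta))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(fs = recording$fs, muscle = recording$muscle,
               channels = c("y", "r", "theta"),
               trial_markers = recording$trial_markers,
               events = recording$events,
               contraction_blocks = recording$contraction_blocks)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(fs = side$fs, y = as.numeric(df$y), r = as.numeric(df$r),
                 theta = as.numeric(df$theta),
                 trial_markers = as.integer(side$trial_markers),
                 events = as_tibble(side$events),
                 contraction_blocks = as_tibble(side$contraction_blocks),
                 muscle = side$muscle, truth = NULL),
            class = "llr_recording")
}

#' NIfTI-1 volume I/O
#'
#' Thin wrappers over RNifti for 3D/4D arrays with isotropic voxels.
#'
#' @param arr numeric 3D or 4D array.
#' @param path file path (`.nii`).
#' @param voxel_mm voxel size (mm).
#' @export
write_volume <- function(arr, path, voxel_mm = 2) {
  img <- RNifti::asNifti(arr, pixdim = rep(voxel_mm, min(3L, length(dim(arr)))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "voxel_mm") <- RNifti::pixdim(img)[1]
  arr
}
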