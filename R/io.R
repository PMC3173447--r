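#' Read a 4D DCE series from NIfTI
#'
#' @param image Path to a 4D NIfTI file (.nii or .nii.gz).
#' @param frame_times Either a numeric vector of acquisition times in minutes
#'   or the path to a two-column CSV sidecar (`frame`, `time_min`).
#' @param baseline_frames Number of leading pre-contrast frames.
#' @return A [dce_series()]; voxel spacing is taken from the NIfTI header.
#' @export
read_dce_series <- function(image, frame_times, baseline_frames = 1L) {
  img <- RNifti::readNifti(image)
  if (is.character(frame_times)) {
    sidecar <- utils::read.csv(frame_times)
    frame_times <- sidecar[[2]][order(sidecar[[1]])]
  }
  spacing <- RNifti::pixdim(img)[1:3]
  dce_series(unclass(img)[, , , , drop = FALSE], frame_times,
             voxel_spacing = spacing, baseline_frames = baseline_frames)
}

#' Read an ROI from a NIfTI label mask
#'
#' @param mask Path to a 3D NIfTI mask; all non-zero voxels join the ROI.
#' @param label ROI role, `"tumor"` or `"artery"`.
#' @return A [roi()].
#' @export
read_roi_mask <- function(mask, label = "tumor") {
  img <- RNifti::readNifti(mask)
  idx <- which(unclass(img) != 0, arr.ind = TRUE)
  roi(idx, label = label)
}

#' Read an ROI from a CSV voxel list
#'
#' Expects columns x, y, z of 0-based voxel indices (x-fastest order as
#' written by most conversion tools); indices are converted to R's 1-based
#' convention.
#'
#' @param path CSV file path.
#' @param label ROI role.
#' @return A [roi()].
#' @export
read_roi_csv <- function(path, label = "tumor") {
  tab <- utils::read.csv(path)
  roi(as.matrix(tab[, 1:3]) + 1L, label = label)
}

#' Write an AIF as a two-column CSV
#'
#' @param aif An [aif()].
#' @param path Output path; columns `time_min`, `cp`.
#' @export
write_aif_csv <- function(aif, path) {
  utils::write.csv(data.frame(time_min = aif$times, cp = aif$cp),
                   path, row.names = FALSE)
}

#' Write fitted parameter maps as NIfTI volumes
#'
#' Writes `ktrans.nii.gz`, `ve.nii.gz` and `mask.nii.gz` into a directory,
#' plus a per-voxel CSV `voxels.csv`. Unfitted voxels hold NA in the
#' parameter volumes and 0 in the mask.
#'
#' @param map A `param_map` from [fit_tofts_map()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_param_map <- function(map, dir) {
  if (!inherits(map, "param_map")) stop_input("`map` must be a param_map")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mk <- function(values, fill = NA_real_) {
    a <- array(fill, dim = map$dim)
    a[as.matrix(map$voxels[, c("x", "y", "z")])] <- values
    a
  }
  paths <- file.path(dir, c("ktrans.nii.gz", "ve.nii.gz", "mask.nii.gz",
                            "voxels.csv"))
  RNifti::writeNifti(mk(map$voxels$ktrans), paths[1])
  RNifti::writeNifti(mk(map$voxels$ve), paths[2])
  RNifti::writeNifti(mk(as.numeric(map$voxels$fitted), fill = 0), paths[3])
  utils::write.csv(map$voxels, paths[4], row.names = FALSE)
  invisible(paths)
}
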