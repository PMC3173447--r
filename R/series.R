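#' Default DCE acquisition schedule
#'
#' Frame times, in minutes, of the eight-frame breast DCE protocol the package
#' is built around: one pre-contrast frame at 0 min followed by seven
#' post-contrast frames sampling the decay phase at roughly 1.1-min intervals.
#'
#' @return Numeric vector of 8 acquisition times (minutes).
#' @export
dce_frame_times <- function() {
  c(0, 1.36, 2.47, 3.59, 5.10, 6.21, 7.32, 8.44)
}

#' Construct a 4D DCE-MRI series
#'
#' Bundles a 4D signal-intensity array (x, y, z, frame) with its acquisition
#' times and the number of pre-contrast baseline frames.
#'
#' @param signal 4D numeric array of non-negative signal intensities,
#'   dimensions x, y, z, frame.
#' @param frame_times Numeric vector of acquisition times in minutes, one per
#'   frame, strictly increasing.
#' @param voxel_spacing Numeric length-3 voxel size in mm (informational).
#' @param baseline_frames Number of pre-contrast frames at the start of the
#'   series (>= 1).
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(signal, frame_times, voxel_spacing = c(1, 1, 1),
                       baseline_frames = 1L) {
  if (!is.array(signal) || length(dim(signal)) != 4L)
    stop_input("`signal` must be a 4D array (x, y, z, frame)")
  if (any(signal < 0)) stop_input("`signal` must be non-negative")
  nt <- dim(signal)[4]
  if (length(frame_times) != nt)
    stop_input("length(frame_times) must equal the number of frames (", nt, ")")
  if (any(diff(frame_times) <= 0))
    stop_input("`frame_times` must be strictly increasing")
  baseline_frames <- as.integer(baseline_frames)
  if (baseline_frames < 1L || baseline_frames >= nt)
    stop_input("`baseline_frames` must be in [1, n_frames - 1]")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop_input("`voxel_spacing` must be 3 positive values (mm)")
  structure(
    list(signal = signal, frame_times = as.numeric(frame_times),
         voxel_spacing = as.numeric(voxel_spacing),
         baseline_frames = baseline_frames),
    class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dce_series> %d x %d x %d grid, %d frames (%.2f-%.2f min), %d baseline frame(s)\n",
              d[1], d[2], d[3], d[4], min(x$frame_times), max(x$frame_times),
              x$baseline_frames))
  invisible(x)
}

#' Construct a voxel region of interest
#'
#' @param voxel_indices Integer matrix with one row per voxel and columns
#'   (x, y, z); 1-based indices into the series grid.
#' @param label ROI role, `"tumor"` or `"artery"`.
#' @return An object of class `roi`.
#' @export
roi <- function(voxel_indices, label = c("tumor", "artery")) {
  label <- match.arg(label)
  voxel_indices <- as.matrix(voxel_indices)
  if (nrow(voxel_indices) == 0L) stop_input("ROI must contain at least one voxel")
  if (ncol(voxel_indices) != 3L) stop_input("`voxel_indices` must have 3 columns (x, y, z)")
  storage.mode(voxel_indices) <- "integer"
  if (any(is.na(voxel_indices)) || any(voxel_indices < 1L))
    stop_input("ROI indices must be positive integers (1-based)")
  dimnames(voxel_indices) <- list(NULL, c("x", "y", "z"))
  structure(list(voxel_indices = voxel_indices, label = label), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s, %d voxel(s)\n", x$label, nrow(x$voxel_indices)))
  invisible(x)
}

check_roi_in_grid <- function(series, roi) {
  d <- dim(series$signal)[1:3]
  idx <- roi$voxel_indices
  bad <- idx[, 1] > d[1] | idx[, 2] > d[2] | idx[, 3] > d[3]
  if (any(bad))
    stop_input(sum(bad), " ROI voxel(s) fall outside the ",
               paste(d, collapse = "x"), " grid")
  invisible(TRUE)
}

#' Mean signal time course over an ROI
#'
#' Arithmetic mean of the raw signal over the ROI voxels, one value per frame.
#'
#' @param series A [dce_series()].
#' @param roi A [roi()] whose voxels lie inside the series grid.
#' @return Numeric vector with one mean signal value per frame.
#' @export
roi_mean_signal <- function(series, roi) {
  if (!inherits(series, "dce_series")) stop_input("`series` must be a dce_series")
  if (!inherits(roi, "roi")) stop_input("`roi` must be an roi object")
  check_roi_in_grid(series, roi)
  idx <- roi$voxel_indices
  nt <- length(series$frame_times)
  vapply(seq_len(nt),
         function(k) mean(series$signal[cbind(idx, k)]),
         numeric(1))
}
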