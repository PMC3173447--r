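#' Construct a concentration curve
#'
#' A time course of relative contrast-agent concentration. Concentrations are
#' relative: signal is converted by baseline subtraction under a linear
#' signal-concentration assumption with unit amplitude constant, so tissue and
#' plasma curves share the same arbitrary scale and the kinetic parameters of
#' the Tofts model are unaffected by it.
#'
#' @param times Numeric vector of sample times in minutes.
#' @param values Numeric vector of relative concentrations, same length.
#' @return An object of class `concentration_curve`.
#' @export
concentration_curve <- function(times, values) {
  if (length(times) != length(values))
    stop_input("`times` and `values` must have the same length")
  if (any(diff(times) <= 0)) stop_input("`times` must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "concentration_curve")
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf("<concentration_curve> %d samples, t in [%.2f, %.2f] min, peak %.4g\n",
              length(x$times), min(x$times), max(x$times), max(x$values)))
  invisible(x)
}

#' Convert a signal time course to relative concentration
#'
#' Subtracts the mean of the pre-contrast baseline frames from every frame.
#' Under the low-concentration linearity assumption the result is proportional
#' to the contrast-agent concentration; the proportionality constant is fixed
#' to 1 and cancels out of the Tofts model because tissue and arterial curves
#' share it. Negative post-subtraction values (noise) are retained, not
#' clipped.
#'
#' @param signal_course Numeric vector of per-frame signal intensities.
#' @param baseline_frames Number of leading pre-contrast frames averaged to
#'   form the baseline (>= 1, fewer than the course length).
#' @param times Sample times in minutes (defaults to 0-based frame index).
#' @return A [concentration_curve()].
#' @export
signal_to_concentration <- function(signal_course, baseline_frames = 1L,
                                    times = seq_along(signal_course) - 1) {
  n <- length(signal_course)
  baseline_frames <- as.integer(baseline_frames)
  if (baseline_frames < 1L) stop_input("`baseline_frames` must be >= 1")
  if (n <= baseline_frames)
    stop_input("signal course has ", n, " frame(s); need more than ",
               baseline_frames, " baseline frame(s)")
  base <- mean(signal_course[seq_len(baseline_frames)])
  concentration_curve(times, signal_course - base)
}
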