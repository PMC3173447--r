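#' Construct an arterial input function
#'
#' Low-level constructor; most users call [weinmann_aif()] or [measure_aif()].
#'
#' @param times Sample times in minutes.
#' @param cp Plasma concentration values (mmol/L for theoretical AIFs,
#'   relative units for measured AIFs).
#' @param kind `"measured"` or `"theoretical"`.
#' @param dose Injected dose in mmol per kg body weight (theoretical only).
#' @param constants Named list with `a1`, `a2` (kg/L) and `m1`, `m2` (1/min)
#'   for a biexponential theoretical AIF.
#' @param quality_warning Logical flag set by [measure_aif()] when the artery
#'   curve shows no credible enhancement.
#' @return An object of class `aif`.
#' @export
aif <- function(times, cp, kind = c("measured", "theoretical"),
                dose = NULL, constants = NULL, quality_warning = FALSE) {
  kind <- match.arg(kind)
  if (length(times) != length(cp))
    stop_input("`times` and `cp` must have the same length")
  if (any(diff(times) <= 0)) stop_input("`times` must be strictly increasing")
  structure(
    list(times = as.numeric(times), cp = as.numeric(cp), kind = kind,
         dose = dose, constants = constants,
         quality_warning = isTRUE(quality_warning)),
    class = "aif")
}

#' @export
print.aif <- function(x, ...) {
  cat(sprintf("<aif> %s, %d samples, t in [%.2f, %.2f] min%s\n",
              x$kind, length(x$times), min(x$times), max(x$times),
              if (x$quality_warning) " [quality warning]" else ""))
  invisible(x)
}

#' Theoretical (Weinmann) arterial input function
#'
#' Population plasma concentration curve after bolus injection, modelled as a
#' biexponential decay `Cp(t) = D * (a1 exp(-m1 t) + a2 exp(-m2 t))` with the
#' standard amplitude constants a1 = 3.99 kg/L, a2 = 4.78 kg/L and rate
#' constants m1 = 0.144/min, m2 = 0.0111/min. Time zero is the injection; when
#' only the decay phase is sampled, pass times measured from the first
#' post-contrast acquisition.
#'
#' @param times Evaluation times in minutes since injection (>= 0).
#' @param dose Injected dose D in mmol per kg body weight (default 0.1).
#' @param a1,a2 Amplitude constants in kg/L.
#' @param m1,m2 Decay rate constants in 1/min.
#' @return An [aif()] of kind `"theoretical"` carrying its constants so that
#'   downstream convolution can evaluate it analytically on a fine grid.
#' @examples
#' weinmann_aif(c(0, 1.11, 2.22))$cp
#' @export
weinmann_aif <- function(times, dose = 0.1, a1 = 3.99, a2 = 4.78,
                         m1 = 0.144, m2 = 0.0111) {
  if (dose <= 0) stop_input("`dose` must be positive")
  if (any(times < 0)) stop_input("`times` must be non-negative (minutes since injection)")
  cp <- dose * (a1 * exp(-m1 * times) + a2 * exp(-m2 * times))
  aif(times, cp, kind = "theoretical", dose = dose,
      constants = list(a1 = a1, a2 = a2, m1 = m1, m2 = m2))
}

# analytic evaluation of a theoretical AIF at arbitrary times
eval_theoretical_cp <- function(x, t) {
  k <- x$constants
  x$dose * (k$a1 * exp(-k$m1 * t) + k$a2 * exp(-k$m2 * t))
}

#' Measure an arterial input function from an artery ROI
#'
#' Averages the signal over a 3 x 3 in-plane pixel square (a seed pixel in the
#' artery centre plus its 8 in-plane neighbours) at every frame, optionally
#' translated frame-by-frame by externally supplied integer shifts to follow
#' patient motion, then converts the mean course to relative concentration by
#' baseline subtraction.
#'
#' @param series A [dce_series()].
#' @param seed_center Integer (x, y, z) voxel index of the square's centre,
#'   at least one pixel away from the in-plane grid edge.
#' @param selection_frame Frame at which the seed was placed (recorded in the
#'   returned track; default 2, the first post-contrast frame).
#' @param translations Optional integer matrix/data frame with one row per
#'   frame and columns (dx, dy): in-plane shift of the square at that frame.
#'   Default: no shift.
#' @param enhancement_factor Quality-control factor: if the post-baseline
#'   concentration maximum does not exceed `enhancement_factor` times the
#'   baseline pixel standard deviation, the AIF is flagged with a quality
#'   warning.
#' @return A list with elements `aif` (an [aif()] of kind `"measured"`, value
#'   0 at baseline) and `track` (data frame recording the square position and
#'   shift at every frame).
#' @export
measure_aif <- function(series, seed_center, selection_frame = 2L,
                        translations = NULL, enhancement_factor = 1.5) {
  if (!inherits(series, "dce_series")) stop_input("`series` must be a dce_series")
  d <- dim(series$signal)
  nt <- d[4]
  seed_center <- as.integer(seed_center)
  if (length(seed_center) != 3L) stop_input("`seed_center` must be (x, y, z)")
  if (is.null(translations)) {
    translations <- matrix(0L, nrow = nt, ncol = 2)
  } else {
    translations <- as.matrix(translations)
    if (nrow(translations) != nt || ncol(translations) != 2L)
      stop_input("`translations` must have one (dx, dy) row per frame")
    storage.mode(translations) <- "integer"
  }
  if (seed_center[3] < 1L || seed_center[3] > d[3])
    stop_input("seed slice outside the grid")

  off <- expand.grid(dx = -1:1, dy = -1:1)
  means <- numeric(nt)
  track <- data.frame(frame = seq_len(nt),
                      center_x = seed_center[1] + translations[, 1],
                      center_y = seed_center[2] + translations[, 2],
                      slice = seed_center[3],
                      dx = translations[, 1], dy = translations[, 2])
  for (k in seq_len(nt)) {
    cx <- track$center_x[k]; cy <- track$center_y[k]
    if (cx < 2L || cx > d[1] - 1L || cy < 2L || cy > d[2] - 1L)
      stop_input("artery square exits the grid at frame ", k,
                 " (centre ", cx, ",", cy, ")")
    px <- cbind(cx + off$dx, cy + off$dy, seed_center[3], k)
    means[k] <- mean(series$signal[px])
  }

  conc <- signal_to_concentration(means, series$baseline_frames,
                                  times = series$frame_times)

  # QC: enhancement must rise credibly above the baseline pixel noise
  b <- series$baseline_frames
  base_px <- as.vector(vapply(seq_len(b), function(k) {
    cx <- track$center_x[k]; cy <- track$center_y[k]
    series$signal[cbind(cx + off$dx, cy + off$dy, seed_center[3], k)]
  }, numeric(9)))
  base_sd <- stats::sd(base_px)
  peak <- max(conc$values[-seq_len(b)])
  qflag <- !(peak > enhancement_factor * base_sd)
  if (qflag)
    warning("measured AIF shows no credible arterial enhancement ",
            "(peak ", signif(peak, 3), " vs baseline sd ", signif(base_sd, 3), ")",
            call. = FALSE)

  out <- aif(series$frame_times, conc$values, kind = "measured",
             quality_warning = qflag)
  attr(track, "selection_frame") <- as.integer(selection_frame)
  list(aif = out, track = track)
}
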