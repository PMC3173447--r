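#' Tofts model parameters
#'
#' @param ktrans Volume transfer constant in 1/min (>= 0).
#' @param ve Fractional volume of the extravascular extracellular space,
#'   in (0, 1].
#' @return An object of class `tofts_params` with derived efflux rate
#'   `kep = ktrans / ve` (1/min).
#' @export
tofts_params <- function(ktrans, ve) {
  if (!is.finite(ktrans) || ktrans < 0) stop_input("`ktrans` must be >= 0")
  if (!is.finite(ve) || ve <= 0 || ve > 1) stop_input("`ve` must be in (0, 1]")
  structure(list(ktrans = ktrans, ve = ve, kep = ktrans / ve),
            class = "tofts_params")
}

#' @export
print.tofts_params <- function(x, ...) {
  cat(sprintf("<tofts_params> ktrans = %.4g /min, ve = %.4g, kep = %.4g /min\n",
              x$ktrans, x$ve, x$kep))
  invisible(x)
}

# Convolution y(t) = int_0^t cp(u) exp(-kep (t-u)) du on a uniform grid,
# via the recursive exponential-kernel update that is exact when cp is
# piecewise linear between grid nodes:
#   y_{j+1} = E y_j + c_j (1-E)/kep + s_j (dt - (1-E)/kep)/kep,  E = exp(-kep dt)
# This is numerically stable for any kep >= 0 (no exp(+kep t) factors).
conv_exp_uniform <- function(dt, cp, kep) {
  n <- length(cp)
  if (n < 2L) return(numeric(n))
  c0 <- cp[-n]
  c1 <- cp[-1]
  E <- exp(-kep * dt)
  if (kep * dt > 1e-8) {
    g <- (1 - E) / kep
    inc <- c0 * g + (c1 - c0) * (dt - g) / (dt * kep)
  } else {
    inc <- (c0 + c1) / 2 * dt  # kep -> 0 limit (plain area increment)
  }
  c(0, as.numeric(stats::filter(inc, E, method = "recursive")))
}

# one exact step of the same update over an interval of length h (vectorised)
conv_exp_step <- function(y0, cp0, cp1, h, kep) {
  E <- exp(-kep * h)
  small <- kep * h <= 1e-8
  g <- ifelse(small, h, (1 - E) / kep)
  inc <- ifelse(small,
                (cp0 + cp1) / 2 * h,
                cp0 * g + (cp1 - cp0) * (h - g) / (h * kep))
  y0 * E + inc
}

# sample cp on arbitrary times: analytic for theoretical AIFs, linear
# interpolation of the stored samples otherwise
aif_cp_at <- function(aif, t) {
  if (aif$kind == "theoretical" && !is.null(aif$constants)) {
    eval_theoretical_cp(aif, t)
  } else {
    stats::approx(aif$times, aif$cp, xout = t, rule = 2)$y
  }
}

#' Forward Tofts (modified Kety) model
#'
#' Tissue concentration
#' `Ct(t) = ktrans * int_0^t Cp(u) exp(-(ktrans/ve) (t-u)) du`,
#' assuming negligible plasma volume. The convolution is evaluated on a
#' uniform fine grid (default step 0.01 min) with the plasma curve taken
#' analytically for theoretical AIFs and linearly interpolated for measured
#' ones; the exponential kernel is integrated exactly over each step.
#'
#' @param params A [tofts_params()].
#' @param aif An [aif()] whose support covers `[0, max(eval_times)]`.
#' @param eval_times Output sample times in minutes (within the AIF support).
#' @param dt Integration step in minutes (default 0.01).
#' @return A [concentration_curve()] sampled at `eval_times`.
#' @export
tofts_forward <- function(params, aif, eval_times, dt = 0.01) {
  if (!inherits(params, "tofts_params")) stop_input("`params` must be tofts_params")
  if (!inherits(aif, "aif")) stop_input("`aif` must be an aif object")
  if (any(eval_times < 0) || max(eval_times) > max(aif$times) + 1e-9)
    stop_input("`eval_times` outside the AIF support [0, ",
               max(aif$times), "] min")
  if (params$ktrans == 0)
    return(concentration_curve(eval_times, rep(0, length(eval_times))))

  kep <- params$kep
  tmax <- max(eval_times)
  n <- floor(tmax / dt + 1e-9)
  tg <- seq(0, by = dt, length.out = n + 1)
  cp <- aif_cp_at(aif, tg)
  y <- conv_exp_uniform(dt, cp, kep)

  # sample at eval_times: exact partial step from the last grid node below t
  j <- pmin(floor(eval_times / dt + 1e-9), n)
  rem <- eval_times - j * dt
  out <- y[j + 1]
  part <- which(rem > 1e-12)
  if (length(part)) {
    t0 <- j[part] * dt
    out[part] <- conv_exp_step(y[j[part] + 1],
                               aif_cp_at(aif, t0),
                               aif_cp_at(aif, eval_times[part]),
                               rem[part], kep)
  }
  concentration_curve(eval_times, params$ktrans * out)
}

#' Closed-form Tofts model under a biexponential AIF
#'
#' For `Cp(t) = D (a1 exp(-m1 t) + a2 exp(-m2 t))` the Tofts convolution has
#' the analytic solution
#' `Ct(t) = D ktrans sum_i a_i (exp(-kep t) - exp(-m_i t)) / (m_i - kep)`.
#' Serves as the exact reference for [tofts_forward()] and as the generating
#' model of the synthetic phantom. The removable singularity at `kep = m_i`
#' is handled by its limit `a_i t exp(-kep t)`.
#'
#' @param params A [tofts_params()].
#' @param eval_times Output sample times in minutes since injection.
#' @param dose,a1,a2,m1,m2 Biexponential AIF constants as in [weinmann_aif()].
#' @return A [concentration_curve()].
#' @export
tofts_forward_biexp <- function(params, eval_times, dose = 0.1,
                                a1 = 3.99, a2 = 4.78,
                                m1 = 0.144, m2 = 0.0111) {
  if (!inherits(params, "tofts_params")) stop_input("`params` must be tofts_params")
  if (any(eval_times < 0)) stop_input("`eval_times` must be >= 0")
  kep <- params$kep
  t <- eval_times
  term <- function(a, m) {
    if (abs(m - kep) < 1e-8) a * t * exp(-kep * t)
    else a * (exp(-kep * t) - exp(-m * t)) / (m - kep)
  }
  ct <- dose * params$ktrans * (term(a1, m1) + term(a2, m2))
  concentration_curve(eval_times, ct)
}

#' Fit result container
#' @keywords internal
fit_result <- function(params, rss, converged, n_iter, degenerate = FALSE,
                       scale_note = "absolute") {
  structure(list(params = params, rss = rss, converged = converged,
                 n_iter = n_iter, degenerate = degenerate,
                 scale_note = scale_note),
            class = "tofts_fit")
}

#' @export
print.tofts_fit <- function(x, ...) {
  cat(sprintf("<tofts_fit> ktrans = %.4g /min, ve = %.4g (rss %.3g, %s%s)\n",
              x$params$ktrans, x$params$ve, x$rss,
              if (x$converged) "converged" else "not converged",
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

default_fit_options <- function(options = list()) {
  modifyList(list(
    lower = c(ktrans = 0, ve = 1e-3),
    upper = c(ktrans = 10, ve = 1),
    init = c(ktrans = 0.1, ve = 0.3),
    dt = 0.01,
    multistart_ktrans = 10^seq(-2, 0, length.out = 3),
    multistart_ve = 10^seq(-2, 0, length.out = 3),
    maxiter = 200,
    enhancement_threshold = 3
  ), options)
}

#' Fit the Tofts model to a tissue concentration curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \code{minpack.lm::nls.lm}) of [tofts_forward()] to an observed curve,
#' minimising the residual sum of squares. Bounds are
#' `ktrans` in `[0, 10]` /min and `ve` in `[1e-3, 1]`; the default start is
#' `(0.1, 0.3)`. If the first fit does not converge, a 3 x 3 log-spaced
#' multi-start grid is tried and the best fit by residual sum of squares
#' (ties broken toward lower `ktrans`) is returned with its convergence flag.
#' An all-zero or all-negative curve is unidentifiable and returns
#' `ktrans = 0` (with `ve` pinned to the initial value) flagged `degenerate`.
#'
#' @param ct A [concentration_curve()] of tissue concentration, on the same
#'   clock as the AIF (time 0 = start of the AIF support).
#' @param aif An [aif()] covering the curve's time span.
#' @param options Named list overriding the defaults listed above
#'   (`lower`, `upper`, `init`, `dt`, `maxiter`, ...).
#' @return A `tofts_fit` with elements `params`, `rss`, `converged`,
#'   `n_iter`, `degenerate` and `scale_note` (`"relative"` when a measured
#'   AIF was used, since measured AIFs carry an arbitrary amplitude).
#' @export
fit_tofts <- function(ct, aif, options = list()) {
  opt <- default_fit_options(options)
  if (!inherits(ct, "concentration_curve"))
    ct <- concentration_curve(ct$times, ct$values)
  if (!inherits(aif, "aif")) stop_input("`aif` must be an aif object")
  if (length(ct$values) < 4L)
    stop_input("need at least 4 samples to fit the two-parameter model")
  if (max(ct$times) > max(aif$times) + 1e-9)
    stop_input("tissue curve extends beyond the AIF support (mismatched time axes)")
  scale_note <- if (aif$kind == "measured") "relative" else "absolute"

  if (max(ct$values) <= 0) {
    p <- tofts_params(0, opt$init[["ve"]])
    return(fit_result(p, sum(ct$values^2), converged = TRUE, n_iter = 0L,
                      degenerate = TRUE, scale_note = scale_note))
  }

  obs <- ct$values
  resid_fn <- function(par) {
    p <- tofts_params(par[1], par[2])
    tofts_forward(p, aif, ct$times, dt = opt$dt)$values - obs
  }
  run_fit <- function(start) {
    fit <- minpack.lm::nls.lm(
      par = unname(start), lower = unname(opt$lower), upper = unname(opt$upper),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = opt$maxiter))
    list(par = fit$par, rss = fit$deviance,
         converged = fit$info %in% 1:3, n_iter = fit$niter)
  }

  best <- run_fit(opt$init)
  at_bound <- any(abs(best$par - opt$lower) < 1e-8 |
                    abs(best$par - opt$upper) < 1e-8)
  if (!best$converged || at_bound) {
    starts <- expand.grid(ktrans = opt$multistart_ktrans, ve = opt$multistart_ve)
    fits <- c(list(best),
              lapply(seq_len(nrow(starts)),
                     function(i) run_fit(c(starts$ktrans[i], starts$ve[i]))))
    rss <- vapply(fits, `[[`, numeric(1), "rss")
    kt <- vapply(fits, function(f) f$par[1], numeric(1))
    best <- fits[[order(rss, kt)[1]]]
  }
  fit_result(tofts_params(best$par[1], best$par[2]), best$rss,
             best$converged, best$n_iter, scale_note = scale_note)
}

#' Theoretical AIF aligned to a series' decay-phase clock
#'
#' Builds the Weinmann AIF on the clock used for fitting: time 0 at the first
#' post-contrast frame, where the sampled decay phase begins.
#'
#' @param series A [dce_series()].
#' @param dose,a1,a2,m1,m2 Constants passed to [weinmann_aif()].
#' @return An [aif()] sampled at the post-contrast frame times.
#' @export
series_theoretical_aif <- function(series, dose = 0.1, a1 = 3.99, a2 = 4.78,
                                   m1 = 0.144, m2 = 0.0111) {
  b <- series$baseline_frames
  t <- series$frame_times
  weinmann_aif(t[-seq_len(b)] - t[b + 1L], dose = dose,
               a1 = a1, a2 = a2, m1 = m1, m2 = m2)
}

# re-express an AIF on the decay-phase clock of a series
shift_aif_to_series <- function(aif, series) {
  b <- series$baseline_frames
  t <- series$frame_times
  tfit <- t[-seq_len(b)] - t[b + 1L]
  if (aif$kind == "theoretical") {
    if (length(aif$times) == length(tfit) &&
        max(abs(aif$times - tfit)) < 1e-9) return(aif)
    if (is.null(aif$constants))
      stop_input("theoretical AIF lacks constants; cannot re-align to the series")
    weinmann_aif(tfit, dose = aif$dose, a1 = aif$constants$a1,
                 a2 = aif$constants$a2, m1 = aif$constants$m1,
                 m2 = aif$constants$m2)
  } else {
    if (length(aif$times) != length(t))
      stop_input("measured AIF must be sampled at the series frame times")
    out <- aif
    out$times <- tfit
    out$cp <- aif$cp[-seq_len(b)]
    out
  }
}

#' Voxelwise Tofts parameter maps over an ROI
#'
#' Applies [fit_tofts()] to the baseline-subtracted signal course of every ROI
#' voxel, on the decay-phase clock (time 0 at the first post-contrast frame).
#' Voxels whose enhancement peak does not exceed
#' `enhancement_threshold` times the baseline noise (standard deviation of the
#' baseline-frame signal across the ROI) are excluded from fitting, mirroring
#' the exclusion of non-enhancing (necrotic or unperfused) areas; they remain
#' in the map flagged unfitted, never zero-filled.
#'
#' @param series A [dce_series()].
#' @param roi A tumor [roi()].
#' @param aif Either a measured [aif()] sampled at the series frame times
#'   (from [measure_aif()]) or a theoretical one (from
#'   [series_theoretical_aif()] or [weinmann_aif()]).
#' @param options Fit options as in [fit_tofts()]; additionally
#'   `enhancement_threshold` (default 3).
#' @return A `param_map`: data frame `voxels` with per-voxel coordinates,
#'   `fitted` flag, `ktrans`, `ve`, `kep`, `rss`, `converged`, `degenerate`,
#'   plus the grid dimensions as attribute.
#' @export
fit_tofts_map <- function(series, roi, aif, options = list()) {
  opt <- default_fit_options(options)
  check_roi_in_grid(series, roi)
  aif_fit <- shift_aif_to_series(aif, series)
  b <- series$baseline_frames
  t <- series$frame_times
  tfit <- t[-seq_len(b)] - t[b + 1L]
  idx <- roi$voxel_indices
  nv <- nrow(idx)

  # baseline noise level across the ROI
  base_vals <- as.vector(vapply(seq_len(b),
    function(k) series$signal[cbind(idx, k)], numeric(nv)))
  sigma <- stats::sd(base_vals)
  if (!is.finite(sigma)) sigma <- 0

  vox <- data.frame(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                    fitted = FALSE, ktrans = NA_real_, ve = NA_real_,
                    kep = NA_real_, rss = NA_real_, converged = NA,
                    degenerate = NA)
  for (i in seq_len(nv)) {
    course <- series$signal[idx[i, 1], idx[i, 2], idx[i, 3], ]
    conc <- course - mean(course[seq_len(b)])
    post <- conc[-seq_len(b)]
    if (!(max(post) > opt$enhancement_threshold * sigma) || max(post) <= 0)
      next
    fit <- tryCatch(
      fit_tofts(concentration_curve(tfit, post), aif_fit, options = opt),
      error = function(e) NULL)
    if (is.null(fit)) next
    vox$fitted[i] <- TRUE
    vox$ktrans[i] <- fit$params$ktrans
    vox$ve[i] <- fit$params$ve
    vox$kep[i] <- fit$params$kep
    vox$rss[i] <- fit$rss
    vox$converged[i] <- fit$converged
    vox$degenerate[i] <- fit$degenerate
  }
  if (!any(vox$fitted))
    warning("no ROI voxel passed the enhancement pre-filter; map is empty",
            call. = FALSE)
  structure(list(voxels = vox, dim = dim(series$signal)[1:3],
                 label = roi$label, aif_kind = aif$kind),
            class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  cat(sprintf("<param_map> %d voxel(s), %d fitted (%s AIF)\n",
              nrow(x$voxels), sum(x$voxels$fitted), x$aif_kind))
  invisible(x)
}
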