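#' Configure a synthetic 4D DCE phantom
#'
#' Describes a digital phantom: a uniform-baseline volume containing one or
#' more spherical lesion sub-regions with known Tofts parameters and a small
#' artery patch following the Weinmann input function, imaged at the default
#' eight-frame decay-phase schedule. Signal is generated on the decay-phase
#' clock: the pre-contrast frame stays at baseline, the first post-contrast
#' frame is the arterial peak, and tissue accumulates contrast from there on.
#'
#' @param grid_dim Integer (nx, ny, nz) grid size.
#' @param frame_times Acquisition times (min), default [dce_frame_times()].
#' @param lesions List of lesion sub-regions, each a list with `center`
#'   (x, y, z), `radius` (voxels), `ktrans` (1/min) and `ve`.
#' @param artery List with `center` (x, y, z) of a 3 x 3 in-plane artery patch
#'   and `dose` (mmol/kg, default 0.1).
#' @param noise_model `"rician"` (magnitude MRI, default) or `"gaussian"`.
#' @param sigma Noise standard deviation as a fraction of the peak artery
#'   signal enhancement (default 0 = noise-free).
#' @param baseline Pre-contrast signal level in arbitrary units.
#' @param signal_scale Gain converting relative concentration to signal units;
#'   shared by tissue and artery, so fitted parameters do not depend on it.
#' @param seed Optional RNG seed for reproducible noise.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_dim = c(24, 24, 3),
                           frame_times = dce_frame_times(),
                           lesions = list(list(center = c(8, 8, 2), radius = 3,
                                               ktrans = 0.2, ve = 0.3)),
                           artery = list(center = c(19, 19, 2), dose = 0.1),
                           noise_model = c("rician", "gaussian"),
                           sigma = 0, baseline = 100, signal_scale = 100,
                           seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (sigma < 0) stop_input("`sigma` must be >= 0")
  if (any(diff(frame_times) <= 0))
    stop_input("`frame_times` must be strictly increasing")
  cfg <- structure(list(grid_dim = as.integer(grid_dim),
                        frame_times = frame_times, lesions = lesions,
                        artery = artery, noise_model = noise_model,
                        sigma = sigma, baseline = baseline,
                        signal_scale = signal_scale, seed = seed),
                   class = "phantom_config")
  # overlap check
  occ <- c(lapply(lesions, lesion_voxels, grid_dim = cfg$grid_dim),
           list(artery_voxels(artery$center)))
  keys <- lapply(occ, function(m) paste(m[, 1], m[, 2], m[, 3]))
  if (anyDuplicated(unlist(keys)))
    stop_input("lesion and artery regions must be disjoint")
  cfg
}

lesion_voxels <- function(lesion, grid_dim) {
  ctr <- lesion$center
  r <- ceiling(lesion$radius)
  g <- expand.grid(x = max(1, ctr[1] - r):min(grid_dim[1], ctr[1] + r),
                   y = max(1, ctr[2] - r):min(grid_dim[2], ctr[2] + r),
                   z = max(1, ctr[3] - r):min(grid_dim[3], ctr[3] + r))
  d2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
  as.matrix(g[d2 <= lesion$radius^2, , drop = FALSE])
}

artery_voxels <- function(center) {
  g <- expand.grid(x = center[1] + (-1:1), y = center[2] + (-1:1), z = center[3])
  as.matrix(g)
}

#' Generate a synthetic DCE series with known ground truth
#'
#' Tissue voxels follow the closed-form Tofts solution under the Weinmann
#' input; artery voxels follow the Weinmann curve itself; both are scaled to
#' signal units, offset by the baseline and optionally corrupted with
#' Gaussian or Rician noise whose level is a fraction of the peak artery
#' enhancement. The same seed reproduces the series bit for bit.
#'
#' @param config A [phantom_config()].
#' @return A list of class `dce_phantom` with `series` (a [dce_series()]),
#'   `truth` (per-voxel data frame of generating `ktrans`/`ve`),
#'   `aif` (the true theoretical [aif()] on the decay-phase clock, mmol/L),
#'   `aif_signal_units` (the same curve expressed in signal units, i.e.
#'   multiplied by the phantom's concentration-to-signal gain, for fitting
#'   baseline-subtracted signal directly against a theoretical input),
#'   `tumor_roi` (a [roi()] over all lesion voxels) and `artery_center`.
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) stop_input("`config` must be a phantom_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- config$grid_dim
  t <- config$frame_times
  nt <- length(t)
  t0 <- t[2]                       # first post-contrast frame
  s <- t - t0                      # decay-phase clock; s < 0 = pre-contrast
  post <- which(s >= 0)
  dose <- config$artery$dose %||% 0.1

  signal <- array(config$baseline, dim = c(d, nt))

  # artery patch: Weinmann curve on the decay-phase clock
  true_aif <- weinmann_aif(s[post], dose = dose)
  avox <- artery_voxels(config$artery$center)
  for (j in seq_along(post)) {
    k <- post[j]
    signal[cbind(avox, k)] <- config$baseline +
      config$signal_scale * true_aif$cp[j]
  }

  # lesion sub-regions: closed-form Tofts curves
  truth <- NULL
  for (les in config$lesions) {
    lvox <- lesion_voxels(les, d)
    ct <- tofts_forward_biexp(tofts_params(les$ktrans, les$ve),
                              eval_times = s[post], dose = dose)$values
    for (j in seq_along(post)) {
      k <- post[j]
      signal[cbind(lvox, k)] <- config$baseline + config$signal_scale * ct[j]
    }
    truth <- rbind(truth, data.frame(x = lvox[, 1], y = lvox[, 2],
                                     z = lvox[, 3], ktrans = les$ktrans,
                                     ve = les$ve))
  }

  if (config$sigma > 0) {
    peak <- config$signal_scale * max(true_aif$cp)
    sd_abs <- config$sigma * peak
    if (config$noise_model == "gaussian") {
      signal <- signal + array(stats::rnorm(length(signal), 0, sd_abs),
                               dim = dim(signal))
    } else {
      e1 <- array(stats::rnorm(length(signal), 0, sd_abs), dim = dim(signal))
      e2 <- array(stats::rnorm(length(signal), 0, sd_abs), dim = dim(signal))
      signal <- sqrt((signal + e1)^2 + e2^2)
    }
  }
  signal[signal < 0] <- 0

  structure(list(
    series = dce_series(signal, t, baseline_frames = 1L),
    truth = truth,
    aif = true_aif,
    aif_signal_units = weinmann_aif(s[post], dose = dose * config$signal_scale),
    tumor_roi = roi(as.matrix(truth[, c("x", "y", "z")]), label = "tumor"),
    artery_center = config$artery$center),
    class = "dce_phantom")
}

#' Configure a synthetic patient cohort
#'
#' Grade-conditional distributions of treatment-induced percent changes in
#' `ktrans` and `ve` (for both AIF kinds) and in tumour size. Each group draws
#' from a shifted logistic distribution around its configured median, with a
#' small heavy-tailed mixture component reproducing occasional large outliers
#' (such as a leakage-space increase of about +190% under treatment).
#' `ve` and size changes are truncated below at -100%.
#'
#' Default group medians follow the reference 24-patient cohort
#' (complete responders A, partial responders B, non-responders C+D).
#'
#' @param n_a,n_b,n_cd Group sizes (>= 1).
#' @param ve_measured_medians,ktrans_measured_medians Named medians
#'   (A, B, CD) of percent changes with the measured AIF.
#' @param ve_theoretical_medians,ktrans_theoretical_medians Same for the
#'   theoretical AIF.
#' @param size_medians Median size changes per group.
#' @param scale Logistic scale parameter of the within-group spread (percent
#'   points).
#' @param heavy_tail_prob Probability of drawing from the wide mixture
#'   component.
#' @param heavy_tail_scale Logistic scale of the wide component.
#' @param seed Optional RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_a = 6, n_b = 7, n_cd = 11,
                          ve_measured_medians = c(A = -90, B = -75, CD = -52),
                          ktrans_measured_medians = c(A = -94, B = -89, CD = -23),
                          ve_theoretical_medians = c(A = -82, B = -68, CD = -50),
                          ktrans_theoretical_medians = c(A = -22, B = -94, CD = -85),
                          size_medians = c(A = -98, B = -73, CD = -72),
                          scale = 12, heavy_tail_prob = 0.05,
                          heavy_tail_scale = 60, seed = NULL) {
  if (any(c(n_a, n_b, n_cd) < 1)) stop_input("group sizes must be >= 1")
  if (scale <= 0 || heavy_tail_scale <= 0) stop_input("scales must be positive")
  if (heavy_tail_prob < 0 || heavy_tail_prob > 1)
    stop_input("`heavy_tail_prob` must be in [0, 1]")
  structure(as.list(environment()), class = "cohort_config")
}

draw_changes <- function(n, location, cfg, truncate = TRUE) {
  heavy <- stats::runif(n) < cfg$heavy_tail_prob
  x <- stats::rlogis(n, location,
                     ifelse(heavy, cfg$heavy_tail_scale, cfg$scale))
  if (truncate) pmax(x, -100) else x
}

#' Generate a synthetic patient cohort
#'
#' Draws one record per patient: percent changes in `ktrans` and `ve` for both
#' AIF kinds, size change, a clinical response label and the pathology grade.
#' Deterministic under the configured seed.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `id`, `ktrans_change_measured`,
#'   `ktrans_change_theoretical`, `ve_change_measured`,
#'   `ve_change_theoretical`, `size_change`, `clinical_response`,
#'   `sataloff_grade`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop_input("`config` must be a cohort_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  ns <- c(A = config$n_a, B = config$n_b, CD = config$n_cd)
  grp <- rep(names(ns), ns)
  draw_param <- function(medians, truncate) {
    unlist(lapply(names(ns),
                  function(g) draw_changes(ns[[g]], medians[[g]], config,
                                           truncate = truncate)),
           use.names = FALSE)
  }
  # clinical-response mix per pathology group, matching the reference cohort
  clin_probs <- list(A = c(CR = 4, PR = 2, SD = 0) / 6,
                     B = c(CR = 1, PR = 4, SD = 2) / 7,
                     CD = c(CR = 1, PR = 8, SD = 2) / 11)
  clinical <- unlist(lapply(names(ns), function(g)
    sample(c("CR", "PR", "SD"), ns[[g]], replace = TRUE,
           prob = clin_probs[[g]])), use.names = FALSE)
  grade <- unlist(lapply(names(ns), function(g) {
    if (g == "CD") sample(c("C", "D"), ns[[g]], replace = TRUE,
                          prob = c(10, 1) / 11)
    else rep(g, ns[[g]])
  }), use.names = FALSE)
  data.frame(
    id = seq_along(grp),
    ktrans_change_measured = draw_param(config$ktrans_measured_medians, FALSE),
    ktrans_change_theoretical = draw_param(config$ktrans_theoretical_medians, FALSE),
    ve_change_measured = draw_param(config$ve_measured_medians, TRUE),
    ve_change_theoretical = draw_param(config$ve_theoretical_medians, TRUE),
    size_change = draw_param(config$size_medians, TRUE),
    clinical_response = clinical,
    sataloff_grade = grade)
}
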