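param_grid <- expand.grid(ktrans = c(0.05, 0.2, 1.0), ve = c(0.1, 0.3, 0.6))

test_that("closed-form solution agrees with adaptive quadrature of the integral", {
  times <- dce_frame_times()
  for (i in seq_len(nrow(param_grid))) {
    p <- tofts_params(param_grid$ktrans[i], param_grid$ve[i])
    cf <- tofts_forward_biexp(p, times)$values
    oracle <- quad_tofts(p$ktrans, p$ve, times)
    expect_lt(max(abs(cf - oracle)) / max(abs(oracle)), 1e-10)
  }
})

test_that("closed form handles the removable singularity kep = m_i", {
  # kep exactly equal to m1: limit term a1 t exp(-kep t)
  p <- tofts_params(0.144 * 0.5, 0.5)     # kep = 0.144 = m1
  t <- c(1, 3, 6)
  got <- tofts_forward_biexp(p, t)$values
  expected <- 0.1 * p$ktrans * (3.99 * t * exp(-0.144 * t) +
    4.78 * (exp(-0.144 * t) - exp(-0.0111 * t)) / (0.0111 - 0.144))
  expect_equal(got, expected, tolerance = 1e-7)
})

test_that("zero transfer constant gives a zero curve in both formulations", {
  p <- tofts_params(0, 0.3)
  t <- dce_frame_times()
  expect_equal(tofts_forward_biexp(p, t)$values, rep(0, 8))
  expect_equal(tofts_forward(p, weinmann_aif(t), t)$values, rep(0, 8))
})

test_that("numerical convolution matches the closed form on the acquisition grid", {
  times <- dce_frame_times()
  a <- weinmann_aif(times)
  for (i in seq_len(nrow(param_grid))) {
    p <- tofts_params(param_grid$ktrans[i], param_grid$ve[i])
    num <- tofts_forward(p, a, times)$values
    cf <- tofts_forward_biexp(p, times)$values
    expect_lt(max(abs(num - cf)) / max(abs(cf)), 1e-4)
  }
})

test_that("numerical error decreases at least linearly in the step size", {
  times <- dce_frame_times()
  a <- weinmann_aif(times)
  p <- tofts_params(1.0, 0.1)             # stiffest case, kep = 10
  cf <- tofts_forward_biexp(p, times)$values
  err <- vapply(c(0.08, 0.02), function(dt) {
    max(abs(tofts_forward(p, a, times, dt = dt)$values - cf))
  }, numeric(1))
  expect_gt(err[1] / err[2], 4)           # >= order 1 over a 4x refinement
})

test_that("tissue curve is linear in the plasma curve", {
  t <- decay_times()
  p <- tofts_params(0.3, 0.4)
  cp <- weinmann_aif(t)$cp
  ct1 <- tofts_forward(p, aif(t, cp, kind = "measured"), t)$values
  ct3 <- tofts_forward(p, aif(t, 3 * cp, kind = "measured"), t)$values
  expect_equal(ct3, 3 * ct1, tolerance = 1e-12)
})

test_that("eval times outside the AIF support are rejected", {
  a <- weinmann_aif(decay_times())
  p <- tofts_params(0.2, 0.3)
  expect_error(tofts_forward(p, a, c(0, 20)), "support")
  expect_error(fit_tofts(concentration_curve(c(0, 5, 10, 20), rep(1, 4)), a),
               "mismatched")
})

test_that("parameter constraints are enforced", {
  expect_error(tofts_params(-0.1, 0.3), "ktrans")
  expect_error(tofts_params(0.2, 0), "ve")
  expect_error(tofts_params(0.2, 1.2), "ve")
  expect_equal(tofts_params(0.2, 0.4)$kep, 0.5)
})

test_that("noise-free curves are recovered to high accuracy", {
  t <- dce_frame_times()
  truth <- tofts_params(0.25, 0.4)
  ct <- tofts_forward_biexp(truth, t)
  fit <- fit_tofts(ct, weinmann_aif(t))
  expect_true(fit$converged)
  expect_equal(fit$params$ktrans, 0.25, tolerance = 1e-3)
  expect_equal(fit$params$ve, 0.4, tolerance = 1e-3)
})

test_that("degenerate curves return a flagged zero-ktrans fit", {
  t <- dce_frame_times()
  a <- weinmann_aif(t)
  z <- fit_tofts(concentration_curve(t, rep(0, 8)), a)
  expect_true(z$degenerate)
  expect_equal(z$params$ktrans, 0)
  neg <- fit_tofts(concentration_curve(t, rep(-0.5, 8)), a)
  expect_true(neg$degenerate)
  expect_error(fit_tofts(concentration_curve(0:2, rep(1, 3)), a),
               "at least 4")
})

test_that("optimizer reaches at least the truth's residual", {
  set.seed(11)
  t <- dce_frame_times()
  a <- weinmann_aif(t)
  truth <- tofts_params(0.2, 0.3)
  clean <- tofts_forward_biexp(truth, t)$values
  obs <- clean + rnorm(8, 0, 0.02 * max(clean))
  fit <- fit_tofts(concentration_curve(t, obs), a)
  rss_truth <- sum((tofts_forward(truth, a, t)$values - obs)^2)
  expect_lte(fit$rss, rss_truth + 1e-9)
})

test_that("parameters are recovered from noisy curves in the median", {
  set.seed(20)
  t <- dce_frame_times()
  a <- weinmann_aif(t)
  truth <- tofts_params(0.2, 0.3)
  clean <- tofts_forward_biexp(truth, t)$values
  sd_abs <- 0.02 * max(clean)
  est <- t(replicate(100, {
    fit <- fit_tofts(concentration_curve(t, clean + rnorm(8, 0, sd_abs)), a)
    c(fit$params$ktrans, fit$params$ve)
  }))
  expect_lt(abs(median(est[, 1]) - 0.2) / 0.2, 0.10)
  expect_lt(abs(median(est[, 2]) - 0.3) / 0.3, 0.10)
})

test_that("kep is invariant to the AIF amplitude while ktrans and ve rescale", {
  # rescaling the arterial curve alone divides both fitted ktrans and ve by
  # the same factor, so their ratio kep is the amplitude-free quantity
  t <- decay_times()
  truth <- tofts_params(0.3, 0.4)
  ct <- tofts_forward_biexp(truth, t)
  cp <- weinmann_aif(t)$cp
  abs_fit <- fit_tofts(ct, aif(t, cp, kind = "measured"))
  rel_fit <- fit_tofts(ct, aif(t, cp * 5, kind = "measured"))
  expect_equal(rel_fit$params$kep, abs_fit$params$kep, tolerance = 1e-4)
  expect_equal(rel_fit$params$ktrans, abs_fit$params$ktrans / 5,
               tolerance = 1e-4)
  expect_equal(rel_fit$params$ve, abs_fit$params$ve / 5, tolerance = 1e-4)
  expect_identical(rel_fit$scale_note, "relative")
})

test_that("voxelwise maps recover a two-region lesion at 1% noise", {
  cfg <- phantom_config(
    grid_dim = c(26, 14, 3),
    lesions = list(list(center = c(6, 7, 2), radius = 2.5, ktrans = 0.1, ve = 0.3),
                   list(center = c(14, 7, 2), radius = 2.5, ktrans = 0.4, ve = 0.3)),
    artery = list(center = c(21, 7, 2), dose = 0.1),
    noise_model = "gaussian", sigma = 0.01, seed = 303)
  ph <- generate_phantom(cfg)
  map <- fit_tofts_map(ph$series, ph$tumor_roi, ph$aif_signal_units)
  v <- merge(map$voxels, ph$truth, by = c("x", "y", "z"),
             suffixes = c("", "_true"))
  for (kt_true in c(0.1, 0.4)) {
    sub <- v[v$ktrans_true == kt_true & v$fitted, ]
    expect_gt(nrow(sub), 0)
    expect_lt(abs(median(sub$ktrans) - kt_true) / kt_true, 0.05)
    expect_lt(abs(median(sub$ve) - 0.3) / 0.3, 0.05)
  }
})

test_that("non-enhancing ROIs yield an empty fitted mask with a warning", {
  s <- uniform_series(100, dims = c(6, 6, 2))
  r <- roi(matrix(c(2, 2, 1, 3, 3, 1), ncol = 3, byrow = TRUE))
  a <- series_theoretical_aif(s)
  expect_warning(map <- fit_tofts_map(s, r, a), "enhancement")
  expect_equal(sum(map$voxels$fitted), 0)
  expect_true(all(is.na(map$voxels$ktrans)))   # flagged, not zero-filled
})

test_that("noise-free map medians equal the generating parameters", {
  ph <- generate_phantom(phantom_config(sigma = 0))
  map <- fit_tofts_map(ph$series, ph$tumor_roi, ph$aif_signal_units)
  s <- summarize_roi(map)
  expect_equal(unname(s["ktrans"]), 0.2, tolerance = 1e-5)
  expect_equal(unname(s["ve"]), 0.3, tolerance = 1e-5)
})
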