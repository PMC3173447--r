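# shared fixtures: everything is generated in code, nothing is stored

decay_times <- function() {
  t <- dce_frame_times()
  t[-1] - t[2]
}

uniform_series <- function(value = 100, dims = c(4, 4, 2)) {
  nt <- length(dce_frame_times())
  dce_series(array(value, dim = c(dims, nt)), dce_frame_times())
}

# independent oracle for the Tofts convolution under a biexponential input:
# adaptive quadrature of the defining integral, no shared code with the
# package's forward model
quad_tofts <- function(ktrans, ve, times, dose = 0.1, a1 = 3.99, a2 = 4.78,
                       m1 = 0.144, m2 = 0.0111) {
  kep <- ktrans / ve
  vapply(times, function(tt) {
    if (tt == 0) return(0)
    f <- function(u) {
      dose * (a1 * exp(-m1 * u) + a2 * exp(-m2 * u)) * exp(-kep * (tt - u))
    }
    ktrans * stats::integrate(f, 0, tt, rel.tol = 1e-12, abs.tol = 0)$value
  }, numeric(1))
}

# minimal param_map for summary tests
manual_param_map <- function(ktrans, ve = rep(0.3, length(ktrans))) {
  n <- length(ktrans)
  structure(list(
    voxels = data.frame(x = seq_len(n), y = 1L, z = 1L, fitted = TRUE,
                        ktrans = ktrans, ve = ve, kep = ktrans / ve,
                        rss = 0, converged = TRUE, degenerate = FALSE),
    dim = c(n, 1L, 1L), label = "tumor", aif_kind = "measured"),
    class = "param_map")
}

nonresponder_truth <- function(grade) {
  factor(ifelse(grade %in% c("C", "D"), "non_responder", "responder"),
         levels = c("responder", "non_responder"))
}
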