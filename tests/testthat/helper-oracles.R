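# Shared oracles and fixture builders.  Every oracle is independent of the
# code path it checks: finite differences of kernel_matrix, dense linear
# algebra for the marginal likelihood, and closed-form curves.

# Central finite differences of kernel_matrix with 4-level Richardson
# extrapolation in h^2 (needed to resolve third/fourth cross-derivatives to
# well below 1e-5).
fd_kernel_oracle <- function(spec, x, y, i, j, h0 = 0.08, levels = 4) {
  f <- function(dx, dy) kernel_matrix(spec, x + dx, y + dy)[1, 1]
  d1 <- function(g, h) (g(h) - g(-h)) / (2 * h)
  d2 <- function(g, h) (g(h) - 2 * g(0) + g(-h)) / h^2
  base <- function(h) {
    gy <- function(u) {
      gfun <- function(v) f(u, v)
      if (j == 0) gfun(0) else if (j == 1) d1(gfun, h) else d2(gfun, h)
    }
    if (i == 0) gy(0) else if (i == 1) d1(gy, h) else d2(gy, h)
  }
  hs <- h0 / 2^(0:(levels - 1))
  Tk <- vapply(hs, base, 0)
  for (m in 1:(levels - 1)) {
    Tk <- (4^m * Tk[-1] - Tk[-length(Tk)]) / (4^m - 1)
  }
  Tk
}

# -log of the multivariate normal density N(0, S) at y, via explicit
# inverse and determinant (dense-linear-algebra oracle for the NLL).
mvn_nll_oracle <- function(S, y) {
  as.numeric(0.5 * t(y) %*% solve(S, y) + 0.5 * determinant(S)$modulus +
               0.5 * length(y) * log(2 * pi))
}

# Covariance spec with wide bounds so any hand-picked log10 parameters are
# admissible.
wide_spec <- function(family, log10_params) {
  cov_spec(family, lower = rep(-12, 3), upper = rep(12, 3),
           log10_params = log10_params)
}

# Noiseless exponential growth data on the natural-log scale:
# log y(t) = log y0 + r t.
exp_log_data <- function(r = 0.25, y0 = 0.05, n = 40, t_max = 12) {
  t <- seq(0, t_max, length.out = n)
  gp_timeseries(t, log(y0) + r * t, transformed = TRUE)
}

# Hand-built posterior sample container (for statistic-level unit tests).
fake_samples <- function(f, g, times) {
  structure(list(f = f, g = g, times = times), class = "gp_samples")
}

# One GP fit of a synthetic growth curve, returning the trimmed error score
# of the inferred specific growth rate.
gp_growthrate_score <- function(n_points, data_seed, opt_seed,
                                family = "squared_exponential") {
  sim <- mixed_noisy_curve(n_points = n_points, seed = data_seed)
  logd <- gp_timeseries(sim$times, log(sim$observed), transformed = TRUE)
  opt <- suppressWarnings(
    optimize_hyperparameters(logd, cov_spec(family), n_restarts = 1,
                             seed = opt_seed))
  post <- joint_posterior(opt, logd, prediction_times = sim$times, derivs = 1)
  error_score(post$mean_g, sim$growth_rate)$value
}
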