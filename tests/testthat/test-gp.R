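test_that("marginal likelihood matches a dense multivariate-normal oracle", {
  set.seed(21)
  X <- sort(runif(6, 0, 10))
  y <- rnorm(6)
  d <- gp_timeseries(X, y)
  for (fam in c("squared_exponential", "matern_5_2", "neural_network")) {
    s <- wide_spec(fam, c(0.2, -0.3, -1))
    S <- kernel_matrix(s, X) + diag(10^(2 * -1), 6)
    expect_equal(negative_log_marginal_likelihood(s, d),
                 mvn_nll_oracle(S, y), tolerance = 1e-9)
  }
  # empirical (time-varying) noise enters as a diagonal scaling
  d2 <- gp_timeseries(rep(X, 2), c(y, y + rnorm(6, 0, 0.4)),
                      rep(1:2, each = 6))
  nz <- estimate_relative_noise(d2, 0.1)
  s <- wide_spec("squared_exponential", c(0.2, -0.3, -1))
  dvec <- gpgrowth:::.noise_diagonal(nz, d2$times)
  S <- kernel_matrix(s, d2$times) + diag(10^(2 * -1) * dvec)
  expect_equal(negative_log_marginal_likelihood(s, d2, nz),
               mvn_nll_oracle(S, d2$values), tolerance = 1e-9)
})

test_that("zero observations leave only the complexity penalty", {
  X <- seq(0, 5, length.out = 8)
  d <- gp_timeseries(X, rep(0, 8))
  s <- wide_spec("squared_exponential", c(0, -0.5, -1))
  S <- kernel_matrix(s, X) + diag(10^(2 * -1), 8)
  expect_equal(negative_log_marginal_likelihood(s, d),
               0.5 * as.numeric(determinant(2 * pi * S)$modulus),
               tolerance = 1e-9)
})

test_that("analytic likelihood gradients match central differences", {
  set.seed(22)
  X <- sort(runif(12, 0, 8))
  y <- sin(X) + rnorm(12, 0, 0.2)
  d <- gp_timeseries(X, y)
  for (fam in c("squared_exponential", "matern_5_2", "neural_network")) {
    s <- wide_spec(fam, c(0.2, 0.1, -0.8))
    g <- gpgrowth:::.nll_gradient(s, d, noise_constant())
    num <- vapply(1:3, function(i) {
      h <- 1e-6
      sp <- s; sp$log10_params[i] <- s$log10_params[i] + h
      sm <- s; sm$log10_params[i] <- s$log10_params[i] - h
      (negative_log_marginal_likelihood(sp, d) -
         negative_log_marginal_likelihood(sm, d)) / (2 * h)
    }, 0)
    expect_equal(g, num, tolerance = 1e-5)
  }
})

test_that("hyperparameter optimization is deterministic and honors bounds", {
  sim <- mixed_noisy_curve(n_points = 60, seed = 301)
  d <- gp_timeseries(sim$times, log(sim$observed), transformed = TRUE)
  o1 <- suppressWarnings(
    optimize_hyperparameters(d, cov_spec("squared_exponential"),
                             n_restarts = 1, seed = 5))
  o2 <- suppressWarnings(
    optimize_hyperparameters(d, cov_spec("squared_exponential"),
                             n_restarts = 1, seed = 5))
  expect_identical(o1$log10_params, o2$log10_params)
  expect_true(all(o1$log10_params >= o1$lower - 1e-9))
  expect_true(all(o1$log10_params <= o1$upper + 1e-9))
  # degenerate equal bounds pin the parameter at the bound
  o3 <- suppressWarnings(
    optimize_hyperparameters(d,
      cov_spec("squared_exponential", lower = c(-5, 0.5, -5),
               upper = c(5, 0.5, 0)),
      n_restarts = 1, seed = 5))
  expect_identical(o3$log10_params[2], 0.5)
})

test_that("noise magnitude is recovered from data simulated at known truth", {
  # draws from a known squared-exponential GP plus noise; sigma should come
  # back within a factor of 2 in at least 90% of seeds
  truth <- wide_spec("squared_exponential", c(0, -0.6, -1))
  n <- 200
  ok <- 0L
  n_seeds <- 20L
  for (sd_i in seq_len(n_seeds)) {
    set.seed(4000 + sd_i)
    X <- sort(runif(n, 0, 10))
    K <- kernel_matrix(truth, X)
    f <- drop(crossprod(chol(K + diag(1e-10, n)), rnorm(n)))
    y <- f + rnorm(n, 0, 0.1)
    d <- gp_timeseries(X, y)
    opt <- suppressWarnings(
      optimize_hyperparameters(d,
        cov_spec("squared_exponential", lower = c(-3, -3, -4),
                 upper = c(3, 2, 1)),
        n_restarts = 1, seed = sd_i))
    sig <- 10^opt$log10_params[3]
    if (sig > 0.05 && sig < 0.2) ok <- ok + 1L
  }
  expect_gte(ok / n_seeds, 0.9)
})

test_that("posterior interpolates noiseless data and nests plain regression", {
  X <- seq(0, 10, length.out = 25)
  y <- sin(X / 2)
  d <- gp_timeseries(X, y)
  s <- wide_spec("squared_exponential", c(0, 0.3, -5))
  post <- joint_posterior(s, d, prediction_times = X)
  expect_lt(max(abs(post$mean_f - y)), 1e-6)
  # f block reproduces the standard regression posterior computed densely
  sig2 <- 10^(2 * -5)
  K <- kernel_matrix(s, X)
  Ky <- K + diag(sig2, 25)
  mu_ref <- drop(K %*% solve(Ky, y))
  cov_ref <- K - K %*% solve(Ky, K)
  expect_equal(post$mean_f, mu_ref, tolerance = 1e-8)
  expect_equal(post$cov[1:25, 1:25], cov_ref, tolerance = 1e-6)
})

test_that("posterior derivative means are derivatives of the posterior mean", {
  sim <- mixed_noisy_curve(n_points = 80, seed = 302)
  d <- gp_timeseries(sim$times, log(sim$observed), transformed = TRUE)
  opt <- suppressWarnings(
    optimize_hyperparameters(d, cov_spec("squared_exponential"),
                             n_restarts = 1, seed = 7))
  grid <- seq(min(d$times), max(d$times), length.out = 600)
  post <- joint_posterior(opt, d, prediction_times = grid)
  dt <- diff(grid)
  fd_g <- diff(post$mean_f) / dt
  mid_g <- (post$mean_g[-1] + post$mean_g[-length(grid)]) / 2
  expect_lt(max(abs(fd_g - mid_g)) / max(abs(post$mean_g)), 1e-3)
  fd_h <- diff(post$mean_g) / dt
  mid_h <- (post$mean_h[-1] + post$mean_h[-length(grid)]) / 2
  expect_lt(max(abs(fd_h - mid_h)) / max(abs(post$mean_h)), 1e-3)
})

test_that("posterior variance never exceeds the prior variance at the data", {
  sim <- mixed_noisy_curve(n_points = 50, seed = 303)
  d <- gp_timeseries(sim$times, log(sim$observed), transformed = TRUE)
  s <- wide_spec("squared_exponential", c(0.5, -0.5, -1.5))
  post <- joint_posterior(s, d, prediction_times = sim$times)
  prior_var <- diag(kernel_matrix(s, sim$times))
  expect_true(all(post$sd_f^2 <= prior_var + 1e-10))
})

test_that("Matern posteriors stop at the first derivative", {
  sim <- mixed_noisy_curve(n_points = 40, seed = 304)
  d <- gp_timeseries(sim$times, log(sim$observed), transformed = TRUE)
  s <- wide_spec("matern_5_2", c(0.3, -0.3, -1.5))
  expect_error(joint_posterior(s, d, derivs = 2), "first-derivative")
  post <- joint_posterior(s, d)
  expect_identical(post$derivs, 1L)
  expect_null(post$mean_h)
})

test_that("posterior samples reproduce the posterior moments", {
  sim <- mixed_noisy_curve(n_points = 40, seed = 305)
  d <- gp_timeseries(sim$times, log(sim$observed), transformed = TRUE)
  s <- wide_spec("squared_exponential", c(0.4, -0.4, -1.5))
  grid <- seq(1, 14, length.out = 8)
  post <- joint_posterior(s, d, prediction_times = grid)
  smp <- sample_posterior(post, 10000, seed = 9)
  # reproducibility
  smp2 <- sample_posterior(post, 10000, seed = 9)
  expect_identical(smp$g, smp2$g)
  # empirical mean of f within 3 standard errors componentwise
  se <- post$sd_f / sqrt(10000)
  expect_true(all(abs(colMeans(smp$f) - post$mean_f) <= 3 * se + 1e-12))
  # empirical variance of g within 20% of the analytic diagonal
  vg <- apply(smp$g, 2, var)
  expect_true(all(abs(vg - post$sd_g^2) / pmax(post$sd_g^2, 1e-12) < 0.2))
})

test_that("2-sd credible bands cover GP-generated truth at >= 90% of points", {
  truth <- wide_spec("squared_exponential", c(0, -0.6, -1))
  n <- 30
  cover <- numeric(50)
  for (sd_i in 1:50) {
    set.seed(6000 + sd_i)
    X <- sort(runif(n, 0, 10))
    K <- kernel_matrix(truth, X)
    f <- drop(crossprod(chol(K + diag(1e-10, n)), rnorm(n)))
    y <- f + rnorm(n, 0, 0.1)
    d <- gp_timeseries(X, y)
    opt <- suppressWarnings(
      optimize_hyperparameters(d,
        cov_spec("squared_exponential", lower = c(-3, -3, -4),
                 upper = c(3, 2, 1)),
        n_restarts = 1, seed = sd_i))
    post <- joint_posterior(opt, d, prediction_times = X, derivs = 1)
    cover[sd_i] <- mean(abs(f - post$mean_f) <= 2 * post$sd_f)
  }
  expect_gte(mean(cover), 0.9)
})
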