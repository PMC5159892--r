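test_that("hand-built samples give the documented means and deviations", {
  times <- seq(0, 10, length.out = 5)
  # two samples with maximum rates 0.1 and 0.3 attained at the third point
  g <- rbind(c(0, 0.05, 0.1, 0.05, 0), c(0, 0.1, 0.3, 0.1, 0))
  f <- rbind(log(0.05) + 0.1 * times, log(0.05) + 0.3 * times)
  smp <- fake_samples(f, g, times)
  st <- growth_statistics(smp, y0_log = log(0.05))
  rate <- st[st$statistic == "max_growth_rate", ]
  expect_equal(rate$mean, 0.2)
  expect_equal(rate$sd, 0.1)           # population sd (divisor n)
  st2 <- growth_statistics(smp, y0_log = log(0.05), sd_type = "sample")
  expect_equal(st2[st2$statistic == "max_growth_rate", "sd"],
               sd(c(0.1, 0.3)))        # ~0.1414 with divisor n-1
  # doubling time is ln(2)/rate per sample, then averaged
  dt <- st[st$statistic == "doubling_time", ]
  expect_equal(dt$mean, mean(log(2) / c(0.1, 0.3)))
  # identical samples have zero spread
  st3 <- growth_statistics(fake_samples(f[c(1, 1), ], g[c(1, 1), ], times),
                           y0_log = log(0.05))
  expect_true(all(st3$sd == 0))
})

test_that("samples with non-positive maximum rate are excluded and counted", {
  times <- seq(0, 4, length.out = 4)
  g <- rbind(c(-0.2, -0.1, -0.3, -0.2), c(0.1, 0.4, 0.2, 0.1))
  f <- rbind(rep(0, 4), log(0.05) + 0.2 * times)
  smp <- fake_samples(f, g, times)
  expect_warning(st <- growth_statistics(smp, y0_log = log(0.05)),
                 "non-positive")
  expect_identical(attr(st, "n_excluded"), 1L)
  # the rate itself is still summarized over all samples
  expect_equal(st[st$statistic == "max_growth_rate", "mean"],
               mean(c(-0.1, 0.4)))
})

test_that("exponential growth yields rate r, zero lag and ln2/r doubling", {
  r <- 0.25
  d <- exp_log_data(r = r, n = 40)
  s <- wide_spec("squared_exponential", c(0.5, -1, -4))
  post <- joint_posterior(s, d, prediction_times = d$times)
  smp <- sample_posterior(post, 200, seed = 3)
  st <- growth_statistics(smp, y0_log = post$mean_f[1])
  get <- function(w) st[st$statistic == w, "mean"]
  # the max over the grid of sampled derivatives carries a small
  # extreme-value bias, so a 1% band is appropriate for 200 samples
  expect_equal(get("max_growth_rate"), r, tolerance = 0.01)
  expect_equal(get("lag_time"), 0, tolerance = 0.05)
  expect_equal(get("doubling_time"), log(2) / r, tolerance = 0.01)
  # the time of maximum always lies inside the observed window
  tm <- st[st$statistic == "time_of_max", "mean"]
  expect_gte(tm, min(d$times)); expect_lte(tm, max(d$times))
})

test_that("recovered maximum rate is consistent with Gompertz truth", {
  # log-scale Gompertz growth: mu_m is the exact maximum specific rate.
  # The narrow derivative peak of a Gompertz curve is slightly attenuated
  # by the smoothing implied by the marginal likelihood, a bias the
  # posterior spread of the statistic does not cover, so recovery is
  # checked against a 10% accuracy band (see the methods vignette).
  mu_m <- 0.6
  t <- seq(0, 15, length.out = 100)
  clean <- gompertz_curve(t, mu_m = mu_m)$values
  n_seeds <- 50L
  rel_err <- numeric(n_seeds)
  for (sd_i in seq_len(n_seeds)) {
    set.seed(7000 + sd_i)
    d <- gp_timeseries(t, clean + rnorm(100, 0, 0.02), transformed = TRUE)
    opt <- suppressWarnings(
      optimize_hyperparameters(d, cov_spec("squared_exponential"),
                               n_restarts = 2, seed = sd_i))
    post <- joint_posterior(opt, d, prediction_times = t)
    smp <- sample_posterior(post, 100, seed = sd_i)
    st <- suppressWarnings(growth_statistics(smp, y0_log = post$mean_f[1]))
    est <- st[st$statistic == "max_growth_rate", ]
    rel_err[sd_i] <- abs(est$mean - mu_m) / mu_m
  }
  expect_lt(median(rel_err), 0.10)
  expect_lt(max(rel_err), 0.15)
})

test_that("statistic uncertainty shrinks with the measurement noise", {
  t <- seq(0, 15, length.out = 80)
  clean <- gompertz_curve(t)$values
  sds <- vapply(c(0.05, 0.005), function(noise_sd) {
    set.seed(81)
    d <- gp_timeseries(t, clean + rnorm(80, 0, noise_sd), transformed = TRUE)
    opt <- suppressWarnings(
      optimize_hyperparameters(d, cov_spec("squared_exponential"),
                               n_restarts = 1, seed = 81))
    post <- joint_posterior(opt, d, prediction_times = t)
    smp <- sample_posterior(post, 200, seed = 82)
    st <- suppressWarnings(growth_statistics(smp, y0_log = post$mean_f[1]))
    st[st$statistic == "max_growth_rate", "sd"]
  }, 0)
  expect_lt(sds[2], sds[1])
})
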