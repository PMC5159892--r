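#' Trimmed mean-absolute-deviation error score
#'
#' Scores a derivative estimate against the exact derivative by the mean
#' absolute deviation, ignoring a fraction of points at each end of the
#' series so that endpoint effects do not dominate.  With `n` points and
#' trim fraction `f`, indices `floor(f n)` points in from each end are kept
#' (a half-open convention: points `floor(f n) + 1` to `n - floor(f n)`).
#'
#' @param inferred,exact Numeric vectors of equal length.
#' @param trim_fraction Fraction trimmed at each end (default 0.05;
#'   must satisfy `0 <= trim_fraction < 0.5`).
#' @return An object of class `error_score`: a list with `value` (the
#'   trimmed mean absolute deviation) and `n_trimmed` (points dropped per
#'   end).
#' @export
error_score <- function(inferred, exact, trim_fraction = 0.05) {
  n <- length(inferred)
  if (length(exact) != n) stop("inputs must have equal length", call. = FALSE)
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("'trim_fraction' must be in [0, 0.5)", call. = FALSE)
  k <- floor(trim_fraction * n)
  idx <- (k + 1L):(n - k)
  if (length(idx) < 1L || k >= n - k)
    stop("all points trimmed", call. = FALSE)
  structure(list(value = mean(abs(inferred[idx] - exact[idx])),
                 n_trimmed = as.integer(k)),
            class = "error_score")
}

#' @export
print.error_score <- function(x, ...) {
  cat("Error score (trimmed mean absolute deviation):",
      format(x$value, digits = 5), "—", x$n_trimmed,
      "point(s) ignored per end\n")
  invisible(x)
}

#' Smoothing-spline baseline for derivative estimation
#'
#' Fits a cubic smoothing spline to the (time, value) data — values should
#' already be on the natural-log scale when the specific growth rate is the
#' quantity of interest — and returns the spline's first derivative at the
#' data times.  The smoothing strength is expressed as a target residual sum
#' of squares: the penalty is chosen (by root-finding over
#' [stats::smooth.spline()]'s `spar`) so that the fitted residual sum of
#' squares equals `smoothing`; the classical choice for noise of standard
#' deviation \eqn{\sigma_m} is \eqn{n \sigma_m^2}.
#'
#' @param data A [gp_timeseries()] (values on the scale to differentiate).
#' @param smoothing Target residual sum of squares (>= 0).
#' @return Numeric vector of derivative estimates at `data$times`, with
#'   attributes `rss` (achieved residual sum of squares) and `spar`.
#' @export
spline_baseline <- function(data, smoothing) {
  .check_timeseries(data)
  if (smoothing < 0) stop("'smoothing' must be >= 0", call. = FALSE)
  x <- data$times; y <- data$values
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct time points for a cubic spline", call. = FALSE)
  rss_at <- function(spar) {
    # extreme spar probes can trigger harmless df clamping messages
    fit <- suppressWarnings(stats::smooth.spline(x, y, spar = spar, cv = FALSE))
    sum((y - stats::predict(fit, x)$y)^2)
  }
  lo <- -1.5; hi <- 2  # beyond spar ~ 2 the penalty overflows numerically
  rlo <- rss_at(lo); rhi <- rss_at(hi)
  # floor the residual target at numerical noise so that interpolation
  # requests on exactly representable data stay well conditioned
  s_tol <- max(smoothing, 1e-10 * sum((y - mean(y))^2))
  spar <- if (rlo >= s_tol) lo
          else if (rhi <= s_tol) hi
          else stats::uniroot(function(s) rss_at(s) - s_tol,
                              c(lo, hi), tol = 1e-6)$root
  fit <- suppressWarnings(stats::smooth.spline(x, y, spar = spar, cv = FALSE))
  deriv <- stats::predict(fit, x, deriv = 1)$y
  structure(deriv, rss = sum((y - stats::predict(fit, x)$y)^2), spar = spar)
}

#' Benchmark derivative inference on synthetic growth curves
#'
#' Generates replicate synthetic growth curves (weighted Gompertz +
#' Richards with log-normal noise, see [mixed_noisy_curve()]), infers the
#' specific growth rate with a Gaussian process for each requested
#' covariance family and with the smoothing-spline baseline, and scores
#' every estimate by the trimmed mean absolute deviation from the exact
#' growth rate.  The spline's smoothing parameter is set from the true
#' generating noise variance (`n * noise_sd^2`) — a deliberate advantage
#' for the baseline, since the Gaussian process must infer the noise.
#'
#' @param n_datasets Number of independently noised datasets per size
#'   (>= 2).
#' @param n_points_list Integer vector of dataset sizes.
#' @param seed Integer seed; the full benchmark is reproducible.
#' @param families Covariance families to run the GP with.
#' @param noise_sd Log-normal noise standard deviation of the generator.
#' @param trim_fraction Trim fraction for the error score.
#' @param n_restarts Optimization restarts per GP fit.
#' @param time_range Time range of the synthetic grid.
#' @return An object of class `gp_benchmark`: a list with `scores`, a data
#'   frame (`dataset`, `n`, `method`, `score`), and `medians`, the median
#'   score by `n` and `method`.
#' @export
benchmark_growthrate <- function(n_datasets = 20, n_points_list = c(10, 100, 1000),
                                 seed = 1, families = "squared_exponential",
                                 noise_sd = 0.03, trim_fraction = 0.05,
                                 n_restarts = 1, time_range = c(0, 15)) {
  if (n_datasets < 2) stop("'n_datasets' must be >= 2", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             2L * n_datasets * length(n_points_list)),
                  ncol = 2L)

  rows <- list()
  irow <- 0L
  for (ni in seq_along(n_points_list)) {
    n <- n_points_list[ni]
    for (d in seq_len(n_datasets)) {
      sd_pair <- seeds[(ni - 1L) * n_datasets + d, ]
      sim <- mixed_noisy_curve(n_points = n, time_range = time_range,
                               noise_sd = noise_sd, seed = sd_pair[1])
      logdata <- gp_timeseries(sim$times, log(sim$observed), transformed = TRUE)
      for (fam in families) {
        spec <- cov_spec(fam)
        opt <- suppressWarnings(
          optimize_hyperparameters(logdata, spec, n_restarts = n_restarts,
                                   seed = sd_pair[2])
        )
        post <- joint_posterior(opt, logdata, prediction_times = sim$times,
                                derivs = 1L)
        sc <- error_score(post$mean_g, sim$growth_rate, trim_fraction)$value
        irow <- irow + 1L
        rows[[irow]] <- data.frame(dataset = d, n = n,
                                   method = paste0("gp_", fam), score = sc)
      }
      spl <- spline_baseline(logdata, smoothing = n * noise_sd^2)
      sc <- error_score(as.numeric(spl), sim$growth_rate, trim_fraction)$value
      irow <- irow + 1L
      rows[[irow]] <- data.frame(dataset = d, n = n, method = "spline", score = sc)
    }
  }
  scores <- do.call(rbind, rows)
  medians <- stats::aggregate(score ~ n + method, data = scores, FUN = stats::median)
  structure(list(scores = scores, medians = medians), class = "gp_benchmark")
}

#' @export
print.gp_benchmark <- function(x, ...) {
  cat("Growth-rate inference benchmark:",
      length(unique(x$scores$dataset)), "datasets per size\n")
  cat("Median error scores:\n")
  print(x$medians, row.names = FALSE, digits = 4)
  invisible(x)
}
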