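#' Growth-curve summary statistics with sampling-based errors
#'
#' Computes, for every posterior sample of the log growth curve and its
#' first derivative, the classical growth characteristics, and reports the
#' mean and standard deviation of each over samples:
#'
#' * maximum specific growth rate — the maximum of the first derivative of
#'   the log curve over the prediction grid;
#' * time of maximum — the grid time at which the maximum is attained
#'   (ties broken by the earliest time);
#' * lag time — where the tangent to the log curve at the point of maximum
#'   growth rate meets the horizontal line through the initial
#'   log-measurement: \eqn{t^* - (f(t^*) - \ln y(0)) / g(t^*)};
#' * doubling time — \eqn{\ln(2)} divided by the maximum growth rate,
#'   computed per sample before averaging.
#'
#' Samples whose maximum growth rate is not positive have no meaningful lag
#' or doubling time; such samples are excluded from those two statistics and
#' their count reported.
#'
#' @param samples A [sample_posterior()] result drawn on the natural-log
#'   scale of the measurements.
#' @param times Prediction-grid times (defaults to `samples$times`).
#' @param y0_log The initial log-measurement \eqn{\ln y(0)} used by the lag
#'   construction; a robust choice is the posterior mean of the latent
#'   function at the earliest time.
#' @param sd_type `"population"` (divisor n, default) or `"sample"`
#'   (divisor n-1) standard deviation over statistic samples.
#' @return An object of class `growth_statistics`: a data frame with
#'   columns `statistic`, `mean`, `sd`, plus attributes `n_samples` and
#'   `n_excluded`.
#' @export
growth_statistics <- function(samples, times = NULL, y0_log,
                              sd_type = c("population", "sample")) {
  if (!inherits(samples, "gp_samples"))
    stop("'samples' must come from sample_posterior()", call. = FALSE)
  sd_type <- match.arg(sd_type)
  if (is.null(times)) times <- samples$times
  g <- samples$g
  ns <- nrow(g)
  if (ns < 2L) stop("need at least 2 posterior samples", call. = FALSE)
  if (length(times) != ncol(g))
    stop("'times' must match the sample grid", call. = FALSE)

  imax <- max.col(g, ties.method = "first")
  gmax <- g[cbind(seq_len(ns), imax)]
  tmax <- times[imax]
  fmax <- samples$f[cbind(seq_len(ns), imax)]

  ok <- gmax > 0
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    warning(n_excluded, " sample(s) with non-positive maximum growth rate ",
            "excluded from lag and doubling time", call. = FALSE)
  if (!any(ok))
    stop("no sample has a positive maximum growth rate", call. = FALSE)

  lag <- tmax[ok] - (fmax[ok] - y0_log) / gmax[ok]
  doubling <- log(2) / gmax[ok]

  sdfun <- if (sd_type == "population") {
    function(x) sqrt(mean((x - mean(x))^2))
  } else {
    stats::sd
  }
  row <- function(name, x) data.frame(statistic = name, mean = mean(x), sd = sdfun(x))
  out <- rbind(
    row("max_growth_rate", gmax),
    row("time_of_max", tmax),
    row("lag_time", lag),
    row("doubling_time", doubling)
  )
  structure(out, n_samples = ns, n_excluded = n_excluded,
            sd_type = sd_type,
            class = c("growth_statistics", "data.frame"))
}

#' @export
print.growth_statistics <- function(x, ...) {
  cat("Growth statistics from", attr(x, "n_samples"), "posterior samples")
  if (attr(x, "n_excluded") > 0)
    cat(" (", attr(x, "n_excluded"), " excluded for lag/doubling)", sep = "")
  cat("\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
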