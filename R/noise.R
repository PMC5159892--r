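#' Constant measurement-noise model
#'
#' Measurement errors are independent Gaussians with a common standard
#' deviation; the noise covariance is \eqn{\sigma^2 I} with \eqn{\sigma}
#' optimized as the third hyperparameter of the covariance specification.
#'
#' @return An object of class `gp_noise`.
#' @seealso [estimate_relative_noise()] for time-varying noise.
#' @export
noise_constant <- function() {
  structure(list(kind = "constant"), class = "gp_noise")
}

#' Empirically estimated time-varying measurement noise
#'
#' When the magnitude of the measurement noise changes over the course of an
#' experiment, its relative scale can be estimated from replicates: the
#' variance across replicates is computed at each time point and smoothed
#' along time with a Gaussian filter whose standard deviation is a fraction
#' of the total duration.  The resulting profile replaces the identity
#' matrix in the noise covariance, which becomes \eqn{\sigma^2 D} with
#' \eqn{D} the diagonal of relative variances; the overall constant
#' \eqn{\sigma} is still optimized as a hyperparameter.  The profile is
#' normalized to mean one so that \eqn{\sigma^2} is interpretable as the
#' mean noise variance.
#'
#' @param data A [gp_timeseries()] with at least two replicate observations
#'   at every unique time point.
#' @param filter_width_fraction Standard deviation of the Gaussian smoothing
#'   filter as a fraction of the total time span (default 0.10); zero
#'   disables smoothing.
#' @return An object of class `gp_noise` with fields `times` (unique time
#'   points) and `relative` (smoothed, mean-one relative variances).
#' @export
estimate_relative_noise <- function(data, filter_width_fraction = 0.1) {
  .check_timeseries(data)
  if (filter_width_fraction < 0)
    stop("'filter_width_fraction' must be >= 0", call. = FALSE)
  tu <- sort(unique(data$times))
  counts <- tabulate(match(data$times, tu), nbins = length(tu))
  if (any(counts < 2L))
    stop("empirical noise estimation needs >= 2 replicates at every time ",
         "point; use noise_constant() for single-replicate data",
         call. = FALSE)
  v <- vapply(tu, function(t) stats::var(data$values[data$times == t]), 0)
  if (all(v == 0))
    stop("all replicates are identical: across-replicate variance is zero ",
         "everywhere, so no relative noise profile can be estimated",
         call. = FALSE)
  if (filter_width_fraction > 0 && length(tu) > 1L) {
    v <- .gaussian_smooth_reflect(tu, v,
                                  sd = filter_width_fraction * diff(range(tu)))
  }
  v <- pmax(v, 1e-4 * mean(v))  # floor avoids zero-noise singularities
  v <- v / mean(v)
  structure(list(kind = "empirical", times = tu, relative = v,
                 filter_width_fraction = filter_width_fraction),
            class = "gp_noise")
}

# Gaussian kernel smoothing on a possibly uneven grid with reflected
# boundaries, so that the filter conserves the mean away from strong edge
# gradients.
.gaussian_smooth_reflect <- function(t, v, sd) {
  n <- length(t)
  if (sd <= 0 || n < 2L) return(v)
  tl <- 2 * t[1] - rev(t[-1]); vl <- rev(v[-1])
  tr <- 2 * t[n] - rev(t[-n]); vr <- rev(v[-n])
  tp <- c(tl, t, tr); vp <- c(vl, v, vr)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- stats::dnorm(tp - t[i], sd = sd)
    out[i] <- sum(w * vp) / sum(w)
  }
  out
}

# Relative noise variance on the diagonal of the noise covariance at the
# given times (1 for constant noise).
.noise_diagonal <- function(noise, times) {
  if (!inherits(noise, "gp_noise"))
    stop("'noise' must be a gp_noise object", call. = FALSE)
  if (noise$kind == "constant") return(rep(1, length(times)))
  stats::approx(noise$times, noise$relative, xout = times, rule = 2)$y
}

#' @export
print.gp_noise <- function(x, ...) {
  if (x$kind == "constant") {
    cat("Constant measurement noise (sigma^2 I)\n")
  } else {
    cat("Empirical time-varying measurement noise over", length(x$times),
        "time points\n")
    cat("  relative variance range:",
        format(range(x$relative), digits = 3), "\n")
    cat("  Gaussian filter width fraction:", x$filter_width_fraction, "\n")
  }
  invisible(x)
}
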