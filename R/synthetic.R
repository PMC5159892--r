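#' Gompertz growth curve (Zwietering re-parameterization)
#'
#' Evaluates the modified Gompertz model
#' \deqn{y(t) = A \exp(-\exp(\mu_m e (\lambda - t)/A + 1))}
#' in which the parameters are directly interpretable: `A` is the asymptote,
#' `mu_m` the maximum slope (at the inflection point) and `lambda` the lag
#' time.  The analytic first derivative is returned alongside the values.
#'
#' @param times Numeric vector of times.
#' @param A Asymptote (> 0).
#' @param mu_m Maximum slope (> 0).
#' @param lambda Lag time.
#' @return A list with `values` and `deriv`, both the length of `times`.
#' @export
gompertz_curve <- function(times, A = 1.1, mu_m = 0.6, lambda = 2.3) {
  stopifnot(A > 0, mu_m > 0, all(is.finite(times)))
  u <- mu_m * exp(1) / A * (lambda - times) + 1
  inner <- exp(u)
  values <- A * exp(-inner)
  deriv <- values * inner * mu_m * exp(1) / A
  list(values = values, deriv = deriv)
}

#' Richards growth curve (Zwietering re-parameterization)
#'
#' Evaluates the modified Richards model
#' \deqn{y(t) = A [1 + \nu e^{1+\nu} \exp(\mu_m (1+\nu)^{1+1/\nu} (\lambda - t)/A)]^{-1/\nu}}
#' with asymptote `A`, maximum slope `mu_m`, lag `lambda` and shape `nu`
#' (`nu = 1` recovers the logistic re-parameterization).  The analytic first
#' derivative is returned alongside the values.
#'
#' @inheritParams gompertz_curve
#' @param nu Shape parameter (> 0).
#' @return A list with `values` and `deriv`.
#' @export
richards_curve <- function(times, A = 1.5, mu_m = 0.3, lambda = 4.3, nu = 0.8) {
  stopifnot(A > 0, mu_m > 0, nu > 0, all(is.finite(times)))
  B <- nu * exp(1 + nu)
  cc <- mu_m / A * (1 + nu)^(1 + 1 / nu)
  E <- exp(cc * (lambda - times))
  base <- 1 + B * E
  values <- A * base^(-1 / nu)
  deriv <- (A * cc * B / nu) * E * base^(-1 / nu - 1)
  list(values = values, deriv = deriv)
}

#' Synthetic growth curve: weighted Gompertz + Richards with log-normal noise
#'
#' Generates the benchmark growth curves used to test derivative inference:
#' a weighted sum of a Gompertz and a Richards model — a curve that neither
#' model alone can fit, but whose exact specific growth rate
#' \eqn{d\ln y/dt} is available in closed form — observed under
#' multiplicative log-normal measurement noise (additive Gaussian noise of
#' standard deviation `noise_sd` on the log of the curve).
#'
#' Defaults are the benchmark conditions: Gompertz (A = 1.1, mu_m = 0.6,
#' lambda = 2.3) with weight 0.3 plus Richards (A = 1.5, mu_m = 0.3,
#' lambda = 4.3, nu = 0.8) with weight 0.7, noise sd 0.03, on an even grid
#' over 0 to 15 time units (covering lag through saturation).
#'
#' @param n_points Number of evenly spaced time points (>= 2).
#' @param time_range Length-2 numeric range of times.
#' @param noise_sd Standard deviation of the log-normal noise (>= 0).
#' @param seed Optional integer seed; fixed seeds give bit-reproducible data.
#' @param gompertz,richards Named lists of model parameters passed to
#'   [gompertz_curve()] and [richards_curve()].
#' @param weights Length-2 non-negative weights (Gompertz, Richards).
#' @return A list with `data` (a [gp_timeseries()] of the raw noisy
#'   observations), `times`, `observed`, `clean` (noise-free curve) and
#'   `growth_rate` (exact specific growth rate of the clean curve).
#' @export
mixed_noisy_curve <- function(n_points = 100, time_range = c(0, 15),
                              noise_sd = 0.03, seed = NULL,
                              gompertz = list(A = 1.1, mu_m = 0.6, lambda = 2.3),
                              richards = list(A = 1.5, mu_m = 0.3, lambda = 4.3, nu = 0.8),
                              weights = c(0.3, 0.7)) {
  stopifnot(n_points >= 2, length(time_range) == 2, noise_sd >= 0,
            length(weights) == 2, all(weights >= 0))
  times <- seq(time_range[1], time_range[2], length.out = n_points)
  g <- do.call(gompertz_curve, c(list(times = times), gompertz))
  r <- do.call(richards_curve, c(list(times = times), richards))
  clean <- weights[1] * g$values + weights[2] * r$values
  clean_deriv <- weights[1] * g$deriv + weights[2] * r$deriv
  growth_rate <- clean_deriv / clean
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  eps <- if (noise_sd > 0) stats::rnorm(n_points, 0, noise_sd) else numeric(n_points)
  observed <- clean * exp(eps)
  list(
    data = gp_timeseries(times, observed, transformed = FALSE),
    times = times, observed = observed, clean = clean,
    growth_rate = growth_rate
  )
}
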