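#' Pooled time-series observations
#'
#' Container for the observations a Gaussian process is fitted to.
#' Replicate measurements are pooled into a single set of (time, value)
#' pairs — times may therefore repeat — and sorted stably by time, after
#' which the algorithm treats them exactly like a single replicate.
#'
#' @param times Numeric vector of observation times.
#' @param values Numeric vector of observations, same length as `times`.
#' @param replicate Optional integer replicate labels.
#' @param transformed Logical; `TRUE` if `values` are natural logarithms of
#'   the raw measurements (the scale on which specific growth rates are
#'   defined).
#' @return An object of class `gp_timeseries`.
#' @export
gp_timeseries <- function(times, values, replicate = NULL, transformed = FALSE) {
  times <- as.numeric(times); values <- as.numeric(values)
  n <- length(times)
  if (n < 2L || length(values) != n)
    stop("'times' and 'values' must have equal length >= 2", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("'times' and 'values' must be finite", call. = FALSE)
  if (is.null(replicate)) replicate <- rep(1L, n)
  if (length(replicate) != n)
    stop("'replicate' must match the length of 'times'", call. = FALSE)
  ord <- order(times)  # stable: preserves replicate order at tied times
  structure(
    list(times = times[ord], values = values[ord],
         replicate = as.integer(replicate)[ord],
         transformed = isTRUE(transformed), n = n),
    class = "gp_timeseries"
  )
}

.check_timeseries <- function(data) {
  if (!inherits(data, "gp_timeseries"))
    stop("'data' must be created with gp_timeseries()", call. = FALSE)
}

#' @export
print.gp_timeseries <- function(x, ...) {
  cat("Time series with", x$n, "pooled observations,",
      length(unique(x$replicate)), "replicate(s)\n")
  cat("  time range:", format(range(x$times), digits = 4),
      if (x$transformed) " (values on natural-log scale)" else "", "\n")
  invisible(x)
}

# Cholesky with additive jitter escalation.  Starts at 1e-10 * trace/n and
# escalates tenfold up to 1e-4 * trace/n before giving up.
.chol_jitter <- function(M, what = "covariance matrix") {
  base <- mean(diag(M))
  jit <- 0
  for (expo in c(-Inf, -10:-4)) {
    jit <- if (is.finite(expo)) base * 10^expo else 0
    R <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = jit))
  }
  stop("Cholesky factorization of the ", what, " failed even with jitter ",
       "up to 1e-4 * mean diagonal; the matrix is numerically singular",
       call. = FALSE)
}

# Data covariance K(X, X) + sigma^2 D and its Cholesky factor.
.data_chol <- function(spec, data, noise) {
  K <- kernel_matrix(spec, data$times)
  sig2 <- 10^(2 * spec$log10_params[3])
  dvec <- .noise_diagonal(noise, data$times)
  Ky <- K + diag(sig2 * dvec, data$n)
  c(.chol_jitter(Ky, "data covariance"), list(K = K, dvec = dvec, sig2 = sig2))
}

#' Negative log marginal likelihood
#'
#' Evaluates \eqn{-\log P(y \mid \theta, X)} for the Gaussian-process model
#' \eqn{y \sim N(0, K(X, X) + \sigma^2 D)}, where \eqn{D} is the identity
#' for constant noise or the diagonal of relative noise variances for an
#' empirical noise model.  Computed via a Cholesky factorization with
#' additive jitter escalation.
#'
#' @inheritParams kernel_matrix
#' @param data A [gp_timeseries()].
#' @param noise A noise model, see [noise_constant()].
#' @return A finite scalar for in-bounds hyperparameters.
#' @export
negative_log_marginal_likelihood <- function(spec, data, noise = noise_constant()) {
  .check_spec(spec); .check_timeseries(data)
  ch <- tryCatch(.data_chol(spec, data, noise), error = function(e) {
    stop("numerical conditioning failure at log10 hyperparameters (",
         paste(format(spec$log10_params, digits = 4), collapse = ", "),
         "): ", conditionMessage(e), call. = FALSE)
  })
  y <- data$values
  alpha <- backsolve(ch$R, forwardsolve(t(ch$R), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch$R))) + 0.5 * data$n * log(2 * pi)
}

# Analytic gradient of the NLL with respect to the log10 hyperparameters.
# Uses dNLL/dtheta = 0.5 tr(Kinv dKy) - 0.5 alpha' dKy alpha with the trace
# evaluated elementwise.  Kernel-parameter derivatives are closed form for
# the stationary families and symbolic for the neural-network kernel.
.nll_gradient <- function(spec, data, noise, ch = NULL) {
  if (is.null(ch)) ch <- .data_chol(spec, data, noise)
  y <- data$values
  R <- ch$R
  alpha <- backsolve(R, forwardsolve(t(R), y))
  Kinv <- chol2inv(R)
  M <- Kinv - tcrossprod(alpha)           # tr(Kinv dK) - a' dK a = sum(M * dK)
  X <- data$times
  p <- 10^spec$log10_params
  ln10 <- log(10)
  if (spec$family == "neural_network") {
    dK1 <- .nn_eval(.nn_expr(0L, 0L, "b"), X, X, p[1], p[2]) * ln10 * p[1]
    dK2 <- .nn_eval(.nn_expr(0L, 0L, "w"), X, X, p[1], p[2]) * ln10 * p[2]
  } else {
    dK1 <- ch$K * ln10
    d <- outer(X, X, "-")
    if (spec$family == "squared_exponential") {
      dK2 <- ch$K * (-d^2 / 2) * p[2] * ln10
    } else { # matern_5_2
      s <- sqrt(5 * p[2]); r <- abs(d)
      dkds <- -(p[1] * s * r^2 / 3) * (1 + s * r) * exp(-s * r)
      dK2 <- dkds * (s * ln10 / 2)
    }
  }
  g1 <- 0.5 * sum(M * dK1)
  g2 <- 0.5 * sum(M * dK2)
  dnoise <- 2 * ln10 * ch$sig2 * ch$dvec
  g3 <- 0.5 * sum(diag(M) * dnoise)
  c(g1, g2, g3)
}

#' Optimize hyperparameters by maximizing the marginal likelihood
#'
#' Runs bounded quasi-Newton (L-BFGS-B) optimization of the negative log
#' marginal likelihood from `n_restarts` starting points drawn uniformly (on
#' the log10 scale) within the hyperparameter bounds, and returns the
#' specification with the lowest value found.  A single run usually
#' suffices; multiple restarts guard against local maxima.  Parameters with
#' equal lower and upper bounds are held fixed.  A warning is issued when an
#' optimum lies on a (non-degenerate) bound, since bound saturation signals
#' that the prior range is constraining the fit.
#'
#' @inheritParams negative_log_marginal_likelihood
#' @param n_restarts Number of optimization runs (>= 1; default 3).
#' @param seed Optional integer seed controlling the random starting points.
#' @return A `gp_cov_spec` with optimized `log10_params` and attributes
#'   `nll` (the minimized negative log marginal likelihood) and
#'   `bound_saturated` (logical per hyperparameter).
#' @export
optimize_hyperparameters <- function(data, spec, noise = noise_constant(),
                                     n_restarts = 3, seed = NULL) {
  .check_spec(spec); .check_timeseries(data)
  if (n_restarts < 1) stop("'n_restarts' must be >= 1", call. = FALSE)
  free <- spec$upper > spec$lower
  theta0 <- spec$log10_params
  theta0[!free] <- spec$lower[!free]

  make_spec <- function(th_free) {
    th <- theta0; th[free] <- th_free
    s2 <- spec; s2$log10_params <- th
    s2
  }
  fn <- function(th_free) {
    tryCatch(
      negative_log_marginal_likelihood(make_spec(th_free), data, noise),
      error = function(e) 1e10
    )
  }
  gr <- function(th_free) {
    g <- tryCatch(.nll_gradient(make_spec(th_free), data, noise),
                  error = function(e) rep(0, 3))
    if (!all(is.finite(g))) g <- rep(0, 3)
    g[free]
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  nfree <- sum(free)
  starts <- matrix(stats::runif(n_restarts * nfree,
                                rep(spec$lower[free], each = n_restarts),
                                rep(spec$upper[free], each = n_restarts)),
                   nrow = n_restarts)

  best <- NULL
  for (k in seq_len(n_restarts)) {
    res <- if (nfree == 0L) {
      list(par = numeric(0), value = fn(numeric(0)))
    } else {
      tryCatch(
        stats::optim(starts[k, ], fn, gr, method = "L-BFGS-B",
                     lower = spec$lower[free], upper = spec$upper[free],
                     control = list(maxit = 200)),
        error = function(e) NULL
      )
    }
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e10) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("hyperparameter optimization failed in all ", n_restarts,
         " restarts", call. = FALSE)

  out <- make_spec(best$par)
  tol <- 1e-6
  saturated <- free &
    (abs(out$log10_params - spec$lower) < tol |
     abs(out$log10_params - spec$upper) < tol)
  if (any(saturated))
    warning("optimized hyperparameter(s) ",
            paste(which(saturated) - 1L, collapse = ", "),
            " lie on a bound; consider widening the bounds", call. = FALSE)
  attr(out, "nll") <- best$value
  attr(out, "bound_saturated") <- saturated
  out
}

#' Joint posterior over the latent function and its derivatives
#'
#' Conditions the joint Gaussian prior over the observations and the latent
#' function \eqn{f}, its first derivative \eqn{g} and (when the covariance
#' family supports it) its second derivative \eqn{h} at the prediction
#' times on the observed data.  The \eqn{f} block is the standard
#' Gaussian-process regression posterior; prediction times need not
#' coincide with data times, so interpolation comes for free.
#'
#' @inheritParams negative_log_marginal_likelihood
#' @param prediction_times Times at which to evaluate the posterior.
#' @param derivs Highest derivative to infer: 2 (default) or 1.  Matern 5/2
#'   supports at most 1 (its latent functions are only twice
#'   differentiable, so the second derivative has no finite variance
#'   process); requesting 2 is an error.
#' @return An object of class `gp_posterior` with posterior means
#'   (`mean_f`, `mean_g`, `mean_h`), their pointwise standard deviations
#'   (`sd_f`, ...), the full joint covariance `cov` over the stacked
#'   `(f*, g*, h*)` vector, and the prediction `times`.
#' @export
joint_posterior <- function(spec, data, noise = noise_constant(),
                            prediction_times = NULL, derivs = NULL) {
  .check_spec(spec); .check_timeseries(data)
  if (is.null(derivs))
    derivs <- if (spec$family == "matern_5_2") 1L else 2L
  derivs <- as.integer(derivs)
  if (derivs < 1L || derivs > 2L) stop("'derivs' must be 1 or 2", call. = FALSE)
  if (spec$family == "matern_5_2" && derivs == 2L)
    stop("the Matern 5/2 covariance supports only first-derivative ",
         "inference; use derivs = 1", call. = FALSE)
  if (is.null(prediction_times)) prediction_times <- sort(unique(data$times))
  Xs <- as.numeric(prediction_times)
  ns <- length(Xs)

  ch <- .data_chol(spec, data, noise)
  y <- data$values
  alpha <- backsolve(ch$R, forwardsolve(t(ch$R), y))

  A <- do.call(rbind, lapply(0:derivs, function(m)
    kernel_derivative_matrix(spec, Xs, data$times, m, 0L)))
  B <- .joint_prior_cov(spec, Xs, derivs)

  mu <- drop(A %*% alpha)
  V <- forwardsolve(t(ch$R), t(A))
  S <- B - crossprod(V)
  S <- (S + t(S)) / 2
  vars <- pmax(diag(S), 0)

  idx <- function(m) m * ns + seq_len(ns)
  structure(
    list(times = Xs, derivs = derivs,
         mean_f = mu[idx(0)], mean_g = mu[idx(1)],
         mean_h = if (derivs == 2L) mu[idx(2)] else NULL,
         sd_f = sqrt(vars[idx(0)]), sd_g = sqrt(vars[idx(1)]),
         sd_h = if (derivs == 2L) sqrt(vars[idx(2)]) else NULL,
         cov = S, spec = spec,
         jitter = ch$jitter),
    class = "gp_posterior"
  )
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat("Joint Gaussian-process posterior at", length(x$times),
      "prediction times (latent function +", x$derivs, "derivative(s))\n")
  cat("  covariance family:", x$spec$family, "\n")
  invisible(x)
}

#' Sample latent functions and derivatives from the posterior
#'
#' Draws internally consistent `(f*, g*, h*)` triples from the full joint
#' posterior Gaussian (a single factorization of the stacked covariance, so
#' each sample's derivative really is the derivative of that sample's latent
#' function).  Used to propagate inference uncertainty into any summary
#' statistic of the growth curve.
#'
#' @param post A [joint_posterior()] result.
#' @param n_samples Number of samples (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `gp_samples`: a list of matrices `f`, `g`
#'   (and `h` when available), each `n_samples` by `length(post$times)`.
#' @export
sample_posterior <- function(post, n_samples = 100, seed = NULL) {
  if (!inherits(post, "gp_posterior"))
    stop("'post' must come from joint_posterior()", call. = FALSE)
  if (n_samples < 1) stop("'n_samples' must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  ns <- length(post$times)
  nb <- post$derivs + 1L
  mu <- c(post$mean_f, post$mean_g, post$mean_h)
  R <- .chol_jitter(post$cov, "posterior covariance")$R
  Z <- matrix(stats::rnorm(n_samples * nb * ns), n_samples, nb * ns)
  draws <- sweep(Z %*% R, 2L, mu, "+")
  idx <- function(m) m * ns + seq_len(ns)
  out <- list(f = draws[, idx(0), drop = FALSE],
              g = draws[, idx(1), drop = FALSE])
  if (nb == 3L) out$h <- draws[, idx(2), drop = FALSE]
  out$times <- post$times
  structure(out, class = "gp_samples")
}
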