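#' Covariance specification for Gaussian-process regression
#'
#' Constructs the covariance (kernel) specification used throughout the
#' package.  Every family has exactly three hyperparameters, all handled on
#' the log10 scale: two kernel parameters and the magnitude of the
#' measurement noise.  For the squared-exponential and Matern kernels the
#' kernel parameters are the amplitude of the latent function and its
#' flexibility (an inverse squared length-scale); for the neural-network
#' (arcsine) kernel they are the bias variance, which sets the variance of
#' the latent function at time zero, and the input-weight variance
#' (flexibility).
#'
#' Hyperparameters are optimized within box bounds (uniform priors on the
#' log10 scale).  Equal lower and upper bounds fix a parameter.
#'
#' @param family One of `"squared_exponential"`, `"matern_5_2"`,
#'   `"neural_network"`.
#' @param lower,upper Numeric length-3 vectors of log10 bounds for the
#'   hyperparameters (amplitude/bias, flexibility, noise magnitude).
#'   Defaults are sensible ranges for plate-reader growth curves.
#' @param log10_params Optional starting values on the log10 scale; default
#'   is the midpoint of the bounds.
#' @return An object of class `gp_cov_spec`.
#' @examples
#' spec <- cov_spec("squared_exponential")
#' kernel_matrix(spec, 0:3)
#' @export
cov_spec <- function(family = c("squared_exponential", "matern_5_2", "neural_network"),
                     lower = NULL, upper = NULL, log10_params = NULL) {
  family <- match.arg(family)
  defaults <- switch(family,
    squared_exponential = list(lower = c(-5, -6, -5), upper = c(5, 2, 0)),
    matern_5_2          = list(lower = c(-5, -6, -5), upper = c(5, 2, 0)),
    neural_network      = list(lower = c(-1, 1, -6),  upper = c(5, 2.5, 2))
  )
  if (is.null(lower)) lower <- defaults$lower
  if (is.null(upper)) upper <- defaults$upper
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L)
    stop("'lower' and 'upper' must each contain 3 log10 bounds", call. = FALSE)
  if (any(upper < lower))
    stop("each upper bound must be >= the corresponding lower bound", call. = FALSE)
  if (is.null(log10_params)) log10_params <- (lower + upper) / 2
  log10_params <- as.numeric(log10_params)
  if (length(log10_params) != 3L)
    stop("'log10_params' must have length 3", call. = FALSE)
  if (any(log10_params < lower - 1e-12) || any(log10_params > upper + 1e-12))
    stop("'log10_params' must lie within the bounds", call. = FALSE)
  structure(
    list(family = family, log10_params = log10_params,
         lower = lower, upper = upper),
    class = "gp_cov_spec"
  )
}

#' @export
print.gp_cov_spec <- function(x, ...) {
  cat("Gaussian-process covariance:", x$family, "\n")
  tab <- data.frame(
    hyperparameter = c(
      if (x$family == "neural_network") "bias variance" else "amplitude",
      "flexibility", "noise magnitude"),
    log10_value = x$log10_params, log10_lower = x$lower, log10_upper = x$upper)
  print(tab, row.names = FALSE)
  if (!is.null(attr(x, "nll")))
    cat("negative log marginal likelihood:", format(attr(x, "nll")), "\n")
  invisible(x)
}

# m-th derivative with respect to the lag d = x - x' of a stationary kernel.
# a = amplitude, e = flexibility (inverse squared length-scale).
.stationary_lag_deriv <- function(family, m, d, a, e) {
  if (family == "squared_exponential") {
    E <- a * exp(-e * d^2 / 2)
    switch(m + 1L,
      E,
      -e * d * E,
      e * (e * d^2 - 1) * E,
      e^2 * d * (3 - e * d^2) * E,
      e^2 * (e^2 * d^4 - 6 * e * d^2 + 3) * E
    )
  } else { # matern_5_2: k = a (1 + s r + s^2 r^2 / 3) exp(-s r), s = sqrt(5 e)
    s <- sqrt(5 * e)
    r <- abs(d)
    E <- exp(-s * r)
    switch(m + 1L,
      a * (1 + s * r + s^2 * r^2 / 3) * E,
      -(a * s^2 / 3) * d * (1 + s * r) * E,
      -(a * s^2 / 3) * (1 + s * r - s^2 * d^2) * E,
      (a * s^4 / 3) * d * (3 - s * r) * E,
      stop("the Matern 5/2 latent function is only twice differentiable: ",
           "the fourth cross-derivative of the kernel needed for cov(h, h) ",
           "does not exist at zero lag", call. = FALSE)
    )
  }
}

# Symbolic machinery for the neural-network (arcsine) kernel.  The base
# expression is differentiated with stats::D as needed and the results are
# memoized, giving closed-form cross-derivatives without hand algebra.
.nn_env <- new.env(parent = emptyenv())

.nn_base_expr <- quote(
  (2 / pi) * asin(2 * (b + w * x * y) /
    sqrt((1 + 2 * (b + w * x^2)) * (1 + 2 * (b + w * y^2))))
)

.nn_expr <- function(order1, order2, param = NULL) {
  key <- paste0("d", order1, "_", order2,
                if (!is.null(param)) paste0("_", param))
  if (!is.null(.nn_env[[key]])) return(.nn_env[[key]])
  ex <- .nn_base_expr
  if (order1 > 0) for (i in seq_len(order1)) ex <- stats::D(ex, "x")
  if (order2 > 0) for (i in seq_len(order2)) ex <- stats::D(ex, "y")
  if (!is.null(param)) ex <- stats::D(ex, param)
  .nn_env[[key]] <- ex
  ex
}

.nn_eval <- function(ex, X, X2, b, w) {
  n <- length(X); m <- length(X2)
  env <- list(
    x = matrix(X, n, m), y = matrix(X2, n, m, byrow = TRUE),
    b = b, w = w, pi = pi)
  out <- eval(ex, env)
  if (!is.matrix(out)) out <- matrix(out, n, m)
  out
}

.check_spec <- function(spec) {
  if (!inherits(spec, "gp_cov_spec"))
    stop("'spec' must be created with cov_spec()", call. = FALSE)
}

#' Kernel matrix
#'
#' Evaluates the covariance function at all pairs of the two input vectors,
#' giving `K[i, j] = k(X[i], X2[j])`.
#'
#' @param spec A [cov_spec()] object.
#' @param X,X2 Numeric vectors of input times; `X2` defaults to `X`.
#' @return A `length(X)` by `length(X2)` matrix.
#' @seealso [kernel_derivative_matrix()]
#' @export
kernel_matrix <- function(spec, X, X2 = X) {
  kernel_derivative_matrix(spec, X, X2, 0L, 0L)
}

#' Kernel cross-derivative matrix
#'
#' Evaluates the matrix of partial derivatives of the covariance function,
#' \eqn{\partial_1^{i} \partial_2^{j} k(x, x')}, where \eqn{\partial_1} and
#' \eqn{\partial_2} differentiate with respect to the first and second
#' argument.  These cross-covariances build the joint prior over the latent
#' function and its first and second time derivatives.  All derivatives are
#' closed-form analytic expressions, not finite differences.
#'
#' The Matern 5/2 kernel supports a latent function that is only twice
#' differentiable, so the fourth cross-derivative (`order1 = order2 = 2`),
#' required for the covariance of the second derivative, is refused.
#'
#' @inheritParams kernel_matrix
#' @param order1,order2 Integer derivative orders (0 to 2) with respect to
#'   the first and second kernel argument.
#' @return A `length(X)` by `length(X2)` matrix.
#' @export
kernel_derivative_matrix <- function(spec, X, X2 = X, order1 = 0L, order2 = 0L) {
  .check_spec(spec)
  order1 <- as.integer(order1); order2 <- as.integer(order2)
  if (order1 < 0L || order1 > 2L || order2 < 0L || order2 > 2L)
    stop("derivative orders must be between 0 and 2", call. = FALSE)
  X <- as.numeric(X); X2 <- as.numeric(X2)
  if (!all(is.finite(X)) || !all(is.finite(X2)))
    stop("inputs must be finite", call. = FALSE)
  p <- 10^spec$log10_params
  if (spec$family == "neural_network") {
    return(.nn_eval(.nn_expr(order1, order2), X, X2, b = p[1], w = p[2]))
  }
  d <- outer(X, X2, "-")
  m <- order1 + order2
  (-1)^order2 * .stationary_lag_deriv(spec$family, m, d, a = p[1], e = p[2])
}

# Joint prior covariance over (f, g, h) (or (f, g)) at prediction times:
# block (i, j) is partial_1^i partial_2^j k(Xs, Xs).
.joint_prior_cov <- function(spec, Xs, derivs) {
  ns <- length(Xs)
  nb <- derivs + 1L
  B <- matrix(0, nb * ns, nb * ns)
  for (i in 0:derivs) for (j in 0:derivs) {
    B[i * ns + seq_len(ns), j * ns + seq_len(ns)] <-
      kernel_derivative_matrix(spec, Xs, Xs, i, j)
  }
  (B + t(B)) / 2
}
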