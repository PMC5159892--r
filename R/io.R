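#' Read a delimited time-series file with replicate columns
#'
#' Reads comma- or tab-delimited text with a header row, one time column
#' and one or more replicate value columns, and pools all replicates into a
#' single [gp_timeseries()] sorted stably by time.  Rows with missing
#' values are dropped per replicate with a warning reporting the count.
#'
#' @param path Path to the delimited file.
#' @param time_col Name of the time column; defaults to the first column.
#' @param value_cols Character vector of replicate column names; defaults
#'   to every column except the time column, in file order.
#' @param log_transform If `TRUE`, apply the natural log to the values
#'   (required for specific growth rates); non-positive values are an
#'   error.
#' @param sep Field separator; auto-detected from the header line
#'   (tab or comma) when `NULL`.
#' @return A [gp_timeseries()].
#' @export
read_timeseries <- function(path, time_col = NULL, value_cols = NULL,
                            log_transform = FALSE, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(time_col)) time_col <- names(df)[1]
  if (is.null(value_cols)) value_cols <- setdiff(names(df), time_col)
  missing_cols <- setdiff(c(time_col, value_cols), names(df))
  if (length(missing_cols) > 0)
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (cn in c(time_col, value_cols)) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))) &
                   !is.na(df[[cn]]) & df[[cn]] != "")
      stop("non-numeric value(s) in column '", cn, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  times <- rep(df[[time_col]], times = length(value_cols))
  values <- unlist(df[value_cols], use.names = FALSE)
  replicate <- rep(seq_along(value_cols), each = nrow(df))
  drop <- is.na(times) | is.na(values)
  if (any(drop)) {
    warning("dropped ", sum(drop), " observation(s) with missing values",
            call. = FALSE)
    times <- times[!drop]; values <- values[!drop]
    replicate <- replicate[!drop]
  }
  if (log_transform) {
    if (any(values <= 0)) {
      bad <- which(values <= 0)
      stop("log transform requires positive values; offending pooled ",
           "observation(s): ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
    values <- log(values)
  }
  gp_timeseries(times, values, replicate, transformed = log_transform)
}

#' Configuration for a full inference run
#'
#' Bundles every option of the end-to-end pipeline: input location and
#' column mapping, covariance family and bounds, noise model, prediction
#' grid, sampling, seed and output directory.
#'
#' @param input Path to the delimited input file.
#' @param time_col,value_cols,log_transform,sep Passed to
#'   [read_timeseries()]; `log_transform` defaults to `TRUE` since growth
#'   rates live on the log scale.
#' @param family,bounds Covariance family and optional list with `lower`
#'   and `upper` log10 bound vectors, see [cov_spec()].
#' @param noise_kind `"constant"` or `"empirical"`.
#' @param filter_width_fraction Gaussian filter width for empirical noise.
#' @param grid_size Optional size of an even prediction grid; default is
#'   the sorted unique data times.
#' @param n_samples Posterior samples for the growth statistics.
#' @param n_restarts Hyperparameter optimization restarts.
#' @param seed Integer seed for every stochastic step.
#' @param output_dir Directory the pipeline writes into.
#' @return An object of class `run_config`.
#' @export
make_run_config <- function(input, time_col = NULL, value_cols = NULL,
                            log_transform = TRUE, sep = NULL,
                            family = "squared_exponential", bounds = NULL,
                            noise_kind = c("constant", "empirical"),
                            filter_width_fraction = 0.1,
                            grid_size = NULL, n_samples = 100,
                            n_restarts = 3, seed = 1, output_dir = ".") {
  noise_kind <- match.arg(noise_kind)
  if (!is.null(bounds) && (is.null(bounds$lower) || is.null(bounds$upper)))
    stop("'bounds' must be a list with 'lower' and 'upper'", call. = FALSE)
  structure(
    list(input = input, time_col = time_col, value_cols = value_cols,
         log_transform = isTRUE(log_transform), sep = sep,
         family = family, bounds = bounds, noise_kind = noise_kind,
         filter_width_fraction = filter_width_fraction,
         grid_size = grid_size, n_samples = n_samples,
         n_restarts = n_restarts, seed = as.integer(seed),
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [make_run_config()]; keys absent from the
#' file keep their defaults, and any settings in `...` override the file.
#'
#' @param path Path to a YAML configuration file.
#' @param ... Overrides passed on to [make_run_config()].
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configuration requires the 'yaml' package", call. = FALSE)
  conf <- yaml::read_yaml(path)
  overrides <- list(...)
  conf[names(overrides)] <- overrides
  ok <- intersect(names(conf), names(formals(make_run_config)))
  do.call(make_run_config, conf[ok])
}

.write_table_full_precision <- function(df, path) {
  fm <- df
  for (cn in names(fm)) {
    if (is.double(fm[[cn]])) fm[[cn]] <- sprintf("%.17g", fm[[cn]])
  }
  utils::write.table(fm, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full inference pipeline
#'
#' Reads the data, estimates the noise model, optimizes the covariance
#' hyperparameters, computes the joint posterior over the latent function
#' and its derivatives, samples it, derives growth statistics and writes
#' three files into the output directory:
#'
#' * `predictions.tsv` — time, `f_mean`, `f_sd`, `g_mean`, `g_sd` and,
#'   for covariance families supporting second derivatives, `h_mean`,
#'   `h_sd` (absent for Matern 5/2, with a warning);
#' * `statistics.tsv` — the growth statistics table;
#' * `manifest.json` — optimized hyperparameters, the negative log
#'   marginal likelihood, the seed, bound-saturation warnings and sample
#'   exclusion counts.
#'
#' Numbers are written in full double precision, so re-running with the
#' same configuration reproduces the outputs byte for byte.
#'
#' @param config A [make_run_config()] object.
#' @return Invisibly, a list with the fitted objects (`data`, `noise`,
#'   `spec`, `posterior`, `statistics`) and output `paths`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop("'config' must be created with make_run_config()", call. = FALSE)
  data <- read_timeseries(config$input, config$time_col, config$value_cols,
                          config$log_transform, config$sep)
  noise <- if (config$noise_kind == "empirical") {
    estimate_relative_noise(data, config$filter_width_fraction)
  } else {
    noise_constant()
  }
  spec <- cov_spec(config$family,
                   lower = config$bounds$lower, upper = config$bounds$upper)
  opt <- optimize_hyperparameters(data, spec, noise,
                                  n_restarts = config$n_restarts,
                                  seed = config$seed)
  grid <- if (is.null(config$grid_size)) {
    sort(unique(data$times))
  } else {
    seq(min(data$times), max(data$times), length.out = config$grid_size)
  }
  if (config$family == "matern_5_2")
    warning("Matern 5/2: second derivative not inferred; ",
            "h columns omitted from predictions", call. = FALSE)
  post <- joint_posterior(opt, data, noise, prediction_times = grid)
  samples <- sample_posterior(post, config$n_samples, seed = config$seed + 1L)
  n_excluded <- 0L
  stats_tab <- withCallingHandlers(
    growth_statistics(samples, grid, y0_log = post$mean_f[1]),
    warning = function(w) invokeRestart("muffleWarning")
  )
  n_excluded <- attr(stats_tab, "n_excluded")

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  pred <- data.frame(time = grid,
                     f_mean = post$mean_f, f_sd = post$sd_f,
                     g_mean = post$mean_g, g_sd = post$sd_g)
  if (post$derivs == 2L) {
    pred$h_mean <- post$mean_h
    pred$h_sd <- post$sd_h
  }
  paths <- list(
    predictions = file.path(config$output_dir, "predictions.tsv"),
    statistics = file.path(config$output_dir, "statistics.tsv"),
    manifest = file.path(config$output_dir, "manifest.json")
  )
  .write_table_full_precision(pred, paths$predictions)
  stats_out <- as.data.frame(stats_tab)
  stats_out$n_samples <- attr(stats_tab, "n_samples")
  stats_out$n_excluded <- n_excluded
  .write_table_full_precision(stats_out, paths$statistics)
  manifest <- list(
    package = "gpgrowth",
    version = as.character(utils::packageVersion("gpgrowth")),
    family = opt$family,
    log10_params = opt$log10_params,
    lower_bounds = opt$lower, upper_bounds = opt$upper,
    nll = attr(opt, "nll"),
    bound_saturated = attr(opt, "bound_saturated"),
    noise_kind = config$noise_kind,
    n_observations = data$n,
    n_samples = config$n_samples,
    n_excluded_samples = n_excluded,
    seed = config$seed
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(data = data, noise = noise, spec = opt, posterior = post,
                 samples = samples, statistics = stats_tab, paths = paths))
}
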