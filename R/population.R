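# Stage 2: pool tuning results across neurons of a cell type — regressions
# of A, r and mean activity on DoP with Lilliefors-guided model selection,
# significance tallies, and the DoP threshold for reliable AoP coding.

#' Lilliefors test of normality with a Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov statistic of the sample against a normal distribution
#' with mean and standard deviation estimated from the same sample. Because
#' the parameters are estimated, the usual KS null does not apply; the
#' p-value is the fraction of `n_mc` Gaussian samples of the same size whose
#' statistic (computed the same way) exceeds the observed one. The statistic
#' is location-scale invariant, so the null needs no parameter matching.
#'
#' @param values numeric sample, `n >= 4`.
#' @param n_mc Monte-Carlo null samples (default 2000).
#' @param seed optional seed for the Monte-Carlo draw.
#' @return list with `statistic` (D), `p`, `n`.
#' @export
lilliefors_test <- function(values, n_mc = 2000, seed = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4L) stop("lilliefors_test needs at least 4 values")
  if (stats::sd(values) == 0)
    stop(structure(class = c("polspike_degenerate_error", "error", "condition"),
                   list(message = "constant sample: normality test undefined",
                        call = NULL)))
  D_of <- function(x) {
    x <- sort(x)
    z <- stats::pnorm(x, mean(x), stats::sd(x))
    i <- seq_len(length(x))
    max(i / length(x) - z, z - (i - 1) / length(x))
  }
  D <- D_of(values)
  exceed <- with_seed(seed, {
    null <- matrix(stats::rnorm(n * n_mc), nrow = n)
    sum(apply(null, 2L, D_of) >= D)
  })
  list(statistic = D, p = (1 + exceed) / (n_mc + 1), n = n)
}

#' Regression of a response metric on the degree of polarization
#'
#' Pools responses of one cell type (only neurons tested at three or more
#' DoPs are eligible) and regresses the chosen metric on DoP by ordinary
#' least squares. If the residuals fail the Lilliefors normality test at
#' `cfg$alpha`, the regression is redone on the log10-transformed axis
#' (`cfg$regression_log_axis`: the DoP predictor by default); if that
#' model's residuals also fail, the model with the higher R-squared is
#' chosen. The selection path is recorded.
#'
#' @param results data frame of per-response rows (see
#'   [results_data_frame()]), or a list of `tuning_result`s.
#' @param response_var `"A"`, `"r"` or `"mean_rate"`.
#' @param cell_type restrict to one cell type; `NULL` pools all rows.
#' @param cfg an [analysis_config()].
#' @return An object of class `"dop_regression"`: `model_form`
#'   (`"linear_dop"` or `"linear_logdop"`), `slope`, `intercept`,
#'   `r_squared`, `slope_p`, `resid_normal_p`, `n_points`, `neurons_used`,
#'   `selection_path`, and the underlying `lm` fit; or an empty result with
#'   a `reason` when too few eligible neurons exist.
#' @export
fit_dop_regression <- function(results, response_var = c("A", "r", "mean_rate"),
                               cell_type = NULL, cfg = analysis_config()) {
  response_var <- match.arg(response_var)
  df <- results_data_frame(results)
  if (!is.null(cell_type)) df <- df[df$cell_type == cell_type, , drop = FALSE]
  eligible <- names(which(tapply(df$dop, df$neuron_id,
                                 function(d) length(unique(d))) >= 3))
  df <- df[df$neuron_id %in% eligible, , drop = FALSE]
  empty <- function(reason)
    structure(list(response_var = response_var, cell_type = cell_type,
                   model_form = NA_character_, slope = NA_real_,
                   intercept = NA_real_, r_squared = NA_real_,
                   slope_p = NA_real_, resid_normal_p = NA_real_,
                   n_points = nrow(df), neurons_used = eligible,
                   selection_path = character(0), fit = NULL,
                   reason = reason),
              class = "dop_regression")
  if (length(eligible) < 1L) return(empty("no neurons tested at >= 3 DoPs"))
  y <- df[[response_var]]
  ok <- is.finite(y) & is.finite(df$dop) & df$dop > 0
  df <- df[ok, , drop = FALSE]; y <- y[ok]
  if (length(unique(df$dop)) < 2L) return(empty("fewer than 2 distinct DoPs"))

  fit_one <- function(x, y) {
    m <- stats::lm(y ~ x)
    lp <- tryCatch(
      lilliefors_test(stats::residuals(m), n_mc = cfg$n_mc,
                      seed = cfg$rng_seed)$p,
      error = function(e) NA_real_)
    sm <- summary(m)
    list(fit = m, slope = unname(stats::coef(m)[2L]),
         intercept = unname(stats::coef(m)[1L]), r2 = sm$r.squared,
         slope_p = if (nrow(sm$coefficients) > 1L) sm$coefficients[2L, 4L]
         else NA_real_,
         lillie_p = lp)
  }
  lin <- fit_one(df$dop, y)
  path <- "linear_dop"
  chosen <- lin; form <- "linear_dop"
  if (!is.na(lin$lillie_p) && lin$lillie_p < cfg$alpha) {
    logm <- if (cfg$regression_log_axis == "dop")
      fit_one(log10(df$dop), y)
    else fit_one(df$dop, log10(pmax(y, .Machine$double.eps)))
    path <- c(path, "residuals non-normal -> linear_logdop")
    chosen <- logm; form <- "linear_logdop"
    if (!is.na(logm$lillie_p) && logm$lillie_p < cfg$alpha) {
      path <- c(path, "both non-normal -> higher R2")
      if (lin$r2 >= logm$r2) { chosen <- lin; form <- "linear_dop" }
    }
  }
  structure(list(response_var = response_var, cell_type = cell_type,
                 model_form = form, slope = chosen$slope,
                 intercept = chosen$intercept, r_squared = chosen$r2,
                 slope_p = chosen$slope_p, resid_normal_p = chosen$lillie_p,
                 n_points = nrow(df), neurons_used = eligible,
                 selection_path = path, fit = chosen$fit, reason = NULL),
            class = "dop_regression")
}

#' @export
print.dop_regression <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat(sprintf("<dop_regression> %s ~ DoP: no fit (%s)\n",
                x$response_var, x$reason))
    return(invisible(x))
  }
  cat(sprintf("<dop_regression> %s ~ %s%s: slope %.4g (p %.3g), R2 %.3f, n %d\n",
              x$response_var,
              if (x$model_form == "linear_logdop") "log10(DoP)" else "DoP",
              if (is.null(x$cell_type)) "" else paste0(" [", x$cell_type, "]"),
              x$slope, x$slope_p, x$r_squared, x$n_points))
  invisible(x)
}

#' Tally of significant responses per cell type and DoP
#'
#' @param results data frame of per-response rows or list of
#'   `tuning_result`s.
#' @param cfg an [analysis_config()] (unused beyond interface symmetry).
#' @return data frame with `cell_type`, `dop`, `n_significant`, `n_tested`.
#' @export
significance_tally <- function(results, cfg = analysis_config()) {
  df <- results_data_frame(results)
  if (!nrow(df))
    return(data.frame(cell_type = character(0), dop = numeric(0),
                      n_significant = integer(0), n_tested = integer(0)))
  agg <- stats::aggregate(significant ~ cell_type + dop, data = df,
                          FUN = function(s) c(sum(s), length(s)))
  out <- data.frame(cell_type = agg$cell_type, dop = agg$dop,
                    n_significant = agg$significant[, 1L],
                    n_tested = agg$significant[, 2L])
  out[order(out$cell_type, -out$dop), , drop = FALSE]
}

#' Mean and confidence limits of the no-stimulus control values
#'
#' Arithmetic mean of the control r (or A) values with two-sided confidence
#' limits of the mean from the t distribution with n-1 degrees of freedom;
#' the upper limit is what the threshold procedure compares against.
#'
#' @param controls numeric vector of control values (`n >= 3`).
#' @param cfg an [analysis_config()] (uses `ci_level`).
#' @return list with `mean`, `lower`, `upper`, `n`.
#' @export
nostim_confidence_limit <- function(controls, cfg = analysis_config()) {
  controls <- as.numeric(controls[is.finite(controls)])
  n <- length(controls)
  if (n < 3L)
    stop(structure(class = c("polspike_insufficient_controls", "error",
                             "condition"),
                   list(message = "need at least 3 no-stimulus control values",
                        call = NULL)))
  m <- mean(controls)
  se <- stats::sd(controls) / sqrt(n)
  tq <- stats::qt(1 - (1 - cfg$ci_level) / 2, df = n - 1)
  list(mean = m, lower = m - tq * se, upper = m + tq * se, n = n)
}

#' DoP threshold for reliable AoP coding
#'
#' Walks the DoP ladder from the highest DoP down and returns the lowest
#' DoP at which the metric values (r, or A) of *all* responses at that DoP
#' and every higher ladder DoP exceed the upper confidence limit of the
#' mean no-stimulus control value; `NA` if the criterion already fails at
#' the highest DoP.
#'
#' @param results data frame of per-response rows or list of
#'   `tuning_result`s.
#' @param controls numeric vector of no-stimulus control values for the same
#'   metric.
#' @param cell_type restrict to one cell type; `NULL` pools all rows.
#' @param metric `"r"` or `"A"`.
#' @param cfg an [analysis_config()].
#' @return An object of class `"threshold_result"`: `threshold_dop`,
#'   `nostim_mean`, `nostim_upper`, and `per_dop_pass` (data frame of
#'   `dop`, `n_above`, `n_total`).
#' @export
estimate_threshold <- function(results, controls, cell_type = NULL,
                               metric = c("r", "A"),
                               cfg = analysis_config()) {
  metric <- match.arg(metric)
  df <- results_data_frame(results)
  if (!is.null(cell_type)) df <- df[df$cell_type == cell_type, , drop = FALSE]
  lim <- nostim_confidence_limit(controls, cfg)
  ladder <- sort(unique(df$dop), decreasing = TRUE)
  per <- data.frame(dop = ladder, n_above = NA_integer_,
                    n_total = NA_integer_)
  threshold <- NA_real_
  all_pass_so_far <- TRUE
  for (i in seq_along(ladder)) {
    v <- df[[metric]][df$dop == ladder[i]]
    v <- v[is.finite(v)]
    per$n_total[i] <- length(v)
    per$n_above[i] <- sum(v > lim$upper)
    pass <- length(v) > 0 && all(v > lim$upper)
    all_pass_so_far <- all_pass_so_far && pass
    if (all_pass_so_far) threshold <- ladder[i]
  }
  structure(list(cell_type = cell_type, metric = metric,
                 nostim_mean = lim$mean, nostim_upper = lim$upper,
                 threshold_dop = threshold, per_dop_pass = per),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result>%s metric %s: threshold DoP = %s\n",
              if (is.null(x$cell_type)) "" else paste0(" ", x$cell_type),
              x$metric,
              if (is.na(x$threshold_dop)) "none" else format(x$threshold_dop)))
  cat(sprintf("  no-stimulus mean %.4f, upper %.0f%% limit %.4f\n",
              x$nostim_mean, 95, x$nostim_upper))
  print(x$per_dop_pass, row.names = FALSE)
  invisible(x)
}

#' Flatten tuning results into one row per response
#'
#' @param results a list of `tuning_result`s or an already-flat data frame
#'   (returned unchanged).
#' @return data frame with one row per (neuron, DoP) response.
#' @export
results_data_frame <- function(results) {
  if (is.data.frame(results)) return(results)
  if (inherits(results, "tuning_result")) results <- list(results)
  do.call(rbind, lapply(results, summary))
}
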