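#' polspike: polarization-tuning analysis of spike trains
#'
#' Quantifies how polarization-sensitive neurons encode the angle of
#' polarization (AoP) of light at different degrees of polarization (DoP),
#' from spike times recorded under a rotating-polarizer protocol. The
#' package provides axial circular statistics, a circular-linear correlation
#' test of tuning significance, bimodal von Mises tuning-curve fits, the
#' response-amplitude statistic A, DoP-dependence regressions with
#' Lilliefors-based model selection, and estimation of the DoP threshold for
#' reliable AoP coding. A seeded inhomogeneous-Poisson simulator with
#' cell-type presets generates recordings with the statistical structure the
#' analysis assumes.
#'
#' @keywords internal
"_PACKAGE"

#' Recognised central-complex cell-type labels
#'
#' Tangential (TL2, TL3) and columnar (CL1a) input neurons of the central
#' body, protocerebral-bridge tangential neurons (TB1) and columnar output
#' neurons (CPU1, CPU2), plus a catch-all.
#' @export
CELL_TYPES <- c("TL2", "TL3", "CL1a", "TB1", "CPU1", "CPU2", "OTHER")

stop_validation <- function(field, msg) {
  stop(structure(
    class = c("polspike_validation_error", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg), call = NULL,
         field = field)
  ))
}

#' Spike train of one neuron over one recording session
#'
#' @param neuron_id character identifier.
#' @param cell_type one of [CELL_TYPES].
#' @param spike_times numeric vector of spike times in seconds from session
#'   start; must be strictly increasing and lie in `[0, session_duration]`.
#' @param session_duration session length in seconds.
#' @return An object of class `"spike_train"`.
#' @export
spike_train <- function(neuron_id, cell_type, spike_times, session_duration) {
  if (!is.character(neuron_id) || length(neuron_id) != 1L || !nzchar(neuron_id))
    stop_validation("neuron_id", "must be a non-empty string")
  if (!is.character(cell_type) || length(cell_type) != 1L ||
      !cell_type %in% CELL_TYPES)
    stop_validation("cell_type",
                    paste("must be one of", paste(CELL_TYPES, collapse = ", ")))
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times))
    stop_validation("spike_times", "contains NA")
  if (length(spike_times) > 1L && any(diff(spike_times) <= 0))
    stop_validation("spike_times", "must be strictly increasing")
  if (!is.numeric(session_duration) || length(session_duration) != 1L ||
      !is.finite(session_duration) || session_duration <= 0)
    stop_validation("session_duration", "must be a positive number")
  if (length(spike_times) &&
      (spike_times[1L] < 0 || spike_times[length(spike_times)] > session_duration))
    stop_validation("spike_times",
                    "must lie within [0, session_duration]")
  structure(list(neuron_id = neuron_id, cell_type = cell_type,
                 spike_times = spike_times,
                 session_duration = as.numeric(session_duration)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s (%s): %d spikes over %.1f s (mean %.2f sp/s)\n",
              x$neuron_id, x$cell_type, length(x$spike_times),
              x$session_duration,
              length(x$spike_times) / x$session_duration))
  invisible(x)
}

#' One 360-degree (or partial) rotation of the polarizer
#'
#' Clockwise (`"CW"`) rotations increase the polarizer angle, counter-
#' clockwise (`"CCW"`) rotations decrease it; this sign convention is
#' recorded in the on-disk file header so data and analysis always agree.
#'
#' @param t_start rotation onset, seconds.
#' @param direction `"CW"` or `"CCW"`.
#' @param start_angle polarizer angle at onset, degrees in `[0, 360)`.
#' @param speed rotation speed, degrees per second (positive).
#' @param sweep total angular travel, degrees (default 360).
#' @return An object of class `"polarizer_rotation"`.
#' @export
polarizer_rotation <- function(t_start, direction = c("CW", "CCW"),
                               start_angle = 0, speed = 40, sweep = 360) {
  direction <- match.arg(direction)
  if (!is.finite(t_start)) stop_validation("t_start", "must be finite")
  if (!is.finite(start_angle) || start_angle < 0 || start_angle >= 360)
    stop_validation("start_angle", "must lie in [0, 360)")
  if (!is.finite(speed) || speed <= 0)
    stop_validation("speed", "must be positive")
  if (!is.finite(sweep) || sweep <= 0)
    stop_validation("sweep", "must be positive")
  structure(list(t_start = as.numeric(t_start), direction = direction,
                 start_angle = as.numeric(start_angle),
                 speed = as.numeric(speed), sweep = as.numeric(sweep)),
            class = "polarizer_rotation")
}

#' Duration of a rotation in seconds
#' @param rot a [polarizer_rotation()].
#' @return sweep / speed, seconds.
#' @export
rotation_duration <- function(rot) rot$sweep / rot$speed

#' Polarizer angle at time t
#'
#' Commanded polarizer angle during a rotation. Defined only for
#' `t` within `[t_start, t_start + sweep/speed]`; `NA` outside.
#'
#' @param rot a [polarizer_rotation()].
#' @param t numeric vector of times, seconds.
#' @return angles in degrees, modulo 360.
#' @export
angle_at <- function(rot, t) {
  sgn <- if (rot$direction == "CW") 1 else -1
  ang <- (rot$start_angle + sgn * rot$speed * (t - rot$t_start)) %% 360
  ang[t < rot$t_start | t > rot$t_start + rotation_duration(rot)] <- NA_real_
  ang
}

#' One light-on stimulus epoch with a fixed degree of polarization
#'
#' @param t_on,t_off epoch start and end, seconds; `t_on < t_off`.
#' @param dop degree of polarization in `[0, 1]`.
#' @param rotations list of [polarizer_rotation()]s, time-ordered,
#'   non-overlapping, all contained in `[t_on, t_off]`.
#' @param label free-text epoch label.
#' @return An object of class `"stimulus_epoch"`.
#' @export
stimulus_epoch <- function(t_on, t_off, dop, rotations, label = "") {
  if (!is.finite(t_on) || !is.finite(t_off) || t_on >= t_off)
    stop_validation("t_on/t_off", "must satisfy t_on < t_off")
  if (!is.finite(dop) || dop < 0 || dop > 1)
    stop_validation("dop", "must lie in [0, 1]")
  if (!is.list(rotations) ||
      !all(vapply(rotations, inherits, TRUE, "polarizer_rotation")))
    stop_validation("rotations", "must be a list of polarizer_rotation")
  if (length(rotations)) {
    starts <- vapply(rotations, `[[`, 0, "t_start")
    ends <- starts + vapply(rotations, rotation_duration, 0)
    if (is.unsorted(starts, strictly = FALSE))
      stop_validation("rotations", "must be time-ordered")
    if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)] - 1e-9))
      stop_validation("rotations", "must not overlap")
    if (min(starts) < t_on - 1e-9 || max(ends) > t_off + 1e-9)
      stop_validation("rotations", "must lie within [t_on, t_off]")
  }
  structure(list(t_on = as.numeric(t_on), t_off = as.numeric(t_off),
                 dop = as.numeric(dop), rotations = rotations,
                 label = as.character(label)),
            class = "stimulus_epoch")
}

epoch_directions <- function(epoch)
  vapply(epoch$rotations, `[[`, "", "direction")

#' A spike train together with its stimulus-epoch annotations
#'
#' Epochs must be time-ordered and non-overlapping. Each epoch should be
#' preceded by at least 5 s of epoch-free time for the background window;
#' epochs that are not are analysed with a truncated background window and
#' flagged downstream rather than rejected.
#'
#' @param spike_train a [spike_train()].
#' @param epochs list of [stimulus_epoch()]s.
#' @param metadata free-form named list (seed, generator parameters when
#'   synthetic, sign convention, ...).
#' @return An object of class `"recording"`.
#' @export
recording <- function(spike_train, epochs = list(), metadata = list()) {
  if (!inherits(spike_train, "spike_train"))
    stop_validation("spike_train", "must be a spike_train object")
  if (!is.list(epochs) ||
      !all(vapply(epochs, inherits, TRUE, "stimulus_epoch")))
    stop_validation("epochs", "must be a list of stimulus_epoch")
  if (length(epochs) > 1L) {
    ons <- vapply(epochs, `[[`, 0, "t_on")
    offs <- vapply(epochs, `[[`, 0, "t_off")
    if (is.unsorted(ons, strictly = TRUE))
      stop_validation("epochs", "must be time-ordered")
    if (any(ons[-1L] < offs[-length(offs)] - 1e-9))
      stop_validation("epochs", "must not overlap")
  }
  structure(list(spike_train = spike_train, epochs = epochs,
                 metadata = metadata),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  print(x$spike_train)
  dops <- vapply(x$epochs, `[[`, 0, "dop")
  cat(sprintf("  %d stimulus epochs (DoP: %s)\n", length(x$epochs),
              paste(format(dops), collapse = ", ")))
  invisible(x)
}

#' Epoch-free time preceding each epoch of a recording
#'
#' @param rec a [recording()].
#' @return numeric vector, seconds of stimulus-free time before each
#'   epoch's `t_on` (bounded below by session start).
#' @export
epoch_pre_gap <- function(rec) {
  if (!length(rec$epochs)) return(numeric(0))
  ons <- vapply(rec$epochs, `[[`, 0, "t_on")
  offs <- vapply(rec$epochs, `[[`, 0, "t_off")
  ons - c(0, offs[-length(offs)])
}

#' Analysis configuration
#'
#' Holds every tunable of the response analysis. AoP is an axial quantity
#' with a 180-degree period; spikes are assigned to `aop_period / bin_width`
#' bins (18 at the defaults).
#'
#' @param bin_width AoP bin width, degrees (default 10).
#' @param aop_period axial period, degrees (fixed at 180 for AoP).
#' @param ba_window background window preceding each stimulus, seconds.
#' @param ba_bin background bin width, seconds.
#' @param alpha significance level for the tuning test and the regressions.
#' @param min_spikes minimum pooled spike count for the significance test;
#'   below it the response is flagged untestable rather than tested.
#' @param ci_level confidence level for the no-stimulus limit.
#' @param p_method `"asymptotic"` (chi-square) or `"permutation"` p-values
#'   for the circular-linear correlation.
#' @param n_perm permutations when `p_method = "permutation"`.
#' @param n_mc Monte-Carlo samples for the Lilliefors null distribution.
#' @param control_source `"pre_stimulus"` sham-rotation controls, or
#'   `"lowest_dop"` to use responses at the lowest DoP tested as the
#'   no-stimulus reference.
#' @param regression_log_axis which variable the log10 transform applies to
#'   in the fallback regression model: the DoP predictor (default) or the
#'   response.
#' @param rng_seed integer seed for seeded operations; `NULL` leaves the
#'   RNG state alone.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(bin_width = 10, aop_period = 180, ba_window = 5,
                            ba_bin = 1, alpha = 0.05, min_spikes = 10,
                            ci_level = 0.95,
                            p_method = c("asymptotic", "permutation"),
                            n_perm = 1000, n_mc = 2000,
                            control_source = c("pre_stimulus", "lowest_dop"),
                            regression_log_axis = c("dop", "response"),
                            rng_seed = NULL) {
  p_method <- match.arg(p_method)
  control_source <- match.arg(control_source)
  regression_log_axis <- match.arg(regression_log_axis)
  if (360 %% aop_period != 0)
    stop_validation("aop_period", "must divide 360")
  if (aop_period %% bin_width != 0)
    stop_validation("bin_width", "must divide aop_period")
  if (ba_window <= 0 || ba_bin <= 0 || ba_bin > ba_window)
    stop_validation("ba_window/ba_bin", "must be positive with ba_bin <= ba_window")
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha", "must lie in (0, 1)")
  if (ci_level <= 0 || ci_level >= 1)
    stop_validation("ci_level", "must lie in (0, 1)")
  structure(list(bin_width = bin_width, aop_period = aop_period,
                 ba_window = ba_window, ba_bin = ba_bin, alpha = alpha,
                 min_spikes = min_spikes, ci_level = ci_level,
                 p_method = p_method, n_perm = n_perm, n_mc = n_mc,
                 control_source = control_source,
                 regression_log_axis = regression_log_axis,
                 rng_seed = rng_seed),
            class = "analysis_config")
}

n_bins <- function(cfg) as.integer(cfg$aop_period / cfg$bin_width)

bin_centers_aop <- function(cfg) {
  # half-open bins [lo, hi) over AoP mod aop_period, first edge at 0
  seq(cfg$bin_width / 2, cfg$aop_period - cfg$bin_width / 2, by = cfg$bin_width)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Unknown keys are an error (named), so typos never silently fall back to
#' defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file of configuration fields.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  do.call(analysis_config, vals)
}

# evaluate a seeded expression without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
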