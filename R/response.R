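# Stage 1: per (neuron, DoP) response metrics. Spikes fired during polarizer
# rotations are assigned to the commanded polarizer orientation modulo 180
# (AoP is axial) and binned; the bin counts feed the significance test and
# the response amplitude A, the per-spike angles feed the axial mean.

# length of the overlap between the axial arc swept from `from` over `len`
# degrees (len < period, already reduced) and the bin [lo, hi)
arc_bin_overlap <- function(from, len, lo, hi, period = 180) {
  from <- from %% period
  seg <- if (from + len <= period) list(c(from, from + len))
  else list(c(from, period), c(0, from + len - period))
  sum(vapply(seg, function(s) max(0, min(s[2L], hi) - max(s[1L], lo)), 0))
}

# exact angular dwell time (s) per axial bin for one rotation
rotation_exposure <- function(rot, cfg) {
  nb <- n_bins(cfg)
  bw <- cfg$bin_width
  per <- cfg$aop_period
  full <- floor(rot$sweep / per)
  rem <- rot$sweep - full * per
  expo <- rep(full * bw, nb)
  if (rem > 1e-12) {
    a0 <- rot$start_angle %% per
    from <- if (rot$direction == "CW") a0 else (a0 - rem) %% per
    lo <- (seq_len(nb) - 1L) * bw
    expo <- expo + vapply(seq_len(nb), function(i)
      arc_bin_overlap(from, rem, lo[i], lo[i] + bw, per), 0)
  }
  expo / rot$speed
}

#' Bin the spikes of one stimulus epoch by angle of polarization
#'
#' Each spike fired during a polarizer rotation is assigned the commanded
#' polarizer orientation at its time, reduced modulo 180 (AoP is axial), and
#' counted into its 10-degree bin. Counts are pooled across all rotations of
#' the epoch; the angular dwell time (exposure) per bin is accumulated
#' exactly. Per-rotation counts are kept for the rotation-scoped response
#' amplitude.
#'
#' @param rec a [recording()].
#' @param epoch one of its [stimulus_epoch()]s; must contain at least one
#'   clockwise and one counterclockwise rotation.
#' @param cfg an [analysis_config()].
#' @return An object of class `"binned_response"`: pooled `counts`,
#'   `exposure` (s), `rates` (spikes/s), `n_total`, `n_bar`, per-rotation
#'   count matrix, per-spike AoP angles, bin centres (and doubled centres).
#' @export
bin_response <- function(rec, epoch, cfg = analysis_config()) {
  dirs <- epoch_directions(epoch)
  if (!("CW" %in% dirs) || !("CCW" %in% dirs))
    stop(structure(class = c("polspike_protocol_error", "error", "condition"),
                   list(message = paste0(
                     "epoch '", epoch$label,
                     "' lacks a rotation in each direction; skipped"),
                     call = NULL)))
  nb <- n_bins(cfg)
  spikes <- rec$spike_train$spike_times
  per_rot <- matrix(0L, nrow = length(epoch$rotations), ncol = nb)
  exposure <- rep(0, nb)
  angles <- numeric(0)
  rot_time <- 0
  n_rot_spikes <- 0L
  for (k in seq_along(epoch$rotations)) {
    rot <- epoch$rotations[[k]]
    t_end <- rot$t_start + rotation_duration(rot)
    s <- spikes[spikes >= rot$t_start & spikes <= t_end]
    a <- angle_at(rot, s) %% cfg$aop_period
    idx <- pmin(floor(a / cfg$bin_width) + 1L, nb)
    per_rot[k, ] <- tabulate(idx, nbins = nb)
    exposure <- exposure + rotation_exposure(rot, cfg)
    angles <- c(angles, a)
    rot_time <- rot_time + rotation_duration(rot)
    n_rot_spikes <- n_rot_spikes + length(s)
  }
  counts <- colSums(per_rot)
  structure(list(counts = counts, exposure = exposure,
                 rates = counts / exposure, n_total = sum(counts),
                 n_bar = sum(counts) / nb, per_rotation_counts = per_rot,
                 spike_angles = angles, rotation_time = rot_time,
                 mean_rate = n_rot_spikes / rot_time,
                 bin_centers = bin_centers_aop(cfg),
                 bin_centers_doubled = 2 * bin_centers_aop(cfg),
                 rotations_used = length(epoch$rotations)),
            class = "binned_response")
}

#' Response amplitude A
#'
#' The absolute amplitude of spike-frequency modulation,
#' \deqn{A = \sum_{i=1}^{18} |n_i - \bar n|,}
#' where \eqn{n_i} is the spike count in AoP bin i during one 360-degree
#' rotation and \eqn{\bar n} is that rotation's total count divided by the
#' number of bins. A is computed per rotation and averaged across the
#' epoch's rotations.
#'
#' @param binned a [bin_response()] result, or a matrix/vector of counts
#'   (rows = rotations).
#' @return A, in spikes (averaged over rotations).
#' @export
response_amplitude <- function(binned) {
  m <- if (inherits(binned, "binned_response")) binned$per_rotation_counts
  else if (is.matrix(binned)) binned
  else matrix(binned, nrow = 1L)
  mean(apply(m, 1L, function(n) sum(abs(n - mean(n)))))
}

#' Background activity preceding a stimulus epoch
#'
#' Spike counts in 1 s bins over the 5 s window ending at stimulus onset,
#' summarised by median and 2.5th/97.5th percentiles (linear-interpolation
#' percentile rule). When less than 5 s of epoch-free time is available the
#' window is truncated and flagged; with no full bin available the result
#' carries `missing = TRUE` and downstream normalisation is disabled.
#'
#' @inheritParams bin_response
#' @return list of class `"background_activity"`: `median`, `p2_5`,
#'   `p97_5` (spikes/s), `rates` per bin, `n_bins`, `truncated`, `missing`.
#' @export
background_activity <- function(rec, epoch, cfg = analysis_config()) {
  offs <- vapply(rec$epochs, `[[`, 0, "t_off")
  prev_off <- offs[offs <= epoch$t_on + 1e-9]
  floor_t <- if (length(prev_off)) max(0, max(prev_off)) else 0
  avail <- min(cfg$ba_window, epoch$t_on - floor_t)
  nb <- floor(avail / cfg$ba_bin + 1e-9)
  if (nb < 1L)
    return(structure(list(median = NA_real_, p2_5 = NA_real_,
                          p97_5 = NA_real_, rates = numeric(0), n_bins = 0L,
                          truncated = TRUE, missing = TRUE),
                     class = "background_activity"))
  edges <- epoch$t_on - rev(seq_len(nb + 1L) - 1L) * cfg$ba_bin
  s <- rec$spike_train$spike_times
  cnt <- tabulate(findInterval(s[s >= edges[1L] & s < epoch$t_on], edges),
                  nbins = nb)
  rates <- cnt / cfg$ba_bin
  q <- stats::quantile(rates, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  structure(list(median = q[2L], p2_5 = q[1L], p97_5 = q[3L], rates = rates,
                 n_bins = nb, truncated = nb < cfg$ba_window / cfg$ba_bin,
                 missing = FALSE),
            class = "background_activity")
}

#' Full per-response tuning analysis
#'
#' Composes the stage-1 metrics for one (neuron, DoP) response: the
#' preferred AoP `phi_max` and resultant length `r` from the axial mean of
#' per-spike polarizer angles; the significance of AoP tuning from the
#' circular-linear correlation of pooled bin counts with bin angle; the
#' response amplitude `A`; a bimodal von Mises fit of the bin rates, whose
#' firing rates at `phi_max` and `phi_min = phi_max + 90` are reported; the
#' mean rate during rotations; and the pre-stimulus background activity.
#'
#' Responses with fewer than `cfg$min_spikes` pooled spikes are emitted with
#' `significant = FALSE` and the p-value flagged untestable rather than
#' tested.
#'
#' @inheritParams bin_response
#' @return An object of class `"tuning_result"`.
#' @export
analyze_response <- function(rec, epoch, cfg = analysis_config()) {
  binned <- bin_response(rec, epoch, cfg)
  flags <- character(0)

  am <- if (binned$n_total > 0) axial_mean(binned$spike_angles) else NULL
  phi_max <- if (!is.null(am) && am$phi_defined) am$phi_max else NA_real_
  r <- if (!is.null(am)) am$r else NA_real_
  if (is.null(am)) flags <- c(flags, "no_spikes")
  else if (!am$phi_defined) flags <- c(flags, "phi_undefined")

  p <- NA_real_
  r_cl <- NA_real_
  if (binned$n_total < cfg$min_spikes) {
    flags <- c(flags, "untestable")
  } else {
    ct <- tryCatch(
      circ_linear_corr(binned$counts, binned$bin_centers_doubled,
                       method = cfg$p_method, n_perm = cfg$n_perm,
                       seed = cfg$rng_seed),
      polspike_degenerate_error = function(e) NULL)
    if (is.null(ct)) flags <- c(flags, "degenerate_counts")
    else { p <- ct$p; r_cl <- ct$r_cl }
  }
  significant <- !is.na(p) && p < cfg$alpha

  fit <- fit_bimodal_von_mises(binned)
  if (!fit$converged) flags <- c(flags, "fit_failed")
  rate_of <- function(theta) {
    if (fit$converged) rate_at(fit, theta)
    else binned$rates[pmin(floor((theta %% cfg$aop_period) / cfg$bin_width) + 1L,
                           n_bins(cfg))]
  }
  phi_min <- if (!is.na(phi_max)) (phi_max + 90) %% 180 else NA_real_
  ba <- background_activity(rec, epoch, cfg)
  if (ba$missing) flags <- c(flags, "no_background")
  else if (ba$truncated) flags <- c(flags, "truncated_background")

  structure(list(
    neuron_id = rec$spike_train$neuron_id,
    cell_type = rec$spike_train$cell_type,
    dop = epoch$dop, label = epoch$label,
    n_spikes = binned$n_total,
    phi_max = phi_max, phi_min = phi_min,
    r = r, r_cl = r_cl, p = p, significant = significant,
    A = response_amplitude(binned),
    rate_phi_max = if (!is.na(phi_max)) rate_of(phi_max) else NA_real_,
    rate_phi_min = if (!is.na(phi_min)) rate_of(phi_min) else NA_real_,
    mean_rate = binned$mean_rate,
    background = ba, fit = fit, binned = binned,
    alpha = cfg$alpha, flags = flags),
    class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %s (%s), DoP %g: %d spikes\n",
              x$neuron_id, x$cell_type, x$dop, x$n_spikes))
  cat(sprintf("  phi_max = %s, r = %.3f, p = %s (%ssignificant at %.2g)\n",
              if (is.na(x$phi_max)) "undefined" else sprintf("%.1f deg", x$phi_max),
              x$r,
              if (is.na(x$p)) "untestable" else format.pval(x$p, digits = 3),
              if (x$significant) "" else "not ", x$alpha))
  cat(sprintf("  A = %.1f spikes; rate at phi_max/phi_min = %.1f / %.1f sp/s; mean %.1f sp/s\n",
              x$A, x$rate_phi_max, x$rate_phi_min, x$mean_rate))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tuning_result <- function(object, ...) {
  out <- as.data.frame(object[c("neuron_id", "cell_type", "dop", "n_spikes",
                                "phi_max", "phi_min", "r", "p", "significant",
                                "A", "rate_phi_max", "rate_phi_min",
                                "mean_rate")])
  out$ba_median <- object$background$median
  out$flags <- paste(object$flags, collapse = ";")
  out
}

#' @export
plot.tuning_result <- function(x, ...) {
  plot(x$fit, main = sprintf("%s  DoP %g", x$neuron_id, x$dop), ...)
  if (!is.na(x$phi_max)) graphics::abline(v = x$phi_max, lty = 2)
  invisible(x)
}

#' Activity at the preferred and anti-preferred AoP relative to background
#'
#' @param tr a [analyze_response()] result.
#' @return list with `act_max` and `act_min`, the fitted rates at `phi_max`
#'   and `phi_min` divided by the background median; both `NA` (with a
#'   reason attribute) when the background median is zero or missing.
#' @export
normalized_extremes <- function(tr) {
  ba <- tr$background
  if (ba$missing || is.na(ba$median) || ba$median <= 0) {
    out <- list(act_max = NA_real_, act_min = NA_real_)
    attr(out, "reason") <- "background median zero or missing"
    return(out)
  }
  list(act_max = tr$rate_phi_max / ba$median,
       act_min = tr$rate_phi_min / ba$median)
}

#' No-stimulus control: null directedness of background spiking
#'
#' Applies the epoch's rotation trajectory, shifted into a stimulus-free
#' window ending where the background window begins, to the background
#' spikes, and computes the axial resultant length r as if those spikes were
#' stimulus-driven. This is the null distribution of r the threshold
#' procedure compares against.
#'
#' @inheritParams bin_response
#' @return A `"circ_result"` (see [axial_mean()]), or an object of class
#'   `"control_skipped"` carrying the reason when no stimulus-free window of
#'   the required length exists or the window holds no spikes.
#' @export
no_stimulus_control <- function(rec, epoch, cfg = analysis_config()) {
  skipped <- function(reason)
    structure(list(reason = reason), class = "control_skipped")
  if (!length(epoch$rotations)) return(skipped("epoch has no rotations"))
  starts <- vapply(epoch$rotations, `[[`, 0, "t_start")
  ends <- starts + vapply(epoch$rotations, rotation_duration, 0)
  span_end <- epoch$t_on - cfg$ba_window
  shift <- span_end - max(ends)
  offs <- vapply(rec$epochs, `[[`, 0, "t_off")
  prev_off <- offs[offs <= epoch$t_on + 1e-9]
  floor_t <- if (length(prev_off)) max(0, max(prev_off)) else 0
  if (min(starts) + shift < floor_t - 1e-9)
    return(skipped("no stimulus-free window long enough"))
  spikes <- rec$spike_train$spike_times
  angles <- numeric(0)
  for (rot in epoch$rotations) {
    t0 <- rot$t_start + shift
    t1 <- t0 + rotation_duration(rot)
    s <- spikes[spikes >= t0 & spikes <= t1]
    sham <- polarizer_rotation(t0, rot$direction, rot$start_angle,
                               rot$speed, rot$sweep)
    angles <- c(angles, angle_at(sham, s) %% cfg$aop_period)
  }
  if (!length(angles)) return(skipped("silent control window"))
  axial_mean(angles)
}
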