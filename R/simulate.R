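# Synthetic recordings: an inhomogeneous-Poisson neuron whose firing rate
# combines a baseline, a DoP-dependent sinusoidal AoP tuning term, a tonic
# response to near-unpolarized light, and exponential on/off transients
# (rebounds). Spikes are drawn by thinning against a fixed rate ceiling, so
# every downstream statistic can be checked against known ground truth.

#' Generative rate model of a polarization-sensitive neuron
#'
#' During a stimulus epoch with degree of polarization d, the firing rate is
#' \deqn{\lambda(t) = clip(B + T(d) + M(d)\cos(2(\theta(t)-\phi)) + on(t) + off(t),\ 0,\ ceiling)}
#' where B is the baseline, \eqn{\phi} the true preferred AoP, \eqn{\theta(t)}
#' the polarizer angle, \eqn{T(d) = \tau_0 (1-d)} a signed tonic term that is
#' maximal under near-unpolarized light, M(d) the DoP-dependent modulation
#' amplitude, and on/off are signed exponential transients started at epoch
#' onset/offset (the off transient models the rebound).
#'
#' @param baseline background rate B, spikes/s.
#' @param phi_max_true true preferred AoP, degrees in `[0, 180)`.
#' @param amp_law `"linear"`: `M(d) = m0 * d`, `amp_params = c(m0 = ...)`;
#'   `"log"`: `M(d) = max(0, a0 + a1 * log10(d))`,
#'   `amp_params = c(a0 = ..., a1 = ...)`.
#' @param amp_params numeric parameters of the amplitude law (see `amp_law`).
#' @param tonic_gain signed tonic gain \eqn{\tau_0}, spikes/s; positive means
#'   excitation under unpolarized light.
#' @param on_transient,off_transient `c(amp = spikes/s (signed), tau = s)`;
#'   kernel `amp * exp(-(t - t_event)/tau)` added from epoch on/off onwards.
#' @param dra_occluded if `TRUE` (dorsal rim area covered), all
#'   stimulus-driven terms are zeroed and only the baseline remains.
#' @param rate_ceiling hard upper bound on the rate, spikes/s; also the
#'   envelope of the thinning sampler.
#' @param dead_time absolute refractory period, seconds (default 0, i.e.
#'   pure Poisson; 0.002 is a typical value when enabled).
#' @return An object of class `"neuron_model"`.
#' @export
neuron_model <- function(baseline, phi_max_true, amp_law = c("linear", "log"),
                         amp_params, tonic_gain = 0,
                         on_transient = c(amp = 0, tau = 1),
                         off_transient = c(amp = 0, tau = 5),
                         dra_occluded = FALSE, rate_ceiling = NULL,
                         dead_time = 0) {
  amp_law <- match.arg(amp_law)
  if (baseline < 0) stop_validation("baseline", "must be >= 0")
  if (phi_max_true < 0 || phi_max_true >= 180)
    stop_validation("phi_max_true", "must lie in [0, 180)")
  amp_params <- as.numeric(amp_params)
  if (amp_law == "linear") {
    if (length(amp_params) != 1L)
      stop_validation("amp_params", "linear law takes one parameter m0")
    if (amp_params[1L] < 0)
      stop_validation("amp_params", "m0 must be >= 0 so M(d) >= 0")
  } else if (length(amp_params) != 2L) {
    stop_validation("amp_params", "log law takes two parameters (a0, a1)")
  }
  on_transient <- as.numeric(on_transient)
  off_transient <- as.numeric(off_transient)
  if (length(on_transient) != 2L || length(off_transient) != 2L ||
      on_transient[2L] <= 0 || off_transient[2L] <= 0)
    stop_validation("transients", "need c(amp, tau) with tau > 0")
  if (is.null(rate_ceiling))
    rate_ceiling <- baseline + abs(tonic_gain) + amp_max(amp_law, amp_params) +
      max(on_transient[1L], 0) + max(off_transient[1L], 0) + 1
  if (rate_ceiling < baseline)
    stop_validation("rate_ceiling", "must be >= baseline")
  if (dead_time < 0) stop_validation("dead_time", "must be >= 0")
  structure(list(baseline = baseline, phi_max_true = phi_max_true,
                 amp_law = amp_law, amp_params = amp_params,
                 tonic_gain = tonic_gain,
                 on_transient = c(amp = on_transient[1L], tau = on_transient[2L]),
                 off_transient = c(amp = off_transient[1L], tau = off_transient[2L]),
                 dra_occluded = isTRUE(dra_occluded),
                 rate_ceiling = rate_ceiling, dead_time = dead_time),
            class = "neuron_model")
}

amp_max <- function(amp_law, amp_params) {
  if (amp_law == "linear") amp_params[1L]
  else max(0, amp_params[1L])  # log law is increasing in d, max at d = 1
}

#' Modulation amplitude M(d) of a neuron model
#' @param model a [neuron_model()].
#' @param dop degree(s) of polarization in `[0, 1]`.
#' @return spikes/s, always `>= 0`.
#' @export
modulation_amplitude <- function(model, dop) {
  if (model$dra_occluded) return(rep(0, length(dop)))
  if (model$amp_law == "linear") model$amp_params[1L] * dop
  else pmax(0, model$amp_params[1L] + model$amp_params[2L] * log10(pmax(dop, 1e-12)))
}

tonic_term <- function(model, dop) {
  if (model$dra_occluded) rep(0, length(dop)) else model$tonic_gain * (1 - dop)
}

# polarizer angle held between rotations: last completed rotation's end
# angle; before the first rotation, its start angle (the device does not
# jump while the light stays on)
epoch_theta <- function(epoch, t) {
  th <- rep(NA_real_, length(t))
  if (!length(epoch$rotations)) return(th)
  first <- epoch$rotations[[1L]]
  held <- first$start_angle
  prev_end <- epoch$t_on
  for (rot in epoch$rotations) {
    t_end <- rot$t_start + rotation_duration(rot)
    th[t >= prev_end & t < rot$t_start] <- held
    inside <- t >= rot$t_start & t <= t_end
    th[inside] <- angle_at(rot, t[inside])
    sgn <- if (rot$direction == "CW") 1 else -1
    held <- (rot$start_angle + sgn * rot$sweep) %% 360
    prev_end <- t_end
  }
  th[t > prev_end & t <= epoch$t_off] <- held
  th
}

#' Instantaneous firing rate of the generative model
#'
#' Total function of time: baseline outside epochs, baseline + tonic +
#' tuned term inside, plus any on/off transients (which persist after the
#' epoch until they decay).
#'
#' @param model a [neuron_model()].
#' @param epochs list of [stimulus_epoch()]s.
#' @param t numeric vector of times, seconds.
#' @return rate in spikes/s, clipped to `[0, rate_ceiling]`.
#' @export
rate_function <- function(model, epochs, t) {
  lam <- rate_function_raw(model, epochs, t)
  pmin(pmax(lam, 0), model$rate_ceiling)
}

rate_function_raw <- function(model, epochs, t) {
  lam <- rep(model$baseline, length(t))
  if (model$dra_occluded) return(lam)
  for (ep in epochs) {
    inside <- t >= ep$t_on & t <= ep$t_off
    if (any(inside)) {
      add <- tonic_term(model, ep$dop)
      th <- epoch_theta(ep, t[inside])
      tuned <- modulation_amplitude(model, ep$dop) *
        cos(2 * (th - model$phi_max_true) * pi / 180)
      tuned[is.na(tuned)] <- 0
      lam[inside] <- lam[inside] + add + tuned
    }
    if (model$on_transient[["amp"]] != 0) {
      after <- t >= ep$t_on
      lam[after] <- lam[after] + model$on_transient[["amp"]] *
        exp(-(t[after] - ep$t_on) / model$on_transient[["tau"]])
    }
    if (model$off_transient[["amp"]] != 0) {
      after <- t >= ep$t_off
      lam[after] <- lam[after] + model$off_transient[["amp"]] *
        exp(-(t[after] - ep$t_off) / model$off_transient[["tau"]])
    }
  }
  lam
}

#' Stimulus protocol: a descending DoP ladder of rotation epochs
#'
#' Each epoch presents blue light at one DoP and contains the requested
#' number of clockwise then counterclockwise full rotations, back to back,
#' with a short light-on lead-in/out around the rotations. Epochs are
#' separated by `inter_epoch_gap` of darkness, long enough for rebounds to
#' decay and for the 5 s background window.
#'
#' @param dop_ladder DoPs presented, in order.
#' @param rotations_per_epoch `c(cw = ..., ccw = ...)` full rotations.
#' @param speed rotation speed, degrees/s.
#' @param sweep rotation sweep, degrees.
#' @param inter_epoch_gap darkness between epochs (and before the first),
#'   seconds; must cover the background window of the analysis it feeds.
#' @param lead light-on time before the first and after the last rotation
#'   of an epoch, seconds.
#' @param start_angle polarizer angle at the start of each epoch's first
#'   rotation, degrees.
#' @return An object of class `"protocol_spec"`.
#' @export
protocol_spec <- function(dop_ladder = c(0.99, 0.35, 0.1, 0.05, 0.002),
                          rotations_per_epoch = c(cw = 1, ccw = 1),
                          speed = 40, sweep = 360, inter_epoch_gap = 30,
                          lead = 0.5, start_angle = 0) {
  if (any(dop_ladder < 0 | dop_ladder > 1))
    stop_validation("dop_ladder", "DoPs must lie in [0, 1]")
  if (rotations_per_epoch[["cw"]] < 1 || rotations_per_epoch[["ccw"]] < 1)
    stop_validation("rotations_per_epoch",
                    "need at least one rotation per direction")
  if (inter_epoch_gap < 5)
    stop_validation("inter_epoch_gap",
                    "must cover the 5 s background window")
  structure(list(dop_ladder = dop_ladder,
                 rotations_per_epoch = rotations_per_epoch, speed = speed,
                 sweep = sweep, inter_epoch_gap = inter_epoch_gap,
                 lead = lead, start_angle = start_angle),
            class = "protocol_spec")
}

#' Build the epoch list a protocol prescribes
#' @param protocol a [protocol_spec()].
#' @return list with `epochs` (list of [stimulus_epoch()]) and
#'   `session_duration` (seconds).
#' @export
build_epochs <- function(protocol) {
  rot_dur <- protocol$sweep / protocol$speed
  n_rot <- sum(protocol$rotations_per_epoch)
  dirs <- c(rep("CW", protocol$rotations_per_epoch[["cw"]]),
            rep("CCW", protocol$rotations_per_epoch[["ccw"]]))
  epochs <- list()
  t <- protocol$inter_epoch_gap
  for (k in seq_along(protocol$dop_ladder)) {
    t_on <- t
    ang <- protocol$start_angle
    rots <- list()
    rt <- t_on + protocol$lead
    for (d in dirs) {
      rots[[length(rots) + 1L]] <-
        polarizer_rotation(rt, d, ang %% 360, protocol$speed, protocol$sweep)
      ang <- (ang + (if (d == "CW") 1 else -1) * protocol$sweep) %% 360
      rt <- rt + rot_dur
    }
    t_off <- t_on + protocol$lead * 2 + n_rot * rot_dur
    epochs[[k]] <- stimulus_epoch(t_on, t_off, protocol$dop_ladder[k], rots,
                                  label = sprintf("dop%g", protocol$dop_ladder[k]))
    t <- t_off + protocol$inter_epoch_gap
  }
  list(epochs = epochs, session_duration = t)
}

#' Simulate one recording under a stimulus protocol
#'
#' Spike times are drawn from an inhomogeneous Poisson process with
#' intensity [rate_function()], by thinning against `rate_ceiling`.
#' Deterministic for a fixed seed. Errors before sampling if the unclipped
#' intensity ever exceeds the ceiling (clipping would silently distort the
#' model).
#'
#' @param model a [neuron_model()].
#' @param protocol a [protocol_spec()].
#' @param seed integer seed.
#' @param neuron_id,cell_type identity given to the simulated neuron.
#' @return A [recording()]; `metadata` records model, protocol and seed.
#' @export
simulate_recording <- function(model, protocol, seed,
                               neuron_id = sprintf("sim-%d", seed),
                               cell_type = "OTHER") {
  built <- build_epochs(protocol)
  epochs <- built$epochs
  dur <- built$session_duration

  sup <- sup_rate(model, epochs, dur)
  if (sup > model$rate_ceiling + 1e-9)
    stop(sprintf("rate_ceiling (%.3f) below the supremum of the intensity (%.3f)",
                 model$rate_ceiling, sup))

  spikes <- with_seed(seed, {
    n_cand <- stats::rpois(1L, model$rate_ceiling * dur)
    # unique() guards against exact ties from the RNG's finite granularity
    cand <- unique(sort(stats::runif(n_cand, 0, dur)))
    keep <- stats::runif(length(cand)) <
      rate_function(model, epochs, cand) / model$rate_ceiling
    s <- cand[keep]
    if (model$dead_time > 0 && length(s) > 1L) {
      out <- s[1L]
      for (ti in s[-1L]) if (ti - out[length(out)] >= model$dead_time)
        out <- c(out, ti)
      s <- out
    }
    s
  })
  st <- spike_train(neuron_id, cell_type, spikes, dur)
  recording(st, epochs,
            metadata = list(generator = "polspike inhomogeneous Poisson",
                            seed = seed, model = unclass(model),
                            protocol = unclass(protocol)))
}

# supremum of the unclipped intensity: analytic per-epoch peak plus the
# worst-case transient overlap (transients decay, so the peak is at an event)
sup_rate <- function(model, epochs, dur) {
  if (model$dra_occluded) return(model$baseline)
  peak <- model$baseline
  for (ep in epochs) {
    in_ep <- model$baseline + tonic_term(model, ep$dop) +
      modulation_amplitude(model, ep$dop)
    peak <- max(peak, in_ep + max(model$on_transient[["amp"]], 0),
                model$baseline + max(model$off_transient[["amp"]], 0),
                in_ep)
  }
  peak
}

# ---- cell-type presets ------------------------------------------------------

# Qualitative response classes under near-unpolarized light, per cell type:
# sign of the tonic term, sign of the off rebound, and the amplitude law of
# M(d). Magnitudes are package defaults (jittered ~20% when a seed is given);
# the recordings they emulate report signs and trends, not magnitudes.
PRESET_TABLE <- list(
  TL2 = list(
    `inhibited-low-DoP` = list(amp_law = "linear", amp = c(m0 = 15),
                               tonic = -6, on = c(0, 1), off = c(8, 5)),
    `excited-low-DoP` = list(amp_law = "linear", amp = c(m0 = 15),
                             tonic = 6, on = c(0, 1), off = c(-8, 5)),
    `no-change` = list(amp_law = "linear", amp = c(m0 = 15),
                       tonic = 0, on = c(0, 1), off = c(0, 5)),
    default = "inhibited-low-DoP"),
  TL3 = list(
    `inhibited-low-DoP` = list(amp_law = "log", amp = c(a0 = 14, a1 = 5),
                               tonic = -4, on = c(0, 1), off = c(6, 4)),
    `no-change` = list(amp_law = "log", amp = c(a0 = 14, a1 = 5),
                       tonic = 0, on = c(0, 1), off = c(0, 5)),
    default = "no-change"),
  CL1a = list(
    `phasic-onset` = list(amp_law = "log", amp = c(a0 = 14, a1 = 5),
                          tonic = 5, on = c(-12, 0.5), off = c(-8, 1.5)),
    `excited-low-DoP` = list(amp_law = "log", amp = c(a0 = 14, a1 = 5),
                             tonic = 5, on = c(0, 1), off = c(-8, 1.5)),
    default = "phasic-onset"),
  TB1 = list(
    `no-rebound` = list(amp_law = "log", amp = c(a0 = 14, a1 = 5),
                        tonic = 0, on = c(0, 1), off = c(0, 5)),
    default = "no-rebound"),
  CPU1 = list(
    `no-change` = list(amp_law = "log", amp = c(a0 = 14, a1 = 5),
                       tonic = 0, on = c(0, 1), off = c(0, 5)),
    `inhibited-low-DoP` = list(amp_law = "log", amp = c(a0 = 14, a1 = 5),
                               tonic = -4, on = c(0, 1), off = c(6, 3)),
    default = "no-change"),
  CPU2 = list(
    default = list(amp_law = "linear", amp = c(m0 = 14),
                   tonic = 0, on = c(0, 1), off = c(0, 5))),
  OTHER = list(
    default = list(amp_law = "linear", amp = c(m0 = 12),
                   tonic = 0, on = c(0, 1), off = c(0, 5)))
)

#' Preset neuron models per cell type and qualitative response class
#'
#' Encodes the qualitative phenomenology of each central-complex cell type:
#' TL2 neurons are tonically inhibited (most) or excited (some) by
#' near-unpolarized light with an opposite-signed rebound at lights off;
#' CL1a neurons show tonic excitation at low DoP with phasic onset
#' inhibition and a rebound inhibition at offset; TB1 and CPU neurons show
#' little or no tonic response. Modulation amplitude grows linearly with
#' DoP for TL2 and CPU2 presets and logarithmically for the others.
#'
#' @param cell_type one of [CELL_TYPES].
#' @param variant named response class (e.g. `"inhibited-low-DoP"`,
#'   `"excited-low-DoP"`, `"phasic-onset"`, `"no-rebound"`, `"no-change"`)
#'   or `"default"`.
#' @param seed optional integer; when given, the true preferred AoP is drawn
#'   uniformly from `[0, 180)` and magnitudes are jittered by ±20%.
#' @param baseline baseline rate, spikes/s.
#' @return A [neuron_model()].
#' @export
make_celltype_preset <- function(cell_type, variant = "default", seed = NULL,
                                 baseline = 20) {
  if (!cell_type %in% CELL_TYPES)
    stop_validation("cell_type",
                    paste("must be one of", paste(CELL_TYPES, collapse = ", ")))
  tab <- PRESET_TABLE[[cell_type]]
  spec <- tab[[variant]]
  if (is.null(spec))
    stop(sprintf("unknown response class '%s' for cell type %s (known: %s)",
                 variant, cell_type,
                 paste(setdiff(names(tab), "default"), collapse = ", ")))
  if (is.character(spec)) spec <- tab[[spec]]

  phi <- 90
  jit <- function(x) x
  if (!is.null(seed)) {
    draws <- with_seed(seed, stats::runif(6))
    phi <- draws[1L] * 180
    k <- 0
    jit <- function(x) {
      k <<- k + 1
      x * (0.8 + 0.4 * draws[k + 1L])
    }
  }
  neuron_model(
    baseline = baseline, phi_max_true = phi, amp_law = spec$amp_law,
    amp_params = jit(spec$amp), tonic_gain = jit(spec$tonic),
    on_transient = c(jit(spec$on[1L]), spec$on[2L]),
    off_transient = c(jit(spec$off[1L]), spec$off[2L]))
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf("<neuron_model> B=%.1f sp/s, phi_max=%.1f deg, %s amplitude law (%s)\n",
              x$baseline, x$phi_max_true, x$amp_law,
              paste(format(x$amp_params), collapse = ", ")))
  cat(sprintf("  tonic %.1f sp/s, on (%.1f, tau %.1f), off (%.1f, tau %.1f)%s\n",
              x$tonic_gain, x$on_transient[["amp"]], x$on_transient[["tau"]],
              x$off_transient[["amp"]], x$off_transient[["tau"]],
              if (x$dra_occluded) ", DRA occluded" else ""))
  invisible(x)
}
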