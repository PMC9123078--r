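# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# a tiny hand-built recording: one epoch, one CW + one CCW rotation at the
# standard 40 deg/s, spikes placed wherever the caller wants
tiny_recording <- function(spikes, t_on = 10, dop = 0.99, start_angle = 0,
                           session = 60, neuron_id = "n1", cell_type = "TL2") {
  rot1 <- polarizer_rotation(t_on + 0.5, "CW", start_angle, 40, 360)
  rot2 <- polarizer_rotation(t_on + 9.5, "CCW", start_angle, 40, 360)
  ep <- stimulus_epoch(t_on, t_on + 19, dop, list(rot1, rot2), "e1")
  recording(spike_train(neuron_id, cell_type, spikes, session), list(ep))
}

# homogeneous-Poisson neuron: no tuning, no tonic term, no transients
flat_model <- function(baseline = 20)
  neuron_model(baseline, 60, "linear", c(m0 = 0), tonic_gain = 0,
               rate_ceiling = baseline + 1)

# strongly tuned neuron matching the canonical calibration condition
# (baseline 20 sp/s, modulation amplitude 15 sp/s at DoP 0.99)
tuned_model <- function(phi = 60)
  neuron_model(20, phi, "linear", c(m0 = 15 / 0.99), tonic_gain = 0)

short_protocol <- function(dop = 0.99)
  protocol_spec(dop_ladder = dop, inter_epoch_gap = 6)

# brute-force axial mean: explicit vector sum over doubled angles
oracle_axial_mean <- function(angles) {
  th <- 2 * angles * pi / 180
  C <- sum(cos(th)) / length(th)
  S <- sum(sin(th)) / length(th)
  list(r = sqrt(C^2 + S^2),
       phi_max = ((atan2(S, C) * 180 / pi) %% 360) / 2)
}

# brute-force response amplitude: explicit loop over bins
oracle_amplitude <- function(counts) {
  nbar <- sum(counts) / length(counts)
  tot <- 0
  for (ni in counts) tot <- tot + abs(ni - nbar)
  tot
}
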