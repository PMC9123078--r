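cfg <- analysis_config()

test_that("spikes are assigned to the AoP bin of the commanded angle", {
  # one spike while the CW rotation passes 37 deg -> bin [30, 40)
  rec <- tiny_recording(10.5 + 37 / 40)
  b <- bin_response(rec, rec$epochs[[1]], cfg)
  expect_equal(b$n_total, 1)
  expect_equal(which(b$counts == 1), 4L)
  # a spike at raw angle 217 deg lands in the same axial bin
  rec2 <- tiny_recording(10.5 + 217 / 40)
  b2 <- bin_response(rec2, rec2$epochs[[1]], cfg)
  expect_equal(which(b2$counts == 1), 4L)
  # no spikes during rotations -> all-zero counts and rates
  rec0 <- tiny_recording(c(1, 2, 55))
  b0 <- bin_response(rec0, rec0$epochs[[1]], cfg)
  expect_equal(b0$counts, rep(0, 18))
  expect_equal(b0$rates, rep(0, 18))
})

test_that("angular exposure is exact: equal for full sweeps, oracle-checked for partial", {
  rec <- tiny_recording(numeric(0))
  b <- bin_response(rec, rec$epochs[[1]], cfg)
  # CW + CCW full 360 sweeps at 40 deg/s: every axial bin gets 2 x 0.5 s
  expect_equal(b$exposure, rep(1, 18))
  # partial sweep against a numeric dwell-time oracle
  rot <- polarizer_rotation(0, "CCW", 100, 40, 250)
  got <- polspike:::rotation_exposure(rot, cfg)
  dt <- 1e-4
  tt <- seq(0, 250 / 40 - dt, by = dt) + dt / 2
  idx <- pmin(floor((angle_at(rot, tt) %% 180) / 10) + 1L, 18L)
  expect_equal(got, tabulate(idx, 18) * dt, tolerance = 1e-3)
  expect_equal(sum(got), 250 / 40, tolerance = 1e-9)
})

test_that("an epoch lacking one rotation direction is a protocol error", {
  rot <- polarizer_rotation(10.5, "CW", 0, 40, 360)
  ep <- stimulus_epoch(10, 29, 0.99, list(rot))
  rec <- recording(spike_train("n1", "TL2", c(11, 12), 60), list(ep))
  expect_error(bin_response(rec, ep, cfg), class = "polspike_protocol_error")
})

test_that("binned counts match rate x exposure for a constant-rate neuron", {
  m <- flat_model(20)
  p <- short_protocol()
  tot <- rep(0, 18)
  for (s in 1:500) {
    rec <- simulate_recording(m, p, s)
    tot <- tot + bin_response(rec, rec$epochs[[1]], cfg)$counts
  }
  # each bin: 20 sp/s x 1.0 s exposure = 20 expected, pooled over CW + CCW
  se <- sqrt(20 / 500)
  expect_true(all(abs(tot / 500 - 20) < 3.5 * se))
})

test_that("response amplitude A matches hand and brute-force computations", {
  expect_equal(response_amplitude(rep(5, 18)), 0)
  counts <- c(10, rep(0, 17))
  expect_equal(response_amplitude(counts),
               (10 - 10 / 18) + 17 * (10 / 18), tolerance = 1e-12)
  expect_equal(response_amplitude(counts), 18.888888888889, tolerance = 1e-9)
  centers2 <- seq(10, 350, by = 20)
  cosy <- round(10 + 8 * cos(centers2 * pi / 180))
  expect_equal(response_amplitude(cosy), oracle_amplitude(cosy),
               tolerance = 1e-12)
})

test_that("A is computed per rotation and averaged across rotations", {
  m <- rbind(c(10, rep(0, 17)), rep(5, 18))
  expect_equal(response_amplitude(m),
               (oracle_amplitude(m[1, ]) + oracle_amplitude(m[2, ])) / 2)
})

test_that("A is shift-invariant and scales linearly with the counts", {
  withr::local_seed(31)
  for (i in 1:20) {
    n <- rpois(18, 6)
    A <- response_amplitude(n)
    k <- sample(1:17, 1)
    expect_equal(response_amplitude(c(n[-(1:k)], n[1:k])), A, tolerance = 1e-12)
    expect_equal(response_amplitude(3 * n), 3 * A, tolerance = 1e-12)
  }
})

test_that("background activity summarises 1 s bins with interpolated percentiles", {
  # exactly 10 spikes in each of the five pre-stimulus seconds
  spikes <- sort(c(5 + (0:49) / 10, 20))
  rec <- tiny_recording(spikes)
  ba <- background_activity(rec, rec$epochs[[1]], cfg)
  expect_equal(ba$median, 10)
  expect_equal(ba$p2_5, 10)
  expect_equal(ba$p97_5, 10)
  expect_false(ba$truncated)

  # bins holding 2, 4, 6, 8, 10 spikes -> median rate 6 sp/s
  spikes <- sort(unlist(lapply(1:5, function(k)
    5 + (k - 1) + seq(0.05, 0.95, length.out = c(2, 4, 6, 8, 10)[k]))))
  rec <- tiny_recording(spikes)
  ba <- background_activity(rec, rec$epochs[[1]], cfg)
  expect_equal(ba$median, 6)

  # silent pre-window: all-zero rates, not missing
  rec0 <- tiny_recording(numeric(0))
  ba0 <- background_activity(rec0, rec0$epochs[[1]], cfg)
  expect_equal(ba0$median, 0)
  expect_false(ba0$missing)
})

test_that("a short pre-stimulus gap truncates the background window and flags it", {
  st <- spike_train("n", "TB1", c(31, 40), 200)
  mk <- function(on) stimulus_epoch(on, on + 19, 0.5, list(
    polarizer_rotation(on + 0.5, "CW", 0, 40, 360),
    polarizer_rotation(on + 9.5, "CCW", 0, 40, 360)))
  rec <- recording(st, list(mk(10), mk(32)))   # 3 s gap before epoch 2
  ba <- background_activity(rec, rec$epochs[[2]], cfg)
  expect_equal(ba$n_bins, 3L)
  expect_true(ba$truncated)
  tr <- analyze_response(rec, rec$epochs[[2]], cfg)
  expect_true("truncated_background" %in% tr$flags)
})

test_that("responses with too few spikes are flagged untestable, not tested", {
  rec <- tiny_recording(c(11, 12, 13))
  tr <- analyze_response(rec, rec$epochs[[1]], cfg)
  expect_true("untestable" %in% tr$flags)
  expect_true(is.na(tr$p))
  expect_false(tr$significant)
})

test_that("analyze_response recovers the planted preferred angle at strong modulation", {
  m <- tuned_model(phi = 115)
  rec <- simulate_recording(m, short_protocol(0.99), 7, cell_type = "TL2")
  tr <- analyze_response(rec, rec$epochs[[1]], cfg)
  d <- abs(tr$phi_max - 115) %% 180
  expect_lt(min(d, 180 - d), 10)
  expect_true(tr$significant)
  expect_equal(tr$phi_min, (tr$phi_max + 90) %% 180)
  # the fitted rate at phi_max exceeds the rate at phi_min
  expect_gt(tr$rate_phi_max, tr$rate_phi_min)
})

test_that("phi_max is invariant when every spike angle gains 180 degrees", {
  withr::local_seed(77)
  ang <- runif(200) * 180
  a1 <- axial_mean(ang)
  a2 <- axial_mean((ang + 180) %% 360)
  expect_equal(a1$phi_max, a2$phi_max, tolerance = 1e-9)
  expect_equal(a1$r, a2$r, tolerance = 1e-12)
})

test_that("CW-only and CCW-only angle estimates agree without response latency", {
  m <- tuned_model(phi = 50)
  diffs <- vapply(1:20, function(s) {
    rec <- simulate_recording(m, short_protocol(0.99), s)
    ep <- rec$epochs[[1]]
    est <- vapply(ep$rotations, function(rot) {
      tend <- rot$t_start + rotation_duration(rot)
      spk <- rec$spike_train$spike_times
      spk <- spk[spk >= rot$t_start & spk <= tend]
      axial_mean(angle_at(rot, spk) %% 180)$phi_max
    }, 0)
    d <- abs(est[1] - est[2]) %% 180
    min(d, 180 - d)
  }, 0)
  expect_lt(median(diffs), 15)
})

test_that("detection power grows monotonically with modulation depth", {
  p <- short_protocol(0.99)
  power <- vapply(c(0, 2, 5, 10, 15), function(M) {
    hits <- 0
    for (s in 1:400) {
      m <- neuron_model(20, 60, "linear", c(m0 = M / 0.99))
      rec <- simulate_recording(m, p, 7000 + s)
      b <- bin_response(rec, rec$epochs[[1]], cfg)
      pv <- circ_linear_corr(b$counts, b$bin_centers_doubled)$p
      hits <- hits + (pv < cfg$alpha)
    }
    hits / 400
  }, 0)
  # strictly increasing until the test saturates near power 1
  expect_true(all(diff(power) > 0 | pmin(power[-1], power[-5]) > 0.99))
  expect_lt(power[1], 0.1)
  expect_gt(power[5], 0.9)
})

test_that("normalized extremes divide fitted rates by the background median", {
  tr <- list(background = list(median = 20, missing = FALSE),
             rate_phi_max = 30, rate_phi_min = 0)
  ne <- normalized_extremes(tr)
  expect_equal(ne$act_max, 1.5)
  expect_equal(ne$act_min, 0)
  tr$background$median <- 0
  ne0 <- normalized_extremes(tr)
  expect_true(is.na(ne0$act_max))
  expect_match(attr(ne0, "reason"), "zero or missing")
})

test_that("no-stimulus controls match the analytic null resultant length", {
  m <- flat_model(20)
  p <- protocol_spec(dop_ladder = 0.99, inter_epoch_gap = 25)
  rs <- ns <- numeric(1000)
  for (s in 1:1000) {
    rec <- simulate_recording(m, p, s)
    ctl <- no_stimulus_control(rec, rec$epochs[[1]], cfg)
    rs[s] <- ctl$r; ns[s] <- ctl$n
  }
  # E[r] under uniformity is sqrt(pi) / (2 sqrt(n)) for large n
  expected <- mean(sqrt(pi) / (2 * sqrt(ns)))
  expect_lt(abs(mean(rs) - expected) / expected, 0.05)
})

test_that("controls are skipped for silent windows or cramped sessions", {
  rec <- tiny_recording(numeric(0), t_on = 30)
  ctl0 <- no_stimulus_control(rec, rec$epochs[[1]], cfg)
  expect_s3_class(ctl0, "control_skipped")
  expect_match(ctl0$reason, "silent")
  # epoch too close to session start for a sham window
  rot1 <- polarizer_rotation(5.5, "CW", 0, 40, 360)
  rot2 <- polarizer_rotation(14.5, "CCW", 0, 40, 360)
  ep <- stimulus_epoch(5, 24, 0.99, list(rot1, rot2))
  rec2 <- recording(spike_train("n", "TL2", c(1, 2, 3), 60), list(ep))
  ctl <- no_stimulus_control(rec2, ep, cfg)
  expect_s3_class(ctl, "control_skipped")
  expect_match(ctl$reason, "window")
})

test_that("a rhythmic background inflates the control resultant above the null", {
  # slow ~1 Hz burst rhythm, incommensurate with the 9 s rotation window
  base <- 20; amp <- 18; freq <- 0.9
  p <- protocol_spec(dop_ladder = 0.99, inter_epoch_gap = 25)
  built <- build_epochs(p)
  dur <- built$session_duration
  gen <- function(s) {
    with_seed <- polspike:::with_seed
    with_seed(s, {
      n <- rpois(1, (base + amp) * dur)
      cand <- sort(runif(n, 0, dur))
      lam <- base + amp * sin(2 * pi * freq * cand)
      cand[runif(n) < pmax(lam, 0) / (base + amp)]
    })
  }
  r_rhythm <- r_flat <- numeric(200)
  for (s in 1:200) {
    spk <- gen(s)
    rec <- recording(spike_train("n", "OTHER", spk, dur), built$epochs)
    r_rhythm[s] <- no_stimulus_control(rec, rec$epochs[[1]], cfg)$r
    flat <- simulate_recording(flat_model(base), p, s)
    r_flat[s] <- no_stimulus_control(flat, flat$epochs[[1]], cfg)$r
  }
  expect_gt(mean(r_rhythm), mean(r_flat))
})
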