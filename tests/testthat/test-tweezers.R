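test_that("pulse windows land at exact arithmetic positions", {
  g <- generate_bead_trace(trace_phantom_spec(noise_sd = 0, seed = 1))
  win <- segment_pulses(g$trace, pulse_regime(), onset_s = 5)
  expect_equal(nrow(win), 12L)
  t <- g$trace$time_s
  starts <- t[win[, 1]]
  expect_equal(starts, 5 + (0:11) * 7, tolerance = 1e-9)
  # on-phase length: 3 s at 50 Hz
  expect_true(all(win[, 2] - win[, 1] + 1 == 150))
})

test_that("short traces and under-sampled regimes are rejected", {
  g <- generate_bead_trace(trace_phantom_spec(noise_sd = 0))
  short <- bead_trace(g$trace$time_s[1:1500], g$trace$displacement_nm[1:1500])
  expect_error(segment_pulses(short, pulse_regime(), onset_s = 5),
               "too short")
  slow <- bead_trace(seq(0, 100, by = 2), rep(0, 51))
  expect_error(segment_pulses(slow, pulse_regime()), "sample rate too low")
})

test_that("onset estimation on a noiseless phantom is within one sample", {
  g <- generate_bead_trace(trace_phantom_spec(noise_sd = 0, drift_nm_s = 0.5,
                                              seed = 2))
  tr <- bead_trace(g$trace$time_s, g$trace$displacement_nm)  # onset unknown
  win <- segment_pulses(tr, pulse_regime())
  expect_lt(abs(attr(win, "onset_s") - 5), 1 / 50 + 1e-9)
})

test_that("amplitudes recover the programmed schedule", {
  sched <- seq(100, 75, length.out = 12)
  g <- generate_bead_trace(trace_phantom_spec(amplitudes = sched,
                                              noise_sd = 0, drift_nm_s = 0,
                                              seed = 3))
  pm <- pulse_amplitudes(g$trace, segment_pulses(g$trace, onset_s = 5))
  expect_equal(pm$amplitude_nm, g$truth$amplitudes_nm, tolerance = 1e-9)
  expect_lt(max(abs(pm$amplitude_nm - sched)), 2)
  expect_equal(pm$relative[1], 1)

  flat <- bead_trace(seq(0, 90, by = 0.02), rep(3, 4501))
  pmf <- pulse_amplitudes(flat, segment_pulses(flat, onset_s = 5))
  expect_true(all(pmf$amplitude_nm == 0))
})

test_that("drift-only traces are flagged as no initial response", {
  t <- seq(0, 90, by = 0.02)
  drifty <- bead_trace(t, 1.0 * t)            # 1 nm/s, no pulses
  pm <- pulse_amplitudes(drifty, segment_pulses(drifty, onset_s = 5))
  # amplitude ~ slope x 3 s on-phase for every pulse
  expect_equal(unname(pm$amplitude_nm), rep(3, 12) - 0.02, tolerance = 0.05)
  expect_error(mechanosensing_metric(pm, noise_threshold_nm = 10),
               "no initial response")
})

test_that("the stiffening statistic applies the inclusion filter exactly", {
  # constant amplitudes: r12 = 1, decrease 0, excluded
  g <- generate_bead_trace(trace_phantom_spec(amplitudes = 100,
                                              noise_sd = 0, drift_nm_s = 0))
  m <- mechanosensing_metric(
    pulse_amplitudes(g$trace, segment_pulses(g$trace, onset_s = 5)),
    noise_threshold_nm = 0)
  expect_equal(m$r12, 1, tolerance = 1e-9)
  expect_equal(m$decrease_pct, 0, tolerance = 1e-7)
  expect_false(m$included)

  # 25% decay: included
  g2 <- generate_bead_trace(trace_phantom_spec(
    amplitudes = seq(100, 75, length.out = 12), noise_sd = 0, drift_nm_s = 0))
  m2 <- mechanosensing_metric(
    pulse_amplitudes(g2$trace, segment_pulses(g2$trace, onset_s = 5)),
    noise_threshold_nm = 0)
  expect_equal(m2$decrease_pct, 25, tolerance = 0.2)
  expect_true(m2$included)

  # growing response (A12 > A1): excluded
  g3 <- generate_bead_trace(trace_phantom_spec(
    amplitudes = seq(100, 110, length.out = 12), noise_sd = 0,
    drift_nm_s = 0))
  m3 <- mechanosensing_metric(
    pulse_amplitudes(g3$trace, segment_pulses(g3$trace, onset_s = 5)),
    noise_threshold_nm = 0)
  expect_false(m3$included)
  expect_equal(m3$reason, "A12 >= A1")
})

test_that("the statistic is scale- and offset-invariant", {
  g <- generate_bead_trace(trace_phantom_spec(
    amplitudes = seq(100, 75, length.out = 12), noise_sd = 1, seed = 9))
  base <- mechanosensing_metric(
    pulse_amplitudes(g$trace, segment_pulses(g$trace, onset_s = 5)))
  for (f in c(0.5, 3)) {
    tr <- bead_trace(g$trace$time_s, f * g$trace$displacement_nm, onset_s = 5)
    m <- mechanosensing_metric(pulse_amplitudes(tr, segment_pulses(tr)))
    expect_equal(m$r12, base$r12, tolerance = 1e-9)
  }
  tro <- bead_trace(g$trace$time_s, g$trace$displacement_nm + 500,
                    onset_s = 5)
  mo <- mechanosensing_metric(pulse_amplitudes(tro, segment_pulses(tro)))
  expect_equal(mo$r12, base$r12, tolerance = 1e-9)
})
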