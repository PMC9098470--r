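test_that("regular pulse waveform has one pulse of width delta per period", {
  # DBS defaults: one 0.1 ms pulse within each 1000/150 ms period
  tt <- seq(0, 1000 / 150, by = 0.01)
  w <- pulseWaveform(tt, A = 100, f = 150, delta = 0.1)
  expect_true(all(w %in% c(0, 100)))
  on <- tt[w > 0]
  expect_equal(length(on), 10)          # 0.1 ms at 0.01 ms sampling
  expect_lt(max(on) - min(on), 0.1)
  # sensorimotor defaults: 5 ms pulses, 50 ms period
  tt <- seq(0, 200, by = 0.01)
  w <- pulseWaveform(tt, A = 4.5, f = 20, delta = 5)
  runs <- rle(w > 0)
  expect_equal(sum(runs$values), 4)     # four pulses in 200 ms
  expect_equal(max(runs$lengths[runs$values]), 500)  # 5 ms wide
  expect_equal(pulseWaveform(tt, A = 0, f = 20, delta = 5), rep(0, length(tt)))
})

test_that("pulse-train integral over whole periods equals k A delta", {
  dt <- 1e-3
  tt <- seq(0, 5 * 50 - dt, by = dt)   # 5 periods at 20 Hz
  w <- pulseWaveform(tt, A = 4.5, f = 20, delta = 5)
  expect_equal(sum(w) * dt, 5 * 4.5 * 5, tolerance = 1e-6)
})

test_that("Poisson pulse trains are seeded, counted and duty-matched", {
  pt <- poissonPulseTimes(150, 0.1, 10000, seed = 5)
  expect_identical(pt$onsets, poissonPulseTimes(150, 0.1, 10000, 5)$onsets)
  expect_true(all(diff(pt$onsets) > 0))
  n <- length(pt$onsets)
  expect_lt(abs(n - 1500), 3 * sqrt(1500))
  # equal expected duty cycle as the regular train of the same rate
  reg <- regularPulseTimes(150, 0.1, 10000)
  expect_lt(abs(length(reg$onsets) - n) / n, 0.1)
  expect_warning(poissonPulseTimes(150, 10, 100, 1), "near-continuous")
})

test_that("protocols validate amplitude signs and dispatch by kind", {
  expect_error(stimulusProtocol("EDBS", amplitude = -10), "positive")
  expect_error(stimulusProtocol("IDBS", amplitude = 10), "negative")
  expect_error(stimulusProtocol("EDBS", frequency = 150, width = 10),
               "overlap")
  smc <- stimulusProtocol("SMC")
  expect_equal(smc$amplitude, 4.5)
  expect_equal(smc$frequency, 20)
  expect_equal(smc$width, 5)
  idbs <- stimulusProtocol("IDBS", amplitude = -147.36)
  tt <- seq(0, 20, by = 0.01)
  cur <- protocolCurrent(idbs, tt)
  expect_true(all(cur %in% c(0, -147.36)))
  expect_true(any(cur < 0))
  expect_equal(protocolCurrent(stimulusProtocol("none"), tt),
               rep(0, length(tt)))
  # active window gates the current off outside [t_on, t_off]
  gated <- stimulusProtocol("SMC", t_on = 100, t_off = 200)
  expect_equal(protocolCurrent(gated, c(50, 250)), c(0, 0))
})

test_that("Poisson protocol currents use realized onsets and merge overlaps", {
  pr <- stimulusProtocol("EDBS", amplitude = 10, pattern = "poisson")
  pt <- structure(list(onsets = c(5, 5.05, 30), delta = 0.1),
                  class = "pulse_times")
  cur <- protocolCurrent(pr, c(4.9, 5.02, 5.1, 5.2, 30.05, 31), pt)
  expect_equal(cur, c(0, 10, 10, 0, 10, 0))
  expect_error(protocolCurrent(pr, 1:10), "pulse_times")
})

test_that("grid sampling covers each pulse with at least one sample", {
  g <- bgdbs:::.protocol_grid(stimulusProtocol("EDBS", amplitude = 100),
                              nsteps = 20000, dt = 0.05)
  # 1000 ms at 150 Hz: 150 pulses, each covering 2-3 grid samples
  runs <- rle(g > 0)
  expect_equal(sum(runs$values), 150)
  expect_true(all(runs$lengths[runs$values] %in% 2:3))
  expect_error(
    bgdbs:::.protocol_grid(stimulusProtocol("EDBS", width = 0.1),
                           nsteps = 10, dt = 0.2),
    "shorter than the integration step")
})
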