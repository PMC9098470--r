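test_that("initial states are seeded, reproducible and self-consistent", {
  preset <- conditionPreset("healthy")
  a <- initialState(preset, seed = 7)
  b <- initialState(preset, seed = 7)
  c2 <- initialState(preset, seed = 8)
  expect_identical(a$y, b$y)
  expect_true(any(a$y != c2$y))
  n <- 20
  v <- a$y[1:n]
  expect_true(all(v >= -70 & v <= -50))
  # gates start exactly at their steady state for the drawn voltage
  p <- preset$STN
  expect_equal(a$y[n + 1:n], gatingSteadyState(v, p$theta_n, p$sigma_n),
               tolerance = 1e-12)
  expect_equal(a$y[2 * n + 1:n], gatingSteadyState(v, p$theta_h, p$sigma_h),
               tolerance = 1e-12)
  expect_true(all(a$y[5 * n + 1:n] == 0))  # synaptic gates at zero
})

test_that("spike detection applies threshold and refractory rules", {
  expect_equal(detectSpikes(rep(-60, 100), 1), numeric(0))
  # three crossings 20 ms apart on a synthetic trace
  v <- rep(-60, 61)
  v[c(11, 31, 51)] <- 0
  expect_equal(detectSpikes(v, 1), c(10, 30, 50))
  # two crossings 1 ms apart collapse under a 2 ms refractory
  v2 <- rep(-60, 20)
  v2[c(5, 7)] <- 0
  expect_equal(detectSpikes(v2, 0.5), 2)
  expect_equal(length(detectSpikes(v2, 0.5, refractory = 0.5)), 2)
})

test_that("an uncoupled healthy STN cell spikes tonically and reproducibly", {
  p <- neuronParameters("STN", "healthy")
  st <- c(-60, gatingSteadyState(-60, p$theta_n, p$sigma_n),
          gatingSteadyState(-60, p$theta_h, p$sigma_h),
          gatingSteadyState(-60, p$theta_r, p$sigma_r), 0.05)
  run <- function(dt) bgdbs:::.simulate_bg_cell_cpp(
    p, st, rep(p$I_app, round(1000 / dt)), dt, round(1000 / dt), -10, 2, 0)
  a <- run(0.05)
  b <- run(0.05)
  expect_identical(a$spikes, b$spikes)
  isi <- diff(a$spikes)
  expect_gt(length(a$spikes), 20)
  expect_lt(max(abs(diff(tail(isi, 10)))), 0.3)  # smooth slow adaptation
  # single-cell step-halving convergence: count changes by at most 1
  expect_lte(abs(length(run(0.025)$spikes) - length(a$spikes)), 1)
})

test_that("with all conductances and stimuli zero the voltage is constant", {
  preset <- conditionPreset("healthy")
  for (pop in c("STN", "GPe", "GPi", "Th"))
    for (g in grep("^g_", names(preset[[pop]]), value = TRUE))
      preset[[pop]][[g]] <- 0
  for (s in grep("^g_", names(preset$syn), value = TRUE)) preset$syn[[s]] <- 0
  preset$STN$I_app <- 0; preset$GPe$I_app <- 0; preset$GPi$I_app <- 0
  st <- initialState(preset, seed = 1)
  res <- simulateNetwork(preset, state = st, duration = 100, transient = 50)
  n <- 20
  vidx <- c(1:n, 6 * n + 1:n, 12 * n + 1:n, 18 * n + 1:n)
  expect_equal(res$final_state[vidx], st$y[vidx], tolerance = 1e-12)
})

test_that("network integration is deterministic and blow-ups are diagnosed", {
  preset <- conditionPreset("PD")
  a <- simulateNetwork(preset, seed = 4, duration = 400,
                       smc = stimulusProtocol("SMC"))
  b <- simulateNetwork(preset, seed = 4, duration = 400,
                       smc = stimulusProtocol("SMC"))
  expect_identical(a$raw_spikes, b$raw_spikes)
  expect_identical(a$final_state, b$final_state)
  # absurd stimulus drives the state non-finite -> diagnostic with time/index
  bad <- stimulusProtocol("EDBS", amplitude = 1e306, frequency = 150,
                          width = 3)
  expect_error(simulateNetwork(preset, seed = 4, duration = 20,
                               transient = 10, dbs = bad),
               "blow-up at t = .*STN neuron")
})

test_that("gating variables stay in the unit interval during network runs", {
  res <- simulateNetwork(conditionPreset("PD"), seed = 6, duration = 600,
                         smc = stimulusProtocol("SMC"))
  y <- res$final_state
  n <- 20
  gates <- c(n + 1:(3 * n), 6 * n + n + 1:(3 * n), 12 * n + n + 1:(3 * n),
             18 * n + n + 1:(2 * n))
  expect_true(checkGatingRange(y[gates]))
  s <- y[c(5 * n + 1:n, 11 * n + 1:n, 17 * n + 1:n)]
  expect_true(all(s >= 0 & s <= 1))
})

test_that("compiled RK4 agrees with the independent deSolve transcription", {
  preset <- conditionPreset("healthy")
  st <- initialState(preset, seed = 3)
  # tight pathwise agreement at fine step over a short horizon
  fine <- simulateNetwork(preset, state = st, duration = 20, transient = 10,
                          dt = 0.0125)
  ada <- simulateNetwork(preset, state = st, duration = 20, transient = 10,
                         dt = 0.0125, solver = "adaptive")
  expect_lt(median(abs(fine$final_state - ada$final_state)), 1e-3)
  expect_lt(mean(abs(fine$final_state - ada$final_state) > 0.1), 0.05)
  # production step: same vector field, spike-time error below one sample
  prod <- simulateNetwork(preset, state = st, duration = 20, transient = 10)
  expect_lt(median(abs(prod$final_state - ada$final_state)), 0.05)
})

test_that("trial ensembles are reproducible, order-invariant and parallel-safe", {
  sd1 <- trialSeeds(9, 5)
  expect_identical(sd1, trialSeeds(9, 5))
  expect_identical(sd1[1:3], trialSeeds(9, 3))
  expect_true(all(sd1 < 2^31))
  tr <- runTrials("PD", n_trials = 2, master_seed = 9, duration = 400,
                  smc = stimulusProtocol("SMC"))
  expect_length(tr, 2)
  expect_false(identical(tr[[1]]$raw_spikes, tr[[2]]$raw_spikes))
  tr2 <- runTrials("PD", n_trials = 2, master_seed = 9, duration = 400,
                   smc = stimulusProtocol("SMC"), cores = 2)
  expect_identical(lapply(tr, `[[`, "raw_spikes"),
                   lapply(tr2, `[[`, "raw_spikes"))
})

test_that("analysis rasters discard the transient and re-zero times", {
  res <- simulateNetwork(conditionPreset("PD"), seed = 5, duration = 700,
                         smc = stimulusProtocol("SMC"))
  expect_equal(res$rasters$STN$duration, 450)
  allt <- unlist(lapply(res$rasters, `[[`, "times"))
  expect_true(all(allt >= 0 & allt < 450))
  raw <- unlist(res$raw_spikes$STN)
  kept <- unlist(res$rasters$STN$times)
  expect_equal(sort(kept), sort(raw[raw >= 250 & raw < 700] - 250))
  # raster CSV round trip
  csv <- withr::local_tempfile(fileext = ".csv")
  writeRasterCsv(res, csv)
  back <- readRasterCsv(csv, n_neurons = 20, duration = 450,
                        population = "GPi")
  expect_equal(back$times, res$rasters$GPi$times)
})
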