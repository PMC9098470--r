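test_that("population rate counts per window and normalizes per neuron", {
  empty <- spikeRaster(rep(list(numeric(0)), 20), 20, 1000, "STN")
  pr0 <- populationRate(empty)
  expect_equal(length(pr0$values), 1000 - 10 + 1)
  expect_true(all(pr0$values == 0))
  # 20 neurons, one spike each inside one 10 ms window -> 100 sp/s there
  one <- spikeRaster(lapply(1:20, function(i) 105), 20, 1000, "STN")
  pr1 <- populationRate(one)
  expect_equal(max(pr1$values), 20 / (0.01 * 20))
  expect_equal(sum(pr1$values > 0), 10)  # the 10 windows covering t = 105
  # raw population mode drops the neuron normalization
  expect_equal(max(populationRate(one, per_neuron = FALSE)$values), 2000)
})

test_that("population rate of a Poisson raster converges to its rate", {
  ras <- poisson_raster(20, rate = 20, duration = 1e5, seed = 2)
  pr <- populationRate(ras)
  expect_lt(abs(mean(pr$values) - 20) / 20, 0.05)
})

test_that("Fano factor matches hand arithmetic and scales linearly", {
  expect_equal(fanoFactor(c(5, 5, 5, 5)), 0)
  # population variance of {10, 20} is 25; mean 15
  expect_equal(fanoFactor(c(10, 20)), 25 / 15)
  expect_equal(fanoFactor(c(10, 20), ddof = 1), 50 / 15)
  x <- c(3, 9, 4, 8)
  expect_equal(fanoFactor(3 * x), 3 * fanoFactor(x))
  expect_error(fanoFactor(c(0, 0)), "mean")
})

test_that("Welch spectra localize tones and flatten white noise", {
  t <- (0:2999) / 1000
  ps <- welchPSD(5 + sin(2 * pi * 20 * t))
  expect_equal(peakFrequency(ps), 20)
  expect_equal(ps$freq, 0:500)
  # white noise: flat density whose level matches its variance / bandwidth
  set.seed(3)
  x <- rnorm(60000, sd = 2)
  psw <- welchPSD(x)
  expect_lt(max(psw$power[-1]) / median(psw$power[-1]), 3)
  expect_equal(mean(psw$power[2:500]) * 500, 4, tolerance = 0.05)
  expect_error(welchPSD(rnorm(500)), "shorter")
  # averaging identical series equals the single-series PSD
  pr <- structure(list(values = x[1:2000]), class = "rate_series")
  expect_equal(meanPSD(list(pr, pr, pr))$power, welchPSD(pr$values)$power)
})

test_that("oscillation index integrates band fractions on the Welch grid", {
  f <- 0:500
  flat <- structure(list(freq = f, power = rep(1, 501)),
                    class = "spectrum_result")
  expect_equal(oscillationIndex(flat), 17 / 499, tolerance = 1e-12)
  inband <- structure(list(freq = f, power = as.numeric(f >= 14 & f <= 29)),
                      class = "spectrum_result")
  expect_gt(oscillationIndex(inband), 0.95)
  high <- structure(list(freq = f, power = as.numeric(f > 100)),
                    class = "spectrum_result")
  expect_lt(oscillationIndex(high), 0.01)
  # invariant to rescaling; always within [0, 1]
  set.seed(4)
  for (k in 1:20) {
    p <- runif(501)
    s <- structure(list(freq = f, power = p), class = "spectrum_result")
    oi <- oscillationIndex(s)
    expect_true(oi >= 0 && oi <= 1)
    s$power <- 100 * p
    expect_equal(oscillationIndex(s), oi)
  }
  expect_error(oscillationIndex(structure(
    list(freq = f, power = rep(0, 501)), class = "spectrum_result")), "zero")
})

test_that("thalamic response classification matches a crafted raster", {
  onsets <- seq(20, 470, 50)  # 10 pulses, window 25 ms
  ras <- perfect_relay_raster()
  ok <- classifyThalamicResponses(ras, onsets)
  expect_equal(ok$N_exp, 200)
  expect_equal(c(ok$N_M, ok$N_E, ok$N_U), c(0L, 0L, 0L))
  expect_equal(thalamicFidelity(ok), 1)

  # craft 10 misses, 5 double responses, 5 out-of-window spikes
  times <- ras$times
  for (i in 1:10) times[[i]] <- times[[i]][-i]           # miss pulse i
  for (i in 11:15) times[[i]] <- sort(c(times[[i]], onsets[i - 10] + 10))
  for (i in 16:20) times[[i]] <- sort(c(times[[i]], onsets[i - 15] + 30))
  crafted <- spikeRaster(times, 20, 500, "Th")
  cc <- classifyThalamicResponses(crafted, onsets)
  expect_equal(c(cc$N_M, cc$N_E, cc$N_U), c(10L, 5L, 5L))
  expect_equal(thalamicFidelity(cc), 1 - 20 / 200)
  # spike conservation: correct + extras + undesired = total spikes
  expect_equal(cc$N_correct + cc$N_E + cc$N_U, sum(lengths(crafted$times)))

  # an empty raster misses everything; fidelity 0
  none <- spikeRaster(rep(list(numeric(0)), 20), 20, 500, "Th")
  cn <- classifyThalamicResponses(none, onsets)
  expect_equal(cn$N_M, cn$N_exp)
  expect_equal(thalamicFidelity(cn), 0)

  expect_error(classifyThalamicResponses(ras, onsets, window = 60),
               "overlap")
})

test_that("burst detection follows the ISI-run rule and is shift-invariant", {
  iso <- spikeRaster(list(seq(0, 900, 100)), 1, 1000, "GPi")
  expect_equal(burstProfile(iso)$n_bursts, 0)
  tr <- spikeRaster(list(c(0, 5, 10, 200, 204, 208, 212)), 1, 1000, "GPi")
  bp <- burstProfile(tr)
  expect_equal(bp$n_bursts, 2)
  expect_equal(bp$durations[[1]], c(10, 12))
  expect_equal(bp$sizes[[1]], c(3L, 4L))
  expect_equal(bp$mean_duration, 11)
  expect_equal(bp$mean_size, 3.5)
  expect_equal(bp$rate, 2)
  shifted <- spikeRaster(list(c(0, 5, 10, 200, 204, 208, 212) + 300), 1,
                         1000, "GPi")
  bs <- burstProfile(shifted)
  expect_equal(bs$durations, bp$durations)
  expect_equal(bs$sizes, bp$sizes)
})

test_that("mean and resting rates are plain spike counts over time", {
  ras <- spikeRaster(rep(list(c(100, 600)), 20), 20, 1000, "Th")
  expect_equal(meanFiringRate(ras), 2)
  expect_equal(excessiveThalamicActivity(ras), 2)
  empty <- spikeRaster(rep(list(numeric(0)), 20), 20, 1000, "Th")
  expect_equal(excessiveThalamicActivity(empty), 0)
})

test_that("amplitude spectrograms stack per-amplitude mean spectra", {
  set.seed(5)
  mk <- function() structure(list(values = rnorm(1200) + 10),
                             class = "rate_series")
  sweep <- list(`10` = list(mk(), mk()), `20` = list(mk(), mk()))
  sweep$`20` <- sweep$`10`  # duplicated amplitude -> identical rows
  sp <- amplitudeSpectrogram(sweep)
  expect_equal(dim(sp$power), c(2, 501))
  expect_equal(sp$power[1, ], sp$power[2, ])
  expect_error(amplitudeSpectrogram(sweep[1]), "two amplitudes")
})
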