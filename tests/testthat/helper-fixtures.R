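# Raster fixtures built in code.

# every neuron responds once, `window_offset` ms after each pulse
perfect_relay_raster <- function(n_neurons = 20, onsets = seq(20, 470, 50),
                                 offset = 5, duration = 500) {
  spikeRaster(rep(list(onsets + offset), n_neurons), n_neurons, duration,
              "Th")
}

# homogeneous Poisson raster at `rate` Hz per neuron
poisson_raster <- function(n_neurons, rate, duration, seed) {
  set.seed(seed)
  times <- lapply(seq_len(n_neurons), function(i) {
    k <- rpois(1, rate * duration / 1000)
    sort(runif(k, 0, duration))
  })
  spikeRaster(times, n_neurons, duration, "poisson")
}
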