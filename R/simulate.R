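#' Seeded initial network state
#'
#' Membrane potentials are drawn uniformly from \[-70, -50\] mV per neuron;
#' every gating variable starts at its steady state for the drawn voltage,
#' intracellular calcium at `ca0`, synaptic gates at 0. The model definition
#' leaves initial conditions open; this seeded distribution is the source of
#' across-trial variability.
#'
#' @param preset A `condition_preset`.
#' @param n Neurons per population.
#' @param seed Integer seed; identical seeds give identical states.
#' @param ca0 Initial calcium concentration (arbitrary units).
#' @return Object of class `network_state`: named list of per-population
#'   state vectors plus the flat vector `y` in integrator layout.
#' @export
initialState <- function(preset, n = 20, seed = 1, ca0 = 0.05) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v <- lapply(stats::setNames(POPULATIONS, POPULATIONS),
              function(p) runif(n, -70, -50))
  bg_block <- function(pop) {
    p <- preset[[pop]]
    vv <- v[[pop]]
    c(vv,
      gatingSteadyState(vv, p$theta_n, p$sigma_n),
      gatingSteadyState(vv, p$theta_h, p$sigma_h),
      gatingSteadyState(vv, p$theta_r, p$sigma_r),
      rep(ca0, n),
      rep(0, n))
  }
  vth <- v$Th
  th_block <- c(vth,
                1 / (1 + exp((vth + 41) / 4)),   # h_inf
                1 / (1 + exp((vth + 84) / 4)))   # r_inf
  y <- c(bg_block("STN"), bg_block("GPe"), bg_block("GPi"), th_block)
  structure(list(y = y, n = n, seed = seed, condition = preset$condition),
            class = "network_state")
}

#' Spike raster
#'
#' Container for per-neuron sorted spike times of one population over one
#' analysis window. Times live in `[0, duration)`.
#'
#' @param times List of numeric vectors (one per neuron), each sorted.
#' @param n_neurons Number of neurons.
#' @param duration Window length (ms).
#' @param population Population label.
#' @return Object of class `spike_raster`.
#' @export
spikeRaster <- function(times, n_neurons = length(times), duration,
                        population = "raster") {
  stopifnot(length(times) == n_neurons)
  times <- lapply(times, function(x) sort(as.numeric(x)))
  if (n_neurons > 0) {
    allt <- unlist(times)
    if (length(allt) && (min(allt) < 0 || max(allt) >= duration))
      stop("spike times must lie in [0, duration)", call. = FALSE)
  }
  structure(list(times = times, n_neurons = n_neurons, duration = duration,
                 population = population), class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  ns <- lengths(x$times)
  cat(sprintf("<spike_raster> %s: %d neurons, %.0f ms, %d spikes (mean rate %.2f sp/s)\n",
              x$population, x$n_neurons, x$duration, sum(ns),
              meanFiringRate(x)))
  invisible(x)
}

#' Threshold spike detection on a sampled voltage trace
#'
#' Upward crossings of `threshold` separated by at least `refractory` ms; the
#' spike time is the time of the crossing sample.
#'
#' @param v Voltage trace (mV), uniformly sampled.
#' @param times Sample times (ms), same length as `v`, or the sampling step
#'   as a single number.
#' @param threshold Crossing threshold (mV).
#' @param refractory Minimum separation between detected spikes (ms).
#' @return Sorted spike times (ms).
#' @export
detectSpikes <- function(v, times, threshold = -10, refractory = 2) {
  if (length(times) == 1) times <- (seq_along(v) - 1) * times
  stopifnot(length(times) == length(v))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  out <- numeric(0)
  last <- -Inf
  for (k in up) {
    if (times[k] - last >= refractory) {
      out <- c(out, times[k])
      last <- times[k]
    }
  }
  out
}

#' Integrate the full network over time
#'
#' Advances the coupled system (4 populations x `n` cells plus synaptic
#' gates) with the fixed-step RK4 integrator at `dt` (default 0.05 ms), the
#' compiled production path. `solver = "adaptive"` instead integrates an R
#' transcription of the same vector field with deSolve's lsoda as an
#' independent cross-check (slow; use short durations). Spikes are detected
#' during integration (threshold -10 mV, 2 ms refractory); the first
#' `transient` ms are discarded from all analysis-facing rasters, whose times
#' are re-zeroed at the transient boundary.
#'
#' @param preset A `condition_preset`.
#' @param state A `network_state` from [initialState()], or a seed via `seed`.
#' @param duration Total simulated time (ms), including the transient.
#' @param dt Integration step (ms).
#' @param transient Discarded initial span (ms).
#' @param dbs,smc `stimulus_protocol` objects (or `NULL`): DBS current added
#'   to every STN neuron, sensorimotor pulses to every thalamic neuron.
#' @param connectivity A `connectivity_map`; defaults to the ring wiring.
#' @param n Neurons per population (used when `state` is not given).
#' @param seed Seed for [initialState()] and the Poisson pattern, if any.
#' @param solver `"rk4"` (compiled, default) or `"adaptive"` (deSolve lsoda).
#' @param record `"spikes"` (default), `"voltage"` (adds 1 ms-decimated
#'   voltage traces) or `"currents"` (adds T-current and pallido-thalamic
#'   current traces).
#' @param record_step Decimation step (ms) for recorded traces.
#' @return Object of class `simulation_result`: `rasters` (list of
#'   `spike_raster` per population, post-transient, re-zeroed),
#'   `raw_spikes` (absolute times), `duration`, `transient`, `seed`, echo of
#'   the run configuration, and optional `time`/`v`/`currents` traces.
#' @export
simulateNetwork <- function(preset, state = NULL, duration = 1250, dt = 0.05,
                            transient = 250, dbs = NULL, smc = NULL,
                            connectivity = NULL, n = 20, seed = 1,
                            solver = c("rk4", "adaptive"),
                            record = "spikes", record_step = 1) {
  solver <- match.arg(solver)
  stopifnot(inherits(preset, "condition_preset"))
  if (duration <= transient)
    stop("duration must exceed the transient", call. = FALSE)
  if (is.null(state)) state <- initialState(preset, n = n, seed = seed)
  n <- state$n
  if (is.null(connectivity)) connectivity <- buildConnectivity(n)
  if (connectivity$n != n) stop("connectivity size mismatch", call. = FALSE)
  for (prot in list(dbs, smc))
    if (!is.null(prot) && prot$kind != "none" && prot$width < dt)
      stop("pulse width shorter than the integration step", call. = FALSE)

  nsteps <- round(duration / dt)
  i_dbs <- .protocol_grid(dbs, nsteps, dt, seed = seed)
  i_smc <- .protocol_grid(smc, nsteps, dt, seed = seed + 1L)
  aff <- .afferents(connectivity)
  record <- match.arg(record, c("spikes", "voltage", "currents"))
  rec_every <- if (record == "spikes") 0L else as.integer(round(record_step / dt))

  if (solver == "rk4") {
    res <- .simulate_network_cpp(preset$STN, preset$GPe, preset$GPi,
                                 preset$Th, preset$syn, aff, state$y, i_dbs,
                                 i_smc, dt, nsteps, -10, 2, rec_every,
                                 record == "currents")
  } else {
    res <- .simulate_network_lsoda(preset, aff, state$y, i_dbs, i_smc, dt,
                                   nsteps, rec_every)
  }

  rasters <- lapply(stats::setNames(POPULATIONS, POPULATIONS), function(pop) {
    tms <- lapply(res$spikes[[pop]],
                  function(x) x[x >= transient & x < duration] - transient)
    spikeRaster(tms, n, duration - transient, pop)
  })
  out <- list(rasters = rasters, raw_spikes = res$spikes, duration = duration,
              transient = transient, dt = dt, seed = state$seed, n = n,
              condition = preset$condition, solver = solver,
              dbs = dbs, smc = smc, final_state = res$state)
  if (!is.null(res$time)) {
    out$time <- res$time
    out$v <- res$v
    out$currents <- res$currents
  }
  class(out) <- "simulation_result"
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s, %d neurons/pop, %.0f ms (%.0f ms transient), %s\n",
              x$condition, x$n, x$duration, x$transient, x$solver))
  for (pop in POPULATIONS)
    cat(sprintf("  %-4s %6.2f sp/s\n", pop, meanFiringRate(x$rasters[[pop]])))
  invisible(x)
}

# R transcription of the network vector field, integrated with deSolve lsoda
# on the same stimulus grid. Cross-check route only.
.simulate_network_lsoda <- function(preset, aff, y0, i_dbs, i_smc, dt,
                                    nsteps, rec_every) {
  n <- length(aff$gpe_stn)
  rhs <- function(t, y, parms) {
    k <- min(max(floor(t / dt) + 1, 1), nsteps)
    list(.network_rhs_r(y, n, preset, aff, i_dbs[k], i_smc[k]))
  }
  times <- seq(0, nsteps * dt, by = dt)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-8)
  tt <- sol[, 1]
  Y <- sol[, -1, drop = FALSE]
  vidx <- c(1:n, 6 * n + 1:n, 12 * n + 1:n, 18 * n + 1:n)
  spikes <- lapply(stats::setNames(seq_len(4), POPULATIONS), function(pp) {
    lapply(seq_len(n), function(i)
      detectSpikes(Y[, vidx[(pp - 1) * n + i]], tt))
  })
  out <- list(spikes = spikes, state = Y[nrow(Y), ])
  if (rec_every > 0) {
    sel <- seq(1, nrow(Y), by = rec_every)
    out$time <- tt[sel]
    out$v <- lapply(stats::setNames(seq_len(4), POPULATIONS), function(pp)
      Y[sel, vidx[(pp - 1) * n + 1:n], drop = FALSE])
  }
  out
}

# Full network right-hand side in R (literal, vectorized over neurons).
.network_rhs_r <- function(y, n, preset, aff, idbs, ismc) {
  ix <- function(base, block) base + (block - 1) * n + 1:n
  dy <- numeric(length(y))
  sb <- list(STN = 0L, GPe = 6L * n, GPi = 12L * n)
  s_stn <- y[ix(0, 6)]; s_gpe <- y[ix(6 * n, 6)]; s_gpi <- y[ix(12 * n, 6)]
  syn <- preset$syn
  v_stn <- y[ix(0, 1)]; v_gpe <- y[ix(6 * n, 1)]; v_gpi <- y[ix(12 * n, 1)]
  v_th <- y[18 * n + 1:n]

  isyn <- list(
    STN = syn$g_gpe_stn * (v_stn - syn$E_gpe_stn) *
      (s_gpe[aff$stn_gpe1 + 1] + s_gpe[aff$stn_gpe2 + 1]),
    GPe = syn$g_stn_gpe * (v_gpe - syn$E_stn_gpe) * s_stn[aff$gpe_stn + 1] +
      syn$g_gpe_gpe * (v_gpe - syn$E_gpe_gpe) *
        (s_gpe[aff$gpe_gpe1 + 1] + s_gpe[aff$gpe_gpe2 + 1]),
    GPi = syn$g_stn_gpi * (v_gpi - syn$E_stn_gpi) * s_stn[aff$gpi_stn + 1] +
      syn$g_gpe_gpi * (v_gpi - syn$E_gpe_gpi) *
        (s_gpe[aff$gpi_gpe1 + 1] + s_gpe[aff$gpi_gpe2 + 1]))

  for (pop in c("STN", "GPe", "GPi")) {
    p <- preset[[pop]]
    b <- sb[[pop]]
    v <- y[ix(b, 1)]; nn <- y[ix(b, 2)]; h <- y[ix(b, 3)]
    r <- y[ix(b, 4)]; ca <- y[ix(b, 5)]; s <- y[ix(b, 6)]
    minf <- gatingSteadyState(v, p$theta_m, p$sigma_m)
    ainf <- gatingSteadyState(v, p$theta_a, p$sigma_a)
    sinf <- gatingSteadyState(v, p$theta_s, p$sigma_s)
    IL <- p$g_L * (v - p$E_L)
    INa <- p$g_Na * minf^3 * h * (v - p$E_Na)
    IK <- p$g_K * nn^4 * (v - p$E_K)
    ICa <- p$g_Ca * sinf^2 * (v - p$E_Ca)
    tg <- if (isTRUE(p$use_b))
      bSteadyState(r, p$theta_b, p$sigma_b, p$b_form %||% "normalized")^2
    else r
    IT <- p$g_T * ainf^3 * tg * (v - p$E_Ca)
    IAHP <- p$g_AHP * (v - p$E_K) * ca / (ca + p$k1)
    iapp <- p$I_app + if (pop == "STN") idbs else 0
    dy[ix(b, 1)] <- (-IL - INa - IK - ICa - IT - IAHP - isyn[[pop]] + iapp) /
      p$C_m
    dy[ix(b, 2)] <- p$phi_n * (gatingSteadyState(v, p$theta_n, p$sigma_n) - nn) /
      gatingTimeConstant(v, p$tau0_n, p$tau1_n, p$theta_tau_n, p$sigma_tau_n)
    dy[ix(b, 3)] <- p$phi_h * (gatingSteadyState(v, p$theta_h, p$sigma_h) - h) /
      gatingTimeConstant(v, p$tau0_h, p$tau1_h, p$theta_tau_h, p$sigma_tau_h)
    dy[ix(b, 4)] <- p$phi_r * (gatingSteadyState(v, p$theta_r, p$sigma_r) - r) /
      gatingTimeConstant(v, p$tau0_r, p$tau1_r, p$theta_tau_r, p$sigma_tau_r)
    dy[ix(b, 5)] <- p$eps * (-ICa - IT - p$k_Ca * ca)
    dy[ix(b, 6)] <- synapticGateDerivative(s, v, p$alpha, p$beta, p$theta_H,
                                           p$sigma_H, p$theta_pre,
                                           p$theta_shift %||% "double")
  }

  p <- preset$Th
  h <- y[18 * n + n + 1:n]; r <- y[18 * n + 2 * n + 1:n]; v <- v_th
  minf <- 1 / (1 + exp(-(v + 37) / 7))
  pinf <- 1 / (1 + exp(-(v + 60) / 6.2))
  hinf <- 1 / (1 + exp((v + 41) / 4))
  rinf <- 1 / (1 + exp((v + 84) / 4))
  tauh <- 1 / (0.128 * exp(-(v + 46) / 18) + 4 / (1 + exp(-(v + 23) / 5)))
  taur <- 28 + exp(-(v + 25) / 10.5)
  IL <- p$g_L * (v - p$E_L)
  INa <- p$g_Na * minf^3 * h * (v - p$E_Na)
  IK <- p$g_K * (0.75 * (1 - h))^4 * (v - p$E_K)
  IT <- p$g_T * pinf^2 * r * (v - p$E_T)
  igpith <- syn$g_gpi_th * (v - syn$E_gpi_th) * s_gpi[aff$th_gpi + 1]
  dy[18 * n + 1:n] <- (-IL - INa - IK - IT - igpith + ismc) / p$C_m
  dy[18 * n + n + 1:n] <- (hinf - h) / tauh
  dy[18 * n + 2 * n + 1:n] <- (rinf - r) / taur
  dy
}

#' Run a seeded trial ensemble
#'
#' Runs `n_trials` independent simulations. Trial i uses a seed derived
#' deterministically from `(master_seed, i)`, so the ensemble is reproducible
#' and order-invariant; optional process-level parallelism
#' (`parallel::mclapply`) cannot change the results.
#'
#' @inheritParams simulateNetwork
#' @param condition `"healthy"` or `"PD"` (ignored when `preset` is given).
#' @param n_trials Number of trials.
#' @param master_seed Master seed for the ensemble.
#' @param cores Worker processes (1 = serial).
#' @param ... Passed to [simulateNetwork()].
#' @return List of `simulation_result`, one per trial.
#' @export
runTrials <- function(condition = c("healthy", "PD"), n_trials = 10,
                      master_seed = 1, preset = NULL, n = 20, cores = 1,
                      ...) {
  if (is.null(preset)) preset <- conditionPreset(match.arg(condition))
  stopifnot(n_trials >= 1)
  seeds <- trialSeeds(master_seed, n_trials)
  one <- function(i) simulateNetwork(preset,
                                     state = initialState(preset, n = n,
                                                          seed = seeds[i]),
                                     seed = seeds[i], n = n, ...)
  if (cores > 1) {
    parallel::mclapply(seq_len(n_trials), one, mc.cores = cores,
                       mc.preschedule = FALSE)
  } else {
    lapply(seq_len(n_trials), one)
  }
}

#' Deterministic per-trial seeds
#'
#' Trial seeds are drawn once from a generator seeded with the master seed,
#' so trial i's seed depends only on `(master_seed, i)`.
#'
#' @param master_seed Integer master seed.
#' @param n_trials Number of seeds.
#' @return Integer vector of length `n_trials`, all below 2^31.
#' @export
trialSeeds <- function(master_seed, n_trials) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n_trials)
}

#' Write spike rasters as CSV
#'
#' One row per spike: `population, neuron_id, spike_time_ms` (0-based
#' neuron ids).
#'
#' @param result A `simulation_result` (or a single `spike_raster`).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeRasterCsv <- function(result, path) {
  rasters <- if (inherits(result, "spike_raster")) list(result)
             else result$rasters
  rows <- do.call(rbind, lapply(rasters, function(r) {
    k <- lengths(r$times)
    if (sum(k) == 0) return(NULL)
    data.frame(population = r$population,
               neuron_id = rep(seq_len(r$n_neurons) - 1L, k),
               spike_time_ms = unlist(r$times))
  }))
  if (is.null(rows))
    rows <- data.frame(population = character(0), neuron_id = integer(0),
                       spike_time_ms = numeric(0))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Single-cell current-step (rebound) probe
#'
#' Integrates one isolated STN/GPe/GPi cell under a piecewise-constant
#' applied current: baseline, a current step of `step_amp` for `step_ms`,
#' then baseline again. Used to probe post-inhibitory rebound bursting: a
#' sufficiently strong and long hyperpolarizing step recruits the
#' low-threshold T current so the cell fires a burst on release.
#'
#' @param params A `neuron_parameters` for STN, GPe or GPi.
#' @param step_amp Step amplitude (pA/um^2), negative for hyperpolarization.
#' @param step_ms Step length (ms).
#' @param pre_ms,post_ms Baseline spans before/after the step (ms).
#' @param baseline Baseline applied current; defaults to the preset I_app.
#' @param v0 Initial voltage (gates start at steady state, Ca at 0.05).
#' @param dt Integration step (ms).
#' @return List: `spikes` (ms), `time`, `v`, `I_T` (1 ms-decimated traces),
#'   `release` (release time, ms), `n_rebound` (spikes within 100 ms after
#'   release) and `I_T_release` / `I_T_pre` (instantaneous T current at
#'   release vs 10 ms before the step).
#' @export
reboundProbe <- function(params, step_amp = -30, step_ms = 300,
                         pre_ms = 500, post_ms = 300,
                         baseline = params$I_app, v0 = -60, dt = 0.05) {
  stopifnot(params$population %in% c("STN", "GPe", "GPi"))
  nsteps <- round((pre_ms + step_ms + post_ms) / dt)
  I <- rep(baseline, nsteps)
  on <- round(pre_ms / dt); off <- round((pre_ms + step_ms) / dt)
  I[(on + 1):off] <- baseline + step_amp
  st <- c(v0,
          gatingSteadyState(v0, params$theta_n, params$sigma_n),
          gatingSteadyState(v0, params$theta_h, params$sigma_h),
          gatingSteadyState(v0, params$theta_r, params$sigma_r), 0.05)
  r <- .simulate_bg_cell_cpp(params, st, I, dt, nsteps, -10, 2,
                             as.integer(round(1 / dt)))
  release <- pre_ms + step_ms
  list(spikes = r$spikes, time = r$time, v = r$v, I_T = r$I_T,
       release = release,
       n_rebound = sum(r$spikes > release & r$spikes <= release + 100),
       I_T_release = r$I_T[which.min(abs(r$time - release))],
       I_T_pre = r$I_T[which.min(abs(r$time - (pre_ms - 10)))])
}
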