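# Config-driven experiment runners over the simulation + metrics layers.

#' Sensorimotor pulse onsets in the analysis frame of a run
#'
#' Pulse onsets realized over the full simulation, shifted to the
#' post-transient frame and truncated so that every response window fits the
#' analysed raster.
#'
#' @param result A `simulation_result` whose `smc` protocol is not `NULL`.
#' @param window Response window (ms) that must fit before the raster end.
#' @return A `pulse_times` object in the raster time frame.
#' @export
smcPulsesFor <- function(result, window = 25) {
  stopifnot(!is.null(result$smc), result$smc$kind != "none")
  pt <- protocolPulseTimes(result$smc, result$duration,
                           seed = result$seed + 1L)
  on <- pt$onsets - result$transient
  keep <- on >= 0 & (on + window) < (result$duration - result$transient)
  structure(list(onsets = on[keep], delta = pt$delta), class = "pulse_times")
}

# per-trial metric table for one population
.trial_metrics <- function(trials, pop, fidelity_window = 25) {
  rates <- vapply(trials, function(tr) meanFiringRate(tr$rasters[[pop]]), 1)
  series <- lapply(trials, function(tr) populationRate(tr$rasters[[pop]]))
  ff <- vapply(series, function(s)
    if (mean(s$values) > 0) fanoFactor(s) else NA_real_, 1)
  list(rates = rates, series = series, fano = ff)
}

#' Characterize one network condition
#'
#' Runs a seeded trial ensemble with sensorimotor input on and summarizes
#' every population: mean per-neuron firing rate (mean +- sd over trials),
#' Fano factor, trial-averaged Welch PSD with oscillation index and peak
#' frequency, thalamic relay fidelity, and the GPi burst profile.
#'
#' @param condition `"healthy"` or `"PD"`.
#' @param n_trials Trials in the ensemble.
#' @param master_seed Ensemble seed.
#' @param duration,transient Simulated/discarded time (ms). The default
#'   duration leaves 2000 ms of analysed time (two Welch segments).
#' @param dbs Optional `stimulus_protocol` applied to the STN.
#' @param n Neurons per population.
#' @param cores Worker processes for the trial loop.
#' @param fidelity_window Thalamic response window (ms).
#' @return Object of class `metrics_report`.
#' @export
runCharacterization <- function(condition = c("healthy", "PD"),
                                n_trials = 10, master_seed = 1,
                                duration = 2250, transient = 250,
                                dbs = NULL, n = 20, cores = 1,
                                fidelity_window = 25) {
  condition <- match.arg(condition)
  if (duration - transient < 1009)
    stop("characterization needs >= 1009 ms of analysed time so the rate ",
         "series spans a full 1000-sample Welch segment", call. = FALSE)
  preset <- conditionPreset(condition)
  trials <- runTrials(preset = preset, n_trials = n_trials,
                      master_seed = master_seed, n = n, cores = cores,
                      duration = duration, transient = transient,
                      dbs = dbs, smc = stimulusProtocol("SMC"))
  label <- if (is.null(dbs)) condition else
    paste0(condition, "+", dbs$pattern, " ", dbs$kind)

  pops <- lapply(stats::setNames(POPULATIONS, POPULATIONS), function(pop) {
    m <- .trial_metrics(trials, pop)
    psd <- meanPSD(m$series)
    list(rate_mean = mean(m$rates), rate_sd = sd(m$rates),
         fano_mean = mean(m$fano, na.rm = TRUE),
         fano_sd = sd(m$fano, na.rm = TRUE),
         psd = psd,
         oscillation_index = oscillationIndex(psd),
         peak_frequency = peakFrequency(psd))
  })
  fid <- vapply(trials, function(tr)
    thalamicFidelity(tr$rasters$Th, smcPulsesFor(tr, fidelity_window),
                     fidelity_window), 1)
  bp <- lapply(trials, function(tr) burstProfile(tr$rasters$GPi))
  report <- list(kind = "characterization", label = label,
                 condition = condition, n_trials = n_trials,
                 master_seed = master_seed, duration = duration,
                 transient = transient, n = n,
                 populations = pops,
                 fidelity_mean = mean(fid), fidelity_sd = sd(fid),
                 fidelity = fid,
                 gpi_burst_rate_mean = mean(vapply(bp, `[[`, 1, "rate")),
                 gpi_burst_duration_mean =
                   mean(vapply(bp, `[[`, 1, "mean_duration"), na.rm = TRUE),
                 gpi_burst_size_mean =
                   mean(vapply(bp, `[[`, 1, "mean_size"), na.rm = TRUE),
                 dbs = dbs)
  class(report) <- "metrics_report"
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s (%d trials, %g ms analysed per trial)\n",
              x$label, x$n_trials, x$duration - x$transient))
  if (x$kind %in% c("characterization")) {
    for (pop in POPULATIONS) {
      p <- x$populations[[pop]]
      cat(sprintf("  %-4s rate %6.2f +- %.2f sp/s | Fano %6.2f | OI %.3f | peak %g Hz\n",
                  pop, p$rate_mean, p$rate_sd, p$fano_mean,
                  p$oscillation_index, p$peak_frequency))
    }
    cat(sprintf("  thalamic fidelity %.3f +- %.3f | GPi bursts %.2f /s (%.0f ms, %.1f spikes)\n",
                x$fidelity_mean, x$fidelity_sd, x$gpi_burst_rate_mean,
                x$gpi_burst_duration_mean, x$gpi_burst_size_mean))
  }
  if (x$kind == "resting") {
    cat(sprintf("  thalamic resting rate %.2f +- %.2f sp/s | GPi bursts %.2f /s\n",
                x$thalamic_rate_mean, x$thalamic_rate_sd,
                x$gpi_burst_rate_mean))
  }
  invisible(x)
}

#' Compare excitatory and inhibitory DBS against the PD baseline
#'
#' Characterizes the Parkinsonian network without stimulation and under the
#' given DBS protocols, and reports each protocol's metric deltas relative to
#' the PD baseline.
#'
#' @param protocols List of `stimulus_protocol` objects (default: regular
#'   EDBS and IDBS at +-147.36 pA/um^2, 150 Hz).
#' @inheritParams runCharacterization
#' @return List of class `dbs_comparison`: `baseline` (PD `metrics_report`),
#'   `runs` (one report per protocol) and `deltas` (data frame).
#' @export
runDbsComparison <- function(protocols = list(stimulusProtocol("EDBS"),
                                              stimulusProtocol("IDBS")),
                             n_trials = 10, master_seed = 1,
                             duration = 2250, transient = 250, n = 20,
                             cores = 1) {
  baseline <- runCharacterization("PD", n_trials, master_seed, duration,
                                  transient, dbs = NULL, n = n,
                                  cores = cores)
  runs <- lapply(protocols, function(pr)
    runCharacterization("PD", n_trials, master_seed, duration, transient,
                        dbs = pr, n = n, cores = cores))
  names(runs) <- vapply(runs, `[[`, "", "label")
  deltas <- do.call(rbind, lapply(runs, function(r) {
    data.frame(label = r$label,
               d_rate_STN = r$populations$STN$rate_mean -
                 baseline$populations$STN$rate_mean,
               d_fano_STN = r$populations$STN$fano_mean -
                 baseline$populations$STN$fano_mean,
               d_oi_STN = r$populations$STN$oscillation_index -
                 baseline$populations$STN$oscillation_index,
               d_fidelity = r$fidelity_mean - baseline$fidelity_mean,
               d_gpi_burst_rate = r$gpi_burst_rate_mean -
                 baseline$gpi_burst_rate_mean)
  }))
  structure(list(baseline = baseline, runs = runs, deltas = deltas),
            class = "dbs_comparison")
}

#' @export
print.dbs_comparison <- function(x, ...) {
  print(x$baseline)
  for (r in x$runs) print(r)
  cat("deltas vs PD baseline:\n")
  print(x$deltas, row.names = FALSE)
  invisible(x)
}

#' Amplitude sweep of excitatory vs inhibitory DBS
#'
#' For each amplitude the Parkinsonian network is stimulated with regular
#' 150 Hz DBS, excitatory (`+A`) and inhibitory (`-A`), and the trial-mean
#' STN firing rate is recorded; the crossings of the two rate-vs-amplitude
#' curves are located by linear interpolation. Per-amplitude trial-averaged
#' STN spectra are stacked into EDBS/IDBS spectrograms.
#'
#' @param amplitudes Positive amplitude grid (pA/um^2), at least 2 points.
#' @inheritParams runCharacterization
#' @param frequency,width DBS pulse parameters.
#' @return List of class `amplitude_sweep`: `table` (amplitude, rate_edbs,
#'   rate_idbs and sds), `crossings` (all, pA), `crossing_pair` (the first
#'   inversion interval, i.e. the equal-rate operating pair),
#'   `upper_crossing` (the larger of the pair) and `spectrogram`
#'   (EDBS/IDBS amplitude x frequency matrices).
#' @export
runAmplitudeSweep <- function(amplitudes = c(seq(50, 100, 25),
                                             seq(110, 160, 10),
                                             seq(180, 300, 40)),
                              n_trials = 5, master_seed = 1,
                              duration = 1250, transient = 250, n = 20,
                              cores = 1, frequency = 150, width = 0.1) {
  if (length(amplitudes) < 2)
    stop("amplitude grid needs at least 2 points", call. = FALSE)
  amplitudes <- sort(amplitudes)
  preset <- conditionPreset("PD")
  one_point <- function(A, kind) {
    prot <- if (A == 0) NULL else
      stimulusProtocol(kind, amplitude = if (kind == "IDBS") -A else A,
                       frequency = frequency, width = width)
    trials <- runTrials(preset = preset, n_trials = n_trials,
                        master_seed = master_seed, n = n, cores = cores,
                        duration = duration, transient = transient,
                        dbs = prot, smc = stimulusProtocol("SMC"))
    rates <- vapply(trials, function(tr) meanFiringRate(tr$rasters$STN), 1)
    series <- lapply(trials, function(tr) populationRate(tr$rasters$STN))
    list(mean = mean(rates), sd = sd(rates), series = series)
  }
  ed <- lapply(amplitudes, one_point, kind = "EDBS")
  id <- lapply(amplitudes, one_point, kind = "IDBS")
  tab <- data.frame(amplitude = amplitudes,
                    rate_edbs = vapply(ed, `[[`, 1, "mean"),
                    sd_edbs = vapply(ed, `[[`, 1, "sd"),
                    rate_idbs = vapply(id, `[[`, 1, "mean"),
                    sd_idbs = vapply(id, `[[`, 1, "sd"))
  crossings <- curveCrossings(amplitudes, tab$rate_edbs, tab$rate_idbs)
  # The operating pair: the first inversion interval of the two rate curves.
  # Stronger amplitudes can invert the order again through feedback
  # inhibition of the subthalamo-pallidal loop; those crossings are kept in
  # `crossings` but are not part of the pair.
  pair <- head(crossings, 2)
  seg <- min(1000, length(ed[[1]]$series[[1]]$values))
  spg <- list(
    EDBS = amplitudeSpectrogram(stats::setNames(lapply(ed, `[[`, "series"),
                                                amplitudes), nperseg = seg),
    IDBS = amplitudeSpectrogram(stats::setNames(lapply(id, `[[`, "series"),
                                                amplitudes), nperseg = seg))
  structure(list(table = tab, crossings = crossings,
                 crossing_pair = pair,
                 upper_crossing = if (length(pair))
                   pair[length(pair)] else NA_real_,
                 spectrogram = spg, n_trials = n_trials,
                 master_seed = master_seed, duration = duration,
                 transient = transient), class = "amplitude_sweep")
}

#' @export
print.amplitude_sweep <- function(x, ...) {
  cat(sprintf("<amplitude_sweep> %d amplitudes x %d trials\n",
              nrow(x$table), x$n_trials))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("crossings at %s pA (operating pair upper: %.2f)\n",
              paste(sprintf("%.2f", x$crossings), collapse = ", "),
              x$upper_crossing))
  invisible(x)
}

#' Crossings of two sampled curves
#'
#' Locations where `y1 - y2` changes sign on the grid `x`, by linear
#' interpolation; exact grid-point equalities count as crossings.
#'
#' @param x Grid (sorted).
#' @param y1,y2 Curve samples on `x`.
#' @return Crossing abscissae (possibly empty).
#' @export
curveCrossings <- function(x, y1, y2) {
  d <- y1 - y2
  out <- x[d == 0]
  s <- sign(d)
  idx <- which(s[-1] * s[-length(s)] < 0)
  for (k in idx)
    out <- c(out, x[k] + d[k] * (x[k + 1] - x[k]) / (d[k] - d[k + 1]))
  sort(unique(out))
}

#' Resting-state run (sensorimotor input off)
#'
#' Simulates the network with the cortico-thalamic drive set to zero and
#' measures the resting-state thalamic rate (the excessive-activity marker)
#' and the GPi burst profile, optionally under DBS.
#'
#' @inheritParams runCharacterization
#' @param record Pass `"currents"` to keep T-current traces of the last
#'   trial for mechanism plots.
#' @return A `metrics_report` (kind `"resting"`).
#' @export
runRestingState <- function(condition = c("healthy", "PD"), n_trials = 10,
                            master_seed = 1, duration = 1250,
                            transient = 250, dbs = NULL, n = 20, cores = 1,
                            record = "spikes") {
  condition <- match.arg(condition)
  preset <- conditionPreset(condition)
  trials <- runTrials(preset = preset, n_trials = n_trials,
                      master_seed = master_seed, n = n, cores = cores,
                      duration = duration, transient = transient,
                      dbs = dbs, smc = NULL, record = record)
  th <- vapply(trials, function(tr)
    excessiveThalamicActivity(tr$rasters$Th), 1)
  bp <- lapply(trials, function(tr) burstProfile(tr$rasters$GPi))
  label <- paste0(condition, " resting",
                  if (!is.null(dbs)) paste0("+", dbs$kind) else "")
  structure(list(kind = "resting", label = label, condition = condition,
                 n_trials = n_trials, master_seed = master_seed,
                 duration = duration, transient = transient, n = n,
                 thalamic_rate_mean = mean(th), thalamic_rate_sd = sd(th),
                 thalamic_rates = th,
                 gpi_burst_rate_mean = mean(vapply(bp, `[[`, 1, "rate")),
                 gpi_burst_duration_mean =
                   mean(vapply(bp, `[[`, 1, "mean_duration"), na.rm = TRUE),
                 gpi_burst_size_mean =
                   mean(vapply(bp, `[[`, 1, "mean_size"), na.rm = TRUE),
                 dbs = dbs,
                 last_trial = if (record != "spikes")
                   trials[[n_trials]] else NULL),
            class = "metrics_report")
}

#' Serialize a metrics report
#'
#' Writes the scalar summary of a report as JSON and, for characterization
#' reports, the per-population metric table and spectra as CSV.
#'
#' @param report A `metrics_report`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
writeMetricsReport <- function(report, dir, prefix = report$kind) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  scal <- report[!vapply(report, is.object, TRUE)]
  scal$populations <- NULL
  scal$fidelity <- NULL
  scal$thalamic_rates <- NULL
  scal$last_trial <- NULL
  scal$dbs <- if (!is.null(report$dbs)) unclass(report$dbs) else NULL
  if (!is.null(report$populations)) {
    scal$populations <- lapply(report$populations, function(p)
      p[c("rate_mean", "rate_sd", "fano_mean", "fano_sd",
          "oscillation_index", "peak_frequency")])
    tab <- do.call(rbind, lapply(names(report$populations), function(pop) {
      p <- report$populations[[pop]]
      data.frame(population = pop, rate_mean = p$rate_mean,
                 rate_sd = p$rate_sd, fano = p$fano_mean,
                 oscillation_index = p$oscillation_index,
                 peak_frequency = p$peak_frequency)
    }))
    csv <- file.path(dir, paste0(prefix, "_populations.csv"))
    write.csv(tab, csv, row.names = FALSE)
    spec <- do.call(rbind, lapply(names(report$populations), function(pop) {
      s <- report$populations[[pop]]$psd
      data.frame(population = pop, freq = s$freq, power = s$power)
    }))
    csv2 <- file.path(dir, paste0(prefix, "_psd.csv"))
    write.csv(spec, csv2, row.names = FALSE)
    paths <- c(paths, csv, csv2)
  }
  js <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(scal, js, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(js, paths))
}
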