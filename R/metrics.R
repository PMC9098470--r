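#' Sliding-window population firing rate
#'
#' Counts spikes of all neurons in a window of `window` ms slid in steps of
#' `step` ms over `[0, duration)` and converts each count to a per-neuron
#' rate in sp/s (`count / (window_s * n_neurons)`). The per-neuron
#' normalization makes the series comparable with per-neuron mean rates; a
#' raw population mode (`per_neuron = FALSE`) divides by the window only.
#'
#' @param raster A `spike_raster`.
#' @param window Window length (ms), positive.
#' @param step Window step (ms), positive.
#' @param per_neuron Divide by the neuron count (default TRUE).
#' @return Object of class `rate_series`: `values` (sp/s), `window`, `step`,
#'   `t` (window start times), `population`.
#' @export
populationRate <- function(raster, window = 10, step = 1, per_neuron = TRUE) {
  stopifnot(inherits(raster, "spike_raster"), window > 0, step > 0)
  dur <- raster$duration
  starts <- seq(0, dur - window, by = step)
  allt <- unlist(raster$times)
  # bin at `step` resolution, then rolling sum over window/step bins
  nb <- ceiling(dur / step)
  counts <- tabulate(pmin(floor(allt / step) + 1L, nb), nbins = nb)
  k <- round(window / step)
  csum <- c(0, cumsum(counts))
  wcounts <- csum[(k + 1):(length(starts) + k)] - csum[seq_along(starts)]
  denom <- (window / 1000) * if (per_neuron) raster$n_neurons else 1
  structure(list(values = wcounts / denom, window = window, step = step,
                 t = starts, population = raster$population,
                 per_neuron = per_neuron), class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> %s: %d points (%g ms window, %g ms step), mean %.2f sp/s\n",
              x$population, length(x$values), x$window, x$step,
              mean(x$values)))
  invisible(x)
}

#' Mean per-neuron firing rate of a raster
#'
#' Total spikes divided by neuron count and analysed duration.
#'
#' @param raster A `spike_raster`.
#' @return Rate in sp/s.
#' @export
meanFiringRate <- function(raster) {
  sum(lengths(raster$times)) / raster$n_neurons / (raster$duration / 1000)
}

#' Resting-state (excessive) thalamic activity
#'
#' Mean thalamic firing rate over the analysed window; meaningful for
#' resting-state runs (sensorimotor input off), where any spiking is
#' pathological. Identical to [meanFiringRate()].
#'
#' @param raster Thalamic `spike_raster` from a resting-state run.
#' @return Rate in sp/s.
#' @export
excessiveThalamicActivity <- function(raster) meanFiringRate(raster)

#' Fano factor of a population rate series
#'
#' Variance-to-mean ratio of the population firing rate, the synchrony index
#' of the model: synchronized bursting inflates the variance of the
#' population rate at fixed mean. The population (1/N) variance is used by
#' default. Note the value scales linearly with a rescaling of the series.
#'
#' @param series A `rate_series` (or plain numeric vector).
#' @param ddof Variance denominator offset: 0 (population, default) or 1
#'   (sample).
#' @return Dimensionless Fano factor.
#' @export
fanoFactor <- function(series, ddof = 0) {
  x <- if (inherits(series, "rate_series")) series$values else series
  m <- mean(x)
  if (m <= 0) stop("undefined Fano factor: series mean is not positive",
                   call. = FALSE)
  v <- sum((x - m)^2) / (length(x) - ddof)
  v / m
}

#' Welch power spectral density
#'
#' Welch's method with the conventions of the reference implementation in
#' scipy.signal: Hann (periodic) window, segment length `nperseg`, 50%
#' overlap, per-segment constant detrend, one-sided density scaling. At the
#' default 1000 Hz sampling and 1000-sample segments the frequency grid is
#' 0..500 Hz in 1 Hz steps.
#'
#' @param x Numeric series (or `rate_series`).
#' @param fs Sampling rate (Hz).
#' @param nperseg Segment length (samples); `x` must be at least this long.
#' @return Object of class `spectrum_result`: `freq` (Hz), `power`
#'   (density), `fs`, `nperseg`, `n_trials` (1).
#' @export
welchPSD <- function(x, fs = 1000, nperseg = 1000) {
  if (inherits(x, "rate_series")) x <- x$values
  N <- length(x)
  if (N < nperseg)
    stop("series shorter than one Welch segment", call. = FALSE)
  step <- nperseg %/% 2
  nseg <- (N - nperseg) %/% step + 1
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / nperseg)  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nf <- nperseg %/% 2 + 1
  acc <- numeric(nf)
  for (s in seq_len(nseg)) {
    seg <- x[(s - 1) * step + 1:nperseg]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[1:nf]
    P <- scale * (Mod(X)^2)
    P[2:(nf - 1)] <- 2 * P[2:(nf - 1)]  # one-sided
    acc <- acc + P
  }
  structure(list(freq = (0:(nf - 1)) * fs / nperseg, power = acc / nseg,
                 fs = fs, nperseg = nperseg, n_trials = 1L),
            class = "spectrum_result")
}

#' Trial-averaged power spectral density
#'
#' Welch PSD of each trial's population rate series, averaged pointwise
#' across trials.
#'
#' @param serieses List of `rate_series` (or numeric vectors) of equal length.
#' @inheritParams welchPSD
#' @return A `spectrum_result` with `n_trials` set.
#' @export
meanPSD <- function(serieses, fs = 1000, nperseg = 1000) {
  stopifnot(length(serieses) >= 1)
  lens <- vapply(serieses, function(s)
    length(if (inherits(s, "rate_series")) s$values else s), 1L)
  if (length(unique(lens)) != 1)
    stop("series lengths differ", call. = FALSE)
  ps <- lapply(serieses, welchPSD, fs = fs, nperseg = nperseg)
  out <- ps[[1]]
  out$power <- Reduce(`+`, lapply(ps, `[[`, "power")) / length(ps)
  out$n_trials <- length(ps)
  out
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> %d frequencies (0-%g Hz), %d trial(s), peak at %g Hz\n",
              length(x$freq), max(x$freq), x$n_trials, peakFrequency(x)))
  invisible(x)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Beta-band oscillation index
#'
#' Fraction of spectral area inside the oscillation band (default the beta
#' band, 13-30 Hz) relative to the 1-500 Hz total, by trapezoid quadrature on
#' the Welch frequency grid (band edges inclusive). Lies in \[0, 1\] and is
#' invariant to rescaling of the spectrum.
#'
#' @param spectrum A `spectrum_result`.
#' @param band Numerator band (Hz).
#' @param total Denominator range (Hz); the spectrum must cover it.
#' @return Fraction in \[0, 1\].
#' @export
oscillationIndex <- function(spectrum, band = c(13, 30), total = c(1, 500)) {
  f <- spectrum$freq
  p <- spectrum$power
  if (min(f) > total[1] || max(f) < total[2])
    stop("spectrum does not cover the total range", call. = FALSE)
  inb <- f >= band[1] & f <= band[2]
  int <- f >= total[1] & f <= total[2]
  tot <- .trapz(f[int], p[int])
  if (tot <= 0) stop("undefined oscillation index: zero total area",
                     call. = FALSE)
  .trapz(f[inb], p[inb]) / tot
}

#' Dominant oscillation frequency
#'
#' Frequency at which the PSD is maximized, restricted to `total` (DC
#' excluded by default).
#'
#' @inheritParams oscillationIndex
#' @return Frequency (Hz).
#' @export
peakFrequency <- function(spectrum, total = c(1, 500)) {
  sel <- spectrum$freq >= total[1] & spectrum$freq <= total[2]
  spectrum$freq[sel][which.max(spectrum$power[sel])]
}

#' Amplitude-resolved spectrogram
#'
#' Stacks the trial-averaged PSD obtained at each stimulation amplitude into
#' an amplitude x frequency matrix (one row per amplitude).
#'
#' @param sweep Named list: for each amplitude, a list of `rate_series`.
#' @inheritParams welchPSD
#' @return List with `amplitude`, `freq` and `power` (matrix).
#' @export
amplitudeSpectrogram <- function(sweep, fs = 1000, nperseg = 1000) {
  if (length(sweep) < 2) stop("need at least two amplitudes", call. = FALSE)
  ps <- lapply(sweep, meanPSD, fs = fs, nperseg = nperseg)
  list(amplitude = as.numeric(names(sweep)), freq = ps[[1]]$freq,
       power = do.call(rbind, lapply(ps, `[[`, "power")))
}

#' Classify thalamic responses to sensorimotor pulses
#'
#' For every thalamic neuron and every pulse, spikes inside
#' `[onset, onset + window)` are counted: exactly one is a correct response,
#' none a miss, k >= 2 one correct plus k-1 extra spikes. Spikes outside all
#' response windows are undesired. The expected count is
#' `n_neurons * n_pulses`.
#'
#' @param raster Thalamic `spike_raster`.
#' @param pulses A `pulse_times` object or numeric onset vector (ms, same
#'   time frame as the raster).
#' @param window Response window (ms); must not exceed the smallest
#'   inter-pulse interval.
#' @return Object of class `fidelity_counts` with `N_correct`, `N_M`, `N_E`,
#'   `N_U`, `N_exp`.
#' @export
classifyThalamicResponses <- function(raster, pulses, window = 25) {
  onsets <- if (inherits(pulses, "pulse_times")) pulses$onsets else
    sort(as.numeric(pulses))
  if (length(onsets) == 0) stop("no pulses to classify", call. = FALSE)
  if (max(onsets) >= raster$duration)
    stop("pulses outside the raster window", call. = FALSE)
  if (length(onsets) > 1 && window > min(diff(onsets)))
    stop("response windows overlap: window exceeds the inter-pulse interval",
         call. = FALSE)
  nM <- nE <- nU <- nC <- 0L
  for (tms in raster$times) {
    idx <- findInterval(tms, onsets)
    inwin <- idx >= 1 & (tms - onsets[pmax(idx, 1)]) < window
    nU <- nU + sum(!inwin)
    k <- tabulate(idx[inwin], nbins = length(onsets))
    nC <- nC + sum(k >= 1)
    nM <- nM + sum(k == 0)
    nE <- nE + sum(pmax(k - 1L, 0L))
  }
  structure(list(N_correct = nC, N_M = nM, N_E = nE, N_U = nU,
                 N_exp = raster$n_neurons * length(onsets)),
            class = "fidelity_counts")
}

#' @export
print.fidelity_counts <- function(x, ...) {
  cat(sprintf("<fidelity_counts> expected %d: correct %d, missed %d, extra %d, undesired %d (fidelity %.3f)\n",
              x$N_exp, x$N_correct, x$N_M, x$N_E, x$N_U,
              thalamicFidelity(x)))
  invisible(x)
}

#' Thalamic relay fidelity
#'
#' \deqn{1 - (N_M + N_E + N_U) / N_{exp}}: 1 when every neuron answers every
#' sensorimotor pulse with exactly one spike and stays silent otherwise; the
#' value may be negative when errors outnumber the expected spikes.
#'
#' @param counts A `fidelity_counts`, or a thalamic `spike_raster` (then
#'   `pulses`/`window` are forwarded to [classifyThalamicResponses()]).
#' @param pulses,window See [classifyThalamicResponses()].
#' @return Fidelity (dimensionless, at most 1).
#' @export
thalamicFidelity <- function(counts, pulses = NULL, window = 25) {
  if (inherits(counts, "spike_raster"))
    counts <- classifyThalamicResponses(counts, pulses, window)
  if (counts$N_exp <= 0) stop("N_exp must be positive", call. = FALSE)
  1 - (counts$N_M + counts$N_E + counts$N_U) / counts$N_exp
}

#' Burst statistics of a raster
#'
#' A burst is a maximal run of consecutive inter-spike intervals at or below
#' `isi_threshold` containing at least `min_spikes` spikes. Burst duration is
#' last minus first spike time. The burst rate is bursts per neuron per
#' second of analysed time.
#'
#' @param raster A `spike_raster`.
#' @param isi_threshold Maximum intra-burst inter-spike interval (ms).
#' @param min_spikes Minimum spikes per burst.
#' @return Object of class `burst_statistics`: `rate` (bursts/s),
#'   `mean_duration` (ms), `mean_size` (spikes/burst), per-neuron lists
#'   `durations` and `sizes`, and the detection convention.
#' @export
burstProfile <- function(raster, isi_threshold = 10, min_spikes = 3) {
  stopifnot(isi_threshold > 0, min_spikes >= 2)
  durs <- list(); sizes <- list()
  nb <- 0L
  for (i in seq_len(raster$n_neurons)) {
    tms <- raster$times[[i]]
    d <- numeric(0); s <- integer(0)
    if (length(tms) >= min_spikes) {
      grp <- cumsum(c(1, diff(tms) > isi_threshold))
      for (g in split(tms, grp)) {
        if (length(g) >= min_spikes) {
          d <- c(d, max(g) - min(g))
          s <- c(s, length(g))
        }
      }
    }
    durs[[i]] <- d; sizes[[i]] <- s
    nb <- nb + length(d)
  }
  alld <- unlist(durs); alls <- unlist(sizes)
  structure(list(
    rate = nb / raster$n_neurons / (raster$duration / 1000),
    mean_duration = if (nb) mean(alld) else NA_real_,
    mean_size = if (nb) mean(alls) else NA_real_,
    n_bursts = nb, durations = durs, sizes = sizes,
    convention = list(isi_threshold = isi_threshold,
                      min_spikes = min_spikes)), class = "burst_statistics")
}

#' @export
print.burst_statistics <- function(x, ...) {
  cat(sprintf("<burst_statistics> %.2f bursts/s (ISI <= %g ms, >= %d spikes): mean duration %.1f ms, %.1f spikes/burst\n",
              x$rate, x$convention$isi_threshold, x$convention$min_spikes,
              x$mean_duration, x$mean_size))
  invisible(x)
}

#' Read a plain-text spike raster
#'
#' Standalone entry to the metrics layer: reads a CSV with columns
#' `neuron_id` (0-based) and `spike_time_ms` (optionally `population`) as
#' written by [writeRasterCsv()].
#'
#' @param path CSV path.
#' @param n_neurons Number of neurons (default: max id + 1).
#' @param duration Raster window (ms; default: just above the last spike).
#' @param population Label filter when the file holds several populations.
#' @return A `spike_raster`.
#' @export
readRasterCsv <- function(path, n_neurons = NULL, duration = NULL,
                          population = NULL) {
  df <- utils::read.csv(path)
  if (!is.null(population) && "population" %in% names(df))
    df <- df[df$population == population, ]
  if (is.null(n_neurons)) n_neurons <- max(df$neuron_id) + 1L
  if (is.null(duration))
    duration <- if (nrow(df)) max(df$spike_time_ms) + 1 else 1
  times <- lapply(seq_len(n_neurons) - 1L, function(i)
    df$spike_time_ms[df$neuron_id == i])
  spikeRaster(times, n_neurons, duration, population %||% "raster")
}
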