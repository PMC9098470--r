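#' Rectangular pulse-train waveform
#'
#' Periodic rectangular pulses built from Heaviside-gated sinusoids:
#' \deqn{I(t) = A\,H(\sin(2\pi f t/1000))\,(1 - H(\sin(2\pi f (t+\delta)/1000)))}
#' with H the Heaviside step. Each period of length 1000/f ms carries one
#' pulse of width `delta` ms located immediately before the downward zero
#' crossing of the sine; the waveform takes only the values 0 and `A`.
#'
#' @param t Time (ms); vectorized.
#' @param A Pulse amplitude (pA/um^2; sign carried through).
#' @param f Pulse frequency (Hz), positive.
#' @param delta Pulse width (ms), positive and below half a period.
#' @return Current values, same length as `t`.
#' @examples
#' pulseWaveform(c(3.2, 3.3, 4), A = 100, f = 150, delta = 0.1)
#' @export
pulseWaveform <- function(t, A, f, delta) {
  if (f <= 0) stop("f must be positive", call. = FALSE)
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  w <- 2 * pi * f / 1000
  A * as.numeric(sin(w * t) > 0 & sin(w * (t + delta)) <= 0)
}

#' Homogeneous-Poisson pulse onsets
#'
#' Event onsets of a homogeneous Poisson process on `[0, duration)`,
#' reproducible per seed. Each onset carries a rectangle of width `delta`;
#' overlaps merge in the sampled waveform.
#'
#' @param rate Event rate (Hz), positive.
#' @param delta Pulse width (ms).
#' @param duration Window length (ms), positive.
#' @param seed Integer seed.
#' @return Object of class `pulse_times`: list with sorted `onsets` (ms) and
#'   `delta`.
#' @export
poissonPulseTimes <- function(rate, delta, duration, seed) {
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (rate * delta / 1000 >= 1)
    warning("rate * delta >= 1: near-continuous stimulation")
  onsets <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    # exponential gaps; expected count rate * duration / 1000
    gaps <- rexp(ceiling(rate * duration / 1000 * 1.5) + 25, rate / 1000)
    tt <- cumsum(gaps)
    while (sum(gaps) < duration) {
      gaps <- c(gaps, rexp(ceiling(rate * duration / 5000) + 25, rate / 1000))
      tt <- cumsum(gaps)
    }
    tt[tt < duration]
  })
  structure(list(onsets = onsets, delta = delta), class = "pulse_times")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
    envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Regular pulse onsets of the periodic waveform
#'
#' Onset times (ms) of the pulses that [pulseWaveform()] produces on
#' `[0, duration)`: one onset per period at `1000/f * (k + 1/2) - delta`.
#'
#' @param f Frequency (Hz); `delta` width (ms); `duration` window (ms).
#' @inheritParams poissonPulseTimes
#' @return A `pulse_times` object.
#' @export
regularPulseTimes <- function(f, delta, duration) {
  period <- 1000 / f
  onsets <- seq(period / 2 - delta, duration, by = period)
  onsets <- onsets[onsets >= 0 & onsets < duration]
  structure(list(onsets = onsets, delta = delta), class = "pulse_times")
}

#' Stimulation protocol
#'
#' Describes one pulse-train input: excitatory or inhibitory STN deep brain
#' stimulation (EDBS/IDBS, default 150 Hz, 0.1 ms pulses), cortico-thalamic
#' sensorimotor drive (SMC, default 4.5 pA/um^2, 20 Hz, 5 ms pulses) or no
#' input. DBS currents are applied identically to every STN neuron, SMC
#' pulses to every thalamic neuron. The Poisson pattern replaces the regular
#' pulse grid by a homogeneous Poisson process of the same rate (per-trial
#' seeds are derived from the run's master seed).
#'
#' @param kind `"EDBS"`, `"IDBS"`, `"SMC"` or `"none"`.
#' @param amplitude Pulse amplitude A (pA/um^2). Must be positive for EDBS
#'   and SMC, negative for IDBS. Defaults: EDBS 147.36, IDBS -147.36,
#'   SMC 4.5.
#' @param frequency Pulse rate f (Hz). Defaults: DBS 150, SMC 20.
#' @param width Pulse width delta (ms). Defaults: DBS 0.1, SMC 5.
#' @param pattern `"regular"` or `"poisson"`.
#' @param t_on,t_off Active window (ms); the current is zero outside.
#' @return Object of class `stimulus_protocol`.
#' @export
stimulusProtocol <- function(kind = c("EDBS", "IDBS", "SMC", "none"),
                             amplitude = NULL, frequency = NULL, width = NULL,
                             pattern = c("regular", "poisson"),
                             t_on = 0, t_off = Inf) {
  kind <- match.arg(kind)
  pattern <- match.arg(pattern)
  if (kind == "none")
    return(structure(list(kind = "none", amplitude = 0), class =
                     "stimulus_protocol"))
  amplitude <- amplitude %||% switch(kind, EDBS = 147.36, IDBS = -147.36,
                                     SMC = 4.5)
  frequency <- frequency %||% switch(kind, SMC = 20, 150)
  width <- width %||% switch(kind, SMC = 5, 0.1)
  if (kind %in% c("EDBS", "SMC") && amplitude <= 0)
    stop(kind, " requires a positive amplitude", call. = FALSE)
  if (kind == "IDBS" && amplitude >= 0)
    stop("IDBS requires a negative amplitude", call. = FALSE)
  if (width <= 0) stop("width must be positive", call. = FALSE)
  if (frequency * width / 1000 >= 1)
    stop("pulses overlap: frequency * width must stay below 1", call. = FALSE)
  structure(list(kind = kind, amplitude = amplitude, frequency = frequency,
                 width = width, pattern = pattern, t_on = t_on,
                 t_off = t_off), class = "stimulus_protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stimulus_protocol <- function(x, ...) {
  if (x$kind == "none") { cat("<stimulus_protocol> none\n"); return(invisible(x)) }
  cat(sprintf("<stimulus_protocol> %s %s: A = %g pA/um^2, f = %g Hz, delta = %g ms",
              x$pattern, x$kind, x$amplitude, x$frequency, x$width))
  if (is.finite(x$t_off) || x$t_on > 0)
    cat(sprintf(", active [%g, %g] ms", x$t_on, x$t_off))
  cat("\n")
  invisible(x)
}

#' Instantaneous protocol current
#'
#' Evaluates the stimulation current at times `t`. Regular patterns are
#' closed-form; a Poisson protocol needs its realized onsets (pass
#' `pulse_times`, or attach them with [poissonPulseTimes()] beforehand).
#' Outside the active window, and for `kind = "none"`, the value is 0.
#'
#' @param protocol A `stimulus_protocol`.
#' @param t Times (ms), vectorized.
#' @param pulse_times Optional `pulse_times` with realized Poisson onsets.
#' @return Current (pA/um^2) at each `t`.
#' @export
protocolCurrent <- function(protocol, t, pulse_times = NULL) {
  if (!inherits(protocol, "stimulus_protocol"))
    stop("not a stimulus_protocol", call. = FALSE)
  if (protocol$kind == "none") return(rep(0, length(t)))
  active <- t >= protocol$t_on & t <= protocol$t_off
  out <- numeric(length(t))
  if (protocol$pattern == "regular") {
    out[active] <- pulseWaveform(t[active], protocol$amplitude,
                                 protocol$frequency, protocol$width)
  } else {
    if (is.null(pulse_times))
      stop("Poisson protocol needs realized pulse_times", call. = FALSE)
    out[active] <- protocol$amplitude *
      .in_any_window(t[active], pulse_times$onsets, pulse_times$delta)
  }
  out
}

# 1 where t falls inside any [onset, onset + delta) rectangle
.in_any_window <- function(t, onsets, delta) {
  if (length(onsets) == 0) return(numeric(length(t)))
  idx <- findInterval(t, onsets)
  hit <- idx >= 1 & (t - onsets[pmax(idx, 1)]) < delta
  as.numeric(hit)
}

# Stimulus sampled on the integration grid (piecewise constant per step,
# value taken at the left edge of each step). Asserts that each pulse covers
# at least one grid sample.
.protocol_grid <- function(protocol, nsteps, dt, seed = NULL) {
  if (is.null(protocol) || protocol$kind == "none") return(numeric(nsteps))
  if (protocol$width < dt)
    stop("pulse width shorter than the integration step", call. = FALSE)
  tt <- (seq_len(nsteps) - 1) * dt
  pt <- NULL
  if (protocol$pattern == "poisson") {
    if (is.null(seed)) stop("Poisson protocol needs a seed", call. = FALSE)
    pt <- poissonPulseTimes(protocol$frequency, protocol$width, nsteps * dt,
                            seed)
  }
  protocolCurrent(protocol, tt, pt)
}

#' Pulse onsets of a protocol over a window
#'
#' Realized onsets used for response classification (e.g. thalamic fidelity):
#' closed-form for regular patterns, seeded draw for Poisson ones.
#'
#' @inheritParams protocolCurrent
#' @param duration Window (ms).
#' @param seed Seed for Poisson patterns.
#' @return A `pulse_times` object.
#' @export
protocolPulseTimes <- function(protocol, duration, seed = NULL) {
  if (protocol$kind == "none")
    return(structure(list(onsets = numeric(0), delta = 0),
                     class = "pulse_times"))
  if (protocol$pattern == "regular")
    return(regularPulseTimes(protocol$frequency, protocol$width, duration))
  poissonPulseTimes(protocol$frequency, protocol$width, duration, seed)
}
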