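#' Logistic steady state of an ionic gating variable
#'
#' All fast activation/inactivation variables of the model cells relax towards
#' a logistic function of the membrane potential,
#' \deqn{X_\infty(v) = 1 / (1 + \exp(-(v - \theta_X)/\sigma_X)).}
#' The function is strictly monotone in `v` (increasing when `sigma > 0`) and
#' maps the real line to (0, 1).
#'
#' @param v Membrane potential (mV); vectorized.
#' @param theta Half-activation voltage \eqn{\theta_X} (mV).
#' @param sigma Slope factor \eqn{\sigma_X} (mV); must be nonzero.
#' @return Activation fraction in (0, 1), same length as `v`.
#' @examples
#' gatingSteadyState(-24, theta = -32, sigma = 8)  # STN n gate
#' @export
gatingSteadyState <- function(v, theta, sigma) {
  if (!is.numeric(sigma) || any(sigma == 0))
    stop("sigma must be nonzero", call. = FALSE)
  1 / (1 + exp(-(v - theta) / sigma))
}

#' Low-threshold calcium gate as a function of the slow variable r
#'
#' The T-type current of the subthalamic cell uses a gate that is a logistic
#' function of the slow inactivation variable `r` rather than of voltage:
#' \deqn{b_\infty(r) = 1/(1 + e^{(r-\theta_b)/\sigma_b}) - 1/(1 + e^{-\theta_b/\sigma_b}),}
#' normalized so that \eqn{b_\infty(0) = 0}. A non-normalized variant in which
#' the offset is \eqn{e^{\theta_b/\sigma_b}} is selectable with
#' `form = "printed"`; at the default subthalamic constants the two differ by
#' less than 4e-4 but the printed variant loses the zero anchor.
#'
#' @param r Slow gating variable (fraction); vectorized.
#' @param theta_b,sigma_b Gate constants (sigma_b nonzero).
#' @param form `"normalized"` (default) or `"printed"`.
#' @return Gate value; `bSteadyState(0) == 0` under the normalized form.
#' @export
bSteadyState <- function(r, theta_b, sigma_b,
                         form = c("normalized", "printed")) {
  form <- match.arg(form)
  if (!is.numeric(sigma_b) || any(sigma_b == 0))
    stop("sigma_b must be nonzero", call. = FALSE)
  off <- if (form == "printed") exp(theta_b / sigma_b)
         else 1 / (1 + exp(-theta_b / sigma_b))
  1 / (1 + exp((r - theta_b) / sigma_b)) - off
}

#' Voltage-dependent gating time constant
#'
#' \deqn{\tau_X(v) = \tau^0_X + \tau^1_X / (1 + \exp(-(v - \theta^\tau_X)/\sigma^\tau_X))}
#' Bounded between `tau0` and `tau0 + tau1`. With `tau1 = 0` the constant
#' time-constant case of the pallidal slow gate is recovered.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param tau0 Baseline time constant (ms), positive.
#' @param tau1 Voltage-dependent increment (ms), non-negative.
#' @param theta_tau,sigma_tau Midpoint (mV) and slope (mV, nonzero) of the
#'   logistic voltage dependence. Ignored when `tau1 = 0`.
#' @return Time constant (ms).
#' @examples
#' gatingTimeConstant(-57, tau0 = 1, tau1 = 500, theta_tau = -57,
#'                    sigma_tau = -3)  # STN h gate at its midpoint: 251 ms
#' @export
gatingTimeConstant <- function(v, tau0, tau1 = 0, theta_tau = 0,
                               sigma_tau = 1) {
  if (any(tau0 <= 0)) stop("tau0 must be positive", call. = FALSE)
  if (any(tau1 < 0)) stop("tau1 must be non-negative", call. = FALSE)
  if (any(tau1 > 0) && any(sigma_tau == 0))
    stop("sigma_tau must be nonzero", call. = FALSE)
  if (all(tau1 == 0)) return(tau0 + 0 * v)
  tau0 + tau1 / (1 + exp(-(v - theta_tau) / sigma_tau))
}

#' Presynaptic activation function of the synaptic gate
#'
#' \eqn{H_\infty(v) = 1/(1 + \exp(-(v - \theta^H)/\sigma^H))}, evaluated at
#' the (optionally threshold-shifted) presynaptic voltage. Under the default
#' double-shift convention the gate opens around
#' \eqn{v = \theta_{pre} + \theta^H}, i.e. only on presynaptic spikes.
#'
#' @param v_pre Presynaptic membrane potential (mV).
#' @param theta_H,sigma_H Midpoint and slope (mV) of the logistic.
#' @param theta_pre Additional presynaptic threshold shift (mV); applied when
#'   `shift = "double"`.
#' @param shift `"double"` (default; argument is `v_pre - theta_pre`) or
#'   `"single"` (argument is `v_pre`).
#' @return Activation in (0, 1).
#' @export
synapticActivation <- function(v_pre, theta_H, sigma_H, theta_pre = 0,
                               shift = c("double", "single")) {
  shift <- match.arg(shift)
  arg <- if (shift == "double") v_pre - theta_pre else v_pre
  gatingSteadyState(arg, theta_H, sigma_H)
}

#' Time derivative of a synaptic gate
#'
#' First-order kinetics driven by the presynaptic voltage:
#' \deqn{ds/dt = \alpha\,H_\infty(v_{pre})\,(1 - s) - \beta\,s.}
#' The flow preserves the unit interval for any bounded presynaptic waveform;
#' under sustained depolarization s relaxes to \eqn{\alpha/(\alpha+\beta)}.
#'
#' @param s Gate value in \[0, 1\].
#' @param v_pre Presynaptic membrane potential (mV).
#' @param alpha,beta Opening and closing rates (1/ms).
#' @param theta_H,sigma_H,theta_pre,shift Passed to [synapticActivation()].
#' @return ds/dt (1/ms).
#' @export
synapticGateDerivative <- function(s, v_pre, alpha, beta, theta_H, sigma_H,
                                   theta_pre = 0,
                                   shift = c("double", "single")) {
  alpha * synapticActivation(v_pre, theta_H, sigma_H, theta_pre, shift) *
    (1 - s) - beta * s
}

#' Conductance-based synaptic current
#'
#' \eqn{I = g\,(v_{post} - E)\,\sum_j s_j}. The value is subtracted from the
#' membrane equation, so a positive value (post above reversal) is
#' hyperpolarizing.
#'
#' @param v_post Postsynaptic membrane potential (mV).
#' @param g Synaptic conductance (nS/um^2), non-negative.
#' @param E Synaptic reversal potential (mV).
#' @param s_sum Sum of the afferent gate values, non-negative.
#' @return Synaptic current (pA/um^2).
#' @export
synapticCurrent <- function(v_post, g, E, s_sum) {
  if (any(g < 0)) stop("g must be non-negative", call. = FALSE)
  if (any(s_sum < 0)) stop("s_sum must be non-negative", call. = FALSE)
  g * (v_post - E) * s_sum
}
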