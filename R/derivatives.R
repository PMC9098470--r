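#' Vector field of one STN/GPe/GPi cell
#'
#' Right-hand side of the membrane equation
#' \deqn{C_m v' = -I_L - I_{Na} - I_K - I_{Ca} - I_T - I_{AHP} - I_{syn} + I_{app}}
#' together with the gating kinetics \eqn{X' = \phi_X (X_\infty(v) - X)/\tau_X(v)}
#' for X = n, h, r and the intracellular calcium balance
#' \eqn{[Ca]' = \epsilon(-I_{Ca} - I_T - k_{Ca}[Ca])}. The subthalamic T
#' current gates through \eqn{b_\infty(r)^2}; the pallidal cells gate through
#' r itself. Each ionic current is returned by name for diagnostics.
#'
#' @param state Named numeric vector or list with `v`, `n`, `h`, `r`, `Ca`.
#' @param params A `neuron_parameters` object for STN, GPe or GPi.
#' @param i_syn Total synaptic current (pA/um^2), subtracted.
#' @param i_app Applied current (pA/um^2); defaults to the preset value.
#' @return List with `deriv` (named: v, n, h, r, Ca) and `currents`
#'   (I_L, I_Na, I_K, I_Ca, I_T, I_AHP).
#' @export
bgCellDerivatives <- function(state, params, i_syn = 0,
                              i_app = params$I_app) {
  if (!params$population %in% c("STN", "GPe", "GPi"))
    stop("params must describe an STN, GPe or GPi cell", call. = FALSE)
  validateParameters(params)
  st <- unlist(state[c("v", "n", "h", "r", "Ca")])
  .check_state(st)
  .bg_cell_deriv_cpp(params, as.numeric(st), i_syn, i_app)
}

#' Vector field of one thalamocortical relay cell
#'
#' \deqn{C_m v' = -I_L - I_{Na} - I_K - I_T - I_{GPi \to Th} + I_{SMC}} with
#' the closed-form gating of the relay cell: sodium inactivation h with
#' rate-based time constant, potassium activation tied to h through
#' \eqn{(0.75(1-h))^4}, and a low-threshold calcium current
#' \eqn{I_T = g_T\,p_\infty(v)^2\,r\,(v - E_T)}.
#'
#' @param state Named numeric vector or list with `v`, `h`, `r`.
#' @param params A `neuron_parameters` object for `"Th"`.
#' @param i_gpi_th Pallido-thalamic synaptic current (pA/um^2), subtracted.
#' @param i_smc Sensorimotor (cortico-thalamic) pulse current, added.
#' @return List with `deriv` (v, h, r) and `currents` (I_L, I_Na, I_K, I_T).
#' @export
thalamicCellDerivatives <- function(state, params, i_gpi_th = 0, i_smc = 0) {
  if (params$population != "Th")
    stop("params must describe a thalamic cell", call. = FALSE)
  validateParameters(params)
  st <- unlist(state[c("v", "h", "r")])
  .check_state(st)
  .th_cell_deriv_cpp(params, as.numeric(st), i_gpi_th, i_smc)
}

.check_state <- function(st) {
  bad <- !is.finite(st)
  if (any(bad))
    stop("non-finite state variable: ", paste(names(st)[bad], collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Gating-range diagnostic
#'
#' Checks that gating fractions stay within \[-0.01, 1.01\] (small solver
#' overshoot is tolerated; values beyond it indicate an integration problem).
#' Nothing is clamped.
#'
#' @param x Numeric vector/matrix of gating values.
#' @param label Name used in the error message.
#' @return Invisibly `TRUE`; errors if the range is violated.
#' @export
checkGatingRange <- function(x, label = "gating variable") {
  r <- range(x)
  if (r[1] < -0.01 || r[2] > 1.01)
    stop(sprintf("%s out of range [-0.01, 1.01]: observed [%g, %g]",
                 label, r[1], r[2]), call. = FALSE)
  invisible(TRUE)
}
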