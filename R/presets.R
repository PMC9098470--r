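# Parameter presets for the four cell populations and the six projections.
#
# This is the single annotated source of every model constant. All readings
# of ambiguous printed entries are resolved HERE and nowhere else, so that
# alternates can be swapped in one place:
#   * STN: the table prints tau1_h twice (500 ms and 100 ms); the second
#     value is taken as tau1_n, the only otherwise-missing STN time constant.
#   * STN: "theta^1_r 17.5 mV" is read as tau1_r = 17.5 ms.
#   * STN: the garbled entry "theta_X{tau}_n -26 mV" is taken as the slope
#     sigma_tau_n = -26 mV of the n-gate time constant (theta_tau_n = -80 mV
#     is printed explicitly). This reading is uncertain; `sigma_tau_n` is an
#     argument of neuronParameters() so alternates can be tested.
#   * GPe/GPi: "theta^0_h 0.05 mV" is read as tau0_h = 0.05 ms.
#   * GPi: the synaptic rows labelled g_STN->GPe / g_GPe->GPe are the
#     GPi-targeting projections (g_STN->GPi, g_GPe->GPi), per the prose.
#   * Th: "g_GPi->Th 005" is read as 0.05 nS/um^2 (stated in the prose).
#   * Th: g_K and E_K are required by the potassium current but missing from
#     the printed set; filled from the thalamocortical relay cell of the
#     model lineage (g_K = 5 nS/um^2, E_K = -90 mV).
#   * The low-threshold gate b applies to the STN only; the pallidal cells
#     gate their T current directly by the slow variable r (no theta_b /
#     sigma_b exists for them).
# Starred entries (healthy -> PD) are switched by `condition`.

.bg_symbols <- c(
  "g_L", "g_Na", "g_K", "g_T", "g_Ca", "g_AHP",
  "E_L", "E_Na", "E_K", "E_Ca",
  "theta_m", "sigma_m", "theta_h", "sigma_h", "theta_n", "sigma_n",
  "theta_r", "sigma_r", "theta_a", "sigma_a", "theta_s", "sigma_s",
  "tau0_h", "tau1_h", "theta_tau_h", "sigma_tau_h",
  "tau0_n", "tau1_n", "theta_tau_n", "sigma_tau_n",
  "tau0_r", "tau1_r", "theta_tau_r", "sigma_tau_r",
  "phi_h", "phi_n", "phi_r", "eps", "k1", "k_Ca",
  "C_m", "I_app", "alpha", "beta", "theta_H", "sigma_H", "theta_pre")

.th_symbols <- c("g_L", "g_Na", "g_K", "g_T", "E_L", "E_Na", "E_K", "E_T",
                 "C_m")

#' Cell parameters for one population in one condition
#'
#' Returns the full named-constant set of one model population. Values with a
#' healthy/Parkinsonian (PD) alternative (applied currents of STN, GPe, GPi)
#' are resolved by `condition`; the thalamic set is condition-independent.
#' Units follow the model definition: conductances nS/um^2, potentials mV,
#' times ms, applied currents pA/um^2, rates 1/ms; C_m = 1.
#'
#' @param population `"STN"`, `"GPe"`, `"GPi"` or `"Th"`.
#' @param condition `"healthy"` or `"PD"`.
#' @param sigma_tau_n Slope (mV) of the STN n-gate time constant. The printed
#'   source entry is garbled; the default -26 is the adopted reading and can
#'   be overridden. Ignored for other populations.
#' @param b_form Form of the low-threshold gate offset, see [bSteadyState()].
#'   STN only.
#' @param theta_shift Synaptic-gate threshold convention, see
#'   [synapticActivation()].
#' @return An object of class `neuron_parameters`: a named list of constants
#'   plus `population` and `condition` attributes-like fields.
#' @examples
#' neuronParameters("STN", "healthy")$I_app   # 8.4
#' neuronParameters("GPe", "PD")$I_app        # 0.5
#' @export
neuronParameters <- function(population = POPULATIONS,
                             condition = c("healthy", "PD"),
                             sigma_tau_n = -26,
                             b_form = c("normalized", "printed"),
                             theta_shift = c("double", "single")) {
  population <- match.arg(population)
  condition <- match.arg(condition)
  b_form <- match.arg(b_form)
  theta_shift <- match.arg(theta_shift)
  pd <- condition == "PD"

  p <- switch(population,
    STN = list(
      g_L = 2.25, g_Na = 30, g_K = 40, g_T = 0.5, g_Ca = 0.5, g_AHP = 9,
      E_L = -60, E_Na = 55, E_K = -80, E_Ca = 140,
      theta_m = -30, sigma_m = 15,
      theta_h = -39, sigma_h = -3.1,
      theta_n = -32, sigma_n = 8,
      theta_r = -67, sigma_r = -2,
      theta_a = -63, sigma_a = 7.8,
      theta_b = 0.4, sigma_b = -0.1,
      theta_s = -39, sigma_s = 8,
      tau0_h = 1, tau1_h = 500, theta_tau_h = -57, sigma_tau_h = -3,
      tau0_n = 1, tau1_n = 100, theta_tau_n = -80, sigma_tau_n = sigma_tau_n,
      tau0_r = 40, tau1_r = 17.5, theta_tau_r = 68, sigma_tau_r = -2.2,
      phi_h = 5, phi_n = 5, phi_r = 2,
      eps = 3e-5, k1 = 15, k_Ca = 22.5,
      C_m = 1, I_app = if (pd) 3 else 8.4,
      alpha = 2, beta = 0.08, theta_H = -39, sigma_H = 8, theta_pre = 20,
      use_b = TRUE, b_form = b_form),
    GPe = list(
      g_L = 0.1, g_Na = 120, g_K = 30, g_T = 0.5, g_Ca = 0.15, g_AHP = 30,
      E_L = -55, E_Na = 55, E_K = -80, E_Ca = 120,
      theta_m = -37, sigma_m = 10,
      theta_h = -58, sigma_h = -12,
      theta_n = -50, sigma_n = 14,
      theta_r = -70, sigma_r = -2,
      theta_a = -57, sigma_a = 2,
      theta_s = -35, sigma_s = 2,
      tau0_h = 0.05, tau1_h = 0.27, theta_tau_h = -40, sigma_tau_h = -12,
      tau0_n = 0.05, tau1_n = 0.27, theta_tau_n = -40, sigma_tau_n = -12,
      tau0_r = 30, tau1_r = 0, theta_tau_r = 0, sigma_tau_r = 1,
      phi_h = 0.135, phi_n = 0.165, phi_r = 1,
      eps = 0.0055, k1 = 30, k_Ca = 2.4,
      C_m = 1, I_app = if (pd) 0.5 else 5.9,
      alpha = 5, beta = 0.14, theta_H = -57, sigma_H = 2, theta_pre = 30,
      use_b = FALSE),
    GPi = list(
      g_L = 0.1, g_Na = 120, g_K = 30, g_T = 0.5, g_Ca = 0.15, g_AHP = 30,
      E_L = -55, E_Na = 55, E_K = -80, E_Ca = 120,
      theta_m = -37, sigma_m = 10,
      theta_h = -58, sigma_h = -12,
      theta_n = -50, sigma_n = 14,
      theta_r = -70, sigma_r = -2,
      theta_a = -57, sigma_a = 2,
      theta_s = -35, sigma_s = 2,
      tau0_h = 0.05, tau1_h = 0.27, theta_tau_h = -40, sigma_tau_h = -12,
      tau0_n = 0.05, tau1_n = 0.27, theta_tau_n = -40, sigma_tau_n = -12,
      tau0_r = 30, tau1_r = 0, theta_tau_r = 0, sigma_tau_r = 1,
      phi_h = 0.1, phi_n = 0.135, phi_r = 1,
      eps = 0.0055, k1 = 30, k_Ca = 2.4,
      C_m = 1, I_app = if (pd) 4 else 7.7,
      alpha = 5, beta = 0.14, theta_H = -57, sigma_H = 2, theta_pre = 30,
      use_b = FALSE),
    Th = list(
      g_L = 0.05, g_Na = 3, g_K = 5, g_T = 5,
      E_L = -70, E_Na = 50, E_K = -90, E_T = 0,
      C_m = 1))

  if (population != "Th") p$theta_shift <- theta_shift
  p$population <- population
  p$condition <- condition
  structure(p, class = "neuron_parameters")
}

#' @export
print.neuron_parameters <- function(x, ...) {
  cat(sprintf("<neuron_parameters> %s, %s condition\n", x$population,
              x$condition))
  nm <- setdiff(names(x), c("population", "condition", "use_b", "b_form",
                            "theta_shift"))
  vals <- unlist(x[nm])
  print(vals)
  invisible(x)
}

#' Full network preset for one condition
#'
#' Bundles the four population parameter sets with the per-projection
#' synaptic conductances and reversal potentials. The healthy-to-PD switch
#' changes the pallidal and subthalamic applied currents and strengthens the
#' subthalamo-pallidal and intra-pallidal coupling; the GPi-to-thalamus
#' conductance is unchanged.
#'
#' @param condition `"healthy"` or `"PD"`.
#' @param ... Passed to [neuronParameters()] (typo-resolution overrides).
#' @return An object of class `condition_preset` with elements `condition`,
#'   `STN`, `GPe`, `GPi`, `Th` and `syn` (projection constants).
#' @examples
#' conditionPreset("healthy")$syn$g_gpe_stn  # 2.2
#' conditionPreset("PD")$syn$g_gpe_stn       # 7
#' @export
conditionPreset <- function(condition = c("healthy", "PD"), ...) {
  condition <- match.arg(condition)
  pd <- condition == "PD"
  syn <- list(
    g_gpe_stn = if (pd) 7 else 2.2,    E_gpe_stn = -85,
    g_stn_gpe = if (pd) 0.55 else 0.01, E_stn_gpe = 0,
    g_gpe_gpe = if (pd) 0.9 else 0.01,  E_gpe_gpe = -100,
    g_stn_gpi = if (pd) 1.1 else 0.005, E_stn_gpi = 0,
    g_gpe_gpi = if (pd) 1.9 else 0.01,  E_gpe_gpi = -100,
    g_gpi_th = 0.05,                    E_gpi_th = -85)
  structure(list(
    condition = condition,
    STN = neuronParameters("STN", condition, ...),
    GPe = neuronParameters("GPe", condition, ...),
    GPi = neuronParameters("GPi", condition, ...),
    Th = neuronParameters("Th", condition),
    syn = syn), class = "condition_preset")
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf("<condition_preset> %s\n", x$condition))
  cat("  populations: STN, GPe, GPi, Th (20 HH-type cells each by default)\n")
  cat(sprintf("  I_app: STN %.1f, GPe %.1f, GPi %.1f pA/um^2\n",
              x$STN$I_app, x$GPe$I_app, x$GPi$I_app))
  cat(sprintf(
    "  g: GPe->STN %.3g, STN->GPe %.3g, GPe->GPe %.3g, STN->GPi %.3g,\n     GPe->GPi %.3g, GPi->Th %.3g nS/um^2\n",
    x$syn$g_gpe_stn, x$syn$g_stn_gpe, x$syn$g_gpe_gpe, x$syn$g_stn_gpi,
    x$syn$g_gpe_gpi, x$syn$g_gpi_th))
  invisible(x)
}

#' Validate completeness of a parameter set
#'
#' Checks that every symbol the population's vector field looks up is present
#' and finite, and that basic sign constraints hold (conductances and C_m
#' non-negative/positive, baseline time constants positive).
#'
#' @param params A `neuron_parameters` object or plain named list.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validateParameters <- function(params) {
  pop <- params$population
  if (is.null(pop) || !pop %in% POPULATIONS)
    stop("unknown population", call. = FALSE)
  req <- if (pop == "Th") .th_symbols else .bg_symbols
  if (pop == "STN") req <- c(req, "theta_b", "sigma_b")
  missing <- setdiff(req, names(params))
  if (length(missing))
    stop("parameter set for ", pop, " is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  vals <- unlist(params[req])
  if (!all(is.finite(vals)))
    stop("non-finite parameter value in ", pop, " set", call. = FALSE)
  g <- unlist(params[grep("^g_", req, value = TRUE)])
  if (any(g < 0)) stop("negative conductance", call. = FALSE)
  if (params$C_m <= 0) stop("C_m must be positive", call. = FALSE)
  if (pop != "Th") {
    if (any(unlist(params[c("tau0_h", "tau0_n", "tau0_r")]) <= 0))
      stop("tau0 must be positive", call. = FALSE)
    if (any(unlist(params[c("tau1_h", "tau1_n", "tau1_r")]) < 0))
      stop("tau1 must be non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a condition preset as YAML
#'
#' Human-readable serialization of a full preset (one document per
#' population plus the projection block). Numeric values round-trip exactly
#' (full double precision is kept).
#'
#' @param preset A `condition_preset`.
#' @param path File path.
#' @return `writePresetYaml` the path, invisibly; `readPresetYaml` a
#'   `condition_preset`.
#' @export
writePresetYaml <- function(preset, path) {
  stopifnot(inherits(preset, "condition_preset"))
  plain <- list(condition = preset$condition,
                STN = unclass(preset$STN), GPe = unclass(preset$GPe),
                GPi = unclass(preset$GPi), Th = unclass(preset$Th),
                syn = preset$syn)
  yaml::write_yaml(plain, path, precision = 17)
  invisible(path)
}

#' @rdname writePresetYaml
#' @export
readPresetYaml <- function(path) {
  plain <- yaml::read_yaml(path)
  for (pop in POPULATIONS) {
    plain[[pop]] <- structure(plain[[pop]], class = "neuron_parameters")
    validateParameters(plain[[pop]])
  }
  structure(plain[c("condition", POPULATIONS, "syn")],
            class = "condition_preset")
}
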