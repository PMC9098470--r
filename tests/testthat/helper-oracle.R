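# Independent literal transcriptions of the cell equations, written scalar
# and self-contained so they share no code with the package implementation.

oracle_bg_deriv <- function(p, v, nn, h, r, ca, isyn, iapp) {
  lg <- function(x) 1 / (1 + exp(-x))
  minf <- lg((v - p$theta_m) / p$sigma_m)
  ainf <- lg((v - p$theta_a) / p$sigma_a)
  sinf <- lg((v - p$theta_s) / p$sigma_s)
  ninf <- lg((v - p$theta_n) / p$sigma_n)
  hinf <- lg((v - p$theta_h) / p$sigma_h)
  rinf <- lg((v - p$theta_r) / p$sigma_r)
  IL <- p$g_L * (v - p$E_L)
  INa <- p$g_Na * minf^3 * h * (v - p$E_Na)
  IK <- p$g_K * nn^4 * (v - p$E_K)
  ICa <- p$g_Ca * sinf^2 * (v - p$E_Ca)
  tgate <- if (p$population == "STN") {
    b <- 1 / (1 + exp((r - p$theta_b) / p$sigma_b)) -
      1 / (1 + exp(-p$theta_b / p$sigma_b))
    b^2
  } else r
  IT <- p$g_T * ainf^3 * tgate * (v - p$E_Ca)
  IAHP <- p$g_AHP * (v - p$E_K) * ca / (ca + p$k1)
  tau <- function(t0, t1, th, sg)
    if (t1 == 0) t0 else t0 + t1 / (1 + exp(-(v - th) / sg))
  c(v = (-IL - INa - IK - ICa - IT - IAHP - isyn + iapp) / p$C_m,
    n = p$phi_n * (ninf - nn) /
      tau(p$tau0_n, p$tau1_n, p$theta_tau_n, p$sigma_tau_n),
    h = p$phi_h * (hinf - h) /
      tau(p$tau0_h, p$tau1_h, p$theta_tau_h, p$sigma_tau_h),
    r = p$phi_r * (rinf - r) /
      tau(p$tau0_r, p$tau1_r, p$theta_tau_r, p$sigma_tau_r),
    Ca = p$eps * (-ICa - IT - p$k_Ca * ca))
}

oracle_th_deriv <- function(p, v, h, r, igpith, ismc) {
  minf <- 1 / (1 + exp(-(v + 37) / 7))
  pinf <- 1 / (1 + exp(-(v + 60) / 6.2))
  hinf <- 1 / (1 + exp((v + 41) / 4))
  rinf <- 1 / (1 + exp((v + 84) / 4))
  ah <- 0.128 * exp(-(v + 46) / 18)
  bh <- 4 / (1 + exp(-(v + 23) / 5))
  IL <- p$g_L * (v - p$E_L)
  INa <- p$g_Na * minf^3 * h * (v - p$E_Na)
  IK <- p$g_K * (0.75 * (1 - h))^4 * (v - p$E_K)
  IT <- p$g_T * pinf^2 * r * (v - p$E_T)
  c(v = (-IL - INa - IK - IT - igpith + ismc) / p$C_m,
    h = (hinf - h) * (ah + bh),
    r = (rinf - r) / (28 + exp(-(v + 25) / 10.5)))
}
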