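test_that("degenerate limits of the membrane equation are exact", {
  p <- neuronParameters("STN", "healthy")
  for (g in c("g_L", "g_Na", "g_K", "g_T", "g_Ca", "g_AHP")) p[[g]] <- 0
  d <- bgCellDerivatives(list(v = -55, n = .2, h = .4, r = .3, Ca = .1), p,
                         i_syn = 0, i_app = 3.7)
  expect_equal(unname(d$deriv["v"]), 3.7 / p$C_m)
  expect_true(all(d$currents == 0))

  # leak-only cell at its reversal is at equilibrium
  p2 <- neuronParameters("STN", "healthy")
  for (g in c("g_Na", "g_K", "g_T", "g_Ca", "g_AHP")) p2[[g]] <- 0
  d2 <- bgCellDerivatives(list(v = p2$E_L, n = .2, h = .4, r = .3, Ca = 0),
                          p2, i_syn = 0, i_app = 0)
  expect_equal(unname(d2$deriv["v"]), 0)

  th <- neuronParameters("Th", "healthy")
  for (g in c("g_L", "g_Na", "g_K", "g_T")) th[[g]] <- 0
  d3 <- thalamicCellDerivatives(list(v = -60, h = .5, r = .1), th,
                                i_gpi_th = 0, i_smc = 2.5)
  expect_equal(unname(d3$deriv["v"]), 2.5 / th$C_m)
})

test_that("cell vector fields match an independent literal transcription", {
  set.seed(20)
  for (pop in c("STN", "GPe", "GPi")) {
    p <- neuronParameters(pop, sample(c("healthy", "PD"), 1))
    for (k in 1:100) {
      v <- runif(1, -100, 20); nn <- runif(1); h <- runif(1); r <- runif(1)
      ca <- runif(1, 0, 2); isyn <- runif(1, -20, 20)
      got <- bgCellDerivatives(list(v = v, n = nn, h = h, r = r, Ca = ca), p,
                               i_syn = isyn)$deriv
      want <- oracle_bg_deriv(p, v, nn, h, r, ca, isyn, p$I_app)
      expect_equal(unname(got), unname(want), tolerance = 1e-10)
    }
  }
  th <- neuronParameters("Th", "healthy")
  for (k in 1:100) {
    v <- runif(1, -100, 20); h <- runif(1); r <- runif(1)
    ig <- runif(1, 0, 10); is <- runif(1, 0, 5)
    got <- thalamicCellDerivatives(list(v = v, h = h, r = r), th, ig, is)$deriv
    want <- oracle_th_deriv(th, v, h, r, ig, is)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("thalamic gating closed forms hit their printed anchors", {
  th <- neuronParameters("Th", "healthy")
  # h gate midpoint at -41 mV: dh/dt = 0 when h = 1/2 exactly there
  d <- thalamicCellDerivatives(list(v = -41, h = 0.5, r = 0.1), th, 0, 0)
  expect_equal(unname(d$deriv["h"]), 0, tolerance = 1e-12)
  # slow-gate time constant at -25 mV is 28 + e^0 = 29 ms
  r0 <- 0.3
  d2 <- thalamicCellDerivatives(list(v = -25, h = 0.5, r = r0), th, 0, 0)
  rinf <- 1 / (1 + exp((-25 + 84) / 4))
  expect_equal(unname(d2$deriv["r"]), (rinf - r0) / 29, tolerance = 1e-12)
})

test_that("named ionic currents are exposed for diagnostics", {
  p <- neuronParameters("GPe", "PD")
  d <- bgCellDerivatives(list(v = -50, n = .3, h = .5, r = .2, Ca = .3), p)
  expect_named(d$currents, c("I_L", "I_Na", "I_K", "I_Ca", "I_T", "I_AHP"))
  expect_equal(unname(d$currents["I_L"]), p$g_L * (-50 - p$E_L))
  expect_equal(unname(d$currents["I_T"]),
               p$g_T * gatingSteadyState(-50, p$theta_a, p$sigma_a)^3 * 0.2 *
                 (-50 - p$E_Ca))
})

test_that("non-finite states are rejected with the offending name", {
  p <- neuronParameters("STN", "healthy")
  expect_error(
    bgCellDerivatives(list(v = NaN, n = .2, h = .4, r = .3, Ca = .1), p),
    "non-finite state variable: v")
  expect_error(checkGatingRange(c(0.3, 1.2)), "out of range")
  expect_true(checkGatingRange(c(0, 1, 1.005)))
})
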