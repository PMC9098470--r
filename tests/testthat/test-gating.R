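test_that("logistic steady state hits its anchors and rejects sigma = 0", {
  expect_equal(gatingSteadyState(-30, -30, 15), 0.5)
  expect_equal(gatingSteadyState(123.4, 123.4, -7), 0.5)
  # STN n gate one slope-length above midpoint: 1 / (1 + e^-1)
  expect_equal(gatingSteadyState(-24, -32, 8), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_error(gatingSteadyState(-24, -32, 0), "sigma")
})

test_that("steady-state gates are monotone with the sign of sigma and bounded", {
  v <- seq(-100, 50, by = 0.5)
  for (sg in c(8, 7.8, -2, -3.1)) {
    y <- gatingSteadyState(v, -40, sg)
    expect_true(all(y > 0 & y < 1))
    expect_true(all(sign(diff(y)) == sign(sg)))
  }
})

test_that("low-threshold gate b is anchored at zero and matches hand values", {
  expect_equal(bSteadyState(0, 0.4, -0.1), 0)
  # at r = theta_b the logistic term is 1/2
  expect_equal(bSteadyState(0.4, 0.4, -0.1), 0.5 - 1 / (1 + exp(4)),
               tolerance = 1e-12)
  # saturation: logistic term -> 1 for large r with negative slope
  expect_equal(bSteadyState(50, 0.4, -0.1), 1 - 1 / (1 + exp(4)),
               tolerance = 1e-12)
  # printed variant differs only in the offset and loses the zero anchor
  d <- bSteadyState(0, 0.4, -0.1, form = "printed")
  expect_equal(d, 1 / (1 + exp(4)) - exp(-4), tolerance = 1e-12)
  expect_true(abs(d) < 4e-4)
  expect_error(bSteadyState(0.1, 0.4, 0), "sigma")
})

test_that("gating time constant is a bounded logistic in v", {
  # STN h gate at its own midpoint: tau0 + tau1/2
  expect_equal(gatingTimeConstant(-57, 1, 500, -57, -3), 251)
  # negative slope: tau -> tau0 at depolarized voltages
  expect_equal(gatingTimeConstant(1e4, 1, 500, -57, -3), 1)
  v <- seq(-100, 50, 1)
  tau <- gatingTimeConstant(v, 0.05, 0.27, -40, -12)
  expect_true(all(tau >= 0.05 & tau <= 0.32))
  # constant case (pallidal slow gate) ignores the voltage
  expect_equal(gatingTimeConstant(c(-80, 0), 30), c(30, 30))
  expect_error(gatingTimeConstant(-60, 0, 10, -40, -12), "tau0")
})

test_that("synaptic gate kinetics decay, saturate and preserve [0,1]", {
  p <- neuronParameters("STN", "healthy")
  # hyperpolarized presynaptic cell: pure decay at rate beta
  expect_equal(
    synapticGateDerivative(0.5, -1e3, p$alpha, p$beta, p$theta_H, p$sigma_H,
                           p$theta_pre),
    -p$beta * 0.5, tolerance = 1e-12)
  # saturated drive from s = 0: ds/dt = alpha
  expect_equal(
    synapticGateDerivative(0, 1e3, p$alpha, p$beta, p$theta_H, p$sigma_H,
                           p$theta_pre),
    p$alpha, tolerance = 1e-12)
  # fixed point under sustained depolarization: alpha / (alpha + beta)
  sstar <- p$alpha / (p$alpha + p$beta)
  expect_equal(sstar, 2 / 2.08, tolerance = 1e-12)
  expect_equal(
    synapticGateDerivative(sstar, 1e3, p$alpha, p$beta, p$theta_H,
                           p$sigma_H, p$theta_pre),
    0, tolerance = 1e-12)

  # interval preservation under random bounded presynaptic waveforms
  set.seed(41)
  for (rep in 1:5) {
    a <- runif(1, 40, 80); f <- runif(1, 5, 100); ph <- runif(1, 0, 2 * pi)
    s <- runif(1)
    dt <- 0.01
    for (t in seq(0, 50, by = dt)) {
      vpre <- -50 + a * sin(2 * pi * f * t / 1000 + ph)
      s <- s + dt * synapticGateDerivative(s, vpre, p$alpha, p$beta,
                                           p$theta_H, p$sigma_H, p$theta_pre)
      if (s < 0 || s > 1) break
    }
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("synaptic current follows g (v - E) s and validates its inputs", {
  expect_equal(synapticCurrent(-60, 7, -85, 0.5), 87.5)
  expect_equal(synapticCurrent(-60, 7, -85, 0), 0)
  expect_equal(synapticCurrent(-85, 7, -85, 0.73), 0)
  expect_error(synapticCurrent(-60, -1, -85, 0.5), "non-negative")
  expect_error(synapticCurrent(-60, 7, -85, -0.1), "non-negative")
})
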