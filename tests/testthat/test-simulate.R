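# independent bisection oracle for the holding current: settle the
# algebraic steady state for a candidate bias and bisect on the target
.oracle_hold <- function(model, target = -65) {
  area <- model$geom$area
  settle <- function(I) {
    f <- function(V) {
      -(V - model$passive$e_pas) / model$passive$Rm -
        model$ih$gbar * ih_steady_state(V, model$ih) * (V - model$ih$E_h) +
        1e-9 * I / area
    }
    uniroot(f, c(-500, 100), tol = 1e-12)$root
  }
  uniroot(function(I) settle(I) - target, c(-500, 800), tol = 1e-9)$root
}

test_that("holding current follows Ohm's law and the steady-state root", {
  m <- wt1m()
  rest <- steady_state_voltage(m, 0)
  expect_equal(compute_holding_current(m, rest), 0, tolerance = 1e-3)
  m0 <- m; m0$ih$gbar <- 0
  expect_equal(compute_holding_current(m0, -65),
               (-65 - m0$passive$e_pas) * m0$geom$area /
                 m0$passive$Rm * 1e9,
               tolerance = 1e-9)
  expect_equal(compute_holding_current(m0, -65), 158.4, tolerance = 1e-3)
  for (lb in ih_group_params()$label) {
    mi <- cell_from_group(lb)
    expect_equal(compute_holding_current(mi, -65), .oracle_hold(mi),
                 tolerance = 1e-4)
  }
})

test_that("with no I_h the step response is the RC exponential", {
  m <- wt1m(); m$ih$gbar <- 0
  tr <- simulate_step(m, -50)
  tau <- fit_membrane_tau(tr)
  expect_equal(tau, m$passive$Rm * m$passive$Cm / 1e3, tolerance = 0.01)
  expect_lte(as.numeric(measure_sag(tr)), 0.05)
  # mono-exponential: the fitted curve reproduces the decay closely
  w <- ihclamp:::.step_window(tr)
  t <- (seq_along(w) - 1) * tr$dt
  v_ss <- -65 + (-50) * (m$passive$Rm / m$geom$area) * 1e-9  # pA * ohm -> mV
  pred <- v_ss + (-65 - v_ss) * exp(-t / (m$passive$Rm * m$passive$Cm / 1e3))
  expect_lt(max(abs(tr$voltage[w] - pred)), 0.05)
})

test_that("simulated traces agree with an independent stiff-solver run", {
  skip_if_not_installed("deSolve")
  m <- wt1m()
  i_hold <- compute_holding_current(m)
  tr <- simulate_step(m, -50)
  rhs <- function(t, y, parms) {
    I <- i_hold + if (t >= 100 && t < 500) -50 else 0
    dV <- (1 / m$passive$Cm) *
      (-1e3 * (y[1] - m$passive$e_pas) / m$passive$Rm -
         1e3 * m$ih$gbar * y[2] * (y[1] - m$ih$E_h) +
         1e-6 * I / m$geom$area)
    dl <- (ih_steady_state(y[1], m$ih) - y[2]) /
      ih_time_constant(y[1], m$ih, m$temperature)
    list(c(dV, dl))
  }
  times <- seq(0, 600, by = 0.5)
  sol <- deSolve::lsoda(c(V = -65, l = ih_steady_state(-65, m$ih)),
                        times, rhs, NULL, rtol = 1e-9, atol = 1e-9)
  ours <- tr$voltage[round(times / tr$dt) + 1]
  expect_lt(max(abs(ours - sol[, "V"])), 0.1)
  expect_gt(as.numeric(measure_sag(tr)), 0.1)   # I_h sag is present
})

test_that("end-of-step voltages settle at the algebraic steady state for all groups", {
  for (lb in ih_group_params()$label) {
    m <- cell_from_group(lb)
    i_hold <- compute_holding_current(m)
    tr <- simulate_step(m, stim_step(-100, duration = 1500, post = 50),
                        dt = 0.05)
    w <- ihclamp:::.step_window(tr)
    v_end <- tr$voltage[w[length(w)] - 1]
    expect_equal(v_end, steady_state_voltage(m, i_hold - 100),
                 tolerance = 0.1, ignore_attr = TRUE)
  }
})

test_that("solutions are stable under grid refinement", {
  for (lb in c("WT-1m", "AD-10m")) {
    m <- cell_from_group(lb)
    for (amp in c(-200, -50)) {
      a <- simulate_step(m, amp, dt = 0.05)
      b <- simulate_step(m, amp, dt = 0.025)
      idx <- seq(1, length(b$voltage), by = 2)
      expect_lt(max(abs(a$voltage - b$voltage[idx])), 0.05)
    }
  }
})

test_that("sag grows with the peak conductance", {
  m <- wt1m()
  sags <- vapply(c(0, 1, 2, 4) * m$ih$gbar, function(g) {
    mi <- m; mi$ih$gbar <- g
    as.numeric(measure_sag(simulate_step(mi, -100)))
  }, 0)
  expect_lte(sags[1], 0.05)
  expect_true(all(diff(sags) > 0))
})

test_that("protocols produce one sweep per amplitude with shared baseline", {
  expect_identical(protocol_amplitudes(), seq(-200, 400, by = 50))
  expect_length(protocol_amplitudes(), 13)
  m <- wt1m()
  trs <- run_protocol(m, amplitudes = c(-100, -50, 50), dt = 0.05)
  expect_named(trs, c("-100", "-50", "50"))
  for (tr in trs) {
    base <- tr$voltage[trace_time(tr) < tr$stimulus$onset]
    expect_lt(max(abs(base + 65)), 0.1)
  }
  expect_identical(run_protocol(m, amplitudes = numeric(0)),
                   setNames(list(), character(0)))
  expect_error(run_protocol(m, amplitudes = 1e9, dt = 0.05),
               "integration failure")
})
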