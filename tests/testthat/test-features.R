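test_that("resting potential is the baseline mean with the exclusion rule", {
  t0 <- cc_trace(rep(-72, 6001), 0.1, stim_step(0, holding = NA))
  expect_equal(resting_membrane_potential(t0), -72)
  set.seed(3)
  tn <- cc_trace(rep(-72, 6001) + rnorm(6001, 0, 0.5), 0.1,
                 stim_step(0, holding = NA))
  expect_equal(resting_membrane_potential(tn), -72, tolerance = 0.05 / 72)
  # too-short baseline -> missing
  ts <- cc_trace(rep(-72, 6001), 0.1, stim_step(0, onset = 50,
                                                duration = 400, post = 100))
  expect_true(is.na(resting_membrane_potential(ts)))
  expect_true(rmp_excluded(-45))
  expect_false(rmp_excluded(-72))
})

test_that("input resistance from holding current is Ohm's law", {
  expect_equal(input_resistance_hold(-75, 100), 100)
  expect_equal(input_resistance_hold(-70, 50), 100)
  expect_true(is.na(input_resistance_hold(-75, 0)))
  # model-generated cell without I_h: matches Rm/area
  m <- wt1m(); m$ih$gbar <- 0
  rmp <- steady_state_voltage(m, 0)
  ih <- compute_holding_current(m, -65)
  expect_equal(input_resistance_hold(rmp, ih),
               m$passive$Rm / m$geom$area / 1e6, tolerance = 0.02)
})

test_that("input resistance from steady-state steps is the least-squares slope", {
  mk <- function(amp, rin_mohm = 150) {
    v_ss <- -65 + amp * rin_mohm * 1e-3
    exp_step_trace(tau = 5, v_ss = v_ss, amp = amp)
  }
  expect_equal(input_resistance_step(list(mk(-100), mk(-50))), 150,
               tolerance = 1e-3)
  expect_true(is.na(input_resistance_step(list(mk(-50)))))
  # both estimators agree on a model cell (bounded I_h rectification)
  m <- wt1m()
  cellsim <- list(simulate_step(m, -100, dt = 0.05),
                  simulate_step(m, -50, dt = 0.05))
  r2 <- input_resistance_step(cellsim)
  rmp <- steady_state_voltage(m, 0)
  r1 <- input_resistance_hold(rmp, compute_holding_current(m, -65))
  expect_lt(abs(r1 - r2) / r1, 0.10)
})

test_that("membrane time constant fits recover exact exponentials", {
  for (tau in c(5, 20, 50)) {
    tr <- exp_step_trace(tau)
    expect_equal(fit_membrane_tau(tr), tau, tolerance = 1e-3)
  }
  # noisy exponentials stay within 5% of truth across seeds
  errs <- vapply(1:100, function(s) {
    tr <- exp_step_trace(20, noise_sd = 0.2, seed = s)
    fit_membrane_tau(tr) / 20 - 1
  }, 0)
  expect_true(all(abs(errs) < 0.05))
  # positive steps are rejected with a diagnostic
  up <- exp_step_trace(20, v_ss = -55, amp = 50)
  expect_true(is.na(fit_membrane_tau(up)))
})

test_that("sag is the steady-state-minus-minimum deflection, clipped at zero", {
  # smooth valley: min -84 mV, steady -80 mV -> sag 4.0
  dt <- 0.1
  t <- seq(0, 600, by = dt)
  v <- rep(-65, length(t))
  instep <- t >= 100 & t < 500
  ts <- t[instep] - 100
  v[instep] <- -80 - 4 * exp(-((ts - 80) / 40)^2)
  tr <- cc_trace(v, dt, stim_step(-50))
  expect_equal(as.numeric(measure_sag(tr)), 4.0, tolerance = 0.02)
  # monotone RC relaxation has no sag
  expect_lte(as.numeric(measure_sag(exp_step_trace(20))), 0.05)
  # edge minimum (ramp) is flagged with sag 0
  vr <- rep(-65, length(t)); vr[instep] <- -65 - 0.02 * ts
  sr <- measure_sag(cc_trace(vr, dt, stim_step(-50)))
  expect_identical(as.numeric(sr), 0)
  expect_true(attr(sr, "edge"))
})

test_that("spike detection counts threshold crossings at their local maxima", {
  flat <- cc_trace(rep(-65, 24001), 0.025, stim_step(300))
  expect_length(detect_spikes(flat), 0)
  tr <- template_trace(c(120, 180))
  st <- detect_spikes(tr)
  expect_equal(as.numeric(st), c(120, 180), tolerance = 0.025 / 120)
  # sinusoid crossing -10 mV upward three times
  dt <- 0.1; t <- seq(0, 440, by = dt)
  vs <- -20 + 15 * sin(2 * pi * t / 150)
  s3 <- detect_spikes(cc_trace(vs, dt, stim_step(300, onset = 0,
                                                 duration = 400,
                                                 post = 40)))
  expect_length(s3, 3)
})

test_that("first-AP shape features match constructed templates", {
  tr <- template_trace(120, width = 1.20)
  ap <- first_ap_features(tr)
  expect_equal(ap$width_ms, 1.20, tolerance = 0.025 / 1.2)
  expect_equal(ap$peak_mv, -65 + 85, tolerance = 0.5)
  expect_equal(ap$amplitude_mv, 85, tolerance = 0.5)
  expect_equal(ap$time_to_first_ms, 20, tolerance = 0.1)
  # symmetric triangular AP: 2 ms base, 80 mV rise -> width 1.0 ms
  dt <- 0.025; t <- seq(0, 600, by = dt)
  v <- rep(-65, length(t))
  tri <- t >= 200 & t <= 202
  v[tri] <- -65 + 80 * (1 - abs(t[tri] - 201))
  trt <- cc_trace(v, dt, stim_step(300))
  apt <- first_ap_features(trt)
  expect_equal(apt$width_ms, 1.0, tolerance = 0.05)
  # amplitude scaling: width unchanged, max dV/dt scales
  v2 <- rep(-65, length(t)); v2[tri] <- -65 + 120 * (1 - abs(t[tri] - 201))
  ap2 <- first_ap_features(cc_trace(v2, dt, stim_step(300)))
  expect_equal(ap2$width_ms, apt$width_ms, tolerance = 0.03)
  expect_equal(ap2$max_dvdt / apt$max_dvdt, 1.5, tolerance = 0.01)
  # no spike -> all missing
  expect_true(all(is.na(unlist(
    first_ap_features(cc_trace(rep(-65, 24001), 0.025, stim_step(300)))))))
})

test_that("phase-plane samples are consistent with the AP derivative", {
  # pure sine: max dV/dt = A * omega
  dt <- 0.025; t <- seq(0, 600, by = dt)
  A <- 15; period <- 16
  vs <- -20 + A * sin(2 * pi * t / period)
  trs <- cc_trace(vs, dt, stim_step(300))
  pp <- phase_plane(trs)
  expect_gt(nrow(pp), 0)
  expect_equal(max(pp$dvdt), A * 2 * pi / period, tolerance = 1e-3)
  # template trace: phase max equals the first-AP feature
  tr <- template_trace(150)
  expect_equal(max(phase_plane(tr)$dvdt), first_ap_features(tr)$max_dvdt,
               tolerance = 1e-9)
  expect_identical(nrow(phase_plane(cc_trace(rep(-65, 24001), 0.025,
                                             stim_step(300)))), 0L)
})

test_that("instantaneous frequency maps the first ten intervals", {
  expect_equal(instantaneous_frequency(seq(0, 500, by = 50)),
               rep(20, 10))
  f <- instantaneous_frequency(c(100, 120, 160))
  expect_equal(f[1:2], c(50, 25))
  expect_true(all(is.na(f[3:10])))
  acc <- cumsum(c(100, 10 + 2 * (1:11)))
  fa <- instantaneous_frequency(acc)
  expect_true(all(diff(fa) < 0))
  expect_true(all(is.na(instantaneous_frequency(c(100)))))
})

test_that("feature tables are complete, explicit about gaps, and deterministic", {
  g <- default_group_specs(cv = 0.1, noise_sd = 0.1)[["WT-10m"]]
  amps <- c(-200, -100, -50, 100, 300)
  cells <- list()
  for (i in 1:2) {
    cell <- sample_cell(g, 100 + i)
    cells[[paste0("c", i)]] <-
      synthesize_sweeps(cell, amplitudes = amps, dt = 0.05,
                        noise_sd = 0.1, seed = 200 + i,
                        cell_id = paste0("c", i),
                        group_label = g$label)$traces
  }
  ft <- extract_feature_table(cells)
  expect_equal(nrow(ft), 2)
  expect_true(all(c("rmp_mv", "rin_hold_mohm", "sag_mv_m200",
                    "tau_ms_m050", "spike_count_p300",
                    "ap_width_ms_p300", "freq01_hz_p300") %in% names(ft)))
  expect_false(any(is.na(ft$sag_mv_m200)))
  expect_false(any(is.na(ft$spike_count_p300)))
  # absent sweep amplitudes stay NA (no -150 pA sweep in this protocol)
  expect_true(all(is.na(ft$tau_ms_m150)))
  # removing the 300 pA sweep empties the frequency columns only
  cells2 <- cells
  cells2$c1 <- cells2$c1[names(cells2$c1) != "300"]
  ft2 <- extract_feature_table(cells2)
  expect_true(is.na(ft2$freq01_hz_p300[1]))
  expect_false(is.na(ft2$freq01_hz_p300[2]))
  expect_false(is.na(ft2$sag_mv_m200[1]))
  # purity: identical inputs give identical tables
  expect_identical(ft, extract_feature_table(cells))
})
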