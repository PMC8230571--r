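test_that("cell sampling is seed-reproducible with mean-corrected variation", {
  g <- default_group_specs()[["WT-10m"]]
  g0 <- g; g0$cv <- 0
  c0 <- sample_cell(g0, 1)
  expect_equal(c0$model$ih$gbar, g$params$gbar)
  expect_equal(c0$model$passive$Rm, g$params$Rm)
  expect_identical(sample_cell(g, 42), sample_cell(g, 42))
  # lognormal mean correction: empirical mean within 2% at n = 1000
  gb <- vapply(1:1000, function(s) sample_cell(g, s)$model$ih$gbar, 0)
  expect_equal(mean(gb), g$params$gbar, tolerance = 0.02)
  expect_equal(sd(gb) / mean(gb), 0.1, tolerance = 0.15)
})

test_that("noise-free subthreshold sweeps equal the plain model response", {
  g <- default_group_specs()[["WT-1m"]]
  cell <- sample_cell(g, 3)
  sw <- synthesize_sweeps(cell, amplitudes = -50, dt = 0.05, noise_sd = 0,
                          seed = 1, include_rmp = FALSE)
  direct <- simulate_step(cell$model, -50, dt = 0.05)
  expect_equal(sw$traces[["-50"]]$voltage, direct$voltage)
})

test_that("the spiking layer honours rheobase, f-I slope and adaptation", {
  g <- default_group_specs()[["WT-1m"]]
  g$cv <- 0; g$rheobase <- 200; g$fi_slope <- 0.05
  cell <- sample_cell(g, 1)
  sw <- synthesize_sweeps(cell, amplitudes = c(50, 100, 150, 200, 300),
                          dt = 0.05, noise_sd = 0, seed = 1,
                          include_rmp = FALSE)
  counts <- vapply(sw$truth, `[[`, 0, "spike_count")
  expect_identical(unname(counts[1:4]), c(0, 0, 0, 0))  # at/below rheobase
  # 100 pA above rheobase at 0.05 Hz/pA -> 5 Hz -> 2 spikes in 400 ms
  expect_identical(unname(counts[5]), 2)
  expect_equal(1000 * counts[[5]] / 400, 5)
  # adaptation: scheduled ISIs lengthen
  g$fi_slope <- 0.2; g$adapt_ratio <- 2
  cell2 <- sample_cell(g, 1)
  sw2 <- synthesize_sweeps(cell2, amplitudes = 400, dt = 0.05,
                           noise_sd = 0, seed = 1, include_rmp = FALSE)
  isi <- diff(sw2$truth[["400"]]$spike_times)
  expect_true(all(diff(isi) > 0))
})

test_that("sag calibration is a fixed point at matching targets and zeroes at 0", {
  g <- default_group_specs()[["WT-10m"]]
  g$cv <- 0   # fixed-point property on the mean-parameter cell
  m <- cell_from_group("WT-10m")
  cur <- vapply(c(-200, -50), function(a)
    as.numeric(measure_sag(simulate_step(m, a))), 0)
  gc <- calibrate_sag(g, setNames(cur, c(-200, -50)))
  expect_equal(gc$params$gbar, g$params$gbar, tolerance = 1e-9)
  expect_equal(gc$params$kl, g$params$kl, tolerance = 1e-9)
  g0 <- calibrate_sag(g, c("-50" = 0))
  expect_equal(g0$params$gbar, 0)
})

test_that("cohorts are reproducible and protocol-complete", {
  spec <- cohort_spec(default_group_specs(n_cells = rep(2, 6)),
                      amplitudes = c(-200, -50, 300), dt = 0.05, seed = 21)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$cells, co2$cells)
  expect_identical(co1$manifest, co2$manifest)
  expect_length(co1$cells, 12)
  expect_true(all(vapply(co1$cells, length, 0L) == 4))  # 3 sweeps + rmp
})

test_that("extraction closes the loop against generator ground truth", {
  spec <- cohort_spec(default_group_specs(n_cells = rep(2, 6),
                                          noise_sd = 0.2),
                      amplitudes = c(-200, -50, 300), dt = 0.05, seed = 33)
  co <- generate_cohort(spec)
  ft <- extract_feature_table(co$cells)
  man <- co$manifest[ft$cell_id]
  # spike counts are exact
  expect_identical(as.numeric(ft$spike_count_p300),
                   unname(vapply(man, function(m) m$sweeps[["300"]]$spike_count, 0)))
  # AP width within one sample interval
  wtruth <- vapply(man, function(m) m$spiking$ap_width, 0)
  expect_true(all(abs(ft$ap_width_ms_p300 - wtruth) <= 0.05 + 1e-9))
  # instantaneous frequency within 1%
  f1 <- vapply(man, function(m) m$sweeps[["300"]]$inst_freq[[1]], 0)
  expect_true(all(abs(ft$freq01_hz_p300 / f1 - 1) < 0.01))
  # tau within 5% of the noiseless value at 0.2 mV noise
  ttruth <- vapply(man, function(m) m$sweeps[["-200"]]$tau, 0)
  expect_true(all(abs(ft$tau_ms_m200 / ttruth - 1) < 0.05))
  # sag matches exactly on a noiseless cohort
  spec0 <- cohort_spec(default_group_specs(n_cells = rep(1, 6),
                                           noise_sd = 0),
                       amplitudes = c(-200, -50), dt = 0.05, seed = 34)
  co0 <- generate_cohort(spec0)
  ft0 <- extract_feature_table(co0$cells)
  s0 <- vapply(co0$manifest[ft0$cell_id],
               function(m) m$sweeps[["-200"]]$sag, 0)
  expect_true(all(abs(ft0$sag_mv_m200 / s0 - 1) < 0.02))
})

test_that("spike-count and width closure holds over many seeded cells", {
  g <- default_group_specs()[["AD-10m"]]
  bad <- 0L
  for (s in 1:50) {
    cell <- sample_cell(g, 1000 + s)
    sw <- synthesize_sweeps(cell, amplitudes = 300, dt = 0.05,
                            noise_sd = 0.2, seed = 2000 + s,
                            include_rmp = FALSE)
    st <- detect_spikes(sw$traces[["300"]])
    ap <- first_ap_features(sw$traces[["300"]])
    ok <- length(st) == sw$truth[["300"]]$spike_count &&
      abs(ap$width_ms - cell$spiking$template$width) <= 0.05 + 1e-9
    if (!ok) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})
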