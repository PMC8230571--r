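# shared builders for synthetic traces and models

wt1m <- function(...) cell_from_group("WT-1m", ...)

# analytic mono-exponential step response (no I_h), holding -65 mV
exp_step_trace <- function(tau, v_ss = -75, amp = -50, dt = 0.1,
                           onset = 100, duration = 400, post = 100,
                           noise_sd = 0, seed = NULL) {
  t <- seq(0, onset + duration + post, by = dt)
  v <- rep(-65, length(t))
  instep <- t >= onset & t < onset + duration
  v[instep] <- v_ss + (-65 - v_ss) * exp(-(t[instep] - onset) / tau)
  after <- t >= onset + duration
  v_end <- v_ss + (-65 - v_ss) * exp(-duration / tau)
  v[after] <- -65 + (v_end + 65) * exp(-(t[after] - onset - duration) / tau)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + rnorm(length(v), 0, noise_sd)
  }
  cc_trace(v, dt, stim_step(amp, onset = onset, duration = duration,
                            post = post))
}

# flat baseline with AP-template deflections spliced at given times
template_trace <- function(times, width = 1.2, amplitude = 85,
                           rise = 0.4, base = -65, amp_pA = 300,
                           dt = 0.025, onset = 100, duration = 400,
                           post = 100) {
  tpl <- ap_template(width = width, amplitude = amplitude, rise = rise)
  t <- seq(0, onset + duration + post, by = dt)
  v <- rep(base, length(t))
  defl <- ihclamp:::.template_deflection(tpl, dt)
  for (tk in times) {
    i0 <- round((tk - rise) / dt) + 1L
    idx <- i0:min(length(v), i0 + length(defl) - 1L)
    v[idx] <- v[idx] + defl[seq_along(idx)]
  }
  cc_trace(v, dt, stim_step(amp_pA, onset = onset, duration = duration,
                            post = post))
}

# small two-group cohort reused by classifier tests
small_cohort <- function(n = 6, labels = c("WT-10m", "AD-10m"),
                         amplitudes = c(-200, -50, 300), dt = 0.05,
                         seed = 11, cv = 0.1, noise_sd = 0.2) {
  groups <- lapply(labels, function(lb) {
    g <- default_group_specs(cv = cv, noise_sd = noise_sd)[[lb]]
    g$n_cells <- as.integer(n)
    g
  })
  generate_cohort(cohort_spec(groups, amplitudes = amplitudes, dt = dt,
                              seed = seed))
}
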