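#' Analytic action-potential template
#'
#' Deflection waveform spliced onto subthreshold sweeps by the synthetic
#' generator: a linear rise (0 to `amplitude` over `rise` ms) followed by
#' an exponential decay whose rate is chosen so the full width at half
#' height is exactly `width`. The sharp foot makes the derivative-based
#' onset localization exact to one sample.
#'
#' @param width full width at half height, ms (> rise/2)
#' @param amplitude peak deflection above baseline, mV
#' @param rise linear rise time, ms
#' @return an object of class `ap_template`
#' @export
ap_template <- function(width = 1.0, amplitude = 85, rise = 0.4) {
  stopifnot(width > rise / 2, amplitude > 0, rise > 0)
  tau_fall <- (width - rise / 2) / log(2)
  structure(list(width = width, amplitude = amplitude, rise = rise,
                 tau_fall = tau_fall,
                 length_ms = rise + 8 * tau_fall),
            class = "ap_template")
}

.template_deflection <- function(tpl, dt) {
  t <- seq(0, tpl$length_ms, by = dt)
  ifelse(t <= tpl$rise,
         tpl$amplitude * t / tpl$rise,
         tpl$amplitude * exp(-(t - tpl$rise) / tpl$tau_fall))
}

#' Synthetic group specification
#'
#' Describes one cohort group: the subthreshold parameter means (one
#' optimized group parameter row), between-cell variability, recording
#' noise, and the spiking layer (rheobase, frequency-current slope,
#' adaptation, AP template).
#'
#' @param label group label (e.g. `"WT-10m"`)
#' @param n_cells number of cells (>= 1)
#' @param params named list or one-row data.frame with the subthreshold
#'   parameter means (schema of [ih_group_params()])
#' @param cv between-cell coefficient of variation for scale and shape
#'   parameters (Rm, gbar, a0t, zetat, gmt, kl, spiking and template
#'   parameters); lognormal, mean-corrected
#' @param v_sd between-cell standard deviation of the voltage location
#'   parameters (e_pas, Vl_half, Vt_half), mV; additive Gaussian.
#'   Half-voltages vary by a few millivolts between cells, not by a
#'   fixed fraction of their distance to 0 mV
#' @param noise_sd additive white recording noise, mV
#' @param rheobase minimal spiking current, pA
#' @param fi_slope frequency-current slope above rheobase, Hz/pA
#' @param adapt_ratio ISI_10 / ISI_1 adaptation ratio (>= 1 slows down)
#' @param ap_width,ap_amp,ap_rise AP template parameters, see
#'   [ap_template()]
#' @param area membrane area, cm^2 (single-compartment)
#' @return an object of class `group_spec`
#' @export
group_spec <- function(label, n_cells, params, cv = 0.1, v_sd = 2,
                       noise_sd = 0.2,
                       rheobase = 75, fi_slope = 0.08, adapt_ratio = 2,
                       ap_width = 1.0, ap_amp = 85, ap_rise = 0.4,
                       area = 2.0e-4) {
  stopifnot(n_cells >= 1, cv >= 0, v_sd >= 0, noise_sd >= 0, ap_width > 0,
            fi_slope > 0, rheobase > 0, adapt_ratio > 0)
  if (is.data.frame(params)) params <- as.list(params[1, ])
  need <- c("Rm", "e_pas", "gbar", "Vl_half", "kl", "Vt_half", "a0t",
            "zetat", "gmt")
  stopifnot(all(need %in% names(params)))
  structure(list(label = label, n_cells = as.integer(n_cells),
                 params = params[need], cv = cv, v_sd = v_sd,
                 noise_sd = noise_sd,
                 rheobase = rheobase, fi_slope = fi_slope,
                 adapt_ratio = adapt_ratio, ap_width = ap_width,
                 ap_amp = ap_amp, ap_rise = ap_rise, area = area),
            class = "group_spec")
}

#' Default six-group cohort specification
#'
#' Group sizes mirror the study cohort (14, 12, 19, 11, 15, 21 cells);
#' subthreshold means are the six optimized parameter rows; the spiking
#' defaults encode the qualitative group differences (wider first AP in
#' the youngest model group, narrower AP and flatter adaptation with
#' strong amyloidopathy).
#'
#' @param n_cells optional vector (length 6, order WT-1m, AD-1m, WT-4m,
#'   AD-4m, WT-10m, AD-10m) overriding the group sizes
#' @param cv,v_sd,noise_sd shared variability and noise settings
#' @return list of six [group_spec()]
#' @export
default_group_specs <- function(n_cells = NULL, cv = 0.1, v_sd = 2,
                                noise_sd = 0.2) {
  tab <- ih_group_params()
  order <- c("WT-1m", "AD-1m", "WT-4m", "AD-4m", "WT-10m", "AD-10m")
  n <- c("WT-1m" = 14, "AD-1m" = 11, "WT-4m" = 12, "AD-4m" = 15,
         "WT-10m" = 19, "AD-10m" = 21)
  if (!is.null(n_cells)) n[order] <- n_cells
  tweak <- list(
    "WT-1m"  = list(ap_width = 1.00, fi_slope = 0.080, adapt_ratio = 2.0),
    "AD-1m"  = list(ap_width = 1.15, fi_slope = 0.065, adapt_ratio = 2.0),
    "WT-4m"  = list(ap_width = 1.00, fi_slope = 0.080, adapt_ratio = 2.0),
    "AD-4m"  = list(ap_width = 0.90, fi_slope = 0.080, adapt_ratio = 2.0),
    "WT-10m" = list(ap_width = 1.00, fi_slope = 0.080, adapt_ratio = 2.0),
    "AD-10m" = list(ap_width = 0.85, fi_slope = 0.090, adapt_ratio = 1.3))
  out <- lapply(order, function(lb) {
    tw <- tweak[[lb]]
    group_spec(lb, n[[lb]], ih_group_params(lb), cv = cv, v_sd = v_sd,
               noise_sd = noise_sd, ap_width = tw$ap_width,
               fi_slope = tw$fi_slope, adapt_ratio = tw$adapt_ratio)
  })
  names(out) <- order
  out
}

.jitter_ln <- function(m, cv, n = 1) {
  if (cv == 0) return(rep(m, n))
  s <- sqrt(log(1 + cv^2))
  m * exp(rnorm(n, -s^2 / 2, s))   # mean-corrected: E[x] = m
}

#' Sample one synthetic cell from a group specification
#'
#' Parameters vary multiplicatively (lognormal on magnitudes, mean
#' corrected so the expectation equals the group mean); reproducible per
#' seed.
#'
#' @param g a [group_spec()]
#' @param seed integer seed
#' @return list with `model` (a [cell_model()]), `spiking` (rheobase,
#'   f-I slope, adaptation ratio, [ap_template()]), and `seed`
#' @export
sample_cell <- function(g, seed) {
  stopifnot(inherits(g, "group_spec"))
  .with_seed(seed, {
    p <- g$params
    jit <- function(x) .jitter_ln(abs(x), g$cv) * sign(x)   # scale/shape
    jv <- function(x) x + rnorm(1, 0, g$v_sd)               # voltage location
    pv <- list(Rm = jit(p$Rm), e_pas = jv(p$e_pas), gbar = jit(p$gbar),
               Vl_half = jv(p$Vl_half), kl = jit(p$kl),
               Vt_half = jv(p$Vt_half), a0t = jit(p$a0t),
               zetat = jit(p$zetat),
               gmt = min(0.95, max(0.05, jit(p$gmt))))
    pv$e_pas <- min(-40.1, max(-119.9, pv$e_pas))
    model <- cell_model(
      passive_params(Rm = pv$Rm, e_pas = pv$e_pas),
      ih_params(gbar = pv$gbar, Vl_half = pv$Vl_half, kl = pv$kl,
                Vt_half = pv$Vt_half, a0t = pv$a0t, zetat = pv$zetat,
                gmt = pv$gmt),
      geom_single(area = g$area))
    spiking <- list(rheobase = .jitter_ln(g$rheobase, g$cv),
                    fi_slope = .jitter_ln(g$fi_slope, g$cv),
                    adapt_ratio = max(1, .jitter_ln(g$adapt_ratio, g$cv)),
                    template = ap_template(
                      width = .jitter_ln(g$ap_width, g$cv / 2),
                      amplitude = .jitter_ln(g$ap_amp, g$cv / 2),
                      rise = g$ap_rise))
    list(model = model, spiking = spiking, seed = seed)
  })
}

# Deterministic spike schedule from the f-I law: N spikes at mean rate
# slope*(amp - rheobase), geometric ISI progression with ratio
# adapt^(1/9) (ISI_10/ISI_1 = adapt), all spikes inside the step.
.schedule_spikes <- function(spiking, amp, onset, duration) {
  if (amp <= spiking$rheobase) return(numeric(0))
  f_mean <- spiking$fi_slope * (amp - spiking$rheobase)   # Hz
  N <- max(1L, round(f_mean * duration / 1000))
  lat <- duration / (2 * N)
  if (N == 1L) return(onset + lat)
  gr <- spiking$adapt_ratio^(1 / 9)
  raw <- gr^(0:(N - 2))
  isis <- raw * (duration * (N - 1) / N) / sum(raw)
  onset + lat + c(0, cumsum(isis))
}

#' Synthesize the sweep family of one cell
#'
#' Subthreshold steps are simulated with the cell's passive + I_h model.
#' For suprathreshold steps the inter-spike trajectory is the model's
#' response to an effective drive clamped at rheobase (spiking holds the
#' membrane near threshold) and the cell's AP template is spliced at
#' deterministically scheduled times given by its f-I law, so spike
#' count, instantaneous frequencies and AP width have exact ground truth.
#' White Gaussian recording noise is added last.
#'
#' @param cell a cell from [sample_cell()]
#' @param amplitudes protocol step amplitudes, pA
#' @param dt sampling step, ms
#' @param noise_sd additive noise, mV
#' @param seed integer seed for the noise
#' @param onset,duration,holding,post stimulus layout, ms / mV
#' @param include_rmp also synthesize an unclamped 0-pA sweep
#'   (`sweep_id = "rmp"`) for the resting potential
#' @param cell_id,group_label identifiers stored in the traces
#' @return list with `traces` (list of [cc_trace()]) and `truth` (per-sweep
#'   ground-truth records: spike times, count, instantaneous frequencies,
#'   AP width; noiseless sag and fitted tau for hyperpolarizing sweeps)
#' @export
synthesize_sweeps <- function(cell, amplitudes = protocol_amplitudes(),
                              dt = 0.025, noise_sd = 0.2, seed = 1,
                              onset = 100, duration = 400, holding = -65,
                              post = 100, include_rmp = TRUE,
                              cell_id = NA_character_,
                              group_label = NA_character_) {
  spk <- cell$spiking
  traces <- list()
  truth <- list()
  .with_seed(seed, {
    for (i in seq_along(amplitudes)) {
      a <- amplitudes[i]
      times <- .schedule_spikes(spk, a, onset, duration)
      if (length(times) >= 2 && min(diff(times)) <= spk$template$length_ms)
        stop("AP template longer than the shortest scheduled ISI at ",
             a, " pA")
      eff <- if (length(times) > 0) spk$rheobase else a
      core <- simulate_step(cell$model,
                            stim_step(a, onset = onset, duration = duration,
                                      holding = holding, post = post),
                            dt = dt, cell_id = cell_id,
                            group_label = group_label,
                            sweep_id = sprintf("sweep%02d", i))
      if (length(times) > 0) {
        drive <- simulate_step(cell$model,
                               stim_step(eff, onset = onset,
                                         duration = duration,
                                         holding = holding, post = post),
                               dt = dt)
        v <- drive$voltage
        defl <- .template_deflection(spk$template, dt)
        for (tk in times) {
          i0 <- round((tk - spk$template$rise) / dt) + 1L
          idx <- i0:min(length(v), i0 + length(defl) - 1L)
          v[idx] <- v[idx] + defl[seq_along(idx)]
        }
      } else {
        v <- core$voltage
      }
      tw <- list(amplitude = a,
                 spike_times = times,
                 spike_count = length(times),
                 inst_freq = instantaneous_frequency(times),
                 ap_width = if (length(times) > 0) spk$template$width else NA_real_)
      if (a < 0) {
        tw$sag <- as.numeric(measure_sag(core))
        tw$tau <- as.numeric(fit_membrane_tau(core))
      }
      if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
      traces[[i]] <- cc_trace(v, dt, core$stimulus, cell_id = cell_id,
                              group_label = group_label,
                              sweep_id = core$sweep_id,
                              i_hold = core$i_hold)
      truth[[i]] <- tw
    }
    names(traces) <- as.character(amplitudes)
    names(truth) <- as.character(amplitudes)
    if (include_rmp) {
      rest <- steady_state_voltage(cell$model, 0)
      rt <- simulate_step(cell$model,
                          stim_step(0, onset = onset, duration = duration,
                                    holding = NA, post = post),
                          dt = dt, cell_id = cell_id,
                          group_label = group_label, sweep_id = "rmp")
      v <- rt$voltage
      if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
      traces$rmp <- cc_trace(v, dt, rt$stimulus, cell_id = cell_id,
                             group_label = group_label, sweep_id = "rmp",
                             i_hold = 0)
      truth$rmp <- list(amplitude = 0, rmp = rest)
    }
  })
  list(traces = traces, truth = truth)
}

#' Calibrate a group's sag amplitudes to target means
#'
#' Adjusts the peak I_h conductance (multiplicative scale) and, when more
#' than one target is given, the activation shape factor `kl`, so that the
#' noiseless group-mean cell reproduces the target sag amplitude at each
#' given step amplitude (as measured by [measure_sag()] on simulated
#' sweeps).
#'
#' @param g a [group_spec()]
#' @param targets named numeric vector: names are step amplitudes (pA),
#'   values target sag amplitudes (mV)
#' When the group has between-cell variability (`cv > 0`) the calibrated
#' quantity is the expected cohort-mean sag, estimated on a fixed set of
#' `n_mc` seeded parameter draws: the sag response is concave in the
#' parameters, so the cohort mean lies below the sag of the mean-parameter
#' cell and calibrating the latter would bias generated cohorts low.
#'
#' @param tol acceptable relative mismatch per target (default 2%)
#' @param scale_range allowed conductance scale range
#' @param kl_range allowed `kl` range
#' @param dt simulation step, ms
#' @param n_mc number of seeded parameter draws used to estimate the
#'   cohort-mean sag when `g$cv > 0`
#' @param mc_seed base seed of those draws
#' @param strict error when a target cannot be met within `tol` (default);
#'   with `strict = FALSE` the best-effort calibration is returned with a
#'   warning
#' @return the adjusted [group_spec()], with attribute `"calibration"`
#'   (scale, kl, achieved sag per target)
#' @export
calibrate_sag <- function(g, targets, tol = 0.02,
                          scale_range = c(0.05, 400),
                          kl_range = c(-40, -2), dt = 0.025,
                          n_mc = 12, mc_seed = 1000, strict = TRUE) {
  stopifnot(inherits(g, "group_spec"), length(targets) >= 1,
            !is.null(names(targets)))
  amps <- as.numeric(names(targets))
  stopifnot(all(amps < 0), all(targets >= 0))
  base_model <- cell_model(
    passive_params(Rm = g$params$Rm, e_pas = g$params$e_pas),
    ih_params(gbar = g$params$gbar, Vl_half = g$params$Vl_half,
              kl = g$params$kl, Vt_half = g$params$Vt_half,
              a0t = g$params$a0t, zetat = g$params$zetat,
              gmt = g$params$gmt),
    geom_single(area = g$area))
  sag_of_model <- function(m) {
    vapply(amps, function(a)
      as.numeric(measure_sag(simulate_step(m, a, dt = dt))), 0)
  }
  sag_at <- function(scale, kl) {
    g2 <- g
    g2$params$gbar <- g$params$gbar * scale
    g2$params$kl <- kl
    if (g$cv == 0 || n_mc <= 1) {
      m <- base_model
      m$ih$gbar <- g2$params$gbar
      m$ih$kl <- g2$params$kl
      return(sag_of_model(m))
    }
    draws <- vapply(seq_len(n_mc), function(i)
      sag_of_model(sample_cell(g2, mc_seed + i)$model),
      numeric(length(amps)))
    if (length(amps) == 1) mean(draws) else rowMeans(draws)
  }
  finish <- function(scale, kl) {
    ach <- sag_at(scale, kl)
    rel <- ifelse(targets > 0, abs(ach / targets - 1), abs(ach))
    if (any(rel > tol)) {
      msg <- sprintf(
        "sag targets not attainable within %.0f%% (achieved: %s; targets: %s)",
        100 * tol, paste(signif(ach, 3), collapse = ", "),
        paste(targets, collapse = ", "))
      if (strict) stop(msg) else warning(msg, call. = FALSE)
    }
    out <- g
    out$params$gbar <- g$params$gbar * scale
    out$params$kl <- kl
    attr(out, "calibration") <- list(scale = scale, kl = kl,
                                     achieved = setNames(ach, names(targets)))
    out
  }
  if (all(targets == 0)) return(finish(0, g$params$kl))
  if (length(targets) == 1) {
    f <- function(ls) sag_at(exp(ls), g$params$kl)[1] - targets[[1]]
    lo <- log(scale_range[1]); hi <- log(scale_range[2])
    if (f(lo) > 0 || f(hi) < 0) {
      # no sign change: report attainable range
      return(finish(if (f(lo) > 0) scale_range[1] else scale_range[2],
                    g$params$kl))
    }
    r <- uniroot(f, c(lo, hi), tol = 1e-6)
    return(finish(exp(r$root), g$params$kl))
  }
  kl0 <- max(kl_range[1], min(kl_range[2], g$params$kl))
  obj <- function(th) {
    ach <- sag_at(exp(th[1]), th[2])
    sum((ach / targets - 1)^2) +
      1e-5 * (th[1]^2 + ((th[2] - kl0) / 10)^2)
  }
  o <- optim(c(log(4), kl0), obj, method = "L-BFGS-B",
             lower = c(log(scale_range[1]), kl_range[1]),
             upper = c(log(scale_range[2]), kl_range[2]),
             control = list(maxit = 300))
  # keep the no-change solution when the spec already matches
  if (obj(c(0, kl0)) <= o$value) o$par <- c(0, kl0)
  finish(exp(o$par[1]), o$par[2])
}

#' Cohort specification
#'
#' @param groups list of [group_spec()] (unique labels)
#' @param amplitudes protocol amplitudes, pA
#' @param dt sampling step, ms
#' @param seed master seed; every cell's parameters and noise derive from
#'   it
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(groups, amplitudes = protocol_amplitudes(),
                        dt = 0.025, seed = 1) {
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, TRUE, what = "group_spec")))
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("group labels must be unique")
  groups <- lapply(groups, function(g) { g$n_cells <- as.integer(g$n_cells); g })
  names(groups) <- labels
  structure(list(groups = groups, amplitudes = amplitudes, dt = dt,
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Generate a labelled synthetic cohort
#'
#' Fully reproducible from the master seed; the manifest records every
#' cell's sampled parameters and per-sweep ground truth.
#'
#' @param spec a [cohort_spec()]
#' @return an object of class `ih_cohort`: `cells` (named list of sweep
#'   lists), `manifest` (named list of ground-truth records), `spec`
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- sum(vapply(spec$groups, `[[`, 1L, "n_cells"))
  seeds <- .with_seed(spec$seed, sample.int(2147483646L, 2 * n_total))
  cells <- list()
  manifest <- list()
  k <- 0L
  for (g in spec$groups) {
    for (i in seq_len(g$n_cells)) {
      k <- k + 1L
      id <- sprintf("%s_c%02d", g$label, i)
      cell <- sample_cell(g, seeds[2 * k - 1])
      sw <- synthesize_sweeps(cell, amplitudes = spec$amplitudes,
                              dt = spec$dt, noise_sd = g$noise_sd,
                              seed = seeds[2 * k], cell_id = id,
                              group_label = g$label)
      cells[[id]] <- sw$traces
      manifest[[id]] <- list(
        cell_id = id, group_label = g$label,
        param_seed = seeds[2 * k - 1], noise_seed = seeds[2 * k],
        params = .par_of_model(cell$model),
        spiking = list(rheobase = cell$spiking$rheobase,
                       fi_slope = cell$spiking$fi_slope,
                       adapt_ratio = cell$spiking$adapt_ratio,
                       ap_width = cell$spiking$template$width,
                       ap_amp = cell$spiking$template$amplitude,
                       ap_rise = cell$spiking$template$rise),
        sweeps = sw$truth)
    }
  }
  structure(list(cells = cells, manifest = manifest, spec = spec),
            class = "ih_cohort")
}

#' @export
print.ih_cohort <- function(x, ...) {
  cat(sprintf("<ih_cohort> %d cells in %d groups, %d sweeps/cell, seed %d\n",
              length(x$cells), length(x$spec$groups),
              length(x$spec$amplitudes), x$spec$seed))
  invisible(x)
}
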