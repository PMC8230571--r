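#' Spike detection configuration
#'
#' @param threshold detection threshold, mV (default -10: a crossing above
#'   this level counts as an action potential)
#' @param onset_dvdt AP-onset criterion on the voltage derivative, mV/ms
#' @return an object of class `spike_config`
#' @export
spike_config <- function(threshold = -10, onset_dvdt = 20) {
  stopifnot(threshold > -50, onset_dvdt > 0)
  structure(list(threshold = threshold, onset_dvdt = onset_dvdt),
            class = "spike_config")
}

.step_window <- function(trace) {
  t <- trace_time(trace)
  which(t >= trace$stimulus$onset &
        t <= trace$stimulus$onset + trace$stimulus$duration)
}

# boxcar smooth used before taking the trace minimum: the raw minimum of
# thousands of noisy samples is an extreme order statistic biased low by
# several noise SDs
.smooth <- function(v, dt, width_ms = 2) {
  k <- max(1L, round(width_ms / dt))
  if (k <= 1L) return(v)
  sm <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- v[is.na(sm)]   # keep raw values at the window edges
  sm
}

#' Resting membrane potential from an unstimulated baseline
#'
#' Mean of the pre-stimulus baseline (or of an unclamped 0-pA sweep).
#' Cells with RMP above -50 mV should be excluded from analysis; use
#' [rmp_excluded()].
#'
#' @param trace a [cc_trace()]; at least 100 ms of baseline before the
#'   stimulus onset are required
#' @return RMP, mV (NA if there is no usable baseline)
#' @export
resting_membrane_potential <- function(trace) {
  stopifnot(inherits(trace, "cc_trace"))
  t <- trace_time(trace)
  base <- trace$voltage[t < trace$stimulus$onset]
  if (length(base) * trace$dt < 100) return(NA_real_)
  mean(base)
}

#' Exclusion rule for abnormally depolarized cells
#' @param rmp resting membrane potential, mV
#' @return TRUE if the cell should be excluded (RMP > -50 mV)
#' @export
rmp_excluded <- function(rmp) {
  !is.na(rmp) & rmp > -50
}

#' Input resistance from the holding current (Ohm's law)
#'
#' `(-65 - RMP) / I_hold`, the voltage moved from rest to the holding
#' target per unit bias current.
#'
#' @param rmp resting membrane potential, mV
#' @param i_hold holding current, pA (non-zero)
#' @param holding holding target, mV
#' @return input resistance, Mohm (NA when I_hold is 0 or missing)
#' @export
input_resistance_hold <- function(rmp, i_hold, holding = -65) {
  if (is.na(i_hold) || i_hold == 0 || is.na(rmp)) return(NA_real_)
  1e3 * (holding - rmp) / i_hold
}

#' Input resistance from steady-state step responses
#'
#' Least-squares slope of the end-of-step voltage deflection against step
#' current over small negative steps.
#'
#' @param traces list of [cc_trace()] (hyperpolarizing sweeps)
#' @param amplitudes which step amplitudes to use, pA
#' @return input resistance, Mohm (NA with fewer than 2 usable sweeps)
#' @export
input_resistance_step <- function(traces, amplitudes = c(-100, -50)) {
  use <- Filter(function(tr) tr$stimulus$amplitude %in% amplitudes, traces)
  if (length(use) < 2) return(NA_real_)
  di <- vapply(use, function(tr) tr$stimulus$amplitude, 0)
  dv <- vapply(use, function(tr) {
    w <- .step_window(tr)
    n <- length(w)
    steady <- mean(tr$voltage[w[(floor(0.9 * n) + 1):n]])
    base <- mean(tr$voltage[seq_len(w[1] - 1)])
    steady - base
  }, 0)
  1e3 * unname(coef(lm(dv ~ di))[2])
}

#' Membrane time constant fitted up to the sag peak
#'
#' Least-squares fit of `V(t) = V_ss + (V_on - V_ss) exp(-(t - t_on)/tau)`
#' over the window from the stimulus onset to the voltage minimum (the peak
#' of the sag). The two linear coefficients are profiled out; `tau` is
#' optimized on (0.5, 200\] ms.
#'
#' @param trace a hyperpolarizing [cc_trace()] (step amplitude < 0)
#' @return tau, ms; NA with attribute `"diagnostic"` when the fit fails or
#'   hits the search boundary
#' @export
fit_membrane_tau <- function(trace) {
  stopifnot(inherits(trace, "cc_trace"))
  if (trace$stimulus$amplitude >= 0)
    return(structure(NA_real_, diagnostic = "not a hyperpolarizing sweep"))
  w <- .step_window(trace)
  v <- trace$voltage[w]
  sm <- .smooth(v, trace$dt)
  imin <- which.min(sm)
  if (imin < 5)
    return(structure(NA_real_, diagnostic = "no relaxation before minimum"))
  tt <- (seq_len(imin) - 1) * trace$dt
  vv <- v[seq_len(imin)]
  rss <- function(tau) {
    X <- cbind(1, exp(-tt / tau))
    r <- stats::lsfit(X, vv, intercept = FALSE)$residuals
    sum(r * r)
  }
  opt <- optimize(rss, c(0.5, 200))
  tau <- opt$minimum
  if (tau < 0.55 || tau > 199)
    return(structure(NA_real_, diagnostic = "tau at search boundary"))
  tau
}

#' Sag amplitude of a hyperpolarizing step
#'
#' Difference between the steady-state voltage at the end of the stimulus
#' (mean over the last 10% of the step) and the minimal voltage reached
#' during the step, clipped at 0. The minimum is taken on a lightly
#' smoothed copy of the trace (2 ms boxcar) so that recording noise does
#' not bias this order statistic.
#'
#' @param trace a hyperpolarizing [cc_trace()]
#' @return sag, mV (>= 0); attribute `"edge"` is TRUE when the minimum sits
#'   at the window edge (no relaxation)
#' @export
measure_sag <- function(trace) {
  stopifnot(inherits(trace, "cc_trace"))
  if (trace$stimulus$amplitude >= 0)
    return(structure(NA_real_, edge = FALSE))
  w <- .step_window(trace)
  v <- trace$voltage[w]
  n <- length(v)
  sm <- .smooth(v, trace$dt)
  imin <- which.min(sm)
  steady <- mean(v[(floor(0.9 * n) + 1):n])
  sag <- max(0, steady - sm[imin])
  edge <- imin <= 2 || imin >= n - 1
  structure(if (edge) 0 else sag, edge = edge)
}

#' Detect action potentials by threshold crossing
#'
#' One event per upward crossing of the detection threshold; the event time
#' is the time of the local voltage maximum between the upward and the next
#' downward crossing.
#'
#' @param trace a [cc_trace()]
#' @param cfg a [spike_config()]
#' @return numeric vector of spike times, ms; attribute `"truncated"` is
#'   TRUE when the trace ends mid-spike
#' @export
detect_spikes <- function(trace, cfg = spike_config()) {
  stopifnot(inherits(trace, "cc_trace"))
  v <- trace$voltage
  above <- v >= cfg$threshold
  up <- which(diff(above) == 1) + 1L
  down <- which(diff(above) == -1)
  truncated <- FALSE
  times <- numeric(0)
  for (u in up) {
    d <- down[down >= u][1]
    if (is.na(d)) { d <- length(v); truncated <- TRUE }
    ipk <- u - 1L + which.max(v[u:d])
    times <- c(times, (ipk - 1L) * trace$dt)
  }
  structure(times, truncated = truncated)
}

.dvdt <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

#' Shape features of the first action potential
#'
#' Onset is the first sample of the final run with `dV/dt >=` the onset
#' criterion before the peak; amplitude is peak minus onset voltage; width
#' is the full width at the voltage halfway between onset voltage and peak
#' (linear interpolation between samples); the maximal `dV/dt` comes from
#' centered finite differences.
#'
#' @param trace a [cc_trace()] with at least one spike
#' @param cfg a [spike_config()]
#' @return named list with `width_ms`, `amplitude_mv`, `peak_mv`,
#'   `onset_mv`, `max_dvdt`, `time_to_first_ms` (all NA when there is no
#'   spike)
#' @export
first_ap_features <- function(trace, cfg = spike_config()) {
  nafeat <- list(width_ms = NA_real_, amplitude_mv = NA_real_,
                 peak_mv = NA_real_, onset_mv = NA_real_,
                 max_dvdt = NA_real_, time_to_first_ms = NA_real_)
  st <- detect_spikes(trace, cfg)
  if (length(st) == 0) return(nafeat)
  dt <- trace$dt
  ipk <- round(st[1] / dt) + 1L
  v <- trace$voltage
  d <- .dvdt(v, dt)
  # search back from the peak for the start of the suprathreshold-dV/dt run
  i0 <- max(1L, ipk - round(25 / dt))
  run <- which(d[i0:ipk] >= cfg$onset_dvdt)
  if (length(run) == 0) return(nafeat)
  # first index of the run that ends nearest the peak
  brk <- c(0, which(diff(run) > 1))
  ion <- i0 - 1L + run[brk[length(brk)] + 1L]
  onset_v <- v[ion]
  peak_v <- v[ipk]
  half <- (onset_v + peak_v) / 2
  # crossing times at the half level on either flank (linear interpolation)
  iup <- ipk
  while (iup > ion && v[iup - 1] > half) iup <- iup - 1L
  t_up <- if (iup == ion) (ion - 1) * dt else
    ((iup - 2) + (half - v[iup - 1]) / (v[iup] - v[iup - 1])) * dt
  idn <- ipk
  iend <- min(length(v), ipk + round(25 / dt))
  while (idn < iend && v[idn + 1] > half) idn <- idn + 1L
  t_dn <- if (idn == iend) (idn - 1) * dt else
    ((idn - 1) + (half - v[idn]) / (v[idn + 1] - v[idn])) * dt
  w_spk <- max(1L, ion - round(2 / dt)):min(length(v), ipk + round(10 / dt))
  list(width_ms = t_dn - t_up,
       amplitude_mv = peak_v - onset_v,
       peak_mv = peak_v,
       onset_mv = onset_v,
       max_dvdt = max(d[w_spk]),
       time_to_first_ms = st[1] - trace$stimulus$onset)
}

#' Phase-plane samples (dV/dt vs V) around the first action potential
#'
#' @param trace a [cc_trace()] with at least one spike
#' @param cfg a [spike_config()]
#' @param window_ms half-width of the window around the first spike, ms
#' @return data.frame with columns `v` (mV) and `dvdt` (mV/ms); zero rows
#'   when there is no spike
#' @export
phase_plane <- function(trace, cfg = spike_config(), window_ms = 5) {
  st <- detect_spikes(trace, cfg)
  if (length(st) == 0) return(data.frame(v = numeric(0), dvdt = numeric(0)))
  dt <- trace$dt
  ipk <- round(st[1] / dt) + 1L
  w <- max(1L, ipk - round(window_ms / dt)):
       min(length(trace$voltage), ipk + round(window_ms / dt))
  d <- .dvdt(trace$voltage, dt)
  data.frame(v = trace$voltage[w], dvdt = d[w])
}

#' Instantaneous frequencies from the first inter-spike intervals
#'
#' @param spike_times spike times, ms
#' @param n number of intervals to report (default 10)
#' @return numeric vector of length `n`: `f_i = 1000/ISI_i`, Hz; entries
#'   beyond the available intervals are NA
#' @export
instantaneous_frequency <- function(spike_times, n = 10) {
  out <- rep(NA_real_, n)
  if (length(spike_times) < 2) return(out)
  isi <- diff(sort(spike_times))
  k <- min(n, length(isi))
  out[seq_len(k)] <- 1000 / isi[seq_len(k)]
  out
}

.amp_suffix <- function(a) sprintf("%s%03d", ifelse(a < 0, "m", "p"), abs(a))

#' Feature-table column catalogue
#'
#' @param tau_amps,sag_amps hyperpolarizing amplitudes, pA
#' @param spike_amps depolarizing amplitudes, pA
#' @param freq_amp amplitude for the instantaneous-frequency features, pA
#' @return character vector of feature-table column names
#' @export
feature_columns <- function(tau_amps = c(-200, -150, -100, -50),
                            sag_amps = c(-200, -150, -100, -50),
                            spike_amps = seq(50, 400, 50),
                            freq_amp = 300) {
  c("rmp_mv", "rin_hold_mohm", "rin_step_mohm",
    paste0("tau_ms_", vapply(tau_amps, .amp_suffix, "")),
    paste0("sag_mv_", vapply(sag_amps, .amp_suffix, "")),
    paste0("spike_count_", vapply(spike_amps, .amp_suffix, "")),
    as.vector(t(outer(c("ap_width_ms_", "ap_amp_mv_", "ap_peak_mv_",
                        "ap_onset_mv_", "ap_maxdvdt_", "ttfs_ms_"),
                      vapply(spike_amps, .amp_suffix, ""), paste0))),
    sprintf("freq%02d_hz_%s", 1:10, .amp_suffix(freq_amp)),
    "mean_freq_hz", "isi_adapt")
}

#' Extract the per-cell feature table from sweep families
#'
#' One row per cell. Missing features are explicit NAs, never silent
#' zeros; cells whose sweep set cannot be processed are skipped with a
#' warning.
#'
#' @param cells named list; each element is a list of [cc_trace()] sweeps
#'   for one cell (optionally including an unclamped 0-pA sweep for the
#'   resting potential, `sweep_id == "rmp"`)
#' @param cfg a [spike_config()]
#' @param tau_amps,sag_amps,spike_amps,freq_amp which amplitudes feed which
#'   features (defaults follow the standard -200..400 pA protocol)
#' @return data.frame with columns `cell_id`, `group_label`, `rmp_excluded`
#'   and the [feature_columns()] catalogue
#' @export
extract_feature_table <- function(cells, cfg = spike_config(),
                                  tau_amps = c(-200, -150, -100, -50),
                                  sag_amps = c(-200, -150, -100, -50),
                                  spike_amps = seq(50, 400, 50),
                                  freq_amp = 300) {
  stopifnot(is.list(cells), length(cells) > 0)
  cols <- feature_columns(tau_amps, sag_amps, spike_amps, freq_amp)
  rows <- list()
  for (ci in seq_along(cells)) {
    id <- names(cells)[ci]
    if (is.null(id) || !nzchar(id)) id <- sprintf("cell%03d", ci)
    row <- tryCatch(
      .extract_cell_row(cells[[ci]], id, cfg, cols,
                        tau_amps, sag_amps, spike_amps, freq_amp),
      error = function(e) {
        warning("cell ", id, " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.extract_cell_row <- function(sweeps, id, cfg, cols,
                              tau_amps, sag_amps, spike_amps, freq_amp) {
  stopifnot(is.list(sweeps), length(sweeps) > 0)
  ok <- vapply(sweeps, inherits, TRUE, what = "cc_trace")
  if (!all(ok)) stop("sweep set contains non-trace elements")
  amps <- vapply(sweeps, function(tr) tr$stimulus$amplitude, 0)
  is_rmp <- vapply(sweeps, function(tr)
    identical(tr$sweep_id, "rmp") || is.na(tr$stimulus$holding), TRUE)
  group <- sweeps[[1]]$group_label
  feat <- setNames(as.list(rep(NA_real_, length(cols))), cols)

  rmp_tr <- sweeps[is_rmp]
  if (length(rmp_tr) > 0)
    feat$rmp_mv <- resting_membrane_potential(rmp_tr[[1]])
  clamped <- sweeps[!is_rmp]
  camps <- amps[!is_rmp]
  i_hold <- if (length(clamped) > 0) clamped[[1]]$i_hold else NA_real_
  feat$rin_hold_mohm <- input_resistance_hold(feat$rmp_mv, i_hold)
  feat$rin_step_mohm <- input_resistance_step(clamped)

  by_amp <- function(a) {
    k <- which(camps == a)
    if (length(k) == 0) NULL else clamped[[k[1]]]
  }
  for (a in tau_amps) {
    tr <- by_amp(a)
    if (!is.null(tr))
      feat[[paste0("tau_ms_", .amp_suffix(a))]] <- as.numeric(fit_membrane_tau(tr))
  }
  for (a in sag_amps) {
    tr <- by_amp(a)
    if (!is.null(tr))
      feat[[paste0("sag_mv_", .amp_suffix(a))]] <- as.numeric(measure_sag(tr))
  }
  for (a in spike_amps) {
    tr <- by_amp(a)
    if (is.null(tr)) next
    sfx <- .amp_suffix(a)
    st <- detect_spikes(tr, cfg)
    feat[[paste0("spike_count_", sfx)]] <- length(st)
    ap <- first_ap_features(tr, cfg)
    feat[[paste0("ap_width_ms_", sfx)]] <- ap$width_ms
    feat[[paste0("ap_amp_mv_", sfx)]] <- ap$amplitude_mv
    feat[[paste0("ap_peak_mv_", sfx)]] <- ap$peak_mv
    feat[[paste0("ap_onset_mv_", sfx)]] <- ap$onset_mv
    feat[[paste0("ap_maxdvdt_", sfx)]] <- ap$max_dvdt
    feat[[paste0("ttfs_ms_", sfx)]] <- ap$time_to_first_ms
  }
  trf <- by_amp(freq_amp)
  if (!is.null(trf)) {
    st <- detect_spikes(trf, cfg)
    fr <- instantaneous_frequency(st)
    for (i in 1:10)
      feat[[sprintf("freq%02d_hz_%s", i, .amp_suffix(freq_amp))]] <- fr[i]
    if (length(st) >= 2) {
      isi <- diff(st)
      feat$mean_freq_hz <- 1000 * length(st) / trf$stimulus$duration
      feat$isi_adapt <- isi[length(isi)] / isi[1]
    } else if (length(st) == 1) {
      feat$mean_freq_hz <- 1000 / trf$stimulus$duration
    }
  }
  cbind(data.frame(cell_id = id, group_label = group,
                   rmp_excluded = rmp_excluded(feat$rmp_mv),
                   stringsAsFactors = FALSE),
        as.data.frame(feat))
}

#' Current-dependent feature columns of a feature table
#'
#' The per-current feature families (time constant, sag, spike count, AP
#' shape, time to first spike, instantaneous and mean frequency, ISI
#' adaptation) used for trace/cell classification.
#'
#' @param ft a feature table from [extract_feature_table()]
#' @return character vector of column names present in `ft`
#' @export
current_dependent_features <- function(ft) {
  pat <- "^(tau_ms|sag_mv|spike_count|ap_width_ms|ap_amp_mv|ap_peak_mv|ap_onset_mv|ap_maxdvdt|ttfs_ms|freq[0-9]+_hz|mean_freq_hz|isi_adapt)"
  grep(pat, names(ft), value = TRUE)
}
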