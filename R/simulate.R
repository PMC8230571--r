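.geom_vectors <- function(model) {
  g <- model$geom
  gbar <- model$ih$gbar
  if (g$mode == "single") {
    return(list(area = g$area, gbar = gbar, gax = numeric(0)))
  }
  soma_area <- pi * (g$soma_diam * 1e-4)^2            # sphere, cm^2
  seg_L <- g$dend_length / g$nseg
  seg_area <- pi * (g$dend_diam * 1e-4) * (seg_L * 1e-4)
  x <- (seq_len(g$nseg) - 0.5) * seg_L                # um from soma
  mult <- 1 + (g$A_f - 1) / (1 + exp(-(x - g$d_half) / g$z))
  r_seg <- g$Ra * (seg_L * 1e-4) / (pi * (g$dend_diam * 1e-4 / 2)^2) # ohm
  list(area = c(soma_area, rep(seg_area, g$nseg)),
       gbar = gbar * c(1, mult),
       gax = rep(1 / r_seg, g$nseg))
}

.sim_raw <- function(model, gv, v0, i_hold, amp, onset, duration, total, dt) {
  p <- model$ih
  sim_cable(gv$area, gv$gbar, gv$gax,
            model$passive$Rm, model$passive$Cm, model$passive$e_pas, p$E_h,
            p$Vl_half, p$kl, p$Vt_half, p$a0t, p$zetat, p$gmt,
            .qt(p, model$temperature), p$c_per_mV,
            v0, i_hold, amp, onset, duration, total, dt)
}

#' Holding (bias) current that clamps the soma at a target voltage
#'
#' For a single compartment the gate is at steady state at the target, so
#' the bias current follows in closed form from the current balance. For
#' ball-and-stick geometry the current is found by root finding on the
#' settled somatic voltage.
#'
#' @param model a [cell_model()]
#' @param target target somatic voltage, mV (default -65)
#' @return holding current, pA
#' @export
compute_holding_current <- function(model, target = -65) {
  stopifnot(inherits(model, "cell_model"))
  gv <- .geom_vectors(model)
  if (model$geom$mode == "single") {
    l <- ih_steady_state(target, model$ih)
    dens <- (target - model$passive$e_pas) / model$passive$Rm +
      model$ih$gbar * l * (target - model$ih$E_h)      # A/cm^2 * 1e-3
    return(1e9 * gv$area * dens)
  }
  settle <- function(I) {
    v <- .sim_raw(model, gv, target, I, 0, 1e9, 0, 2000, 0.1)
    v[length(v)]
  }
  f <- function(I) settle(I) - target
  # bracket around the uniform-voltage estimate
  l <- ih_steady_state(target, model$ih)
  dens <- (target - model$passive$e_pas) / model$passive$Rm +
    model$ih$gbar * mean(gv$gbar) / model$ih$gbar * l * (target - model$ih$E_h)
  I0 <- 1e9 * sum(gv$area) * dens
  w <- max(200, abs(I0))
  for (k in 1:6) {
    lo <- I0 - w; hi <- I0 + w
    flo <- f(lo); fhi <- f(hi)
    if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0)
      return(uniroot(f, c(lo, hi), tol = 1e-6)$root)
    w <- w * 3
  }
  stop(structure(class = c("ihclamp_nonclampable", "error", "condition"),
                 list(message = sprintf("model cannot be clamped at %g mV (no bias current bracket found)", target),
                      call = sys.call())))
}

#' Steady-state somatic voltage under constant current
#'
#' Solves the algebraic steady state of the coupled voltage/gate system
#' (gate at its steady-state curve) by root finding; for ball-and-stick
#' geometry the settled voltage of a long simulation is used.
#'
#' @param model a [cell_model()]
#' @param I_pA total injected current (bias + step), pA
#' @return steady-state somatic voltage, mV
#' @export
steady_state_voltage <- function(model, I_pA = 0) {
  stopifnot(inherits(model, "cell_model"))
  gv <- .geom_vectors(model)
  if (model$geom$mode == "single") {
    f <- function(V) {
      l <- ih_steady_state(V, model$ih)
      -(V - model$passive$e_pas) / model$passive$Rm -
        model$ih$gbar * l * (V - model$ih$E_h) +
        1e-9 * I_pA / gv$area
    }
    return(uniroot(f, c(-150, 49), tol = 1e-10)$root)
  }
  v <- .sim_raw(model, gv, model$passive$e_pas, I_pA, 0, 1e9, 0, 3000, 0.1)
  v[length(v)]
}

#' Simulate a current-clamp step
#'
#' Integrates the membrane equation
#' `Cm dV/dt = -(V - e_pas)/Rm - gbar l (V - E_h) + (I_inj + I_hold)/area`
#' coupled to the first-order I_h gate, with a backward-Euler voltage update
#' and exponential gate update. The membrane is initialized at the holding
#' target with the gate at steady state and the bias current applied, so
#' the pre-stimulus baseline is flat at the holding voltage.
#'
#' @param model a [cell_model()]
#' @param stim a [stim_step()]; alternatively a numeric step amplitude (pA)
#' @param dt integration/sampling step, ms (<= 0.1)
#' @param cell_id,group_label,sweep_id identifiers stored in the trace
#' @return a [cc_trace()]
#' @export
simulate_step <- function(model, stim, dt = 0.025, cell_id = NA_character_,
                          group_label = NA_character_,
                          sweep_id = NA_character_) {
  stopifnot(inherits(model, "cell_model"))
  if (is.numeric(stim)) stim <- stim_step(stim)
  stopifnot(inherits(stim, "stim_step"))
  if (dt > 0.1) stop("dt must be <= 0.1 ms, got ", dt)
  total <- stim$onset + stim$duration + stim$post
  if (is.na(stim$holding)) {
    i_hold <- 0
    v0 <- steady_state_voltage(model, 0)
  } else {
    i_hold <- compute_holding_current(model, stim$holding)
    v0 <- stim$holding
  }
  gv <- .geom_vectors(model)
  v <- .sim_raw(model, gv, v0, i_hold, stim$amplitude,
                stim$onset, stim$duration, total, dt)
  if (anyNA(v) || max(abs(v)) > 200)
    stop(structure(class = c("ihclamp_integration_failure", "error", "condition"),
                   list(message = sprintf("integration failure (|V| > 200 mV) for step %g pA", stim$amplitude),
                        call = sys.call())))
  cc_trace(v, dt, stim, cell_id = cell_id, group_label = group_label,
           sweep_id = sweep_id, i_hold = i_hold)
}

#' Simulate a full step protocol
#'
#' One sweep per amplitude, all sharing the same holding baseline.
#'
#' @param model a [cell_model()]
#' @param amplitudes step amplitudes, pA (default [protocol_amplitudes()])
#' @param dt integration step, ms
#' @param onset,duration,holding,post passed to [stim_step()]
#' @param cell_id,group_label identifiers stored in each trace
#' @return a list of [cc_trace()], named by amplitude
#' @export
run_protocol <- function(model, amplitudes = protocol_amplitudes(),
                         dt = 0.025, onset = 100, duration = 400,
                         holding = -65, post = 100,
                         cell_id = NA_character_,
                         group_label = NA_character_) {
  out <- vector("list", length(amplitudes))
  for (i in seq_along(amplitudes)) {
    out[[i]] <- tryCatch(
      simulate_step(model,
                    stim_step(amplitudes[i], onset = onset,
                              duration = duration, holding = holding,
                              post = post),
                    dt = dt, cell_id = cell_id, group_label = group_label,
                    sweep_id = sprintf("sweep%02d", i)),
      error = function(e) {
        stop("sweep ", i, " (", amplitudes[i], " pA): ",
             conditionMessage(e), call. = FALSE)
      })
  }
  names(out) <- as.character(amplitudes)
  out
}
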