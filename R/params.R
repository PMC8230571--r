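#' Passive membrane parameters
#'
#' @param Rm specific membrane resistance, ohm cm^2 (> 0)
#' @param Cm specific membrane capacitance, uF/cm^2 (> 0)
#' @param e_pas leak reversal potential, mV (in \[-120, -40\])
#' @return an object of class `passive_params`
#' @export
passive_params <- function(Rm, Cm = 1, e_pas) {
  stopifnot(is.numeric(Rm), Rm > 0, is.numeric(Cm), Cm > 0)
  if (e_pas < -120 || e_pas > -40)
    stop("e_pas must lie in [-120, -40] mV, got ", e_pas)
  structure(list(Rm = Rm, Cm = Cm, e_pas = e_pas), class = "passive_params")
}

#' Hyperpolarization-activated current (I_h) parameters
#'
#' Borg-Graham style first-order gate: the activation curve is a logistic
#' in voltage with half-voltage `Vl_half` and (negative) shape factor `kl`;
#' the time constant is `beta / (qt * a0t * (1 + alpha))` with
#' `alpha = exp(c * zetat * (V - Vt_half))`,
#' `beta = exp(c * zetat * gmt * (V - Vt_half))` and the temperature factor
#' `qt = q10^((T - T_ref)/10)`.
#'
#' @param gbar peak conductance density, S/cm^2 (>= 0)
#' @param E_h reversal potential, mV (default -30, the conventional value
#'   for this channel family)
#' @param Vl_half activation half-voltage, mV
#' @param kl activation shape factor, mV; must be negative (channel opens
#'   with hyperpolarization)
#' @param Vt_half time-constant half-voltage, mV
#' @param a0t rate scale, 1/ms (> 0)
#' @param zetat dimensionless slope of the rate functions
#' @param gmt dimensionless asymmetry, in (0, 1)
#' @param q10 temperature coefficient (> 0)
#' @param T_ref reference temperature for `q10`, degrees C
#' @param c_per_mV thermodynamic constant of the rate exponents,
#'   1/mV (~ F/RT near 34 C)
#' @return an object of class `ih_params`
#' @export
ih_params <- function(gbar, E_h = -30, Vl_half, kl, Vt_half, a0t, zetat, gmt,
                      q10 = 4.5, T_ref = 33, c_per_mV = 0.0378) {
  stopifnot(gbar >= 0, a0t > 0, q10 > 0)
  if (kl >= 0) stop("kl must be negative, got ", kl)
  if (gmt <= 0 || gmt >= 1) stop("gmt must lie in (0, 1), got ", gmt)
  structure(list(gbar = gbar, E_h = E_h, Vl_half = Vl_half, kl = kl,
                 Vt_half = Vt_half, a0t = a0t, zetat = zetat, gmt = gmt,
                 q10 = q10, T_ref = T_ref, c_per_mV = c_per_mV),
            class = "ih_params")
}

#' Single-compartment geometry
#'
#' @param area total membrane area, cm^2. The default (2.0e-4 cm^2) puts the
#'   input resistance of typical CA1 parameter sets in the physiological
#'   100-200 Mohm range.
#' @return an object of class `ih_geometry`
#' @export
geom_single <- function(area = 2.0e-4) {
  stopifnot(area > 0)
  structure(list(mode = "single", area = area), class = "ih_geometry")
}

#' Ball-and-stick geometry with a sigmoidal dendritic I_h gradient
#'
#' A spherical soma plus an unbranched cylindrical dendrite whose I_h
#' density increases sigmoidally with distance from the soma:
#' `gbar(x) = gbar * (1 + (A_f - 1) / (1 + exp(-(x - d_half)/z)))`.
#'
#' @param soma_diam soma diameter, um
#' @param dend_length dendrite length, um
#' @param dend_diam dendrite diameter, um
#' @param nseg number of dendritic segments
#' @param Ra axial resistivity, ohm cm
#' @param A_f distal-to-somatic I_h density fold increase (>= 0)
#' @param d_half distance of half-maximal increase, um
#' @param z sigmoid steepness, um (> 0)
#' @return an object of class `ih_geometry`
#' @export
geom_ballstick <- function(soma_diam = 25, dend_length = 700, dend_diam = 7,
                           nseg = 25, Ra = 150,
                           A_f = 8, d_half = 280, z = 50) {
  stopifnot(soma_diam > 0, dend_length > 0, dend_diam > 0, nseg >= 1,
            Ra > 0, A_f >= 0, z > 0)
  structure(list(mode = "ballstick", soma_diam = soma_diam,
                 dend_length = dend_length, dend_diam = dend_diam,
                 nseg = as.integer(nseg), Ra = Ra,
                 A_f = A_f, d_half = d_half, z = z),
            class = "ih_geometry")
}

#' Reduced CA1 neuron model (passive + I_h)
#'
#' @param passive a [passive_params()] object
#' @param ih an [ih_params()] object
#' @param geom an [geom_single()] or [geom_ballstick()] geometry
#' @param temperature simulation temperature, degrees C (default 34)
#' @return an object of class `cell_model`
#' @export
cell_model <- function(passive, ih, geom = geom_single(), temperature = 34) {
  stopifnot(inherits(passive, "passive_params"), inherits(ih, "ih_params"),
            inherits(geom, "ih_geometry"))
  structure(list(passive = passive, ih = ih, geom = geom,
                 temperature = temperature), class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model>", x$geom$mode, "geometry,", x$temperature, "C\n")
  cat(sprintf("  passive: Rm=%g ohm cm2, Cm=%g uF/cm2, e_pas=%g mV\n",
              x$passive$Rm, x$passive$Cm, x$passive$e_pas))
  cat(sprintf("  I_h: gbar=%.4g S/cm2, E_h=%g, Vl_half=%g, kl=%g, Vt_half=%g, a0t=%.4g, zetat=%g, gmt=%g\n",
              x$ih$gbar, x$ih$E_h, x$ih$Vl_half, x$ih$kl, x$ih$Vt_half,
              x$ih$a0t, x$ih$zetat, x$ih$gmt))
  invisible(x)
}

#' Current-step stimulus descriptor
#'
#' @param amplitude step amplitude, pA
#' @param onset step onset, ms from trace start
#' @param duration step duration, ms (> 0)
#' @param holding holding target before/after the step, mV (NA for an
#'   unclamped sweep with no bias current)
#' @param post post-stimulus baseline, ms
#' @return an object of class `stim_step`
#' @export
stim_step <- function(amplitude, onset = 100, duration = 400,
                      holding = -65, post = 100) {
  stopifnot(duration > 0, onset >= 0, post >= 0)
  structure(list(amplitude = amplitude, onset = onset, duration = duration,
                 holding = holding, post = post), class = "stim_step")
}

#' Default step protocol amplitudes
#'
#' Steps of 50 pA from -200 to +400 pA (13 amplitudes, 0 pA included).
#'
#' @param from,to,by protocol limits and increment, pA
#' @return numeric vector of step amplitudes, pA
#' @export
protocol_amplitudes <- function(from = -200, to = 400, by = 50) {
  seq(from, to, by = by)
}

#' Current-clamp sweep container
#'
#' @param voltage voltage samples, mV (finite)
#' @param dt sampling interval, ms (> 0)
#' @param stimulus a [stim_step()] descriptor
#' @param cell_id,group_label,sweep_id identifiers
#' @param i_hold holding (bias) current applied throughout the sweep, pA
#' @return an object of class `cc_trace`
#' @export
cc_trace <- function(voltage, dt, stimulus, cell_id = NA_character_,
                     group_label = NA_character_, sweep_id = NA_character_,
                     i_hold = NA_real_) {
  stopifnot(dt > 0, is.numeric(voltage))
  if (!all(is.finite(voltage)))
    stop("trace voltage contains non-finite samples")
  stopifnot(inherits(stimulus, "stim_step"))
  if ((length(voltage) - 1L) * dt + 1e-9 <
      stimulus$onset + stimulus$duration + stimulus$post)
    stop("trace shorter than onset + duration + post window")
  structure(list(voltage = voltage, dt = dt, stimulus = stimulus,
                 cell_id = cell_id, group_label = group_label,
                 sweep_id = sweep_id, i_hold = i_hold),
            class = "cc_trace")
}

#' Time axis of a trace
#' @param trace a [cc_trace()]
#' @return numeric vector of sample times, ms
#' @export
trace_time <- function(trace) {
  (seq_along(trace$voltage) - 1) * trace$dt
}

#' @export
print.cc_trace <- function(x, ...) {
  cat(sprintf("<cc_trace> %d samples @ dt=%g ms, step %g pA [%g..%g ms], cell=%s group=%s\n",
              length(x$voltage), x$dt, x$stimulus$amplitude,
              x$stimulus$onset, x$stimulus$onset + x$stimulus$duration,
              x$cell_id, x$group_label))
  invisible(x)
}

#' Optimized group parameter sets
#'
#' Returns the packaged table of optimized passive + I_h parameters for the
#' six experimental groups (wild-type and amyloidopathy model at 1, 3-4 and
#' 9-10 months), or a single row.
#'
#' @param label optional group label (one of `WT-1m`, `AD-1m`, `WT-4m`,
#'   `AD-4m`, `WT-10m`, `AD-10m`)
#' @param file optional path to a JSON parameter file with the same schema
#' @return a data.frame with columns `label`, `Rm`, `e_pas`, `gbar`,
#'   `Vl_half`, `kl`, `Vt_half`, `a0t`, `zetat`, `gmt`
#' @export
ih_group_params <- function(label = NULL, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "group_ih_parameters.json",
                        package = "ihclamp", mustWork = TRUE)
  tab <- jsonlite::fromJSON(file)
  stopifnot(is.data.frame(tab), "label" %in% names(tab))
  if (!is.null(label)) {
    tab <- tab[tab$label == label, , drop = FALSE]
    if (nrow(tab) == 0) stop("unknown group label: ", label)
  }
  rownames(tab) <- NULL
  tab
}

#' Build a cell model from a group parameter row
#'
#' @param label group label, see [ih_group_params()]
#' @param geom geometry (default single compartment)
#' @param Cm specific capacitance, uF/cm^2
#' @param E_h I_h reversal potential, mV
#' @param ... further arguments to [ih_params()]
#' @return a [cell_model()]
#' @export
cell_from_group <- function(label, geom = geom_single(), Cm = 1,
                            E_h = -30, ...) {
  r <- ih_group_params(label)
  cell_from_row(r, geom = geom, Cm = Cm, E_h = E_h, ...)
}

#' Build a cell model from a one-row parameter data.frame
#' @param row one-row data.frame with the [ih_group_params()] schema
#' @inheritParams cell_from_group
#' @return a [cell_model()]
#' @export
cell_from_row <- function(row, geom = geom_single(), Cm = 1, E_h = -30, ...) {
  stopifnot(nrow(row) == 1)
  cell_model(
    passive = passive_params(Rm = row$Rm, Cm = Cm, e_pas = row$e_pas),
    ih = ih_params(gbar = row$gbar, E_h = E_h, Vl_half = row$Vl_half,
                   kl = row$kl, Vt_half = row$Vt_half, a0t = row$a0t,
                   zetat = row$zetat, gmt = row$gmt, ...),
    geom = geom)
}
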