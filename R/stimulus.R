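# Presynaptic stimulus templates for open-loop PRC measurement.
#
# A single presynaptic "spike event" is represented by a voltage waveform
# V_pre(t) that drives the synapse kinetics through the release sigmoid
# T(V_pre). Outside the template the presynaptic potential is held at the
# waveform minimum, where T is effectively zero.

#' Presynaptic spike waveform template
#'
#' One full cycle of the presynaptic neuron's free-running membrane
#' potential, starting at its upward zero crossing. Delivering this waveform
#' to a synapse reproduces the synaptic input one presynaptic spike would
#' cause in the coupled network.
#'
#' @param neuron presynaptic [ml_neuron()].
#' @param dt sampling interval of the waveform.
#' @return data.frame `(t, V)` with `t` starting at 0; attribute `crossing`
#'   gives the template time of the upward zero crossing (0 here).
#' @export
spike_template <- function(neuron, dt = ode_defaults$dt) {
  tr <- simulate_neuron(neuron, 1200, dt = dt)
  sp <- detect_spikes(tr)
  if (length(sp) < 3) stop("presynaptic neuron is not oscillating")
  a <- sp[length(sp) - 1]; b <- sp[length(sp)]
  sel <- tr$time >= a & tr$time <= b
  out <- data.frame(t = tr$time[sel] - a, V = tr$V[sel])
  attr(out, "crossing") <- 0
  out
}

#' Triangular stimulus waveform
#'
#' A piecewise-linear "triangular" presynaptic voltage excursion from `base`
#' up to `peak` and back, an idealization sometimes used in open-loop PRC
#' protocols in place of the true presynaptic waveform. Its rise and fall
#' times are free protocol parameters; results (and hence phase-locked mode
#' predictions) are sensitive to them, which is why the synaptic-event
#' template of [spike_template()] is the package default.
#'
#' @param peak,base apex and baseline potentials (defaults match the type-1
#'   ML spike excursion).
#' @param rise,fall rise and fall durations (time units).
#' @return data.frame `(t, V)`; attribute `crossing` marks the upward zero
#'   crossing on the rising flank, used to align the stimulus time.
#' @export
triangular_template <- function(peak = 0.285, base = -0.34,
                                rise = 1, fall = 1) {
  stopifnot(peak > 0, base < 0, rise > 0, fall > 0)
  out <- data.frame(t = c(0, rise, rise + fall), V = c(base, peak, base))
  attr(out, "crossing") <- rise * (0 - base) / (peak - base)
  out
}

## internal: integrate post neuron + synapse driven by a forced presynaptic
## waveform placed so its zero crossing sits at `ts`.
sim_stimulated <- function(neuron, syn, template, ts, duration, init,
                           dt = ode_defaults$dt) {
  vrest <- min(template$V)
  offset <- attr(template, "crossing")
  if (is.null(offset)) offset <- 0
  t0 <- ts - offset
  forc <- rbind(cbind(min(0, t0) - 1, vrest),
                cbind(t0 - 1e-9, vrest),
                cbind(t0 + template$t, template$V),
                cbind(t0 + max(template$t) + 1e-9, vrest),
                cbind(duration + 1, vrest))
  forc <- forc[order(forc[, 1]), , drop = FALSE]
  parms <- c(neuron_parms(neuron), syn$gsyn, syn$Esyn,
             syn$alpha_on, syn$beta_off, syn$T_half, syn$T_scale)
  out <- deSolve::ode(y = init, times = seq(0, duration, by = dt),
                      func = "deriv_mlstim", parms = parms,
                      dllname = "phaselock", initfunc = "init_mlstim",
                      initforc = "forc_mlstim", forcings = forc,
                      fcontrol = list(method = "linear", rule = 2),
                      method = "lsoda",
                      rtol = ode_defaults$rtol, atol = ode_defaults$atol)
  d <- as.data.frame(check_trajectory(out))
  names(d) <- c("time", "V", "w", "s")
  d
}
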