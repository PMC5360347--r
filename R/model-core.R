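# Model core: right-hand sides, ODE drivers, spike detection, period
# measurement and bias-current calibration.
#
# The exported ml_derivatives()/synapse_derivative() are the reference
# definition of the model; production integration goes through compiled
# right-hand sides in src/ (deSolve compiled-model interface), and a test
# asserts that both paths produce the same trajectories.

sigmoid_gate <- function(V, half, slope) 0.5 * (1 + tanh((V - half) / slope))

#' Morris-Lecar state derivatives
#'
#' Right-hand side of the two-dimensional ML oscillator. The calcium gate is
#' instantaneous, \eqn{m = m_\infty(V)}; the potassium gate relaxes toward
#' \eqn{w_\infty(V)} at rate \eqn{\phi\cosh((V - V_{w,1/2})/(2V_{w,slope}))}.
#'
#' @param state numeric `c(V, w)`: membrane potential and potassium gate.
#' @param neuron an [ml_neuron()].
#' @param i_syn synaptic (or other extrinsic) current, subtracted from dV/dt.
#' @return numeric `c(dV, dw)`.
#' @examples
#' p <- ml_neuron()
#' ml_derivatives(c(V = 0, w = 0.2), p)
#' @export
ml_derivatives <- function(state, neuron, i_syn = 0) {
  V <- state[[1]]; w <- state[[2]]
  minf <- sigmoid_gate(V, neuron$Vm_half, neuron$Vm_slope)
  winf <- sigmoid_gate(V, neuron$Vw_half, neuron$Vw_slope)
  dV <- -neuron$gCa * minf * (V - neuron$ECa) -
    neuron$gK * w * (V - neuron$EK) -
    neuron$gLeak * (V - neuron$ELeak) + neuron$I0 - i_syn
  dw <- neuron$phi * cosh((V - neuron$Vw_half) / (2 * neuron$Vw_slope)) *
    (winf - w)
  c(dV = dV, dw = dw)
}

#' Neurotransmitter release sigmoid
#'
#' @param v_pre presynaptic membrane potential.
#' @param syn an [synapse()] object.
#' @return Release fraction T in (0, 1).
#' @export
transmitter_release <- function(v_pre, syn) {
  1 / (1 + exp(-(v_pre - syn$T_half) * syn$T_scale))
}

#' Synaptic gating derivative
#'
#' First-order kinetics `ds/dt = alpha T(v_pre) (1 - s) - beta s`.
#'
#' @param s fraction of open channels in `[0, 1]`.
#' @param v_pre presynaptic membrane potential.
#' @param syn an [synapse()] object.
#' @return ds/dt.
#' @export
synapse_derivative <- function(s, v_pre, syn) {
  syn$alpha_on * transmitter_release(v_pre, syn) * (1 - s) - syn$beta_off * s
}

neuron_parms <- function(n) {
  c(n$gCa, n$gK, n$gLeak, n$ECa, n$EK, n$ELeak,
    n$Vm_half, n$Vm_slope, n$Vw_half, n$Vw_slope, n$phi, n$I0)
}

ode_defaults <- list(rtol = 1e-8, atol = 1e-10, dt = 0.02)

check_trajectory <- function(out) {
  if (anyNA(out) || !all(is.finite(out)))
    stop(sprintf("integration failure (non-finite state) near t = %g",
                 out[which(!stats::complete.cases(out))[1], 1]))
  out
}

#' Integrate an arbitrary ODE system
#'
#' Thin driver around [deSolve::ode()] (lsoda, stiff-capable, adaptive with
#' dense output) returning a densely sampled trajectory suitable for spike
#' detection.
#'
#' @param rhs function `(t, y, ...) -> list(dy)` or `(t, y) -> dy` vector.
#' @param init initial state (named vector recommended).
#' @param duration total integration time (>= 0).
#' @param dt output sampling interval (default 0.02 time units).
#' @param rtol,atol integration tolerances.
#' @param ... passed to `rhs`.
#' @return A data.frame: `time` column plus one column per state variable.
#' @examples
#' # harmonic oscillator returns to the start after one period
#' traj <- integrate_system(function(t, y) c(y[2], -y[1]), c(x = 1, y = 0),
#'                          duration = 2 * pi)
#' tail(traj, 1)
#' @export
integrate_system <- function(rhs, init, duration, dt = ode_defaults$dt,
                             rtol = ode_defaults$rtol, atol = ode_defaults$atol,
                             ...) {
  stopifnot(duration >= 0)
  if (duration == 0)
    return(as.data.frame(t(c(time = 0, init))))
  wrapped <- function(t, y, parms, ...) {
    d <- rhs(t, y, ...)
    if (!is.list(d)) d <- list(d)
    d
  }
  out <- deSolve::ode(y = init, times = seq(0, duration, by = dt),
                      func = wrapped, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol, ...)
  as.data.frame(check_trajectory(out))
}

## internal: compiled single free-running neuron
sim_neuron_raw <- function(neuron, duration, init, dt = ode_defaults$dt) {
  out <- deSolve::ode(y = init, times = seq(0, duration, by = dt),
                      func = "deriv_ml1", parms = neuron_parms(neuron),
                      dllname = "phaselock", initfunc = "init_ml1",
                      method = "lsoda",
                      rtol = ode_defaults$rtol, atol = ode_defaults$atol)
  check_trajectory(out)
}

#' Simulate a free-running Morris-Lecar neuron
#'
#' @param neuron an [ml_neuron()].
#' @param duration simulation length (time units).
#' @param init initial `c(V, w)`.
#' @param dt output sampling interval.
#' @return data.frame with columns `time`, `V`, `w`.
#' @export
simulate_neuron <- function(neuron, duration, init = c(V = -0.3, w = 0.1),
                            dt = ode_defaults$dt) {
  stopifnot(duration > 0)
  out <- sim_neuron_raw(neuron, duration, init, dt)
  d <- as.data.frame(out)
  names(d) <- c("time", "V", "w")
  d
}

#' Detect spikes as upward threshold crossings
#'
#' Event times where the membrane potential crosses `threshold` with a
#' positive slope, linearly interpolated between samples. These crossings
#' define the phase reference `phi = 0` of the oscillator.
#'
#' @param trajectory data.frame with a `time` column and a voltage column,
#'   or a matrix whose first column is time.
#' @param threshold crossing level (default 0, the conventional reference).
#' @param column name or index of the voltage column (default `"V"`, or the
#'   second column when unnamed).
#' @return A [spike_train()] (possibly empty).
#' @examples
#' tr <- data.frame(time = c(1, 2), V = c(-0.1, 0.1))
#' detect_spikes(tr)   # crossing at t = 1.5
#' @export
detect_spikes <- function(trajectory, threshold = 0, column = "V") {
  trajectory <- as.data.frame(trajectory)
  tt <- trajectory[[1]]
  V <- if (is.character(column) && column %in% names(trajectory))
    trajectory[[column]] else trajectory[[2]]
  n <- length(V)
  if (n < 2) return(spike_train(numeric(0)))
  i <- which(V[-n] < threshold & V[-1] >= threshold)
  if (!length(i)) return(spike_train(numeric(0)))
  cross <- tt[i] + (threshold - V[i]) / (V[i + 1] - V[i]) * (tt[i + 1] - tt[i])
  spike_train(cross)
}

#' Measure the intrinsic (free-running) period
#'
#' Simulates the uncoupled neuron, discards an initial transient and averages
#' the remaining interspike intervals. The cycle-to-cycle spread is reported
#' so callers can verify the oscillation is stationary.
#'
#' @param neuron an [ml_neuron()].
#' @param discard number of initial cycles discarded (default 5).
#' @param n_avg minimum number of cycles averaged (default 8).
#' @param horizon simulation length; enlarged automatically if `NULL`.
#' @param init initial state.
#' @return list with `period` (mean ISI), `spread` (max-min of the averaged
#'   ISIs) and `n_cycles`.
#' @export
intrinsic_period <- function(neuron, discard = 5, n_avg = 8, horizon = NULL,
                             init = c(V = -0.3, w = 0.1)) {
  need <- discard + n_avg + 1
  if (is.null(horizon)) horizon <- 1600
  tr <- simulate_neuron(neuron, horizon, init = init)
  sp <- detect_spikes(tr)
  if (length(sp) < need) {
    ## one retry with a 4x horizon before declaring quiescence
    tr <- simulate_neuron(neuron, 4 * horizon, init = init)
    sp <- detect_spikes(tr)
    if (length(sp) < need)
      stop(sprintf("not oscillating: %d spikes in %g time units (need %d)",
                   length(sp), 4 * horizon, need))
  }
  isi <- diff(unclass(sp))[-seq_len(discard)]
  list(period = mean(isi), spread = max(isi) - min(isi), n_cycles = length(isi))
}

#' Calibrate the bias current to a target intrinsic period
#'
#' Class I excitability makes the period a continuous, monotonically
#' decreasing function of the bias current above rheobase, so the target is
#' bracketed and solved by bisection ([stats::uniroot()]).
#'
#' @param neuron an [ml_neuron()]; its `I0` is ignored.
#' @param target_period desired intrinsic period (time units).
#' @param bracket current interval straddling the target (default
#'   `c(0.0695, 0.075)`, which covers periods of roughly 97 down to 21 for the
#'   default parameter set).
#' @param tol acceptable period error (default 0.05 time units).
#' @return The calibrated bias current `I0` (numeric scalar).
#' @seealso [calibrate_neuron()] which returns the updated neuron.
#' @export
calibrate_bias <- function(neuron, target_period, bracket = c(0.0695, 0.075),
                           tol = 0.05) {
  per_at <- function(I0) {
    n <- neuron; n$I0 <- I0
    intrinsic_period(n)$period
  }
  p_lo <- tryCatch(per_at(bracket[1]), error = function(e) Inf)
  p_hi <- per_at(bracket[2])
  if (!(p_hi <= target_period && target_period <= p_lo))
    stop(sprintf(
      "target unreachable: period range [%.4g, %.4g] over bracket does not straddle %g",
      p_hi, p_lo, target_period))
  root <- stats::uniroot(function(I0) per_at(I0) - target_period,
                         interval = bracket, tol = 1e-9)$root
  achieved <- per_at(root)
  if (abs(achieved - target_period) > tol)
    stop(sprintf("calibration did not converge: period %.5g vs target %g",
                 achieved, target_period))
  root
}

#' @rdname calibrate_bias
#' @return `calibrate_neuron()` returns the neuron with `I0` replaced.
#' @export
calibrate_neuron <- function(neuron, target_period, bracket = c(0.0695, 0.075),
                             tol = 0.05) {
  neuron$I0 <- calibrate_bias(neuron, target_period, bracket, tol)
  neuron
}

#' State on the limit cycle at the phase reference
#'
#' Runs the free neuron past its transient and returns the state at the last
#' upward zero crossing (V = 0 exactly, w interpolated), together with the
#' period measured from the preceding cycles. PRC measurement starts every
#' trial from this state so that phase 0 is reproducible.
#'
#' @param neuron an [ml_neuron()].
#' @param settle simulation length used to settle onto the cycle.
#' @return list `state` (c(V, w)), `period`.
#' @export
limit_cycle_state <- function(neuron, settle = 1200) {
  tr <- simulate_neuron(neuron, settle)
  sp <- detect_spikes(tr)
  if (length(sp) < 8) stop("not oscillating: too few spikes while settling")
  tc <- sp[length(sp)]
  i <- findInterval(tc, tr$time)
  fr <- (tc - tr$time[i]) / (tr$time[i + 1] - tr$time[i])
  w0 <- tr$w[i] + fr * (tr$w[i + 1] - tr$w[i])
  isi <- diff(unclass(sp))
  list(state = c(V = 0, w = w0), period = mean(utils::tail(isi, 5)))
}
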