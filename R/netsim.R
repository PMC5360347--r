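# Closed-loop simulation of the fully connected three-neuron network and
# extraction of the per-cycle timing variables (t2sa[n], t2sb[n], t2r[n]).
# This is the ground truth the open-loop PRC predictions are judged against.

#' Three-neuron network configuration
#'
#' Master neuron 1 excites slave neuron 2 (g12); the slave excites the
#' interneuron 3 (g23); the interneuron inhibits the slave (g32). All three
#' cells share the biophysical template; their bias currents are calibrated
#' to the target intrinsic periods by [calibrate_network()].
#'
#' @param P1i,P2i,P3i target intrinsic periods (defaults 60, 70, 80).
#' @param g12,g23,g32 synaptic conductances (defaults: the reference
#'   operating point 0.015, 0.0275, 0.002).
#' @param neuron biophysical template, an [ml_neuron()].
#' @param syn_kinetics kinetic/release parameters shared by all synapses
#'   (a [synapse()]; its `gsyn`/`Esyn` are ignored).
#' @return object of class `network_config`.
#' @export
network_config <- function(P1i = 60, P2i = 70, P3i = 80,
                           g12 = 0.015, g23 = 0.0275, g32 = 0.002,
                           neuron = ml_neuron(), syn_kinetics = synapse(0)) {
  stopifnot(P1i > 0, P2i > 0, P3i > 0, g12 >= 0, g23 >= 0, g32 >= 0)
  structure(list(P1i = P1i, P2i = P2i, P3i = P3i,
                 g12 = g12, g23 = g23, g32 = g32,
                 neuron = neuron, syn_kinetics = syn_kinetics,
                 neurons = NULL),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> periods %g/%g/%g  g12=%g g23=%g g32=%g  (%s)\n",
              x$P1i, x$P2i, x$P3i, x$g12, x$g23, x$g32,
              if (is.null(x$neurons)) "uncalibrated" else "calibrated"))
  invisible(x)
}

#' @rdname network_config
#' @param config a `network_config`.
#' @param bracket,tol forwarded to [calibrate_bias()].
#' @return `calibrate_network()` returns the config with the three
#'   calibrated neurons stored in `$neurons`.
#' @export
calibrate_network <- function(config, bracket = c(0.0695, 0.075), tol = 0.05) {
  config$neurons <- lapply(c(config$P1i, config$P2i, config$P3i),
                           function(P) calibrate_neuron(config$neuron, P,
                                                        bracket, tol))
  names(config$neurons) <- c("n1", "n2", "n3")
  config
}

network_parms <- function(config) {
  k <- config$syn_kinetics
  c(neuron_parms(config$neurons$n1),
    neuron_parms(config$neurons$n2),
    neuron_parms(config$neurons$n3),
    config$g12, 0, config$g32, -0.6, config$g23, 0,
    k$alpha_on, k$beta_off, k$T_half, k$T_scale)
}

#' Simulate the fully coupled network
#'
#' Integrates the 9-dimensional closed-loop system: three (V, w) neuron
#' pairs plus one kinetic gating state per connection (1->2, 3->2, 2->3),
#' each driven continuously by its presynaptic membrane potential through
#' the release sigmoid — no event queue.
#'
#' @param config a [network_config()] (calibrated automatically if needed).
#' @param n_cycles simulation length in master periods (default 110).
#' @param init `"spike"` starts every neuron at its phase reference;
#'   `"random"` starts each at an independent uniformly random phase of its
#'   limit cycle (uses R's RNG, so `set.seed()` makes runs reproducible);
#'   or a full 9-vector `(V1, w1, V2, w2, V3, w3, s12, s32, s23)`.
#' @param dt output sampling interval.
#' @param keep_traces keep the dense trajectory (memory-heavy) or only the
#'   spike trains.
#' @return list of class `network_sim`: `trains` (three [spike_train()]s),
#'   `config`, and optionally `traces`.
#' @export
simulate_network <- function(config, n_cycles = 110,
                             init = c("random", "spike"),
                             dt = ode_defaults$dt, keep_traces = FALSE) {
  if (is.null(config$neurons)) config <- calibrate_network(config)
  duration <- n_cycles * config$P1i
  if (is.character(init)) {
    init <- match.arg(init)
    y0 <- unlist(lapply(config$neurons, function(n) {
      lc <- limit_cycle_state(n)
      if (init == "spike") return(lc$state)
      ## state at a random phase: integrate one partial period from the spike
      off <- stats::runif(1) * lc$period
      tr <- simulate_neuron(n, max(off, dt), init = lc$state, dt = dt)
      c(V = tr$V[nrow(tr)], w = tr$w[nrow(tr)])
    }))
    y0 <- c(y0, 0, 0, 0)
  } else {
    stopifnot(length(init) == 9)
    y0 <- init
  }
  out <- deSolve::ode(y = unname(y0), times = seq(0, duration, by = dt),
                      func = "deriv_net3", parms = network_parms(config),
                      dllname = "phaselock", initfunc = "init_net3",
                      method = "lsoda",
                      rtol = ode_defaults$rtol, atol = ode_defaults$atol)
  check_trajectory(out)
  cols <- c("time", "V1", "w1", "V2", "w2", "V3", "w3", "s12", "s32", "s23")
  trains <- lapply(c("V1", "V2", "V3"), function(v)
    detect_spikes(data.frame(time = out[, 1],
                             V = out[, match(v, cols)]), column = "V"))
  names(trains) <- c("n1", "n2", "n3")
  quiet <- vapply(trains, length, integer(1)) < 3
  if (any(quiet))
    warning("quiescent neuron: ", paste(names(trains)[quiet], collapse = ", "))
  res <- list(trains = trains, config = config,
              final_state = unname(out[nrow(out), -1]))
  if (keep_traces) {
    traces <- as.data.frame(out)
    names(traces) <- cols
    res$traces <- traces
  }
  structure(res, class = "network_sim")
}

#' Extract per-cycle timing variables from spike trains
#'
#' For each slave (neuron 2) cycle after the discard window the cycle must
#' contain exactly one interneuron spike followed by one master spike; then
#' `t2sa[n]` and `t2sb[n]` are their delays after the slave's spike and
#' `t2r[n]` is the remainder of the cycle after the master's input.
#'
#' @param x a `network_sim` or a list of three [spike_train()]s named
#'   `n1`, `n2`, `n3`.
#' @param discard number of initial slave cycles discarded (default 20).
#' @param tol,window convergence criterion forwarded to
#'   [check_convergence()].
#' @return object of class `mode_measurement`: data.frame `cycles` with
#'   columns `t2sa`, `t2sb`, `t2r`, `P2` plus steady-state summaries and a
#'   convergence flag.
#' @export
extract_mode <- function(x, discard = 20, tol = 0.05, window = 10) {
  trains <- if (inherits(x, "network_sim")) x$trains else x
  s1 <- unclass(trains$n1); s2 <- unclass(trains$n2); s3 <- unclass(trains$n3)
  if (length(s2) < discard + window + 2)
    stop(sprintf("too few slave cycles (%d) for discard = %d and window = %d",
                 length(s2) - 1, discard, window))
  s2 <- s2[-seq_len(discard)]
  n <- length(s2) - 1
  t2sa <- t2sb <- t2r <- P2 <- numeric(n)
  for (k in seq_len(n)) {
    a <- s2[k]; b <- s2[k + 1]
    sp3 <- s3[s3 >= a & s3 < b]
    sp1 <- s1[s1 >= a & s1 < b]
    if (length(sp3) != 1 || length(sp1) != 1 || sp3 >= sp1)
      stop(sprintf(
        "pattern mismatch in cycle %d: expected one interneuron spike then one master spike",
        k + discard))
    t2sa[k] <- sp3 - a; t2sb[k] <- sp1 - a; t2r[k] <- b - sp1; P2[k] <- b - a
  }
  cyc <- data.frame(cycle = seq_len(n) + discard,
                    t2sa = t2sa, t2sb = t2sb, t2r = t2r, P2 = P2)
  ca <- check_convergence(t2sa, tol = tol, window = window)
  cb <- check_convergence(t2sb, tol = tol, window = window)
  cp <- check_convergence(P2, tol = tol, window = window)
  structure(list(cycles = cyc,
                 converged = ca$converged && cb$converged && cp$converged,
                 t2sa = ca$value, t2sb = cb$value, period = cp$value,
                 t2r = cp$value - cb$value,
                 spread = c(t2sa = ca$spread, t2sb = cb$spread,
                            period = cp$spread)),
            class = "mode_measurement")
}

#' @export
print.mode_measurement <- function(x, ...) {
  cat(sprintf(
    "<mode_measurement> %d cycles, %s\n  t2sa* = %.4g  t2sb* = %.4g  t2r* = %.4g  period = %.5g\n",
    nrow(x$cycles), if (x$converged) "converged" else "NOT converged",
    x$t2sa, x$t2sb, x$t2r, x$period))
  invisible(x)
}

#' Steady-state test for a per-cycle sequence
#'
#' A sequence is converged when its range (max - min) over the trailing
#' window does not exceed `tol`; the steady value is the trailing mean.
#'
#' @param x numeric sequence of per-cycle values.
#' @param tol tolerance on the trailing range (default 0.05 time units).
#' @param window number of trailing cycles examined (default 10).
#' @return list `converged`, `value` (trailing mean), `spread`.
#' @export
check_convergence <- function(x, tol = 0.05, window = 10) {
  stopifnot(length(x) >= window, window >= 2)
  tailx <- utils::tail(x, window)
  spread <- max(tailx) - min(tailx)
  list(converged = spread <= tol, value = mean(tailx), spread = spread)
}

#' Compare an open-loop prediction with a closed-loop measurement
#'
#' @param measured a converged [extract_mode()] result.
#' @param predicted a [phase_locked_mode()].
#' @return data.frame with one row per quantity (`t2sa`, `t2sb`): measured,
#'   predicted, absolute and percent error
#'   (`|pred - meas| / meas * 100`).
#' @export
compare_prediction <- function(measured, predicted) {
  stopifnot(inherits(measured, "mode_measurement"),
            inherits(predicted, "phase_locked_mode"))
  if (!measured$converged)
    stop("measurement has not converged; refusing to compare")
  meas <- c(t2sa = measured$t2sa, t2sb = measured$t2sb)
  pred <- c(t2sa = predicted$t2sa, t2sb = predicted$t2sb)
  data.frame(quantity = names(meas),
             measured = unname(meas), predicted = unname(pred),
             abs_error = unname(abs(pred - meas)),
             pct_error = unname(abs(pred - meas) / meas * 100),
             row.names = NULL)
}
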