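# Single-stimulus PRC measurement, the type-1 (SNIC) normal form, and the
# conductance-to-coupling calibration.

#' PRC table
#'
#' Tabulated first-order phase resetting \eqn{F^{(1)}(\phi) = P_1/P_i - 1}
#' on a phase grid. Sign convention: negative values are phase advances
#' (period shortening), positive values are delays.
#'
#' @param phi strictly increasing phase grid in `[0, 1)`.
#' @param F resetting values; must satisfy `F > -1` (the perturbed period
#'   stays positive).
#' @param Pi intrinsic period of the measured neuron.
#' @param label optional description of the synapse/protocol.
#' @return data.frame of class `prc_table` with columns `phi`, `F` and
#'   attributes `Pi`, `label`.
#' @export
prc_table <- function(phi, F, Pi, label = NULL) {
  stopifnot(length(phi) == length(F), Pi > 0)
  if (anyNA(phi) || anyNA(F)) stop("PRC table must not contain NA")
  if (any(phi < 0 | phi >= 1)) stop("phases must lie in [0, 1)")
  if (any(diff(phi) <= 0)) stop("phases must be strictly increasing")
  if (any(F <= -1)) stop("F(1) must exceed -1 (perturbed period positive)")
  structure(data.frame(phi = phi, F = F),
            Pi = Pi, label = label,
            class = c("prc_table", "data.frame"))
}

#' @export
print.prc_table <- function(x, ...) {
  cat(sprintf("<prc_table> %d phases in [%.3g, %.3g], Pi = %.6g%s\n",
              nrow(x), min(x$phi), max(x$phi), attr(x, "Pi"),
              if (!is.null(attr(x, "label"))) paste0("  (", attr(x, "label"), ")")
              else ""))
  cat(sprintf("  F range [%.4g, %.4g]\n", min(x$F), max(x$F)))
  invisible(x)
}

#' Measure a single-stimulus PRC in open loop
#'
#' For each phase `phi` of the grid the postsynaptic neuron is placed on its
#' limit cycle at the phase reference (upward zero crossing), a single
#' presynaptic spike event is delivered at stimulus time `ts = phi * Pi`
#' (the presynaptic waveform drives the synaptic gating `s` through the
#' release sigmoid, with `s(0) = 0`), the perturbed cycle length `P1` is the
#' interval from the reference crossing to the next upward crossing, and
#' \eqn{F^{(1)}(\phi) = P_1/P_i - 1} is tabulated.
#'
#' The reference period `Pi` is re-measured from the same initial state, so
#' the tabulated resetting vanishes identically when `gsyn = 0`.
#'
#' @param post postsynaptic [ml_neuron()] (must oscillate).
#' @param syn the [synapse()] carrying the input.
#' @param pre presynaptic [ml_neuron()] whose waveform shapes the stimulus
#'   (ignored when an explicit `template` is supplied).
#' @param phases phase grid; default 50 evenly spaced points in
#'   `[0.02, 0.98]` (end points excluded to avoid the causality ambiguity of
#'   a stimulus exactly at the spike).
#' @param stimulus `"synaptic"` (default: [spike_template()] of `pre`) or
#'   `"triangular"` ([triangular_template()]).
#' @param template optional explicit waveform data.frame `(t, V)`,
#'   overriding `stimulus`.
#' @param dt output sampling interval.
#' @return A [prc_table()].
#' @export
measure_prc <- function(post, syn, pre = NULL,
                        phases = seq(0.02, 0.98, length.out = 50),
                        stimulus = c("synaptic", "triangular"),
                        template = NULL, dt = ode_defaults$dt) {
  stimulus <- match.arg(stimulus)
  stopifnot(all(phases >= 0 & phases < 1))
  if (is.null(template)) {
    template <- switch(stimulus,
      synaptic = {
        if (is.null(pre)) stop("'pre' neuron required for the synaptic stimulus")
        spike_template(pre, dt = dt)
      },
      triangular = triangular_template())
  }
  lc <- limit_cycle_state(post)
  ## reference period measured from the very state every trial starts from
  ref <- simulate_neuron(post, 6 * lc$period, init = lc$state, dt = dt)
  Pi_ <- mean(diff(unclass(detect_spikes(ref))))
  F1 <- vapply(phases, function(ph) {
    ts <- ph * Pi_
    dur <- ts + 3 * Pi_
    tr <- sim_stimulated(post, syn, template, ts, dur,
                         init = c(lc$state, s = 0), dt = dt)
    sp <- detect_spikes(tr)
    if (!length(sp))
      stop(sprintf("stimulus suppressed firing at phase %.3g", ph))
    sp[1] / Pi_ - 1
  }, numeric(1))
  kind <- if (syn$Esyn >= -0.05) "excitatory" else "inhibitory"
  prc_table(phases, F1, Pi_,
            label = sprintf("%s gsyn=%g (%s stimulus)", kind, syn$gsyn,
                            if (is.null(attr(template, "crossing")) ||
                                attr(template, "crossing") == 0)
                              "synaptic" else "triangular"))
}

#' Type-1 normal-form PRC
#'
#' Near a saddle-node-on-invariant-circle (SNIC) bifurcation the unimodal
#' type-1 PRC is described by
#' \eqn{F^{(1)}(\phi) = c\,(1 - \cos 2\pi\phi)}, where the signed amplitude
#' coefficient `c` absorbs the stimulus strength and the oscillator's
#' angular frequency. This amplitude convention is the one under which the
#' fitted `c` is affine in the synaptic conductance (see
#' [calibrate_coupling_map()]) and under which the closed-form fixed point
#' of the interneuron equation inverts the cosine directly (see
#' [analytic_t2sa()]).
#'
#' @param c signed amplitude; negative for excitatory (advance-only) input
#'   on a type-1 oscillator, positive for inhibitory.
#' @param Pi intrinsic period of the oscillator the curve belongs to.
#' @return object of class `normal_form_prc`.
#' @export
normal_form_prc <- function(c, Pi) {
  stopifnot(is.finite(c), Pi > 0)
  structure(list(c = c, Pi = Pi), class = "normal_form_prc")
}

#' @export
print.normal_form_prc <- function(x, ...) {
  cat(sprintf("<normal_form_prc> F(phi) = %g * (1 - cos 2 pi phi), Pi = %g\n",
              x$c, x$Pi))
  invisible(x)
}

#' Evaluate the normal-form PRC
#'
#' @param prc a [normal_form_prc()].
#' @param phi phase(s).
#' @return `c * (1 - cos(2 pi phi))`.
#' @export
normal_form_value <- function(prc, phi) prc$c * (1 - cos(2 * pi * phi))

#' Evaluate a PRC at given phases
#'
#' Generic evaluation: natural cubic spline through the grid for measured
#' tables (extrapolation beyond the grid is refused), the closed form for
#' normal forms, and direct call for plain functions.
#'
#' @param prc a [prc_table()], [normal_form_prc()] or function of phase.
#' @param phi phases at which to evaluate.
#' @param deriv 0 for the value, 1 for the slope dF/dphi.
#' @return numeric vector.
#' @export
prc_value <- function(prc, phi, deriv = 0) UseMethod("prc_value")

#' @export
prc_value.prc_table <- function(prc, phi, deriv = 0) {
  rng <- range(prc$phi)
  if (any(phi < rng[1] - 1e-12 | phi > rng[2] + 1e-12))
    stop(sprintf("phase outside the measured grid [%.3g, %.3g]; refusing to extrapolate",
                 rng[1], rng[2]))
  sf <- stats::splinefun(prc$phi, prc$F, method = "natural")
  sf(phi, deriv = deriv)
}

#' @export
prc_value.normal_form_prc <- function(prc, phi, deriv = 0) {
  if (deriv == 0) normal_form_value(prc, phi)
  else if (deriv == 1) 2 * pi * prc$c * sin(2 * pi * phi)
  else stop("deriv must be 0 or 1")
}

#' @export
prc_value.function <- function(prc, phi, deriv = 0) {
  if (deriv == 0) vapply(phi, prc, numeric(1))
  else {  # central finite difference for plain functions
    h <- 1e-6
    (vapply(phi + h, prc, numeric(1)) - vapply(phi - h, prc, numeric(1))) / (2 * h)
  }
}

#' PRC slope
#'
#' Derivative dF/dphi of a smooth interpolant at `phi`; for measured tables
#' a natural cubic spline through the grid, for normal forms the analytic
#' `2 pi c sin(2 pi phi)`.
#'
#' @inheritParams prc_value
#' @export
prc_slope <- function(prc, phi) prc_value(prc, phi, deriv = 1)

#' Fit the normal form to a measured PRC
#'
#' Least-squares estimate of the amplitude `c` in
#' `F(phi) = c (1 - cos 2 pi phi)`, holding the period fixed at the table's.
#' Linear in `c`, so the estimate is closed-form.
#'
#' @param table a [prc_table()] with at least 5 points.
#' @return [normal_form_prc()] with attributes `rms` (residual root mean
#'   square) and `n`.
#' @export
fit_normal_form <- function(table) {
  stopifnot(inherits(table, "prc_table"), nrow(table) >= 5)
  b <- 1 - cos(2 * pi * table$phi)
  chat <- sum(table$F * b) / sum(b * b)
  out <- normal_form_prc(chat, attr(table, "Pi"))
  attr(out, "rms") <- sqrt(mean((table$F - chat * b)^2))
  attr(out, "n") <- nrow(table)
  out
}

#' Affine conductance-to-coupling calibration
#'
#' Ordinary least-squares fit of the affine law `c(g) = slope * g +
#' intercept` relating the maximal synaptic conductance to the fitted
#' normal-form amplitude. The law is a weak-coupling linearization: the
#' fitted `c` saturates visibly for strong conductances, so the sweep should
#' stay in the regime where the intercept remains near zero.
#'
#' @param gs conductance values (>= 3 distinct).
#' @param fitted_cs matching normal-form amplitudes.
#' @param label optional synapse identity (e.g. `"1->2"`).
#' @return object of class `coupling_calibration` with fields `slope`,
#'   `intercept`, `label`, `data`.
#' @export
calibrate_coupling_map <- function(gs, fitted_cs, label = NULL) {
  if (length(unique(gs)) < 3)
    stop("insufficient points: need >= 3 distinct conductances")
  stopifnot(length(gs) == length(fitted_cs))
  fit <- stats::lm(fitted_cs ~ gs)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 label = label,
                 data = data.frame(g = gs, c = fitted_cs)),
            class = "coupling_calibration")
}

#' @export
print.coupling_calibration <- function(x, ...) {
  cat(sprintf("<coupling_calibration>%s c(g) = %.5g * g + %.5g  (n = %d)\n",
              if (!is.null(x$label)) paste0(" ", x$label, ":") else "",
              x$slope, x$intercept, nrow(x$data)))
  invisible(x)
}

#' @rdname calibrate_coupling_map
#' @param calibration a `coupling_calibration`.
#' @param g conductance(s).
#' @return `coupling_c()` returns the predicted amplitude(s) `c(g)`.
#' @export
coupling_c <- function(calibration, g) {
  calibration$slope * g + calibration$intercept
}

#' Sweep a synapse's conductance and calibrate c(g)
#'
#' Measures the open-loop PRC of `post` for each conductance in `gs`, fits
#' the normal-form amplitude to each table and regresses the amplitudes on
#' the conductance.
#'
#' @param post,pre postsynaptic and presynaptic [ml_neuron()]s.
#' @param gs conductance sweep (>= 3 values in the weak-coupling regime).
#' @param Esyn synaptic reversal potential (0 excitatory, -0.6 inhibitory).
#' @param phases phase grid passed to [measure_prc()].
#' @param label forwarded to the calibration object.
#' @param ... further arguments to [measure_prc()].
#' @return [calibrate_coupling_map()] result; attribute `tables` holds the
#'   measured PRC tables.
#' @export
sweep_coupling <- function(post, pre, gs, Esyn = 0,
                           phases = seq(0.02, 0.98, length.out = 50),
                           label = NULL, ...) {
  tables <- lapply(gs, function(g)
    measure_prc(post, synapse(g, Esyn = Esyn), pre, phases = phases, ...))
  cs <- vapply(tables, function(tb) fit_normal_form(tb)$c, numeric(1))
  out <- calibrate_coupling_map(gs, cs, label = label)
  attr(out, "tables") <- tables
  out
}
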