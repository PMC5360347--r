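#' Morris-Lecar neuron parameters
#'
#' Constructs the full dimensionless parameterization of a single-compartment
#' Morris-Lecar (ML) oscillator with an instantaneous calcium activation
#' \eqn{m_\infty(V)}, a delayed potassium gate \eqn{w}, a leak current and a
#' constant bias current \eqn{I_0}:
#' \deqn{dV/dt = -\bar g_{Ca} m_\infty(V)(V - E_{Ca}) - \bar g_K w (V - E_K)
#'               - \bar g_{Leak}(V - E_{Leak}) + I_0,}
#' \deqn{dw/dt = \phi \cosh\!\big((V - V_{w,1/2})/(2 V_{w,slope})\big)
#'               (w_\infty(V) - w),}
#' with sigmoidal steady states
#' \eqn{x_\infty(V) = (1 + \tanh((V - V_{x,1/2})/V_{x,slope}))/2}.
#' The gate relaxation time is the reciprocal of the cosh term (the standard
#' ML form; some sources typeset it ambiguously as "cosh^-1").
#'
#' The defaults are the dimensionless class I (type 1 PRC) set: voltages are
#' normalized by 120 mV, conductances by 4 mS/cm^2 and currents by
#' 480 uA/cm^2, so e.g. `ELeak = -0.5` corresponds to -60 mV. With the
#' default bias `I0 = 0.070` the cell fires with an intrinsic period of about
#' 60 time units (1 time unit is identified with 1 ms throughout).
#'
#' @param gCa,gK,gLeak maximal conductances (dimensionless, > 0).
#' @param ECa,EK,ELeak reversal potentials (dimensionless).
#' @param Vm_half,Vm_slope half-activation and slope of the calcium gate.
#' @param Vw_half,Vw_slope half-activation and slope of the potassium gate.
#' @param phi temperature-like rate factor of the potassium gate (> 0).
#' @param I0 constant bias current; sets the firing rate (class I f-I curve).
#' @return An object of class `ml_neuron` (a named list of parameters).
#' @seealso [calibrate_bias()] to set `I0` from a target period,
#'   [intrinsic_period()], [simulate_neuron()].
#' @examples
#' nrn <- ml_neuron()
#' nrn$I0
#' @export
ml_neuron <- function(gCa = 1.33, gK = 2.0, gLeak = 0.5,
                      ECa = 1.0, EK = -0.7, ELeak = -0.5,
                      Vm_half = -0.01, Vm_slope = 0.15,
                      Vw_half = 0.1, Vw_slope = 0.145,
                      phi = 0.6, I0 = 0.070) {
  p <- list(gCa = gCa, gK = gK, gLeak = gLeak,
            ECa = ECa, EK = EK, ELeak = ELeak,
            Vm_half = Vm_half, Vm_slope = Vm_slope,
            Vw_half = Vw_half, Vw_slope = Vw_slope,
            phi = phi, I0 = I0)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    stop("all ml_neuron parameters must be finite numeric scalars")
  if (gCa < 0 || gK < 0 || gLeak < 0)
    stop("conductances gCa, gK, gLeak must be non-negative")
  if (phi <= 0) stop("phi must be positive")
  if (Vm_slope == 0 || Vw_slope == 0)
    stop("gating slopes must be nonzero")
  structure(p, class = "ml_neuron")
}

#' @export
print.ml_neuron <- function(x, ...) {
  cat("<ml_neuron> dimensionless Morris-Lecar parameters\n")
  cat(sprintf("  gCa=%g gK=%g gLeak=%g  ECa=%g EK=%g ELeak=%g\n",
              x$gCa, x$gK, x$gLeak, x$ECa, x$EK, x$ELeak))
  cat(sprintf("  m: half=%g slope=%g   w: half=%g slope=%g  phi=%g\n",
              x$Vm_half, x$Vm_slope, x$Vw_half, x$Vw_slope, x$phi))
  cat(sprintf("  bias current I0=%g\n", x$I0))
  invisible(x)
}

#' Chemical synapse parameters
#'
#' First-order kinetic synapse. The fraction of open channels follows
#' \eqn{s' = \alpha T(V_{pre})(1 - s) - \beta s} with neurotransmitter
#' release \eqn{T(V_{pre}) = 1/(1 + e^{-(V_{pre} - T_{1/2}) T_{scale}})},
#' a rising sigmoid of the presynaptic membrane potential. The synaptic
#' current into the postsynaptic cell is
#' \eqn{I_{syn} = \bar g_{syn} s (V_{post} - E_{syn})}.
#'
#' @param gsyn maximal synaptic conductance (>= 0, dimensionless).
#' @param Esyn reversal potential: 0 for excitatory, -0.6 for inhibitory
#'   coupling (dimensionless).
#' @param alpha_on,beta_off opening and closing rates (> 0).
#' @param T_half,T_scale half-activation (0.2, i.e. 24 mV in physical units)
#'   and steepness (120/5 = 24) of the release sigmoid.
#' @return An object of class `ml_synapse`.
#' @examples
#' excitatory_synapse(0.015)
#' inhibitory_synapse(0.002)
#' @export
synapse <- function(gsyn, Esyn = 0, alpha_on = 15, beta_off = 1.5,
                    T_half = 0.2, T_scale = 120 / 5) {
  stopifnot(is.numeric(gsyn), length(gsyn) == 1, is.finite(gsyn))
  if (gsyn < 0) stop("gsyn must be >= 0")
  if (alpha_on <= 0 || beta_off <= 0) stop("alpha_on and beta_off must be positive")
  structure(list(gsyn = gsyn, Esyn = Esyn, alpha_on = alpha_on,
                 beta_off = beta_off, T_half = T_half, T_scale = T_scale),
            class = "ml_synapse")
}

#' @rdname synapse
#' @export
excitatory_synapse <- function(gsyn, ...) synapse(gsyn, Esyn = 0, ...)

#' @rdname synapse
#' @export
inhibitory_synapse <- function(gsyn, ...) synapse(gsyn, Esyn = -0.6, ...)

#' @export
print.ml_synapse <- function(x, ...) {
  kind <- if (x$Esyn >= -0.05) "excitatory" else "inhibitory"
  cat(sprintf("<ml_synapse> %s: gsyn=%g Esyn=%g alpha=%g beta=%g T(half=%g, scale=%g)\n",
              kind, x$gsyn, x$Esyn, x$alpha_on, x$beta_off, x$T_half, x$T_scale))
  invisible(x)
}

#' Spike train container
#'
#' A strictly increasing vector of spike (threshold-crossing) times.
#'
#' @param times numeric vector of event times, model time units.
#' @return Numeric vector of class `spike_train`.
#' @export
spike_train <- function(times) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  structure(times, class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", length(x)))
  if (length(x) > 1)
    cat(sprintf(" over [%.3g, %.3g], mean ISI %.4g", x[1], x[length(x)],
                mean(diff(unclass(x)))))
  cat("\n")
  invisible(x)
}
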