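# End-to-end pipelines: open-loop prediction of the phase-locked mode, and
# validation of that prediction against the closed-loop simulation.

#' Predict the network's phase-locked mode from open-loop PRCs
#'
#' Runs the full open-loop program: calibrate the three bias currents to the
#' target periods, measure the three single-stimulus PRCs (slave to its
#' inhibitory and excitatory inputs, interneuron to its excitatory input),
#' solve the fixed-point equations for all candidate modes, and analyze the
#' stability of each. The predicted mode is the stable candidate with the
#' smallest `t2sa*` (an unstable mode is never observable in simulation);
#' if no candidate is stable the first candidate is reported and flagged.
#'
#' @param config a [network_config()].
#' @param phases phase grid for PRC measurement.
#' @param stimulus stimulus shape forwarded to [measure_prc()].
#' @return list of class `mode_prediction`: `config` (calibrated), `prcs`
#'   (list `F2_inh`, `F2_exc`, `F3`), `modes`, `stability` (per mode),
#'   `predicted`, `predicted_stability`, `predicted_is_stable`.
#' @export
predict_network_mode <- function(config,
                                 phases = seq(0.02, 0.98, length.out = 50),
                                 stimulus = "synaptic") {
  if (is.null(config$neurons)) config <- calibrate_network(config)
  ns <- config$neurons
  prcs <- list(
    F2_inh = measure_prc(ns$n2, inhibitory_synapse(config$g32), ns$n3,
                         phases = phases, stimulus = stimulus),
    F2_exc = measure_prc(ns$n2, excitatory_synapse(config$g12), ns$n1,
                         phases = phases, stimulus = stimulus),
    F3 = measure_prc(ns$n3, excitatory_synapse(config$g23), ns$n2,
                     phases = phases, stimulus = stimulus))
  modes <- find_modes(prcs$F2_inh, prcs$F2_exc, prcs$F3,
                      config$P1i, config$P2i, config$P3i)
  if (!length(modes))
    no_solution("no phase-locked mode candidates for this configuration")
  stab <- lapply(modes, mode_stability,
                 F2_inh = prcs$F2_inh, F2_exc = prcs$F2_exc, F3 = prcs$F3,
                 P2i = config$P2i, P3i = config$P3i)
  stable <- vapply(stab, function(s) s$verdict == "stable", logical(1))
  pick <- if (any(stable)) which(stable)[1] else 1L
  structure(list(config = config, prcs = prcs, modes = modes,
                 stability = stab,
                 predicted = modes[[pick]],
                 predicted_stability = stab[[pick]],
                 predicted_is_stable = stable[pick]),
            class = "mode_prediction")
}

#' @export
print.mode_prediction <- function(x, ...) {
  cat(sprintf("<mode_prediction> %d candidate mode(s); predicted:\n",
              length(x$modes)))
  print(x$predicted)
  ev <- x$predicted_stability$eigenvalues
  cat(sprintf("  eigenvalues %s -> %s\n",
              paste(format(ev, digits = 4), collapse = ", "),
              x$predicted_stability$verdict))
  invisible(x)
}

#' Validate the open-loop prediction against the closed-loop network
#'
#' Predicts the mode from open-loop PRCs, simulates the fully coupled
#' network from random initial phases, extracts the measured steady timing
#' and reports absolute and percent prediction errors.
#'
#' @param config a [network_config()].
#' @param n_cycles closed-loop simulation length in master periods.
#' @param discard transient cycles dropped before steady-state extraction.
#' @param phases,stimulus forwarded to [predict_network_mode()].
#' @param init forwarded to [simulate_network()].
#' @return list of class `network_validation`: `prediction`, `sim`,
#'   `measured`, `comparison`.
#' @export
validate_network <- function(config, n_cycles = 110, discard = 20,
                             phases = seq(0.02, 0.98, length.out = 50),
                             stimulus = "synaptic", init = "random") {
  pred <- predict_network_mode(config, phases = phases, stimulus = stimulus)
  sim <- simulate_network(pred$config, n_cycles = n_cycles, init = init)
  meas <- extract_mode(sim, discard = discard)
  structure(list(prediction = pred, sim = sim, measured = meas,
                 comparison = compare_prediction(meas, pred$predicted)),
            class = "network_validation")
}

#' @export
print.network_validation <- function(x, ...) {
  cat("<network_validation>\n  measured: ")
  print(x$measured)
  cat("  predicted: ")
  print(x$prediction$predicted)
  print(x$comparison)
  invisible(x)
}
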