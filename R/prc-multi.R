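# Multi-stimulus phase resetting: recursive composition of single-stimulus
# PRCs for two or n inputs arriving within the same cycle.
#
# The key modeling assumption is that each resetting takes effect "almost"
# instantaneously, before the next stimulus arrives, so stimulus k sees the
# oscillator with the period already modified by stimuli 1..k-1. Stimulus
# times (not phases) are the canonical inputs; phases are derived as
# phi_k = ts_k / P_{k-1}.

#' Composed resetting for two stimuli in one cycle
#'
#' The first stimulus at time `tsa` changes the period to
#' `Pa = Pi (1 + F_a(tsa / Pi))`; the second stimulus at `tsb` then arrives
#' at phase `tsb / Pa` of the modified cycle, giving
#' \deqn{F^{(2)}(t_{sa}, t_{sb}) =
#'   (1 + F_a(t_{sa}/P_i))(1 + F_b(t_{sb}/(P_i(1 + F_a(t_{sa}/P_i))))) - 1.}
#' The two stimuli may act through different PRCs (in the three-neuron
#' network the slave's first input is inhibitory, the second excitatory).
#' The composition is not commutative.
#'
#' @param F_a,F_b single-stimulus PRCs of the first and second input: a
#'   [prc_table()], [normal_form_prc()] or function of phase.
#' @param tsa,tsb stimulus times, `0 <= tsa < tsb`; `tsb` must fall inside
#'   the transiently modified cycle (`tsb < Pa`).
#' @param Pi intrinsic period.
#' @return list of class `multi_prc` with the composed resetting `F`, the
#'   intermediate periods `periods = c(P0 = Pi, Pa, Pn)` and the stimulus
#'   phases `phases`.
#' @export
compose_two <- function(F_a, F_b, tsa, tsb, Pi) {
  stopifnot(Pi > 0, tsa >= 0)
  if (tsb <= tsa) stop("stimulus times must satisfy tsa < tsb")
  Fa <- prc_value(F_a, tsa / Pi)
  Pa <- Pi * (1 + Fa)
  if (tsb >= Pa)
    stop(sprintf("second stimulus outside modified cycle: tsb = %g >= Pa = %g",
                 tsb, Pa))
  ## Eq-level single expression for the composed resetting
  F2 <- (1 + Fa) * (1 + prc_value(F_b, tsb / (Pi * (1 + Fa)))) - 1
  structure(list(F = F2,
                 periods = c(P0 = Pi, Pa = Pa, Pn = Pi * (1 + F2)),
                 phases = c(phi_a = tsa / Pi, phi_b = tsb / Pa),
                 ts = c(tsa, tsb)),
            class = "multi_prc")
}

#' Composed resetting for n stimuli in one cycle
#'
#' Running-product generalization:
#' \deqn{P_n = P_i \prod_{k=1}^{n} (1 + F^{(1)}_k(t_{sk}/P_{k-1})),}
#' with `P_0 = Pi` and each `ts_k` required to fall inside the transiently
#' modified period `P_{k-1}` left by the previous stimuli.
#'
#' @param prcs a single PRC (recycled) or list of per-stimulus PRCs
#'   ([prc_table()], [normal_form_prc()] or functions).
#' @param ts strictly increasing stimulus times within the cycle.
#' @param Pi intrinsic period.
#' @return list of class `multi_prc`: composed `F` (so that
#'   `Pn = Pi (1 + F)`), all intermediate `periods` `P0..Pn`, and the
#'   per-stimulus `phases`.
#' @export
compose_n <- function(prcs, ts, Pi) {
  stopifnot(Pi > 0, length(ts) >= 1)
  if (any(ts < 0)) stop("stimulus times must be non-negative")
  if (length(ts) > 1 && any(diff(ts) <= 0))
    stop("stimulus times must be strictly increasing")
  if (!is.list(prcs) || inherits(prcs, c("prc_table", "normal_form_prc")))
    prcs <- rep(list(prcs), length(ts))
  if (length(prcs) != length(ts))
    stop("need one PRC per stimulus (or a single PRC for all)")
  P <- numeric(length(ts) + 1)
  phases <- numeric(length(ts))
  P[1] <- Pi
  for (k in seq_along(ts)) {
    if (ts[k] >= P[k])
      stop(sprintf(
        "stimulus %d outside modified cycle: ts = %g >= P%d = %g",
        k, ts[k], k - 1, P[k]))
    phases[k] <- ts[k] / P[k]
    P[k + 1] <- P[k] * (1 + prc_value(prcs[[k]], phases[k]))
    if (P[k + 1] <= 0)
      stop(sprintf("non-positive intermediate period after stimulus %d", k))
  }
  names(P) <- paste0("P", seq_along(P) - 1)
  structure(list(F = unname(P[length(P)] / Pi - 1),
                 periods = P, phases = phases, ts = ts),
            class = "multi_prc")
}

#' @export
print.multi_prc <- function(x, ...) {
  cat(sprintf("<multi_prc> %d stimuli: F(%d) = %.6g, Pn = %.6g (Pi = %.6g)\n",
              length(x$ts), length(x$ts), x$F,
              x$periods[length(x$periods)], x$periods[1]))
  invisible(x)
}
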