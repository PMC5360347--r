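# Linear stability of a phase-locked mode via the cycle-to-cycle return map
# of the perturbations (delta t2sa[n], delta t2sb[n]).
#
# Linearizing the two recursive timing equations around the fixed point
# gives delta[n+1] = A delta[n] with
#   a11 = (1 - m3)(1 - b)   a12 = (m3 - 1) m2b
#   a21 = -b                a22 = 1 - m2b
#   b   = m2a (1 + F2exc(phi2b*) - m2b phi2b*)
# where m2a, m2b, m3 are PRC slopes at the steady phases. The same matrix
# falls out of an independent re-derivation of the Jacobian of the timing
# map, which is how the ambiguous grouping inside b was fixed.

#' PRC slopes at the steady phases of a mode
#'
#' The three slopes entering the return map, each taken from the PRC the
#' corresponding input acts through, at the mode's steady phases:
#' `phi2a* = t2sa*/P2i` (inhibition onto the slave),
#' `phi2b* = t2sb*/(P2i alpha)` (excitation onto the slave, phase measured
#' in the inhibition-modified cycle), and `phi3* = (P1i - t2sa*)/P3i`
#' (excitation onto the interneuron).
#'
#' @param mode a [phase_locked_mode()].
#' @param F2_inh,F2_exc,F3 the PRCs used to find the mode.
#' @param P2i,P3i slave and interneuron periods.
#' @return list `m2a`, `m2b`, `m3`, `phi2a`, `phi2b`, `phi3`, `F2b`
#'   (the excitatory PRC value at `phi2b*`, needed by the matrix).
#' @export
mode_slopes <- function(mode, F2_inh, F2_exc, F3, P2i, P3i) {
  alpha <- if (!is.na(mode$alpha)) mode$alpha
           else 1 + prc_value(F2_inh, mode$t2sa / P2i)
  phi2a <- mode$t2sa / P2i
  phi2b <- mode$t2sb / (P2i * alpha)
  phi3 <- (mode$P1i - mode$t2sa) / P3i
  list(m2a = prc_slope(F2_inh, phi2a),
       m2b = prc_slope(F2_exc, phi2b),
       m3 = prc_slope(F3, phi3),
       phi2a = phi2a, phi2b = phi2b, phi3 = phi3,
       F2b = prc_value(F2_exc, phi2b))
}

#' Build the perturbation return-map matrix
#'
#' @param m2a,m2b,m3 PRC slopes at the steady phases (see [mode_slopes()]).
#' @param F2b_at_mode value of the slave's excitatory PRC at `phi2b*`.
#' @param phi2b steady phase of the second stimulus.
#' @param tol_marginal half-width of the band around `|lambda| = 1` that is
#'   reported as "marginal" rather than stable/unstable.
#' @return object of class `stability_result`: matrix entries, `b`, trace,
#'   determinant, eigenvalues (decreasing modulus), verdict and root type.
#' @export
stability_matrix <- function(m2a, m2b, m3, F2b_at_mode, phi2b,
                             tol_marginal = 1e-6) {
  stopifnot(is.finite(m2a), is.finite(m2b), is.finite(m3),
            is.finite(F2b_at_mode), is.finite(phi2b))
  b <- m2a * (1 + F2b_at_mode - m2b * phi2b)
  A <- matrix(c((1 - m3) * (1 - b), (m3 - 1) * m2b,
                -b, 1 - m2b),
              nrow = 2, byrow = TRUE)
  Tr <- A[1, 1] + A[2, 2]
  Det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  ev <- eigen(A, only.values = TRUE)$values
  ev <- ev[order(Mod(ev), decreasing = TRUE)]
  cls <- classify(Tr, Det, tol_marginal)
  structure(list(A = A, b = b, slopes = c(m2a = m2a, m2b = m2b, m3 = m3),
                 Tr = Tr, Det = Det, eigenvalues = ev,
                 verdict = cls$verdict, root_type = cls$root_type),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result>\n")
  cat(sprintf("  A = [% .5g % .5g; % .5g % .5g]   b = %.5g\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$b))
  cat(sprintf("  Tr = %.5g  Det = %.5g  eigenvalues: %s (%s)\n",
              x$Tr, x$Det,
              paste(format(x$eigenvalues, digits = 4), collapse = ", "),
              x$root_type))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' Classify a 2-D linear recursion by trace and determinant
#'
#' The characteristic polynomial is
#' `P(lambda) = lambda^2 - Tr lambda + Det`. Roots are complex when
#' `Det > Tr^2 / 4`, in which case both have modulus `sqrt(Det)` and the map
#' is stable iff `Det < 1`. Real roots are stable iff both lie strictly
#' inside the unit interval, equivalently `P(-1) > 0`, `P(1) > 0` and
#' `|Tr| < 1 + Det` — evaluated here directly on the roots.
#'
#' @param Tr,Det trace and determinant of the recursion matrix.
#' @param tol_marginal width of the "marginal" band around modulus 1.
#' @return list `verdict` ("stable", "unstable" or "marginal"),
#'   `root_type` ("real" or "complex"), `max_modulus`.
#' @export
classify <- function(Tr, Det, tol_marginal = 1e-6) {
  disc <- Tr^2 / 4 - Det
  if (disc < 0) {
    root_type <- "complex"
    maxmod <- sqrt(Det)
  } else {
    root_type <- "real"
    roots <- Tr / 2 + c(-1, 1) * sqrt(disc)
    maxmod <- max(abs(roots))
  }
  verdict <- if (abs(maxmod - 1) <= tol_marginal) "marginal"
             else if (maxmod < 1) "stable" else "unstable"
  list(verdict = verdict, root_type = root_type, max_modulus = maxmod)
}

#' Iterate the linear perturbation map
#'
#' Brute-force companion to [classify()]: applies the recursion matrix
#' repeatedly to an initial perturbation.
#'
#' @param A 2x2 recursion matrix (or a `stability_result`).
#' @param delta0 initial perturbation pair.
#' @param n_steps number of iterations (>= 1).
#' @return matrix with `n_steps + 1` rows (row 1 is `delta0`).
#' @export
iterate_map <- function(A, delta0 = c(1, 1), n_steps = 50) {
  if (inherits(A, "stability_result")) A <- A$A
  stopifnot(n_steps >= 1, length(delta0) == 2)
  out <- matrix(NA_real_, n_steps + 1, 2)
  out[1, ] <- delta0
  for (k in seq_len(n_steps)) out[k + 1, ] <- A %*% out[k, ]
  colnames(out) <- c("dt2sa", "dt2sb")
  out
}

#' Stability of a phase-locked mode
#'
#' Convenience wrapper: [mode_slopes()] then [stability_matrix()].
#'
#' @inheritParams mode_slopes
#' @return a `stability_result`.
#' @export
mode_stability <- function(mode, F2_inh, F2_exc, F3, P2i, P3i) {
  s <- mode_slopes(mode, F2_inh, F2_exc, F3, P2i, P3i)
  stability_matrix(s$m2a, s$m2b, s$m3, s$F2b, s$phi2b)
}
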