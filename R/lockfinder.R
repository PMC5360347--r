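# Existence of phase-locked modes in the three-neuron master-slave network
# with a dynamic inhibitory loop.
#
# Topology: neuron 1 (master, period P1i) excites neuron 2 (slave, P2i)
# through g12; neuron 2 excites the interneuron 3 (P3i) through g23;
# neuron 3 inhibits neuron 2 through g32. In the assumed firing pattern the
# slave receives two inputs per cycle: first the inhibition at time t2sa
# after its spike, later the master's excitation at t2sb; it recovers for
# t2r and fires again. At a phase-locked mode the network adopts the master
# period, which pins the steady times by two fixed-point equations:
#
#   interneuron:  F3( (P1i - t2sa*) / P3i ) = P1i/P3i - 1
#   slave:        F2exc( t2sb* / (alpha P2i) ) = P1i/(alpha P2i) - 1,
#                 alpha = 1 + F2inh( t2sa* / P2i )
#
# Both are solved on a fine grid with bisection; all roots are reported.

no_solution <- function(msg) {
  stop(structure(class = c("phaselock_no_solution", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## phase interval a PRC can be evaluated on
prc_domain <- function(prc) {
  if (inherits(prc, "prc_table")) range(prc$phi) else c(0, 1 - 1e-9)
}

## all sign-change roots of f on [lo, hi], grid-then-bisect
grid_roots <- function(f, lo, hi, n = 2000, tol = 1e-12) {
  if (!(hi > lo)) return(numeric(0))
  g <- seq(lo, hi, length.out = n)
  v <- vapply(g, f, numeric(1))
  i <- which(v[-n] * v[-1] < 0)
  r <- vapply(i, function(k)
    stats::uniroot(f, c(g[k], g[k + 1]), tol = tol)$root, numeric(1))
  sort(unique(c(r, g[v == 0])))
}

#' Steady first-stimulus time of the slave: interneuron fixed point
#'
#' Solves `F3((P1i - t2sa)/P3i) = P1i/P3i - 1` for all roots with the
#' interneuron stimulus phase inside the PRC's covered range and `t2sa`
#' inside `domain`. For an excitatory (advance-only) interneuron PRC the
#' equation is solvable only for `P1i < P3i`, and only if the coupling
#' resets the interneuron strongly enough (see [existence_bounds()]).
#'
#' @param F3 interneuron PRC (input from the slave via g23): [prc_table()],
#'   [normal_form_prc()] or function of phase.
#' @param P1i,P3i intrinsic periods of master and interneuron.
#' @param domain admissible `t2sa` interval (default one master period).
#' @param n grid resolution for root bracketing.
#' @return data.frame `(t2sa, phi3, branch)`, branch numbering roots by
#'   increasing `t2sa`.
#' @export
solve_t2sa <- function(F3, P1i, P3i, domain = c(0, P1i), n = 2000) {
  target <- P1i / P3i - 1
  pd <- prc_domain(F3)
  ## tables refuse extrapolation, so shrink the interval just inside the
  ## grid; analytic PRCs keep the exact end points (tangential roots such as
  ## t2sa = k P1i live there)
  eps <- if (inherits(F3, "prc_table")) 1e-9 else 0
  lo <- max(domain[1], P1i - pd[2] * P3i + eps)
  hi <- min(domain[2], P1i - pd[1] * P3i - eps)
  if (!(hi > lo))
    no_solution("no solution: PRC phase coverage excludes the whole domain")
  f <- function(t) prc_value(F3, (P1i - t) / P3i) - target
  r <- grid_roots(f, lo, hi, n)
  if (!length(r)) {
    rngF <- range(vapply(seq(lo, hi, length.out = 512),
                         function(t) prc_value(F3, (P1i - t) / P3i),
                         numeric(1)))
    no_solution(sprintf(
      "no solution: required resetting %.4g outside attainable range [%.4g, %.4g]",
      target, rngF[1], rngF[2]))
  }
  data.frame(t2sa = r, phi3 = (P1i - r) / P3i, branch = seq_along(r))
}

#' Closed-form interneuron fixed point for normal-form PRCs
#'
#' With `F3(phi) = c23 (1 - cos 2 pi phi)` the fixed-point equation inverts
#' to \deqn{\cos\!\big(2\pi (P_{1i} - t_{2sa}^*)/P_{3i}\big) =
#'   1 - \frac{1}{c_{23}}\Big(\frac{P_{1i}}{P_{3i}} - 1\Big),}
#' giving two root branches per period. An empty result signals
#' nonexistence (right-hand side outside `[-1, 1]`).
#'
#' @param c23 normal-form amplitude of the interneuron PRC (signed).
#' @param P1i,P3i intrinsic periods.
#' @param domain admissible `t2sa` interval (default `c(0, P1i)`, closed on
#'   the right so the strong-coupling limit `t2sa -> P1i` is representable).
#' @return data.frame `(t2sa, phi3, k, sign)`; zero rows when no mode exists.
#' @export
analytic_t2sa <- function(c23, P1i, P3i, domain = c(0, P1i)) {
  empty <- data.frame(t2sa = numeric(0), phi3 = numeric(0),
                      k = integer(0), sign = integer(0))
  if (c23 == 0) {
    if (P1i != P3i) return(empty)
    theta <- 0
  } else {
    rhs <- 1 - (P1i / P3i - 1) / c23
    if (rhs < -1 || rhs > 1) return(empty)
    theta <- acos(rhs)            # in [0, pi]
  }
  ## 2 pi phi3 = +-theta + 2 pi k, t2sa = P1i - P3i phi3
  ks <- seq(floor((P1i - domain[2]) / P3i) - 1,
            ceiling((P1i - domain[1]) / P3i) + 1)
  out <- do.call(rbind, lapply(ks, function(k) {
    phi <- c(k + theta / (2 * pi), k - theta / (2 * pi))
    data.frame(t2sa = P1i - P3i * phi, phi3 = phi,
               k = k, sign = c(1L, -1L))
  }))
  out <- out[out$t2sa >= domain[1] - 1e-9 & out$t2sa <= domain[2] + 1e-9, ]
  out <- out[!duplicated(round(out$t2sa, 9)), ]
  out[order(out$t2sa), , drop = FALSE]
}

#' Admissible interneuron period interval
#'
#' An excitatory interneuron PRC (advance-only, minimum `F3_min < 0`) can
#' entrain the interneuron to the master only when
#' `P1i < P3i < P1i / (1 + F3_min)`. The open interval is empty (upper bound
#' not above the lower) when `F3_min >= 0`.
#'
#' @param F3_min minimum of the interneuron PRC.
#' @param P1i master period.
#' @return `c(lower, upper)` of the open interval for `P3i`.
#' @export
existence_bounds <- function(F3_min, P1i) {
  stopifnot(P1i > 0, F3_min > -1)
  c(lower = P1i, upper = P1i / (1 + F3_min))
}

#' Steady second-stimulus time of the slave
#'
#' Given `t2sa*`, computes the inhibition-modified factor
#' `alpha = 1 + F2inh(t2sa*/P2i)` and solves
#' `F2exc(t2sb / (alpha P2i)) = P1i/(alpha P2i) - 1` for all roots with
#' `t2sa* < t2sb < min(P1i, alpha P2i)`. The two PRCs belong to the same
#' neuron but different synapses: the first input is the interneuron's
#' inhibition (g32), the second the master's excitation (g12).
#'
#' @param F2_inh slave PRC to the inhibitory input.
#' @param F2_exc slave PRC to the excitatory input.
#' @param P1i,P2i master and slave intrinsic periods.
#' @param t2sa steady first-stimulus time (from [solve_t2sa()]).
#' @param n grid resolution.
#' @return data.frame `(t2sb, phi2b, branch)` with attribute `alpha`.
#' @export
solve_t2sb <- function(F2_inh, F2_exc, P1i, P2i, t2sa, n = 2000) {
  alpha <- 1 + prc_value(F2_inh, t2sa / P2i)
  target <- P1i / (alpha * P2i) - 1
  pd <- prc_domain(F2_exc)
  lo <- max(t2sa, pd[1] * alpha * P2i) + 1e-9
  hi <- min(P1i, alpha * P2i * pd[2]) - 1e-9
  if (!(hi > lo)) no_solution("no solution: empty t2sb search interval")
  f <- function(t) prc_value(F2_exc, t / (alpha * P2i)) - target
  probe <- vapply(seq(lo, hi, length.out = 512), f, numeric(1))
  if (max(abs(probe)) < 1e-10)
    stop(structure(class = c("phaselock_degenerate", "error", "condition"),
                   list(message = paste(
                     "degenerate: fixed-point residual identically zero;",
                     "any t2sb satisfies the condition"), call = NULL)))
  r <- grid_roots(f, lo, hi, n)
  if (!length(r))
    no_solution(sprintf(
      "no solution: required resetting %.4g outside attainable range [%.4g, %.4g]",
      target, min(probe), max(probe)))
  structure(data.frame(t2sb = r, phi2b = r / (alpha * P2i),
                       branch = seq_along(r)),
            alpha = alpha)
}

#' Phase-locked mode object
#'
#' @param t2sa,t2sb steady stimulus times of the slave's two inputs.
#' @param P1i master period (pins `t2r = P1i - t2sb`).
#' @param alpha inhibition factor `1 + F2inh(t2sa/P2i)`.
#' @param branch integer pair labeling the (t2sa, t2sb) root branches.
#' @return list of class `phase_locked_mode` with fields `t2sa`, `t2sb`,
#'   `t2r`, `alpha`, `branch`.
#' @export
phase_locked_mode <- function(t2sa, t2sb, P1i, alpha = NA_real_,
                              branch = c(1L, 1L)) {
  if (!(0 < t2sa && t2sa < t2sb))
    stop("mode requires 0 < t2sa < t2sb")
  structure(list(t2sa = t2sa, t2sb = t2sb, t2r = P1i - t2sb,
                 P1i = P1i, alpha = alpha, branch = branch),
            class = "phase_locked_mode")
}

#' @export
print.phase_locked_mode <- function(x, ...) {
  cat(sprintf(
    "<phase_locked_mode> t2sa* = %.4g, t2sb* = %.4g, t2r* = %.4g (P = %g)%s\n",
    x$t2sa, x$t2sb, x$t2r, x$P1i,
    if (!is.na(x$alpha)) sprintf("  alpha = %.5g", x$alpha) else ""))
  invisible(x)
}

#' Enumerate phase-locked modes of the three-neuron network
#'
#' Chains [solve_t2sa()] and [solve_t2sb()] over all branches and verifies
#' each candidate against the steady-state conditions re-evaluated through
#' the two-stimulus composition (residual tolerance `1e-8`).
#'
#' @param F2_inh,F2_exc,F3 the three single-stimulus PRCs.
#' @param P1i,P2i,P3i intrinsic periods.
#' @return list of [phase_locked_mode()]s (may be empty if `t2sb` has no
#'   root on any `t2sa` branch; propagates a "no solution" error when the
#'   interneuron equation itself is unsolvable).
#' @export
find_modes <- function(F2_inh, F2_exc, F3, P1i, P2i, P3i) {
  sa <- solve_t2sa(F3, P1i, P3i)
  modes <- list()
  for (i in seq_len(nrow(sa))) {
    sb <- tryCatch(solve_t2sb(F2_inh, F2_exc, P1i, P2i, sa$t2sa[i]),
                   phaselock_no_solution = function(e) NULL)
    if (is.null(sb)) next
    for (j in seq_len(nrow(sb))) {
      m <- phase_locked_mode(sa$t2sa[i], sb$t2sb[j], P1i,
                             alpha = attr(sb, "alpha"),
                             branch = c(sa$branch[i], sb$branch[j]))
      ## re-evaluate both fixed-point residuals via the composed resetting
      comp <- compose_two(F2_inh, F2_exc, m$t2sa, m$t2sb, P2i)
      r1 <- P2i * (1 + comp$F) - P1i
      r2 <- P3i * (1 + prc_value(F3, (P1i - m$t2sa) / P3i)) - P1i
      if (abs(r1) > 1e-8 * P1i || abs(r2) > 1e-8 * P1i)
        stop("internal error: mode fails fixed-point re-evaluation")
      modes <- c(modes, list(m))
    }
  }
  modes
}

#' Minimum excitatory coupling for interneuron entrainment
#'
#' Existence of the interneuron fixed point with a normal-form PRC requires
#' `(P1i/P3i - 1)/c23` to lie in `[0, 2]` (saturation of the cosine). With
#' an affine calibration `c23(g23)` and `P3i > P1i`, the smallest admissible
#' conductance solves `c23(g) = -(1 - P1i/P3i)/2`.
#'
#' @param ratio period ratio `P3i / P1i` (> 1).
#' @param calibration a [calibrate_coupling_map()] result for the 2->3
#'   synapse (negative slope: excitation advances).
#' @param g_range conductance range considered reachable; `Inf` is returned
#'   when the threshold exceeds it.
#' @return `g23_min` (numeric scalar, possibly `Inf`).
#' @export
minimum_coupling <- function(ratio, calibration, g_range = c(0, 0.2)) {
  stopifnot(ratio > 1, calibration$slope < 0)
  c_needed <- -(1 - 1 / ratio) / 2
  g_min <- (c_needed - calibration$intercept) / calibration$slope
  g_min <- max(g_min, 0)
  if (g_min > g_range[2]) return(Inf)
  g_min
}

#' Phase-locked solution surface over (P3i, g23)
#'
#' Sweeps the interneuron period and the 2->3 coupling using normal-form
#' PRCs built from conductance calibrations, recording the primary mode at
#' each grid point (stable mode with the smallest `t2sa` when one exists,
#' otherwise the first existing mode). Per-point failures are recorded as
#' missing values, not errors.
#'
#' @param P3i_values,g23_values sweep grids.
#' @param cal23 calibration for the 2->3 synapse (maps g23 to c23).
#' @param c12,c32 fixed normal-form amplitudes of the slave's two inputs.
#' @param P1i,P2i master and slave periods.
#' @return long-format data.frame `(P3i, g23, exists, t2sa, t2sb, stable)`.
#' @export
mode_surface <- function(P3i_values, g23_values, cal23, c12, c32,
                         P1i = 60, P2i = 70) {
  grid <- expand.grid(P3i = P3i_values, g23 = g23_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    P3i <- grid$P3i[i]; g23 <- grid$g23[i]
    base <- data.frame(P3i = P3i, g23 = g23, exists = FALSE,
                       t2sa = NA_real_, t2sb = NA_real_, stable = NA)
    if (P3i <= P1i) return(base)
    F3 <- normal_form_prc(coupling_c(cal23, g23), P3i)
    F2i <- normal_form_prc(c32, P2i)
    F2e <- normal_form_prc(c12, P2i)
    modes <- tryCatch(find_modes(F2i, F2e, F3, P1i, P2i, P3i),
                      phaselock_no_solution = function(e) list(),
                      phaselock_degenerate = function(e) list())
    if (!length(modes)) return(base)
    st <- vapply(modes, function(m)
      mode_stability(m, F2i, F2e, F3, P2i, P3i)$verdict == "stable",
      logical(1))
    pick <- if (any(st)) which(st)[1] else 1L
    m <- modes[[pick]]
    data.frame(P3i = P3i, g23 = g23, exists = TRUE,
               t2sa = m$t2sa, t2sb = m$t2sb, stable = st[pick])
  })
  do.call(rbind, rows)
}
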