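---
title: "Methods: generalized phase resetting and phase-locked mode prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generalized phase resetting and phase-locked mode prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
neuron and synapse models, the open-loop PRC protocol, the multi-input
composition rule, the fixed-point and stability analysis of the
three-neuron circuit, and the numerical and design choices that a user
extending the package should know about.

## 1. The oscillator and synapse models

Each cell is a dimensionless single-compartment Morris–Lecar oscillator

$$\dot V = -\bar g_{Ca}\, m_\infty(V)(V - E_{Ca}) - \bar g_K\, w (V - E_K)
          - \bar g_{L}(V - E_{L}) + I_0, \qquad
  \dot w = \phi \cosh\!\Big(\frac{V - V_{w,1/2}}{2 V_{w,slope}}\Big)
           \big(w_\infty(V) - w\big),$$

with sigmoidal steady states
$x_\infty(V) = \tfrac12\big(1 + \tanh((V - V_{x,1/2})/V_{x,slope})\big)$.
The gate relaxation time is the *reciprocal* of the hyperbolic cosine — the
standard Morris–Lecar form. (Some sources typeset this factor ambiguously
as "cosh$^{-1}$"; an arccosh reading is undefined for arguments below one
and is not used.) Voltages are normalized by 120 mV, conductances by
4 mS/cm², currents by 480 µA/cm²; one model time unit is identified with
1 ms. The default parameter set (`ml_neuron()`) places the cell in the
class-I regime: oscillations are born through a saddle-node bifurcation on
an invariant circle (SNIC), the firing period grows without bound as the
bias current `I0` approaches rheobase from above (≈ 0.0693 here), and the
cell stops firing by depolarization block above ≈ 0.075. Inside that
window the period is continuous and monotonically decreasing in `I0`,
which is what makes bias calibration by bisection well-posed
(`calibrate_bias()`): targets of 60, 70 and 80 ms are met to within
0.05 ms.

Synapses are first-order kinetic:
$\dot s = \alpha T(V_{pre})(1 - s) - \beta s$ with
$T(V_{pre}) = \big(1 + e^{-(V_{pre} - 0.2)\cdot 24}\big)^{-1}$,
$\alpha = 15$, $\beta = 1.5$, and postsynaptic current
$\bar g_{syn}\, s\,(V_{post} - E_{syn})$ with $E_{syn} = 0$ (excitatory) or
$-0.6$ (inhibitory). $T$ is a *rising* sigmoid of the presynaptic
potential with half-activation at 0.2 (24 mV): transmitter is released
only around the presynaptic spike. The release threshold sits well above
the subthreshold voltage range, so the synapse is effectively
event-driven even though it is integrated as a continuous ODE — no event
queue is needed, and the closed-loop network is a plain 9-dimensional
system (three voltage/gate pairs plus one gating state per connection).

## 2. Open-loop PRC measurement

`measure_prc()` implements the single-stimulus protocol. The phase
reference φ = 0 is the upward zero crossing of the membrane potential. For
each grid phase φ the postsynaptic cell starts exactly on its limit cycle
at the reference (state obtained by settling for many cycles,
`limit_cycle_state()`), one presynaptic spike event is delivered at
$t_s = \varphi P_i$, and the perturbed cycle length $P_1$ — reference
crossing to next crossing — gives $F^{(1)}(\varphi) = P_1/P_i - 1$.
Negative values are advances. Only the current cycle is measured
(first-order resetting); second- and higher-order effects are outside the
package's scope.

Two properties of the protocol matter for accuracy:

* the reference period $P_i$ is re-measured from the very state each trial
  starts from, so a zero-conductance stimulus tabulates exactly zero, and
* the stimulus is the *actual* presynaptic waveform: one full cycle of the
  presynaptic neuron's free-running $V(t)$, aligned so its upward zero
  crossing sits at $t_s$, feeding the synapse kinetics with $s(0)=0$
  (`spike_template()`).

A triangular voltage excursion (`triangular_template()`) is provided as an
alternative stimulus, an idealization that appears in some open-loop
protocols. Its rise and fall times are free parameters that no physiology
pins down, and the measured resetting differs appreciably between the two
waveforms at identical conductance (the test suite quantifies this), so
downstream mode predictions inherit the choice. The synaptic-event
template is the default and is what the validation pipeline uses; it is
the protocol under which the open-loop prediction agrees with the
closed-loop simulation to better than one percent at the reference
operating point.

The default grid is 50 phases evenly spaced on [0.02, 0.98]. The end
points are excluded deliberately: a stimulus delivered exactly at the
spike is causally ambiguous (does it perturb the cycle that just ended or
the one that just began?), and tabulated curves are interpolated, never
extrapolated, beyond the measured grid.

## 3. The normal form and the c(g) calibration

Near the SNIC bifurcation the type-1 PRC is the one-parameter family

$$F^{(1)}(\varphi) = c\,(1 - \cos 2\pi\varphi).$$

The package stores the signed **amplitude** `c` directly
(`normal_form_prc()`), rather than the equivalent bifurcation-theoretic
coefficient that divides by the angular frequency. Two facts make the
amplitude convention the right one here. First, resettings are relative
period changes, so `|2c|` is immediately the strongest possible
fractional resetting and must stay well below 1 for the weak-resetting
picture to make sense; amplitudes keep that constraint visible. Second,
the amplitude fitted to measured tables (`fit_normal_form()`, a linear
least-squares problem) is affine in the synaptic conductance in the
weak-coupling regime, and every closed-form existence result below
inverts the cosine directly in this convention.

`sweep_coupling()` measures a conductance sweep and fits
$c(g) = \text{slope}\cdot g + \text{intercept}$
(`calibrate_coupling_map()`). The affine law is a weak-coupling
linearization: pushing the sweep into strongly resetting conductances
visibly saturates $c(g)$ and drags the intercept away from zero, so the
package's reference sweep for the master-to-slave synapse uses six values
of $g_{12}$ between 0.002 and 0.012 — a window that spans the operating
inhibitory and excitatory couplings while keeping the fitted intercept
within noise of zero, which is the internal consistency check that the
linearization is valid. Fits over substantially wider windows (e.g. up to
$g = 0.05$) produce much shallower slopes and intercepts an order of
magnitude larger, and should not be compared against weak-coupling
calibrations.

## 4. Multiple inputs per cycle

The composition rule (`compose_two()`, `compose_n()`) assumes each
resetting completes before the next input arrives. Stimulus $k$ then sees
the oscillator with period $P_{k-1}$ already modified by its predecessors,
arrives at phase $t_{sk}/P_{k-1}$, and

$$P_n = P_i \prod_{k=1}^n \Big(1 + F^{(1)}\big(t_{sk}/P_{k-1}\big)\Big).$$

Stimulus *times* (not phases) are the canonical inputs — after the first
resetting, "phase" is ambiguous while time is not. Each stimulus may act
through a different PRC (in the circuit below, inhibition first and
excitation second), so the composition is not commutative; times must be
strictly increasing and each must fall inside the transiently modified
period, otherwise the composition refuses with the offending stimulus
named. The two-stimulus composed resetting is algebraically identical to
applying the single-stimulus definition twice; the test suite verifies
this to machine precision on 1000 random schedules, which is the
load-bearing identity of the whole approach.

## 5. Existence of the phase-locked mode

At a locked state the network adopts the master period, which decouples
the two unknowns: the interneuron condition
$F_3\big((P_{1i} - t^*_{2sa})/P_{3i}\big) = P_{1i}/P_{3i} - 1$
determines $t^*_{2sa}$ alone, after which the slave condition with the
inhibition-corrected factor $\alpha = 1 + F_{2,inh}(t^*_{2sa}/P_{2i})$
determines $t^*_{2sb}$. Both are scalar root problems in a periodic
residual; `solve_t2sa()`/`solve_t2sb()` bracket sign changes on a
2000-point grid and polish each root by bisection to residuals below
1e−10, reporting *all* branches. Every candidate mode is re-checked by
substituting into the two-stimulus composition (residuals below 1e−8
required), and the recovery time is pinned exactly by
$t^*_{2r} = P_{1i} - t^*_{2sb}$.

With normal-form PRCs the interneuron condition inverts in closed form
(`analytic_t2sa()`):
$\cos\!\big(2\pi (P_{1i} - t^*_{2sa})/P_{3i}\big) =
 1 - (P_{1i}/P_{3i} - 1)/c_{23}$.
Three consequences follow directly. An excitatory (advance-only)
interneuron PRC can only entrain an interneuron *slower* than the master,
$P_{1i} < P_{3i} < P_{1i}/(1 + F_{3,min})$ (`existence_bounds()`). The
cosine's range bounds the coupling from below: through the affine
$c_{23}(g_{23})$ this gives the minimum conductance needed at a given
period ratio (`minimum_coupling()`) — about 0.024 at ratio 1.5 and 0.036
at ratio 2 with the reference calibration. And in the strong-coupling
limit the lock approaches the master period itself. Note that the
closed-form right-hand side divides the period mismatch by $c_{23}$
*alone*; a formulation that additionally divides by $P_{3i}$ cannot
reproduce these thresholds and mixes units (an amplitude is
dimensionless while the mismatch is too).

`mode_surface()` sweeps $(P_{3i}, g_{23})$ with normal-form PRCs and
records the primary mode per grid point, preferring a stable one; this is
the package's tool for mapping how the solution region widens with
stronger master-to-slave excitation or with more similar intrinsic
periods.

## 6. Stability

Perturbing the steady times, $t_{2sa}[n] = t^*_{2sa} + \delta_a[n]$ (and
likewise for $t_{2sb}$), and linearizing the two per-cycle timing
equations yields $\boldsymbol\delta[n+1] = A\,\boldsymbol\delta[n]$ with

$$A = \begin{pmatrix} (1-m_3)(1-b) & (m_3-1)\,m_{2b} \\ -b & 1 - m_{2b}
\end{pmatrix}, \qquad
b = m_{2a}\big(1 + F_{2,exc}(\varphi^*_{2b}) - m_{2b}\,\varphi^*_{2b}\big),$$

where $m_{2a}, m_{2b}, m_3$ are the PRC slopes at the steady phases
$\varphi^*_{2a} = t^*_{2sa}/P_{2i}$,
$\varphi^*_{2b} = t^*_{2sb}/(\alpha P_{2i})$ and
$\varphi^*_3 = (P_{1i} - t^*_{2sa})/P_{3i}$ — note that each slope comes
from the PRC of the *synapse acting at that phase* and that
$\varphi^*_{2b}$ is normalized by the inhibition-modified cycle. The
grouping inside $b$ (the product $m_{2b}\varphi^*_{2b}$ subtracted inside
the bracket) was fixed by deriving the Jacobian of the timing map from
scratch; the derivation lands exactly on the matrix above. The eliminated
third variable adds no condition: $\delta t_{2r}[n-1] = -\delta_b[n]$, so
its decay is that of $\delta_b$.

The mode is stable iff both eigenvalues of $A$ lie strictly inside the
unit circle (`classify()`): complex roots (Det > Tr²/4) require Det < 1;
real roots are checked directly on the quadratic's solutions. A band of
width 1e−6 around unit modulus is reported as "marginal" rather than
forced into either verdict. `iterate_map()` provides the brute-force
cross-check, and the suite confirms verdict/growth agreement on 200 random
matrices as well as consistency with the nonlinear system: kicking a
converged closed-loop simulation returns it to the same measured mode.

Slopes for tabulated PRCs come from a natural cubic spline through the
grid (`prc_slope()`). Spline-derivative estimates are the least robust
ingredient of the pipeline — eigenvalues inherit a few-percent
sensitivity to the grid and the smoother, which is why stability
quantities should be quoted with wider error bars than the mode times.

## 7. Closed-loop validation and the synthetic generator

`simulate_network()` integrates the fully coupled 9-dimensional system
for 110 master cycles; `extract_mode()` discards 20 cycles of transient
and reads the per-cycle triple $(t_{2sa}, t_{2sb}, t_{2r})$ off the three
spike trains, enforcing the expected firing pattern (exactly one
interneuron spike, then one master spike, per slave cycle). A sequence is
declared steady when its trailing 10-cycle range is below 0.05 ms
(`check_convergence()`), and the per-cycle bookkeeping identities that
tie the three neurons' periods to the timing triple are asserted on every
steady cycle in the tests. Initial conditions are random phases on each
cell's limit cycle under a caller-set seed; the converged mode is
seed-independent at the reference operating point.

The synthetic generator (`make_fixture()`) produces the three test
fixtures the suite is built on: perfectly periodic spike trains with
prescribed offsets (the extraction oracle), noise-free or noisy
normal-form PRC tables (the fitting oracle), and random 2×2 recursion
matrices (the stability oracle). These fixtures emulate the *geometry* of
the real objects, not their physics: they contain no measurement noise
correlations, no cycle-to-cycle jitter, no synaptic delays and no slow
currents. Passing tests therefore certify the algorithms — extraction,
fitting, composition, root-finding, classification — on clean inputs and
the model pipeline on simulated conductance-based data; they say nothing
about biological recordings, where stimulus artifacts, adaptation and
higher-order resetting would all enter.

## 8. Numerical choices

* Integration: `deSolve`'s `lsoda` with rtol 1e−8 / atol 1e−10 and
  compiled right-hand sides; dense output every 0.02 time units. Spike
  times are linearly interpolated at upward zero crossings, giving
  sub-0.01 ms timing accuracy — the mode times are quoted to 0.1 ms.
* The exported R-level derivatives are the reference definition of the
  model; a test integrates both paths and requires identical trajectories.
* Bias calibration: bisection on the monotone period–current curve inside
  the oscillatory window (bracket 0.0695–0.075), period measured after a
  5-cycle transient discard, 8 cycles averaged.
* Root finding: grid-then-bisect (grid 2000, refined to 1e−12) because
  tabulated PRCs are splines — derivative-based methods gain nothing and
  multiple branches must be enumerated anyway. Grid end points are kept
  exact for analytic PRCs so tangential roots (equal periods, strong
  coupling) are found, and shrunk by 1e−9 for tables to respect the
  no-extrapolation rule.
* Degenerate inputs: an identically-zero slave residual (flat excitatory
  PRC with periods already matched) is reported as "degenerate" rather
  than returning an arbitrary root; unsolvable conditions raise a typed
  "no solution" error that sweep drivers catch per grid point.
* Problem sizes: 50-phase PRC grids, 110-cycle network runs with 20
  discarded, 6-point conductance sweeps. These were chosen as the sizes at
  which the measured quantities stop moving at the precision quoted above
  (halving or doubling them changes mode times by far less than the
  0.05 ms convergence tolerance).

## 9. Known limitations

* First-order resetting only: inputs whose effects straddle a spike, or
  oscillators with slow adaptation currents, violate the
  instantaneous-resetting assumption the composition rests on.
* The firing-pattern extraction assumes the canonical order (interneuron
  then master within each slave cycle); other n:m patterns are rejected,
  not analyzed.
* Tabulated PRCs are trusted only on their measured grid; modes whose
  steady phases fall outside it are refused rather than extrapolated.
* The triangular stimulus option is parameterized by unconstrained shape
  parameters; quantitative mode predictions should use the synaptic-event
  protocol unless the experimental stimulus really is a shaped pulse.
* Class II (Hopf-regime) parameter sets are not excluded by the code but
  none of the closed-form machinery (normal form, existence bounds)
  applies to their bimodal PRCs.
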