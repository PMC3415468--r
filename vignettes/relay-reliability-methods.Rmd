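---
title: "Analytic bounds on relay-neuron reliability: models, assumptions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic bounds on relay-neuron reliability: models, assumptions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(relaybounds)
```

## The problem

Thalamic relay neurons receive two kinds of input.  A *driving* input — a
sparse train of strong excitatory pulses on proximal dendrites — carries
the information to be relayed.  A *modulating* input — the ensemble of
inhibitory synapses on distal dendrites — sets how much of that
information gets through.  Relay **reliability** is the fraction of
driving pulses that evoke a successful response (a spike, or a burst
counted once) within a fixed window.

`relaybounds` implements both sides of this question for conductance-based
membrane models:

* an **empirical** side — simulate the model under a stochastic pulse
  train and a sinusoidal modulating conductance and count relayed pulses;
* an **analytic** side — linearize the model around its operating point
  and compose closed-form lower and upper bounds on reliability from a
  handful of measurable quantities.

The value of the analytic side is that it makes the dependence of
reliability on the modulating frequency, its DC offset, the pulse rate and
the membrane conductances explicit, instead of burying it in simulations.

## Models

Two models ship as plain-text fixtures (`inst/extdata/*.yaml`; every value
carries a unit and a source comment).  Both use the unit system mV, ms,
uA/cm², mS/cm², uF/cm², and both put the voltage first in the state
vector — the linearization machinery relies on that ordering.

* **Second order** `(v, h)`: a low-threshold T-type calcium current with
  instantaneous activation and a dynamic inactivation gate, plus a passive
  leak.  Kinetics follow the reduced thalamocortical cell of Rubin &
  Terman (2004).  Responses are low-threshold calcium spikes peaking near
  −25 mV.
* **Third order** `(v, h, r)`: leak, fast sodium, potassium (through the
  `n = 0.75(1−h)` reduction) and the T-current.  The external current
  selects the regime: `I_ext = −0.6` (hyperpolarized) gives multi-spike
  rebound **bursts**; `I_ext = +0.3` (depolarized) gives single **tonic**
  spikes.  The fixture uses `g_T = 2 mS/cm²`, inside the published range
  for reduced thalamocortical cells and chosen so that a delta pulse in
  the hyperpolarized state produces a genuine multi-spike burst; at
  `g_T = 5` the calcium envelope saturates near 0 mV and carries a single
  sodium spike.

The modulating input is `s(t) = S0 + S1 sin(ωt)` entering the voltage
equation as `−s(t)(v − v_rev)` with `v_rev = −85` mV (GABAergic).  The
driving input is a train of delta pulses of height α (units uA·ms/cm², so
a pulse kicks the voltage by `α/C_m` mV) with inter-pulse intervals
`T_R + Exp(λ)`.

Both models are **stable neurons** at their operating points: a single
globally attracting equilibrium under constant input, hence no spikes
without a pulse.  `find_equilibrium()` enforces this constructively — at
an equilibrium the gates sit on their steady-state curves, so equilibria
are the roots of a scalar function of voltage, and finding more than one
root is an error, not a silent choice.  (The depolarized third-order cell
becomes bistable below `S0 ≈ 0.045` with `I_ext = 0.3`; its sweeps stay
above that.)

## The analytic chain

1. **Linearization at the equilibrium** (`linearize`): state matrix `A`,
   input vector `B = −(v_eq − v_rev)/C_m · e₁`, output `C = e₁ᵀ`.  The
   gain `G(jω) = C(jωI − A)⁻¹B` is low-pass for these membranes: fast
   modulation is attenuated, which is why high-frequency inhibition is
   permissive for relay.
2. **Steady-state orbit** (`steady_state_orbit`): under the sinusoid the
   state settles on a small loop around the equilibrium,
   `x_eq + S1|Gᵥ_j| sin(ωt + ∠Gᵥ_j)` per component.  The orbit tube is
   this loop thickened by ε (default 10% of the voltage amplitude, floor
   0.1 mV — diagnostics only; ε never enters the bounds).
3. **Threshold structure** (`threshold_current`): bisection on the pulse
   height applied at the equilibrium gives the threshold current `I_th`;
   the post-jump state at threshold is the **critical point** `x_c` on the
   separatrix between sub- and supra-threshold responses.  This particular
   point is the one actually visited by near-threshold trajectories
   leaving the orbit, which is what the local analysis needs.
4. **Critical-point eigenstructure** (`critical_linearization`): the
   Jacobian at `x_c` has one unstable eigenvalue λ₁ > 0 (trajectories
   divert from the separatrix); its left eigenvector `w₁`, oriented so a
   depolarizing perturbation projects positively, is the local normal
   along which success is decided.  If λ₁ were complex the analytic phase
   interval is replaced by the brute-force scan and flagged
   `numeric-fallback`; at all fixture operating points λ₁ is real.
5. **Success-phase interval** (`success_phase_interval`): a pulse arriving
   at modulating phase φ succeeds iff
   `K0 + |Z| sin(φ + arg Z) > 0`, with
   `K0 = w₁ᵀ(x_eq − x_c) + α w₁₁/C_m` and
   `Z = S1 (w₁ᵀ(jωI − A)⁻¹B + (w₁ᵀB_c)/(λ₁ − jω))`
   (`B_c` is the input direction at `x_c`; the second term integrates the
   future modulating input against the unstable mode).  The solution set
   is one (possibly wrapped, empty or full) interval Φ;
   `P_S = |Φ|/2π` because stationary pulse arrivals sample the phase
   uniformly.
6. **Refractory period** (`refractory_period`): a two-pulse protocol on
   the undriven system.  Recovery need not be monotone — immediately
   after a burst the decaying calcium envelope can still carry an extra
   response — so the protocol scans a lag ladder and bisects the *last*
   fail→success transition: the time to leave the refractory zone.
7. **Bounds** (`reliability_bounds`): with `p = P(T > T_ref)` the interval
   survival at `T_ref`, the stationarity recursion
   `P_T = p·R + q·(1 − R)`, `R = P_S·P_T` bracketed over the unknown
   post-failure refractory period (between 0 and `T_ref`) gives

   `R_lb = P_S · p`,  `R_ub = P_S / (1 + P_S (1 − p))`.

   Limits: `p → 1` collapses both to `P_S`; `T_ref ≤ T_R` likewise;
   `P_S = 0` gives zero; dense pulses with `P_S = 1` drive `R_ub → 1/2`
   (each success is followed by exactly one censored pulse) and
   `R_lb → 0`.

## Detection and counting choices

The critical hypersurface is not observable in a simulation, so successful
responses are detected as upward crossings of a fixed voltage level.  The
level is a **model fixture**: −40 mV for the second-order cell (calcium
spikes peak near −25 mV; a 0 mV level would see nothing) and −25 mV for
the third-order cell (with `g_Na = 3` the sodium spikes peak just above
0 mV and later burst spikelets near −25..−5 mV).  Two artifacts are
excluded by construction:

* a pulse jump that lands *passively* above the level is not a spike —
  crossings must be confirmed by a rising post-crossing trajectory (and,
  in the bisection probes, by a positive voltage derivative at the landing
  point);
* spikes closer than the merge interval (10 ms) collapse into one
  response, so bursts count once.

A pulse is relayed iff a response starts within the relay window Δ after
it (latest-preceding attribution).  Δ is also a model fixture: 25 ms
(second order) and 40 ms (third order).  Near-threshold responses develop
along the slow unstable manifold — latencies reach ~15 ms at λ₁ ≈ 0.18/ms
and ~30 ms at λ₁ ≈ 0.14/ms — so the window must cover the decision time of
the model; with the fixture values the counted reliability is insensitive
to ±50% changes in Δ.  Responses later than Δ count as misses; responses
with no pulse in 3Δ would contradict the stable-neuron assumption and
raise a warning.

## Study conditions and what the generator emulates

The baseline conditions (generator defaults in the sweeps, tests and the
acceptance script):

| quantity | 2nd order | 3rd order | meaning |
|---|---|---|---|
| `S0` | 0.1 | 0.05 | inhibitory DC conductance (mS/cm²) |
| `S1` | 0.02 | 0.02 | modulation amplitude (small-signal regime) |
| frequency | 8–96 Hz | 10–96 Hz | alpha-to-gamma band of the modulating input |
| α | 7.9 | 12.5 (burst) / 11.7 (tonic) | ≈ `I_th` + 0.5–1 at baseline `S0` |
| λ | 0.005 /ms | 0.005 /ms | ~5 Hz driving rate (mean interval 205 ms) |
| `T_R` | 5 ms | 5 ms | driving refractory floor |

`S1 = 0.02` keeps the orbit amplitude at ~0.3–3 mV across the band, inside
the linearization's small-signal regime (phase-scan agreement ≥ 62/64; at
`S1 = 0.05` the first-order expansion visibly underestimates the success
band).  `λ = 0.005` makes the sparse-pulse structure visible against
refractory periods of 150–600 ms, which these models own because T-channel
de-inactivation is slow (τ_r ≈ 90–190 ms when hyperpolarized).  Sweep
sizes (8 frequency, 6 offset, 6 rate points at 20 trials × 200 pulses for
the second-order model; 4+3+3 points at 10 × 150 for each third-order
regime) keep the full suite within minutes on one core while leaving the
Monte-Carlo error well below the bracket width.

What passing tests do **not** show about real neurons: the driving input
is idealized as delta pulses with exponential intervals (no synaptic
kinetics, no correlated spike trains), the modulating input is a clean
deterministic sinusoid (no stochastic background), and the models are
single-compartment.  The bounds also treat pulses independently; real
pulse pairs closer than the membrane integration time sum.  That summation
is visible in the package itself: at the top of the offset sweep, where
the analytic success band is empty and the bounds are exactly zero, ~3% of
pulses still relay because two pulses within ~15 ms jointly cross
threshold.  This is the known containment failure mode (one grid point out
of twenty), and it is a physical effect outside the analysis, not a
numerical artifact.

## Numerical choices

* Integration: `deSolve::lsoda` with compiled right-hand sides; pulses are
  solver events (integration restarts at each pulse, never stepping
  across).  Trajectories for counting are sampled at 0.1 ms (0.05 ms in
  single-run analyses), about ten samples across the narrowest spike at
  the detection level; tolerances 1e-6 (sweeps) / 1e-8 (analysis probes).
  Halving tolerances changes counted reliability by less than one event
  per 200 pulses.
* Equilibria: scalar root scan (0.02 mV grid + `uniroot` to 1e-13) on the
  gate-nullcline reduction; Jacobians by adaptive central differences
  (relative step 1e-6, with an analytic hook for models that provide one).
* Bisection tolerances: 1e-3 (pulse-height units) for `I_th`; 0.1 ms for
  `T_ref` (0.5 ms inside sweeps).  When a sweep point has α at or below
  `I_th`, `T_ref` is measured at `I_th + 0.5` — the protocol needs a
  supra-threshold pulse — and when `P_S = 0` the bounds are exactly zero
  and `T_ref` is not needed.
* Warm-up: counting starts after ≥ 5 modulating periods or 500 ms,
  starting from the linearized orbit state, so transients never contribute.
* Seeds: every stochastic step takes an explicit seed; sweep point `i`
  uses `seed + 1000·i`, trial `j` adds `j − 1`.

## Known limitations

* The success-phase interval inherits the first-order expansion: below
  ~8 Hz (second order) / ~25 Hz (tonic third order) with larger `S1` the
  band edges drift by a few phase bins out of 64.  The numeric phase scan
  (`success_phase_scan`) is the fallback and the arbiter.
* `T_ref` after an *unsuccessful* response is bracketed, never computed —
  that is the point of the bounds — but the bracket can be wide when
  `λ·T_ref` is large.
* The spontaneous-firing adjustment (`spontaneous_extension`) rescales
  reliability by `1 − (T_R + 1/λ)/T_noise`; it is approximate by
  construction, reported unclamped, and can legitimately go negative when
  noise pulses outpace the drive.
* The empirical reliability of a bursting cell depends on the merge
  interval only through burst segmentation; with the fixture spikelet
  spacing (~4 ms) any merge interval in 6–15 ms gives identical counts.
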