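---
title: "Noise, neurostimulation and the stability of E-I spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise, neurostimulation and the stability of E-I spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eistim)
```

## The model

`eistim` simulates a Wilson–Cowan-type network of `N_e` excitatory and `N_i`
inhibitory spiking cells. Each cell `j` of population `n` (with membrane rate
constant `a_n`) carries a membrane variable `u_j` obeying

```
a_n^-1 du_j/dt = -u_j + sum of weighted presynaptic spike trains
                 + baseline drive + tonic drive I_o(t) (E cells only)
                 + global stimulus S(t) + intrinsic white noise
```

and emits spikes through the sharp sigmoid `f[u] = (1 + exp(-beta (u - h)))^-1`
(`beta = 300`, `h = 0` by default): at each step of length `dt` the cell fires
with probability `f[u_j]`, and a spike contributes exactly 1 to the synaptic
sums of the next step. Under this convention the time-average of a spike train
equals the time-average of `f[u]`, which is what makes the rate (mean-field)
description below exact in expectation — the diffusion approximation.
Connectivity is homogeneous all-to-all with population-mean weights
`w_ee = 1.6, w_ei = 3.0, w_ie = -4.7, w_ii = -0.13` (inhibitory weights carry
their sign; self-connections are included, an `O(1/N)` effect). The default
network is 800 E + 200 I cells at `dt` = 1 ms with `a_e` = 100 Hz and
`a_i` = 200 Hz.

With these parameters the network shows the phenomenon the package exists to
study: an abrupt, seizure-onset-like switch from asynchronous irregular firing
into coherent gamma-band oscillation when the tonic excitatory drive `I_o`
steps from 0 to 0.1 — and the suppression of that switch by intrinsic noise or
by an externally applied stimulation waveform.

## The intrinsic-noise convention (the one decision that matters most)

The intrinsic noise variance `D` is defined **per membrane time constant**:
the discrete update is

```
u <- u + (a dt) * (-u + inputs) + sqrt(2 D (a dt)) * z,     z ~ N(0, 1)
```

so a decoupled cell's membrane deviations are stationary with variance `D` in
*both* populations (the faster inhibitory population reaches that variance
sooner, not higher). This is the natural nondimensionalization in which
`a dt` is the integration step of a unit-rate relaxation.

This choice is deliberate and load-bearing. If instead the stationary
deviation variance were `a_n * D` with `a_n` in hertz (e.g. 100 x 0.005 = 0.5
at the default noise levels), the noise-smoothed network gain could never
exceed `w_ee / sqrt(2 pi * 0.5) = 0.90 < 1`, and the multistability that
drives the abrupt transition would be mathematically impossible at any drive.
With variance `D`, the mean-field analysis below places a multistable region
at drives near 0.05 for `D = 0.005`, shrinks it through `D = 0.01` (where a
residual interval survives only near `I_o = 0.01`), and removes it entirely
by `D = 0.025` — exactly the regime in which the spiking simulations switch
from abrupt to graded responses. The simulator and the mean field share the
convention, and the test suite checks their consistency directly (decoupled
membrane variance vs the deviation law; long-run population means vs the
unique high-noise equilibrium).

## Stochastic mean-field reduction

Averaging the membrane equations over cells and replacing each cell's sharp
sigmoid by its expectation over the stationary Gaussian deviation law
`N(0, Dbar)` yields two deterministic equations for the population means with
the **noise-smoothed transfer function**

```
F[u] = Phi(u / sqrt(Dbar)) = (1 + erf(u / sqrt(2 Dbar))) / 2
```

— the exact Gaussian smoothing of the hard threshold, since `1/beta` (0.0033)
is far below every `sqrt(Dbar)` of interest. Noise therefore *linearizes* the
network: larger `Dbar` flattens `F`, caps the recurrent gain `w_ee * F'`, and
eventually forbids multiple fixed points. `effective_transfer_quad()`
evaluates the defining convolution directly as a cross-check; it splits the
integral at the sigmoid's transition point and integrates each half
adaptively, because a fixed Gauss–Hermite rule cannot resolve a transition
of width `1/beta` lying between its nodes (with 200 nodes its error is about
3e-2; the adaptive rule agrees with the closed form to ~1e-4, the true size
of the finite-gain correction).

Steady states solve

```
u_e = w_ee F_e[u_e] + w_ie F_i[u_i] + I_e + I_o
u_i = w_ei F_e[u_e] + w_ii F_i[u_i] + I_i
```

`find_equilibria()` exploits the structure of the second equation: since
`w_ii <= 0`, `g(u_i) = u_i - w_ii F_i[u_i]` is strictly increasing, so the
equilibrium curve can be parameterized by `u_i` alone
(`F_e = (u_i - w_ii F_i - I_i)/w_ei`, `u_e = sqrt(Dbar_e) qnorm(F_e)`), which
turns root *bracketing* into one vectorized pass over 6000 grid points with
no inner root solver. Brackets are polished by damped Newton iteration to
residuals below 1e-12 and deduplicated at 1e-6. Equilibria whose excitatory
transfer saturates numerically (`F_e` within 1e-12 of 0 or 1, outside the
quantile-parameterized stretch) are added as explicit tail candidates; a 1-D
fallback scan covers the degenerate `w_ei = 0` case.

```{r}
bd <- bifurcation_sweep(network_params(D = 0.005), seq(0, 0.12, by = 0.001))
bd
```

Linearizing about a steady state with the transfer slopes
`R_n = F_n'(u_n) = ` the normal density at the equilibrium gives the
rate-scaled Jacobian

```
J = [ a_e (-1 + w_ee R_e)    a_e w_ie R_i ]
    [ a_i w_ei R_e           a_i (-1 + w_ii R_i) ]
```

whose leading eigenvalue's real part is the damping rate (stable iff
negative) and imaginary part the eigenfrequency (reported in both rad/s and
Hz). `linear_stability()` computes the eigenvalues twice — by direct
eigendecomposition and by the quadratic closed form
`lambda = (tr J ± sqrt((tr J)^2 - 4 det J))/2` expanded in the weight and
slope terms — and treats disagreement beyond 1e-9 relative as an internal
error. (The fully expanded discriminant is used in its algebraically
consistent form; one cross-term must carry the inhibitory slope `R_i`, as the
identity `H = G^2 - 4 det J` requires.) At `D = 0.005` the sweep above finds
two saddle-node points bounding the three-equilibrium interval; past its
upper edge the only remaining state is an unstable focus whose eigenfrequency
sits in the gamma range, matching the oscillation frequency seen in the
spiking runs. At `D = 0.05` a single stable equilibrium persists at lower
`u_e` for every drive, with a much lower damped frequency.

## Stimulation waveforms

`stimulus_spec()` describes the global input `S(t)`, injected identically
into every cell of both populations:

* **pulse** — amplitude `S0` held for exactly one integration step at the
  start of every period `1/f_s` (periods rounded to whole steps; the realized
  frequency `1000/round(period)` is what sweep outputs record). `S0 < 0` is
  the inhibitory pulse train.
* **biphasic** — a `+S0` pulse at each period start and `-S0` exactly 2 ms
  later: the charge-balanced, net-zero-mean clinical waveform.
* **sinusoid** — `S0 sin(2 pi f_s t)`.
* **ou_noise** — an Ornstein–Uhlenbeck process with correlation time
  `tau = 1/f_c`, integrated by its exact discretization (decay factor
  `exp(-dt/tau)` plus the exact-variance Gaussian increment, so the
  stationary law is step-size free; a plain Euler variant is kept as a
  numerical cross-check). Its stationary variance is `D_s * f_c / a_ref`
  with `a_ref` the excitatory rate constant: `D_s` acts as a spectral-density
  parameter, so widening the band (raising `f_c`) adds power. In that
  nondimensionalization the deviation variance of a cell with rate `a`
  becomes, by linear filter theory,

  `Dbar = D + (D_s f_c / a_ref) * a / (a + f_c)`

  which grows with both `D_s` and `f_c`, saturating at the white-noise limit
  — and is always larger for the faster inhibitory population. That asymmetry
  is the mechanistic heart of the stimulation results: a global stimulus is
  sampled more effectively by inhibitory cells (`a_i > a_e`), so stimulation
  smooths the inhibitory transfer more, recruits inhibitory firing, and
  suppresses the excitatory population. At the reference noisy-stimulation
  setting (`D_s = 0.08`, `f_c = 400` Hz) the effective variances are 0.074
  (E) and 0.117 (I) — both far beyond the ~0.015 at which multistability
  dies, which is why that stimulus prevents the transition.

Periodic waveforms are analyzed through simulation only; in the mean field
they enter as the time-averaged drive `waveform_mean()` (zero for biphasic
and sinusoidal stimuli). The 2-ms biphasic offset follows the discrete
`delta(0) = 1` convention: a "pulse" is one step of amplitude `S0`, never an
impulse scaled by `1/dt`.

## Metrics

**Spike coherence** bins two excitatory spike trains into 20-ms indicator
bins and computes the normalized binned cross-correlation
`C = sum(x y) / sqrt(sum(x^2) sum(y^2))`, so identical nonempty trains give
exactly 1 and bin-disjoint trains exactly 0. The square-rooted denominator is
required by those calibration points (an unrooted product would give `1/M`
for identical all-ones trains of `M` bins). `spike_coherence()` averages 100
randomly resampled pairs for a stable estimate; the pair-sampling seed is
exposed. Two caveats are inherent to the raw measure and documented rather
than corrected: (i) for dense independent trains its expectation approaches
the per-bin occupancy probability, not 0, so absolute values should be
compared within a protocol, not across firing-rate regimes; (ii) a *common*
stochastic stimulus co-modulates all cells and inflates raw coherence even
while it suppresses the oscillation and the excitatory rate — for the
noise-stimulation family the firing-rate maps are therefore the cleaner
readout of stabilization at this network size.

**Firing rates** are spikes per cell per second over a window. **Single-cell
power spectra**: for a decoupled cell, `a^-1 du/dt = -u + eta` is a
first-order low-pass filter, so its PSD is the Lorentzian
`a^2 (D + stimulus term)/(a^2 + omega^2)` with the family-specific stimulus
term (flat for white-limit noise, an equidistant comb for pulse trains, an
`n^2`-weighted comb for the zero-width biphasic idealization, a single line
for the sinusoid; comb frequencies must be multiples of `1/T` so lines land
on the grid `omega_n = 2 pi n / T`). The half-power point of the noise-only
envelope sits exactly at the rate constant, `omega_c = a` — 100 for
excitatory and 200 for inhibitory cells — so inhibitory cells pass a broader
band of any stimulus; `half_power_frequency()` solves the envelope
numerically. `psd_empirical()` is a segment-averaged periodogram
(`P = |dt sum x e^{-i omega t}|^2 / T`, Parseval-consistent with the trace
variance); the empirical cross-checks integrate the decoupled cell at 0.1-ms
steps so the discrete-time response stays within a few percent of the
continuous Lorentzian over the compared band.

## Experiments and desk-scale defaults

`run_transition()` implements the standard protocol: 2 s of simulation, drive
step `0 -> 0.1` at 1 s, 500 ms burn-in, metrics from the pre-step window and
the final 800 ms, the stimulus applied continuously before and after the
step. `run_noise_sweep()` repeats it over `D` in {0.005, 0.01, 0.025, 0.05};
`run_stim_heatmap()` sweeps (amplitude x frequency) over the built-in
non-uniform period grid (`methods_period_grid()`, sampling 1–200 Hz) with
per-cell derived seeds and missing-cell bookkeeping for unrealizable periods;
`run_psd_comparison()` evaluates the analytic spectra of all four families
plus empirical periodogram checks.

Defaults are desk-scale by design: the 800+200-cell reference network, 2-s
runs, 3 replicates per heatmap cell (10 in the full protocol), which keeps a
4 x 6 biphasic heatmap under half a minute on one CPU. Larger networks
sharpen the transition (finite-size fluctuations scale as `1/sqrt(N)`) but do
not move the mean-field structure, which is `N`-free. Two replicate-averaged
findings are robust at this scale and tested: the post-step coherence at
`D = 0.01` exceeds that at `D = 0.05` by several standard errors, and the
biphasic heatmap's minimum-coherence cell falls in the high-amplitude,
high-frequency corner with inhibitory rates above and excitatory rates below
the unstimulated baseline. One plausible-sounding variant is *not* true in
this model and deliberately not asserted: the excitatory rate *jump* is not
perfectly monotone in `D`, because at the lowest noise the pre-step state is
nearly silent and the post-transition limit cycle has a lower duty cycle than
its noisier counterparts (35.7 vs 37.2 Hz at `D` = 0.005 vs 0.01,
reproducible across seeds); the oscillation-salience measure (coherence) is
monotone, and that is what the tests check.

## Numerical choices and degenerate inputs

* Explicit Euler–Maruyama with `a dt < 1` enforced (0.1 and 0.2 at the
  defaults); initial conditions from the stationary deviation law.
* One RNG stream per run, all cells drawn vectorized in fixed order each
  step, stimulus on its own derived seed — rasters are bitwise reproducible
  from `(params, protocol, spec, seed)`, independent of cell iteration order.
* Heatmap/sweep seeds derive from the base seed and the cell indices, kept
  below 2^31.
* Root scanning uses 6000 grid points over the exact `u_i` range admitted by
  the inhibitory equation; saddle-node endpoints are refined by bisection on
  the equilibrium count to 1e-4 in `I_o`.
* Degenerate inputs are rejected loudly: non-finite parameters, `dt >= tau`
  for the OU stimulus, periods shorter than a step, windows outside the run,
  per-cell trace requests beyond the memory cap, and non-monotone empirical
  envelopes passed to the half-power solver.

## Limitations

The synthetic dynamics are idealized: homogeneous all-to-all weights, no
synaptic or conduction delays, no refractoriness, no plasticity, and Bernoulli
(at most one spike per cell per step) spiking. Coherence is a raw binned
cross-correlation with the baselines discussed above. The mean field is a
Gaussian, stationary-deviation approximation: it locates fixed points and
their linear stability but says nothing quantitative about limit-cycle
amplitude, and under periodic stimulation only the waveform mean enters the
reduction. Oscillatory transitions here model the *onset* of pathological
synchrony in a generic E-I circuit, not any particular clinical condition.
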