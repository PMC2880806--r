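---
title: "Models and methods: stochastic resonance, resting-state network modes, and spatial ICA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodyn)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the numerical conventions, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
design choices made where the design was genuinely open.

## 1. Stochastic integration conventions

All simulators share one integration scheme (`integrate_fixed_step()`):
classical fourth-order Runge–Kutta on the deterministic drift, with the
step's noise value entering as a piecewise-constant additive term on the
state derivative, held fixed across the four RK stages of that step.

Two consequences are worth stating plainly:

- **The noise amplitude is a per-step value in drift units.** A white
  `noise_spec(sd = s)` contributes a constant `s`-scaled Gaussian forcing
  during each step of length `dt`; no `sqrt(dt)` scaling is applied. This is
  the convention of the classic fixed-step neuron simulations this package
  follows, and it means results are tied to the stated `dt` (0.02 ms for the
  neuron model). Changing `dt` changes the effective noise intensity; the
  step is therefore part of the model specification, not a free numerical
  knob. For the double well, a white per-step SD `s` corresponds to an
  effective diffusion intensity `D = s² dt / 2`, the conversion used
  throughout the tests.
- **Determinism.** Every stochastic function takes an explicit seed;
  sub-simulations derive child seeds via `child_seed()`, a fixed integer
  recurrence, so any run is reproducible from one master seed. RK4's global
  error on smooth drift is O(dt⁴) (verified by a halving test with error
  ratio in [12, 20]).

Ornstein–Uhlenbeck ("coloured") noise with intensity `D` and correlation
time `tau` is generated by the exact AR(1) discretization, with the first
value drawn from the stationary law, so the autocovariance is
`(D/tau)·exp(-lag/tau)` at every lag from the first sample on.

A divergence guard aborts integration (naming the step) when a state exceeds
1e6 in magnitude or becomes non-finite; diverged replicates in sweeps are
excluded and counted rather than silently dropped.

## 2. The double-well stochastic-resonance model

The one-dimensional Langevin system
`dx/dt = -U'(x) + A sin(ωt + φ) + ξ(t)` with the reflection-symmetric
quartic `U(x) = -c2 x²/2 + c4 x⁴/4`. The canonical coefficients
`c2 = c4 = 1` place the stable minima at ±1 with barrier ΔU = 1/4;
both coefficients remain configurable.

- `well_transitions()` detects inter-well hops with two-threshold hysteresis
  (default ±0.5, half the canonical minimum position): a hop is only counted
  after the trajectory crosses from beyond one threshold to beyond the
  other, which suppresses intra-well jitter at the cost of missing
  hypothetical sub-threshold excursions. Thresholds must straddle zero.
- `spectral_amplification()` is the SR response: periodogram power at the
  forcing bin divided by the median power over bins within ±20% of the
  forcing frequency (signal bin excluded). The median background was chosen
  for robustness against the Lorentzian (1/f-like) background of bistable
  hopping. It is ~1 for pure noise and large when the output locks to the
  forcing. The measure is a ratio of one exponential-tailed bin to a median,
  so single-run values are heavy-tailed; sweeps aggregate the median over
  seeds.

The SR signature asserted in the tests: on a noise grid bracketing the
barrier (effective D from 0.04 to 1.0 at A = 0.1, ω = 0.1, 40 forcing
periods), the median response over 10 seeds peaks at an interior noise
level — the defining non-monotonicity of stochastic resonance. Kramers
scaling is checked directionally: mean residence time grows when D shrinks.

## 3. The Rinzel-reduced Hodgkin–Huxley neuron

The two-variable reduction

```
C dV/dt = -(a + bV + cV²)(V - E_Na) - d·R·(V - E_K) + I(t)
dR/dt   = (R_∞(V) - R) / τ_R
```

with the published constants `a = 17.81, b = 47.71, c = 32.63, d = 26`,
`E_Na = 0.55`, `E_K = -0.92` (voltage dimensionless, ~100 mV units),
`C = 0.8`, `τ_R = 1.9 ms`, integrated at `dt = 0.02 ms`. The steady-state
recovery law defaults to the affine `R_∞(V) = 1.03 + 1.35 V` of the textbook
model this simulation family derives from; both coefficients are exposed in
`rinzel_config()` so an alternative transcription can be dropped in. The
drive is `I(t) = A sin(2π f t + φ)` with `A = 0.035`, `f = 200 Hz`
(period 5 ms), `φ = 0`; "200 Hz" is read as the drive frequency — the only
reading consistent with the 5-ms ISI structure the model produces. Per-step
Gaussian current noise is added to `I`; the initial state is the numerically
located resting equilibrium (V ≈ -0.698), not an arbitrary point.

Spikes are upward crossings of V = 0 separated by at least 1.5 ms
(refractory); both values are configurable and were chosen so that the ~70
ms-scale action potentials of this model are counted once each. ISI
histograms use 1-ms bins **centered on integer multiples of the bin width**
(breaks at (k ± ½)·bw), so a mode at the 5-ms drive period is reported as
exactly 5.

Model behaviour at the published anchor noise levels (all reproduced in the
test suite):

- SD = 0.01: the drive alone is sub-threshold; no spikes in 2 s.
- SD = 0.19: sustained firing at ~150 Hz with the ISI histogram mode at 5 ms
  and secondary mass at its integer multiples (skipped cycles).
- A = 0, SD ≤ 0.04: noise alone does not fire the neuron.

### Quantifying locking: two measures

`isi_statistics()` reports the **ISI-multiple locking fraction** — the share
of ISIs within ±tolerance of an integer multiple of the drive period. This
is a natural reading of the ISI histogram, but it has a blind spot at high
noise: the recovery variable enforces ~5 ms between spikes regardless of
drive phase, so strongly noise-driven firing still produces period-length
ISIs and the fraction fails to fall in the noise-dominated regime (measured:
0.55 at SD = 0.19 vs 0.57 at SD = 0.50, pooled over 20 × 2 s).

`phase_locking()` therefore provides the canonical SR response:
`locked_per_cycle` = (spikes per drive cycle) × (vector strength of spike
phases). It is zero when the neuron is silent, rises as noise recruits
phase-locked spikes, and falls when noise fires the neuron at arbitrary
phases (measured: 0 at SD = 0.01, ≈ 0.48 at 0.19, ≈ 0.37 at 0.50). The
regime ordering — the resonant level beating both the silent and the
noise-dominated ends — is asserted with this measure; the ISI-based fraction
is retained as an operation because it is what an ISI histogram directly
supports.

`simulate_rinzel()` (and `simulate_double_well()`) inline the RK4 loop for
speed; a test pins them to `integrate_fixed_step()` on a shared noise
sequence at floating-point roundoff.

## 4. Resting-state network dynamics and covariance modes

The rate model `du_i/dt = -α u_i + Σ_j W_ij Θ(u_j) + I_i(t) + ξ_i(t)`
(saturation Θ applied to presynaptic activity, as the model is written; a
post-synaptic variant is out of scope). In the resting state — zero inputs,
identity Θ, Gaussian node noise — Euler discretization gives the linear
recursion `u(t+Δt) = A u(t) + ξ(t)`, `A = (1 - αΔt)I + WΔt`, stable iff the
spectral radius of `A` is below 1 (checked, reported, and enforced unless
overridden). The per-node noise SD is the per-step innovation scale (the Δt
factor of the continuous formulation is absorbed into it).

- `simulate_nonlinear()` with identity saturation and zero input is
  bitwise-equal to `simulate_linear()` on the same seed: both compute the
  update as `(1-αΔt)u + Δt(Wu) + ξ`, so the reduction is exact, not
  approximate.
- `stationary_covariance()` solves the discrete Lyapunov equation
  `C = A C Aᵀ + Σ_ξ` by fixed-point iteration from `C = 0` (max-norm
  tolerance 1e-10, cap 1e5 iterations; convergence is geometric at rate
  ρ(A)²). The fixed-point route was chosen because it is transparent and
  directly oracle-checkable against long simulations; a vectorized direct
  solve would be an optimization, not a behavioural change.
- Eigenmodes use a deterministic sign convention (largest-|entry| coordinate
  positive, ties to the lowest index) so mode comparisons across runs and
  between analytic and empirical covariances are stable. For symmetric `W`
  with isotropic noise, `C` and `W` commute, so their eigenvectors coincide
  and the eigenvalue orderings agree — asserted analytically (cosines >
  0.999) and cross-checked by simulation.
- `empirical_modes()` de-means before computing the sample covariance; the
  linear resting model has zero mean, so this matches the uncentered
  definition up to sampling error (the assumption is noted here
  deliberately: with nonzero inputs the two definitions part ways).
- `mode_occupancy()` operationalizes "time spent near a mode" as the mode
  with the largest squared projection at each step — an explicit, monotone
  stand-in for the loose notion of dwelling in a basin of attraction: the
  occupancy ordering follows the eigenvalue ordering, and projection
  variance shares equal `λ_k/Σλ` exactly.
- `extract_phases()` forms the analytic signal per node via the one-sided
  spectrum; `kuramoto_index()` is `r(t) = |mean_j exp(iθ_j(t))|`. Burn-in
  defaults to `10/(αΔt)` steps — several relaxation times.

Transmission delays are not modelled: the discretized resting-state system
has none, and delayed large-network reproductions are outside this package's
scope.

## 5. The synthetic resting-state fMRI generator

`generate_fmri()` emulates a single-subject resting acquisition: 256 frames
at TR = 2 s. The default voxel grid is 16 × 16 × 8 with an ellipsoidal
"brain" mask (1104 voxels) — a desk-scale stand-in for a full 64 × 64 × 25
EPI matrix, which remains a configuration choice (the ICA acceptance checks
use 20 × 20 × 10 ≈ 2128 masked voxels, the problem size at which recovery is
assessed). Masked voxels are linearized x-fastest, so map↔matrix reshapes
are bit-stable.

- **Maps**: K compact Gaussian blobs (default SD 2 voxels, unit amplitude),
  centers drawn inside the mask with pairwise separation ≥ 2× width
  (enforced, or warned when impossible). Disjoint non-negative blobs still
  carry a small negative mutual correlation through their means — a
  structural fact worth knowing when interpreting "near-orthogonal".
- **Time courses**: a K-node stable linear network (default: weak ring
  coupling 0.02, α = 0.1 s⁻¹) simulated at a 0.1-s neural step, convolved
  with a canonical double-gamma hemodynamic kernel (peak 6 s, undershoot
  16 s, ratio 1/6; a pass-through mode exists so network-level tests can
  avoid the kernel), sampled every TR, and standardized. The network
  relaxation (~0.016 Hz corner) and the kernel's low-pass jointly put > 80%
  (measured ~98%) of each course's periodogram power below 0.1 Hz — the
  resting-state BOLD signature the generator is built to emulate. Narrower
  subject-specific bands (e.g. 0.01–0.02 Hz peaks) are attainable by
  configuration but not asserted.
- **Mixing**: `X = A S + E` with i.i.d. Gaussian noise, default SD 0.5 —
  half the blob peak amplitude. Every dataset carries its ground truth and
  seed record; regeneration from the record is bit-identical.

What the generator does **not** emulate: physiological confounds (cardiac,
respiratory), scanner drift, motion, spatial autocorrelation of scanner
noise, nonlinear hemodynamics. Tests passing on this generator show the
pipeline recovers well-separated, genuinely independent sparse sources under
white noise — they do not certify performance on real scans.

## 6. The spatial ICA pipeline

The generative model is `X = A S`: `X` a p × n matrix (p time points, n
masked voxels), rows of `S` statistically independent non-Gaussian spatial
maps, columns of `A` their time courses. The model itself is noise-free;
PCA truncation is the only noise handling, and the model-order (K) selection
criterion of evidence-based pipelines is deliberately not re-implemented — K
is user-supplied (tests use the true K; the explained-variance curve with
its elbow is reported for exploration).

Stages, matching standard resting-state practice:

1. **Preprocess** (`preprocess_fmri()`): mask, voxel-wise de-mean,
   voxel-wise variance normalization; zero-variance voxels are dropped and
   reported. Idempotent.
2. **Whiten** (`pca_whiten()`): eigendecomposition of the temporal
   covariance `X Xᵀ/n`, projection to K dimensions, scaling to identity
   covariance; back-projection and explained-variance fractions retained.
   K above the numerical rank is an error that names the rank.
3. **Estimate** (`spatial_ica()`): symmetric fixed-point iteration with tanh
   (default) or cubic contrast and symmetric orthonormalization each sweep;
   convergence when the maximum direction change (up to sign) falls below
   1e-5, cap 500 sweeps (conventional settings, configurable). Components
   are identifiable up to signed permutation and scale; each map's sign is
   fixed to positive skewness so thresholded maps are reproducible.
   Non-convergence returns a flagged result rather than an error.
4. **Final maps**: least-squares regression of the estimated time courses
   onto the de-meaned (not variance-normalized) data, each voxel divided by
   the SD of its residual noise. This matters: correlating whitened-space
   sources against ground truth under-reports recovery, because variance
   normalization gives pure-noise background voxels the same weight as
   signal voxels. The regression maps are what `match_components()`
   correlates against truth. For the same reason, a strictly noise-free
   dataset should be analysed without variance normalization (every voxel
   then contains amplified source tails and the sparse spatial structure is
   destroyed) — the lossless-limit test does exactly that.
5. **Threshold** (`zscore_threshold()`): maps standardized over masked
   voxels, suprathreshold set at |Z| > 2 by default.
6. **Match** (`match_components()`): greedy assignment on absolute spatial
   correlation (ties to the lower index), plus the Amari index of
   `W_est · A_true` in the shared K-dimensional subspace. Rows of the
   cross-talk matrix are normalized to unit maximum before the index is
   computed, which makes it exactly invariant under signed permutation and
   rescaling of the estimates (0 = perfect, ~0.5+ for random unmixing).

Known limitations, demonstrated as negative controls in the tests: two
Gaussian sources are unidentifiable (rotation ambiguity — matching quality
degrades below the recovery bar by design, not by error), and the square
p × p mixing of the formal model is never exercised — the reduced
(undercomplete) K-of-p formulation is what runs.

## 7. Problem sizes and reproducibility

The test suite and the acceptance script are sized for a single CPU: 2-s
neuron runs (10⁵ RK4 steps each, ~0.3 s), 20-seed pooled ISI histograms,
2·10⁵-step network simulations for covariance oracles, and 256 × ~2000 fMRI
matrices for ICA (seconds per fit). Every stochastic quantity in reports and
tests derives from explicit seeds through `child_seed()`; reports embed
their resolved configuration, seed, and package version, and regenerate
identically from them.
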