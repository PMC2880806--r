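# neurodyn

Simulation and analysis tools for stochastic neurodynamics and resting-state
fMRI, for computational neuroscientists who want small, fully seeded,
ground-truthed versions of three classic modelling settings:

1. **Stochastic resonance (SR)** — noise-enhanced response of a nonlinear
   system to a weak periodic input, in two models:
   - an overdamped particle in the reflection-symmetric quartic double well
     `U(x) = -c2 x²/2 + c4 x⁴/4` (canonical minima at x = ±1, barrier
     ΔU = 1/4), driven by `dx/dt = -U'(x) + A sin(ωt + φ) + ξ(t)` with white
     or Ornstein–Uhlenbeck noise;
   - a two-variable Rinzel reduction of the Hodgkin–Huxley neuron,
     `C dV/dt = -(a + bV + cV²)(V - E_Na) - d R (V - E_K) + I(t)`,
     `dR/dt = (R_∞(V) - R)/τ_R`, integrated by fixed-step RK4 (Δt = 0.02 ms)
     and driven by a 200 Hz sinusoidal current (A = 0.035) plus per-step
     Gaussian current noise. At intermediate noise the inter-spike-interval
     (ISI) histogram locks to the 5 ms drive period and its integer
     multiples.
2. **Resting-state network dynamics** — the linearized, time-discretized
   Wilson–Cowan system `u(t+Δt) = A u(t) + ξ(t)` with
   `A = (1 - αΔt) I + W Δt`; its stationary covariance solves the discrete
   Lyapunov equation `C = A C Aᵀ + Σ_ξ`, and the eigenvectors of `C` are the
   dominant spatial modes of the resting activity (for symmetric `W` and
   isotropic noise they coincide with the eigenvectors of `W`). Kuramoto
   synchrony and mode-occupancy analyses are included.
3. **Spatial ICA on synthetic resting-state fMRI** — a seeded generator
   (compact Gaussian-blob network maps × slow network time courses passed
   through a double-gamma hemodynamic kernel, 256 frames at TR = 2 s, plus
   Gaussian noise) and a spatial FastICA pipeline fitting `X = A S`:
   masking, voxel-wise de-meaning and variance normalization, PCA whitening,
   symmetric fixed-point estimation with tanh contrast, Z-scored maps
   thresholded at |Z| > 2, and ground-truth matching (per-component spatial
   correlation and Amari index).

## Worked example

Stochastic resonance in the noise-driven neuron:

```r
library(neurodyn)

cfg  <- rinzel_config()                                  # published constants
drv  <- drive_spec(noise = noise_spec("white", sd = 0.19))
traj <- simulate_rinzel(cfg, drv, duration = 2000, seed = 1)
spikes <- detect_spikes(traj)
spikes
#> <spike_train> 306 spikes over 2000 ms (rate 153 Hz)
isi_statistics(spikes)[c("modal_isi", "locking_fraction")]
#> $modal_isi
#> [1] 5
#> $locking_fraction
#> [1] 0.6229508
```

The modal ISI of 5 ms is the 200 Hz drive period: noise at SD = 0.19 lets
the sub-threshold stimulus fire the neuron, phase-locked to the drive. A
sweep over noise levels shows the three regimes (silent, resonant,
noise-dominated); `locked_per_cycle` (spikes per drive cycle × vector
strength) is the SR response, maximal at intermediate noise:

```r
noise_sweep(cfg, drive_spec(), sd_grid = c(0.01, 0.19, 0.5),
            duration = 2000, reps = 5, seed = 1)
#>     sd spike_rate_hz modal_isi locking_fraction vector_strength
#> 1 0.01             0        NA               NA           0.000
#> 2 0.19           153         5            0.562           0.651
#> 3 0.50           185         5            0.558           0.387
#>   locked_per_cycle n_spikes n_diverged
#> 1            0.000        0          0
#> 2            0.498     1528          0
#> 3            0.358     1854          0
```

End-to-end synthetic resting-state ICA (generate → preprocess → whiten →
fixed-point ICA → match against ground truth → component spectra):

```r
run_fmri_pipeline(spec = acquisition_spec(grid_dims = c(20, 20, 10)), seed = 1)
#> <run_report> fmri_ica_pipeline (seed 1)
#>   amari = 0.034584
#>   correlations = 0.9312, 0.9632, 0.9612, 0.9668, 0.9376
#>   low_freq_fraction = 0.9803, 0.9922, 0.9875, 0.9866, 0.9896
#>   suprathreshold_fraction = 0.03994, 0.06297, 0.05451, 0.05545, 0.05028
#>   converged = 1
#>   checks: amari_below_0.1 PASS; all_correlations_above_0.9 PASS; low_freq_power_above_0.8 PASS
```

An Amari index of 0.035 (0 = perfect unmixing) and per-component spatial
correlations above 0.93 mean the five planted "network" maps are recovered
up to sign and order; each recovered time course keeps ~98% of its
periodogram power below 0.1 Hz, the signature band of resting-state BOLD
fluctuations.

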