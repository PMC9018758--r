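# gammacycle

Cycle-by-cycle analysis of gamma-band (30–80 Hz) oscillations in neural
field potentials, for electrophysiologists and methods researchers who need
to measure how individual oscillation cycles vary in amplitude and duration
— and to know when such measurements are artifacts.

## What it does

Naive cycle analysis — band-pass filter, find peaks and troughs, call each
interval a cycle — reports "cycles" in arrhythmic noise, and those spurious
cycles have strongly correlated amplitudes and durations (a random walk
makes large deflections long and small ones short). `gammacycle` provides:

* **A noise-robust cycle detector** (`detectCyclesPhase`): cycles are
  delimited by sign changes of the analytic-signal (Hilbert) phase and kept
  only where the instantaneous frequency stays positive — epochs with
  negative "phase slips" are rejected, so pure noise yields an empty table
  rather than fake cycles. The classical filter-and-extrema baseline
  (`detectCyclesAtallah`) and a band-passed variant with an amplitude
  criterion (`detectCyclesBandpassed`) are included for comparison.
* **The damped-harmonic-oscillator model of gamma**: an AR(2) process
  `x[t] = φ₁x[t−1] + φ₂x[t−2] + ε[t]` with complex eigenvalues
  `m·exp(±i2πf₀/fs)`; the analytic spectrum

      S(f) = σ_z² / (1 + φ₁² + φ₂² − 2φ₁(1−φ₂)cos 2πf − 2φ₂ cos 4πf)

  (`ar2Spectrum`), least-squares spectral fitting with eigenvalue
  extraction (`fitAR2`), and the exact similarity-transform rewriting of
  the AR(2) as a linear excitatory–inhibitory circuit (`ar2ToEI`,
  `decomposeSignal`, `phaseLead`), in which the E and I interaction weights
  always have opposite signs and E phase-leads I.
* **Cycle and spike-field statistics**: time-resolved lagged Spearman
  amplitude–duration correlations with permutation (±3 SD) and exact
  sign-flip inference, regression-residual de-trending, cycle
  autocorrelations, the cycle-based amplitude spectrum (`cbas`),
  cycle-frequency variability estimators (Gaussian fit, Bessel-corrected
  pairs, 2/3-debiased triplets), per-cycle spike counts/rates, PPC1 phase
  locking and phase-bin firing profiles.
* **A synthetic-data layer**: 1/fⁿ colored noise, AR(p) realisations, E–I
  circuit trajectories, noise mixtures, E-modulated Poisson spike trains
  and eye traces with injected microsaccades, all seeded and
  bit-reproducible — every analysis in the package runs end to end on data
  it can generate itself.

## Worked example

Simulate a damped harmonic oscillator at the edge of stability, detect its
cycles, and characterise their joint amplitude–duration statistics:

```r
library(gammacycle)

cfg <- list(synthesis = list(kind = "ar2", magnitude = 0.97, peak_hz = 50,
                             sampling_rate_hz = 2035, n_samples = 120000,
                             seed = 42),
            detector = "phase", stats = list(lags = -2:2),
            output_dir = file.path(tempdir(), "demo_run"))
res <- runPipeline(cfg)

res$cycles
#> HalfCycleTable [phase]: 624 half-cycles, 274 full cycles in 79 epochs
#>   median half-cycle frequency 56.53 Hz, median amplitude 55.1

print(res$correlations, row.names = FALSE)
#>  lag       rho n_effective
#>   -2 0.0135650         466
#>   -1 0.2426798         545
#>    0 0.4636610         624
#>    1 0.3107400         545
#>    2 0.1376637         466

round(res$variability, 2)
#>    gaussian_fit    pairs_bessel triplets_debias
#>           18.92           16.33           15.31

res$ar2fit
#> AR2Model: |lambda| = 0.9694, peak 48.66 Hz (phi1 = 1.9160, phi2 = -0.9398)
#>   spectral fit SSE = 41.21
```

Reading the output: about one minute of signal yields 624 half-cycles in 79
oscillatory epochs (the detector rejects the noise-dominated stretches in
between). The amplitude of a half-cycle correlates with the duration of the
*same* half-cycle (rho = 0.46 at lag 0) much more than with its neighbors'
— the central-peak signature of a noise-driven damped oscillator — and the
spectral fit recovers the generating eigenvalue magnitude (0.9694 vs the
true 0.97) and peak frequency. The three variability estimators agree that
cycle frequency fluctuates with an SD of 15–19 Hz at this oscillation
strength; at stronger oscillation (`magnitude = 0.99`) the same analysis
gives roughly 10 Hz.

Every artifact (cycle tables, correlation tables, CBAS, AR(2) fit, a
manifest with the configuration and seeds) is also written as delimited
text/JSON under `output_dir`; identical configurations produce byte-identical
tables.

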