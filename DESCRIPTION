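Package: gammacycle
Title: Cycle-by-Cycle Analysis of Gamma-Band Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Noise-robust detection of gamma-oscillation half-cycles and
    full cycles from continuous field-potential recordings using the phase of
    the analytic (Hilbert) signal with phase-slip rejection, together with the
    statistics that characterise cycle-by-cycle dynamics: time-resolved
    amplitude-duration correlations with permutation and sign-flip inference,
    cycle amplitude/duration autocorrelations, the cycle-based amplitude
    spectrum, and cycle-frequency variability estimators. Models the
    field potential as a noise-driven damped harmonic oscillator (an AR(2)
    process), fits the AR(2) analytic spectrum to power spectra, and maps
    fitted models onto an equivalent linear excitatory-inhibitory circuit.
    Includes spike-field statistics (pairwise phase consistency, per-cycle
    spike counts and rates, phase-bin firing profiles) and a synthetic-data
    layer (colored noise, AR processes, E-I circuit trajectories, modulated
    Poisson spike trains, eye traces with microsaccades) so every analysis is
    exercisable without recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cycledetect.R'
    'cyclestats.R'
    'ei.R'
    'gammacycle-package.R'
    'io.R'
    'pipeline.R'
    'preprocess.R'
    'spectra.R'
    'spikestats.R'
    'synthgen.R'
    'utils.R'
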