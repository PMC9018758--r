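# Synthetic-data generators: colored noise, AR processes, E-I circuits,
# modulated spikes, mixtures, eye traces.

test_that("colored noise is real, zero-mean and seed-reproducible", {
  rec <- generateColoredNoise(1, 4096, nTraces = 2, samplingRate = 1000,
                              seed = 5)
  x <- extractTrace(rec, 1)
  expect_true(is.numeric(x))
  expect_lt(abs(mean(x)), 1e-10)
  rec2 <- generateColoredNoise(1, 4096, nTraces = 2, samplingRate = 1000,
                               seed = 5)
  expect_identical(samples(rec), samples(rec2))
  expect_error(generateColoredNoise(NaN, 100), "exponent")
  expect_error(generateColoredNoise(1, 1), "nSamples")
})

test_that("colored-noise power-law slope is -2n within 0.1 for n in 0,1,2", {
  # full-length periodogram (segmenting a near-nonstationary 1/f^4 trace
  # would bias the slope) with equal-weight log-spaced frequency bins
  fs <- 1000
  for (n in c(0, 1, 2)) {
    rec <- generateColoredNoise(n, 2^20, samplingRate = fs, seed = 10 + n)
    x <- extractTrace(rec)
    N <- length(x)
    P <- Mod(stats::fft(x)[2:(N / 2)])^2
    f <- seq_len(N / 2 - 1) * fs / N
    edges <- exp(seq(log(2), log(400), length.out = 41))
    bin <- cut(f, edges)
    ok <- !is.na(bin)
    pw <- tapply(P[ok], bin[ok], mean)
    fc <- tapply(f[ok], bin[ok], mean)
    slope <- unname(coef(lm(log(pw) ~ log(fc)))[2L])
    expect_lt(abs(slope - (-2 * n)), 0.1)
  }
})

test_that("ar2FromEigen maps eigen structure to coefficients and back", {
  p <- ar2FromEigen(0.5, 250, 1000)        # peak at fs/4 -> phi1 = 0
  expect_equal(p@phi1, 0, tolerance = 1e-12)
  expect_equal(p@phi2, -0.25, tolerance = 1e-12)
  # companion eigenvalues recover modulus and angle
  m <- 0.93; f <- 41; fs <- 1017
  p2 <- ar2FromEigen(m, f, fs)
  ev <- gammacycle:::ar2Eigenvalues(p2@phi1, p2@phi2)
  expect_equal(sort(Mod(ev)), rep(m, 2), tolerance = 1e-12)
  expect_equal(max(abs(Arg(ev))), 2 * pi * f / fs, tolerance = 1e-12)
  expect_error(ar2FromEigen(1, 50, 1000), "magnitude")
  expect_error(ar2FromEigen(0.9, 600, 1000), "Nyquist")
})

test_that("ar2FromEigen(0.987, 50, 2035) puts the spectral peak near 50 Hz", {
  p <- ar2FromEigen(0.987, 50, 2035)
  # independent oracle: squared gain of the AR transfer function on a grid
  f <- seq(30, 70, by = 0.01)
  w <- 2 * pi * f / 2035
  g <- 1 / Mod(1 - p@phi1 * exp(-1i * w) - p@phi2 * exp(-2i * w))^2
  expect_lt(abs(f[which.max(g)] - 50), 1)
})

test_that("simulateAR is seeded, stationary-checked, and matches S(f)", {
  expect_error(simulateAR(c(1.2, 0.1), 100, seed = 1), "non-stationary")
  # phi = 0 -> white noise with SD sigmaZ
  r0 <- simulateAR(numeric(0), 20000, seed = 2, sigmaZ = 3)
  expect_equal(sd(extractTrace(r0)), 3, tolerance = 0.1)
  r1 <- simulateAR(ar2FromEigen(0.95, 50, 2035), 5000, seed = 7)
  r2 <- simulateAR(ar2FromEigen(0.95, 50, 2035), 5000, seed = 7)
  expect_identical(samples(r1), samples(r2))
  # averaged periodogram vs analytic spectrum, pointwise within 3 MC SEs
  # (Hann taper: rectangular-taper leakage would lift the far floor)
  p <- ar2FromEigen(0.95, 50, 2035)
  K <- 400
  rec <- simulateAR(p, K * 2035, seed = 8)
  sp <- powerSpectrum(rec, epochLength = 1, taper = "hann")
  S <- gammacycle:::ar2SpectrumValues(p, sp@frequencies) * 2 / 2035
  dev <- abs(sp@power - S) / (S / sqrt(K))
  expect_gt(mean(dev < 3), 0.99)
})

test_that("E-I circuit simulation honours structure and noise sharing", {
  expect_error(simulateEICircuit(EIWeights(1.2, 0, 0, 0.9), 100),
               "spectral radius")
  w0 <- EIWeights(0, 0, 0, 0, noiseSD = 2)
  sim <- simulateEICircuit(w0, 20000, seed = 3)
  expect_identical(sim$E, sim$I)          # shared noise, zero coupling
  expect_equal(sd(sim$E), 2, tolerance = 0.1)
  w1 <- EIWeights(0, 0, 0, 0, noiseSD = 2, noiseShared = FALSE)
  sim1 <- simulateEICircuit(w1, 20000, seed = 3)
  expect_lt(abs(cor(sim1$E, sim1$I)), 0.05)
})

test_that("oscillatory circuits have opposite E-I weights and E leads I", {
  mod <- ar2ModelFromParams(ar2FromEigen(0.97, 50, 2035))
  circ <- ar2ToEI(mod)
  w <- circ@weights
  expect_lt(w@vEI * w@vIE, 0)
  sim <- simulateEICircuit(w, 2^18, seed = 12, samplingRate = 2035)
  lead <- phaseLead(sim$E, sim$I, mod@peakFrequency, 2035)
  expect_gt(lead, 0)
})

test_that("modulated Poisson spikes match their rate contract", {
  # gain 0 -> homogeneous Poisson at baseRate
  e <- numeric(50000)
  st <- simulateModulatedSpikes(e, 1000, baseRate = 20, gain = 0, seed = 4)
  n <- nrow(spikes(st))
  expect_equal(n / 50, 20, tolerance = 3 * sqrt(20 * 50) / 50)
  # rate 0 -> empty
  st0 <- simulateModulatedSpikes(e, 1000, baseRate = 0, seed = 5)
  expect_identical(nrow(spikes(st0)), 0L)
  expect_error(simulateModulatedSpikes(e, 1000, baseRate = -1), "baseRate")
  # expected count tracks the integral of the rectified rate
  em <- sin(2 * pi * 50 * (0:49999) / 1000)
  st2 <- simulateModulatedSpikes(em, 1000, baseRate = 10, gain = 40,
                                 seed = 6)
  lam <- pmax(0, 10 + 40 * em)
  expected <- sum(lam) / 1000
  expect_equal(nrow(spikes(st2)), expected,
               tolerance = 4 * sqrt(expected))
})

test_that("spikes modulated by a detected oscillation lock to its cycles", {
  fs <- 2035
  rec <- simulateAR(ar2FromEigen(0.99, 50, fs), 10 * fs, seed = 21)
  x <- extractTrace(rec)
  ez <- as.numeric(scale(x))
  st <- simulateModulatedSpikes(ez, fs, baseRate = 60, gain = 50, seed = 22)
  tab <- detectCyclesPhase(rec)
  cyc <- fullCycles(tab)
  sp <- spikes(st)
  idx <- gammacycle:::assignSpikesToCycles(sp, cyc)
  ph <- spikePhase(sp$time[!is.na(idx)], cyc$start_time[idx[!is.na(idx)]],
                   cyc$duration[idx[!is.na(idx)]])
  h <- hist(ph, breaks = seq(0, 2 * pi, length.out = 9), plot = FALSE)
  # unimodal concentration: max bin well above min bin
  expect_gt(max(h$counts), 2 * min(h$counts))
})

test_that("addNoiseMixture scales noise by the SD ratio", {
  osc <- simulateAR(ar2FromEigen(0.95, 50, 1000), 20000, seed = 30)
  noi <- generateColoredNoise(1, 20000, samplingRate = 1000, seed = 31)
  expect_identical(samples(addNoiseMixture(osc, noi, 0)), samples(osc))
  m1 <- addNoiseMixture(osc, noi, 1)
  v <- var(extractTrace(m1))
  expect_equal(v, 2 * var(extractTrace(osc)), tolerance = 0.1 * v)
  short <- ContinuousRecording(rnorm(100), 1000)
  expect_error(addNoiseMixture(osc, short, 1), "dimensions")
})

test_that("eye traces carry their injected ground truth", {
  tr0 <- generateEyeTrace(5000, 1000, seed = 40)
  expect_identical(nrow(tr0$truth), 0L)
  tr1 <- generateEyeTrace(5000, 1000, saccadeTimes = 2.0, amplitudes = 0.5,
                          durations = 0.02, seed = 41)
  expect_identical(nrow(tr1$truth), 1L)
  expect_equal(tr1$truth$onset, 2.0, tolerance = 1e-3)
  expect_error(generateEyeTrace(5000, 1000,
                                saccadeTimes = c(1, 1.01),
                                durations = 0.02, seed = 1),
               "overlap")
})
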