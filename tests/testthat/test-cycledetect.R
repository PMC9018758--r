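# Phase-based cycle detection, the band-passed variant, the baseline
# filter-and-extrema method, and time-point assignment.

test_that("analytic phase matches the textbook identities on a cosine", {
  fs <- 1000
  t <- (0:4095) / fs
  x <- cos(2 * pi * 50 * t)
  ph <- analyticPhase(x)
  # phase zero crossings sit at signal maxima
  zc <- which(ph$phase[-length(t)] < 0 & ph$phase[-1L] >= 0)
  peaks <- gammacycle:::localExtrema(x, TRUE)
  expect_lt(max(abs(vapply(zc[5:50], function(i)
    min(abs(peaks - i)), numeric(1)))), 2)
  # instantaneous frequency = f
  instf <- diff(ph$unwrapped) * fs / (2 * pi)
  expect_equal(median(instf), 50, tolerance = 0.1)
  expect_error(analyticPhase(numeric(100) * 0), "all-zero")
})

test_that("analytic amplitude tracks an AM envelope", {
  fs <- 1000
  t <- (0:8191) / fs
  env <- 1 + 0.5 * sin(2 * pi * 2 * t)
  x <- env * cos(2 * pi * 60 * t)
  ph <- analyticPhase(x)
  mid <- 1000:7000
  expect_lt(max(abs(ph$amplitude[mid] - env[mid])), 0.05)
})

test_that("a pure sinusoid yields exact alternating half-cycles", {
  fs <- 1000
  A <- 2.5
  rec <- ContinuousRecording(A * sin(2 * pi * 50 * (0:9999) / fs), fs)
  tab <- detectCyclesPhase(rec)
  hc <- halfCycles(tab)
  expect_gt(nrow(hc), 900)
  expect_true(all(abs(hc$duration - 0.010) < 1.5 / fs))
  expect_true(all(abs(hc$amplitude - 2 * A) < 0.02))
  expect_true(all(head(hc$polarity, -1) != tail(hc$polarity, -1)))
  fc <- fullCycles(tab)
  expect_true(all(abs(fc$frequency - 50) < 1))
  # exactly one trough between the two peaks of each full cycle
  expect_true(all(fc$polarity == "peak_peak"))
})

test_that("detector output scales equivariantly with the signal", {
  rec <- simulateAR(ar2FromEigen(0.97, 50, 2035), 60000, seed = 60)
  tab1 <- detectCyclesPhase(rec)
  rec2 <- ContinuousRecording(samples(rec) * 7.5, samplingRate(rec))
  tab2 <- detectCyclesPhase(rec2)
  expect_equal(halfCycles(tab2)$amplitude, 7.5 * halfCycles(tab1)$amplitude,
               tolerance = 1e-12)
  expect_identical(halfCycles(tab2)$duration, halfCycles(tab1)$duration)
})

test_that("retained cycles contain no negative instantaneous frequency", {
  rec <- simulateAR(ar2FromEigen(0.95, 50, 2035), 2e5, seed = 61)
  x <- extractTrace(rec)
  fs <- samplingRate(rec)
  ph <- analyticPhase(x)
  d <- diff(ph$unwrapped)
  hc <- halfCycles(detectCyclesPhase(rec))
  bad <- vapply(seq_len(nrow(hc)), function(i) {
    i0 <- round(hc$start_time[i] * fs) + 1L
    i1 <- round(hc$end_time[i] * fs)
    any(d[i0:min(i1, length(d))] <= 0)
  }, logical(1))
  expect_identical(sum(bad), 0L)
})

test_that("epoch structure is contiguous, alternating and long enough", {
  rec <- simulateAR(ar2FromEigen(0.98, 50, 2035), 2e5, seed = 62)
  tab <- detectCyclesPhase(rec)
  hc <- halfCycles(tab)
  for (e in unique(hc$epoch_id)) {
    h <- hc[hc$epoch_id == e, ]
    h <- h[order(h$start_time), ]
    expect_true(all(abs(h$start_time[-1L] - h$end_time[-nrow(h)]) < 1e-9))
    expect_true(all(head(h$polarity, -1) != tail(h$polarity, -1)))
    # two full peak-to-peak cycles require >= 4 half-cycles
    expect_gte(nrow(h), 4L)
    ep <- epochs(tab)[epochs(tab)$epoch_id == e, ]
    expect_equal(sum(h$duration), ep$end_time - ep$start_time,
                 tolerance = 1e-9)
  }
})

test_that("1/f^2-power noise yields few phase-detected cycles", {
  fs <- 1000
  rec <- generateColoredNoise(1, 30 * fs, samplingRate = fs, seed = 63)
  ph <- detectCyclesPhase(rec)
  at <- detectCyclesAtallah(rec, gammaPeak = 50)
  expect_lt(nrow(halfCycles(ph)), 0.1 * nrow(halfCycles(at)))
})

test_that("detected cycle frequencies concentrate at the spectral peak", {
  # mode estimated by kernel density (durations are sample-quantised, so
  # raw 1-Hz histograms are combs); averaged over seeds. At moderate
  # oscillation strength the distribution sits slightly above the spectral
  # peak (slip-free selection favours fast rotation), tightening as
  # |lambda| -> 1.
  kdeMode <- function(m, seed) {
    rec <- simulateAR(ar2FromEigen(m, 50, 2035), 5e5, seed = seed)
    fc <- fullCycles(detectCyclesPhase(rec))
    kd <- density(fc$frequency, bw = 2, from = 20, to = 90, n = 512)
    kd$x[which.max(kd$y)]
  }
  m97 <- mean(vapply(64:66, function(s) kdeMode(0.97, s), numeric(1)))
  expect_lt(abs(m97 - 50), 2)
  truePk97 <- ar2ModelFromParams(ar2FromEigen(0.97, 50, 2035))@peakFrequency
  expect_lt(abs(m97 - truePk97), 3)
  m99 <- kdeMode(0.99, 67)
  truePk99 <- ar2ModelFromParams(ar2FromEigen(0.99, 50, 2035))@peakFrequency
  expect_lt(abs(m99 - truePk99), 2)
})

test_that("mean cycle frequency tracks the oscillation frequency", {
  freqs <- vapply(c(40, 50, 60), function(f0) {
    rec <- simulateAR(ar2FromEigen(0.97, f0, 2035), 3e5, seed = f0)
    mean(fullCycles(detectCyclesPhase(rec))$frequency)
  }, numeric(1))
  expect_true(all(diff(freqs) > 5))
})

test_that("the amplitude criterion calibrates against the reference", {
  fs <- 1000
  band <- c(20, 100)
  ref <- generateColoredNoise(0, 30 * fs, samplingRate = fs, seed = 65)
  st <- prestimAmplitudeStats(
    detectCyclesPhase(applyFilter(ref, "pass", band), minFullCycles = 1L))
  tst <- generateColoredNoise(0, 30 * fs, samplingRate = fs, seed = 66)
  all <- detectCyclesPhase(applyFilter(tst, "pass", band),
                           minFullCycles = 1L)
  kept <- detectCyclesBandpassed(tst, band, st, minFullCycles = 1L)
  surv <- nrow(halfCycles(kept)) / nrow(halfCycles(all))
  expect_gt(surv, 0.005)                  # one-sided tail survives
  expect_lt(surv, 0.12)                   # ... and only the tail
  # strong oscillation: nearly everything survives
  osc <- simulateAR(ar2FromEigen(0.97, 50, fs), 30 * fs, seed = 67)
  keptO <- detectCyclesBandpassed(osc, band, st, minFullCycles = 1L)
  allO <- detectCyclesPhase(applyFilter(osc, "pass", band),
                            minFullCycles = 1L)
  expect_gt(nrow(halfCycles(keptO)) / nrow(halfCycles(allO)), 0.5)
  # reference far stronger than the test data: nothing survives
  keptBig <- detectCyclesBandpassed(tst, band, c(50 * st[1L], st[2L]))
  expect_identical(nrow(halfCycles(keptBig)), 0L)
  expect_error(detectCyclesBandpassed(tst, band, c(1, 0)), "sigma")
})

test_that("the baseline method agrees with the phase method on a sinusoid", {
  fs <- 1000
  rec <- ContinuousRecording(sin(2 * pi * 50 * (0:19999) / fs), fs)
  at <- detectCyclesAtallah(rec, gammaPeak = 50)
  fc <- fullCycles(at)
  expect_gt(nrow(fc), 100)
  expect_true(all(abs(fc$duration - 0.020) < 2 / fs))
  ph <- fullCycles(detectCyclesPhase(rec))
  expect_equal(median(fc$duration), median(ph$duration), tolerance = 1e-3)
})

test_that("baseline amplitude-duration correlation grows with noise color", {
  fs <- 1000
  rhos <- vapply(c(0, 1, 2), function(n) {
    rec <- generateColoredNoise(n, 40 * fs, samplingRate = fs,
                                seed = 70 + n)
    at <- detectCyclesAtallah(rec, gammaPeak = 50)
    cycleLaggedCorrelation(at, 0, cycleKind = "full")$rho
  }, numeric(1))
  expect_true(all(rhos > 0.3))
  expect_true(all(diff(rhos) > 0))
})

test_that("time-point assignment uses half-open cycle intervals", {
  tab <- makeCycleTable(1, 4, fs = 1000,
                        durationFun = function(tr, i) 0.010,
                        amplitudeFun = function(tr, i) i)
  asg <- assignCyclesToTimepoints(tab, nSamples = 45)
  # each 10 ms cycle claims exactly 10 grid points at 1 kHz
  expect_identical(as.integer(table(asg$cycle[asg$valid])), rep(10L, 4))
  expect_identical(sum(asg$valid), 40L)
  expect_true(all(!asg$valid[41:45, ]))
  # boundary point belongs to the later cycle ([start, end))
  expect_identical(asg$cycle[11, 1], 2L)
  # empty table -> all invalid
  empty <- gammacycle:::emptyCycleTable(1000, "phase")
  asgE <- assignCyclesToTimepoints(empty, 20)
  expect_false(any(asgE$valid))
})
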