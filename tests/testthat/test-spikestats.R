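# Spike-field statistics.

test_that("spike phase is linear interpolation within the cycle", {
  expect_equal(spikePhase(0.1, 0.1, 0.02), 0)
  expect_equal(spikePhase(0.11, 0.1, 0.02), pi)
  expect_equal(spikePhase(0.015, 0, 0.02), 3 * pi / 2)
  expect_error(spikePhase(0.3, 0.1, 0.02), "outside")
})

test_that("ppc1 matches its defining pairwise average", {
  # all phases identical -> 1
  expect_equal(ppc1(rep(1.3, 20), rep(1:4, 5)), 1, tolerance = 1e-12)
  # two trials, one spike each at 0 and pi -> cos(pi) = -1
  expect_equal(ppc1(c(0, pi), c(1, 2)), -1, tolerance = 1e-12)
  # brute-force cross-trial pairwise oracle on random inputs
  set.seed(120)
  for (rep in 1:10) {
    ph <- runif(25, 0, 2 * pi)
    tr <- sample(1:4, 25, replace = TRUE)
    if (length(unique(tr)) < 2) next
    acc <- 0; np <- 0
    for (i in 1:25) for (j in 1:25) if (tr[i] != tr[j]) {
      acc <- acc + cos(ph[i] - ph[j]); np <- np + 1
    }
    expect_equal(ppc1(ph, tr), acc / np, tolerance = 1e-12)
  }
  expect_error(ppc1(runif(5), rep(1, 5)), "one trial")
})

test_that("ppc1 is unbiased on uniform phases and invariant as claimed", {
  set.seed(121)
  vals <- replicate(1000, ppc1(runif(40, 0, 2 * pi),
                               rep(1:4, each = 10)))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-3)
  # duplicating every spike within its trial leaves PPC1 unchanged
  ph <- runif(30, 0, 2 * pi); tr <- rep(1:3, each = 10)
  expect_equal(ppc1(c(ph, ph), c(tr, tr)), ppc1(ph, tr), tolerance = 1e-12)
  # global phase rotation leaves PPC1 unchanged
  expect_equal(ppc1((ph + 1.1) %% (2 * pi), tr), ppc1(ph, tr),
               tolerance = 1e-12)
})

test_that("count equals rate times duration per cycle, and signs follow", {
  set.seed(122)
  # cycles of varying duration, homogeneous Poisson spikes
  tab <- makeCycleTable(30, 8, fs = 1000,
    durationFun = function(tr, i) 0.008 + 0.017 * runif(1),
    amplitudeFun = function(tr, i) 1)
  tab@fullCycles <- tab@halfCycles       # treat as full cycles for metrics
  sp <- do.call(rbind, lapply(1:30, function(tr) {
    tmax <- max(tab@halfCycles$end_time[tab@halfCycles$trial == tr])
    times <- sort(runif(rpois(1, 300 * tmax), 0, tmax))
    if (!length(times)) return(NULL)
    data.frame(unit = 1L, trial = tr, time = times)
  }))
  sset <- SpikeTrainSet(sp)
  m <- perCycleSpikeMetrics(sset, tab, binWidth = 2, minSpikes = 30)
  expect_lt(m$correlations$rho_count[1], -0.3)   # count ~ duration
  expect_lt(abs(m$correlations$rho_rate[1]), 0.15)
  # per-cycle identity count = rate * duration is structural: check by bin
  expect_true(all(m$byBin$n_spikes >= 0))
  # rate proportional to cycle frequency by construction -> positive
  sp2 <- do.call(rbind, lapply(1:30, function(tr) {
    h <- tab@halfCycles[tab@halfCycles$trial == tr, ]
    do.call(rbind, lapply(seq_len(nrow(h)), function(i) {
      lam <- 20 * h$frequency[i] * h$duration[i]
      k <- rpois(1, lam)
      if (!k) return(NULL)
      data.frame(unit = 1L, trial = tr,
                 time = sort(runif(k, h$start_time[i],
                                   h$end_time[i] - 1e-9)))
    }))
  }))
  m2 <- perCycleSpikeMetrics(SpikeTrainSet(sp2), tab, binWidth = 2)
  expect_gt(m2$correlations$rho_rate[1], 0.3)
})

test_that("waveform classification thresholds at 0.235 ms", {
  expect_identical(classifyWaveform(0.30), "BW")
  expect_identical(classifyWaveform(0.20), "NW")
  expect_warning(cls <- classifyWaveform(0.235), "boundary")
  expect_identical(cls, "NW")
  expect_error(classifyWaveform(NA_real_), "finite")
})

test_that("phase-bin profiles resolve flat and concentrated firing", {
  set.seed(123)
  tab <- makeCycleTable(20, 6, fs = 1000,
    durationFun = function(tr, i) 0.01 + 0.02 * (tr %% 2),
    amplitudeFun = function(tr, i) 1)
  tab@fullCycles <- tab@halfCycles
  # phase-uniform spikes: flat profile, near-zero contrasts
  spU <- do.call(rbind, lapply(1:20, function(tr) {
    h <- tab@halfCycles[tab@halfCycles$trial == tr, ]
    data.frame(unit = 1L, trial = tr,
               time = sort(runif(200, 0, max(h$end_time) - 1e-9)))
  }))
  pbU <- phaseBinProfile(SpikeTrainSet(spU), tab)
  expect_lt(max(abs(c(pbU$contrastPreferred, pbU$contrastNonPreferred))),
            0.35)
  expect_lt(diff(range(colSums(pbU$rates))) / mean(colSums(pbU$rates)),
            0.4)
  # all spikes in one bin -> indicator profile
  spI <- do.call(rbind, lapply(1:20, function(tr) {
    h <- tab@halfCycles[tab@halfCycles$trial == tr, ]
    data.frame(unit = 1L, trial = tr,
               time = h$start_time + 0.05 * h$duration)
  }))
  pbI <- phaseBinProfile(SpikeTrainSet(spI), tab)
  expect_identical(pbI$preferredBin, 1L)
  expect_true(all(pbI$rates[, -1] == 0))
  # rates summed over bins recover total spikes / total time
  totRate <- sum(pbI$rates[1, ] * (sum(tab@halfCycles$duration[
    tab@halfCycles$duration <= median(tab@halfCycles$duration)]) / 8)) +
    sum(pbI$rates[2, ] * (sum(tab@halfCycles$duration[
      tab@halfCycles$duration > median(tab@halfCycles$duration)]) / 8))
  expect_equal(totRate, nrow(spI), tolerance = 1e-9)
})

test_that("trough-to-peak rate correlates with the next half-cycle only
           when constructed to", {
  set.seed(124)
  tab <- makeCycleTable(40, 8, fs = 1000,
    durationFun = function(tr, i) 0.008 + 0.017 * runif(1),
    amplitudeFun = function(tr, i) 1)
  # independent rates -> ~0
  spR <- do.call(rbind, lapply(1:40, function(tr) {
    tmax <- max(tab@halfCycles$end_time[tab@halfCycles$trial == tr])
    data.frame(unit = 1L, trial = tr,
               time = sort(runif(rpois(1, 80 * tmax), 0, tmax)))
  }))
  r0 <- leadlagRateDuration(SpikeTrainSet(spR), tab)
  expect_lt(abs(r0$rho), 0.12)
  # rate in each trough->peak half-cycle proportional to next duration
  hc <- tab@halfCycles
  spP <- do.call(rbind, lapply(seq_len(nrow(hc) - 1), function(i) {
    if (hc$polarity[i] != "trough_peak") return(NULL)
    if (hc$trial[i + 1] != hc$trial[i]) return(NULL)
    lam <- 4000 * hc$duration[i + 1]
    k <- rpois(1, lam)
    if (!k) return(NULL)
    data.frame(unit = 1L, trial = hc$trial[i],
               time = sort(runif(k, hc$start_time[i],
                                 hc$end_time[i] - 1e-9)))
  }))
  spP <- spP[order(spP$trial, spP$time), ]
  r1 <- leadlagRateDuration(SpikeTrainSet(spP), tab)
  expect_gt(r1$rho, 0.4)
})
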