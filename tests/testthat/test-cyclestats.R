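# Cycle statistics: lagged correlations, permutation/sign-flip inference,
# regression residuals, CBAS, variability estimators.

test_that("Spearman agrees with a rank-then-Pearson oracle, ties included", {
  set.seed(100)
  for (i in 1:60) {
    n <- sample(3:20, 1)
    x <- sample(1:6, n, replace = TRUE) + rnorm(n, sd = 0.01 * (i %% 2))
    y <- sample(1:6, n, replace = TRUE)
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
    expect_equal(gammacycle:::spearmanRho(x, y), spearmanOracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("timewise lag-0 correlation is exact on degenerate inputs", {
  set.seed(101)
  # amplitudes identical to durations -> rho = 1
  tab <- makeCycleTable(10, 5, fs = 100,
    durationFun = function(tr, i) 0.04 + 0.02 * ((tr * 7 + i) %% 5),
    amplitudeFun = function(tr, i) 0.04 + 0.02 * ((tr * 7 + i) %% 5))
  r <- cycleLaggedCorrelation(tab, 0, scheme = "timewise")
  expect_equal(r$rho, 1, tolerance = 1e-12)
  # shuffled independent durations -> rho ~ 0
  tab2 <- makeCycleTable(40, 5, fs = 100,
    durationFun = function(tr, i) 0.04 + 0.02 * runif(1),
    amplitudeFun = function(tr, i) rlnorm(1))
  r2 <- cycleLaggedCorrelation(tab2, 0, scheme = "timewise")
  expect_lt(abs(r2$rho), 0.15)
})

test_that("permutation inference calibrates and detects coupling", {
  set.seed(102)
  tabNull <- makeCycleTable(20, 4, fs = 100,
    durationFun = function(tr, i) 0.04 + 0.02 * runif(1),
    amplitudeFun = function(tr, i) rlnorm(1))
  pn <- permutationNull(tabNull, nPerm = 1000, seed = 1)
  expect_false(pn$significant)
  expect_lt(abs(pn$surrogateMean), 0.05)
  tabC <- makeCycleTable(20, 4, fs = 100,
    durationFun = function(tr, i) 0.04 + 0.02 * ((tr * 3 + i) %% 7) / 7,
    amplitudeFun = function(tr, i) 0.04 + 0.02 * ((tr * 3 + i) %% 7) / 7)
  pc <- permutationNull(tabC, nPerm = 500, seed = 2)
  expect_true(pc$significant)
  expect_warning(permutationNull(tabNull, nPerm = 50, seed = 3), "nPerm")
})

test_that("permutation shuffles never mix values across time points", {
  # label trick: make each time point's duration set disjoint; the surrogate
  # statistic distribution must stay within what per-time-point shuffles of
  # identical-amplitude sets can produce (rho exactly defined per tp).
  tab <- makeCycleTable(6, 3, fs = 100,
    durationFun = function(tr, i) 0.05,
    amplitudeFun = function(tr, i) tr)
  # all durations equal within a time point -> every shuffle leaves the
  # statistic untouched; surrogate SD must be ~0 only if ties make rho NA.
  # Use instead per-cycle-index distinct durations:
  tab2 <- makeCycleTable(6, 3, fs = 100,
    durationFun = function(tr, i) 0.05 + 0.001 * tr,
    amplitudeFun = function(tr, i) tr)
  pn <- permutationNull(tab2, nPerm = 300, seed = 4)
  # durations are a fixed set per time point; every surrogate rho must lie
  # in [-1, 1] and the empirical equals 1 (amplitude = trial = duration rank)
  expect_equal(pn$rho, 1, tolerance = 1e-12)
  expect_true(all(pn$surrogates <= 1 + 1e-12 &
                  pn$surrogates >= -1 - 1e-12))
})

test_that("sign-flip test matches exhaustive enumeration", {
  vals <- c(0.2, 0.15, 0.3, 0.22, 0.18, 0.25)
  r <- signflipMeanTest(vals)
  expect_equal(r$p, 2 / 2^6, tolerance = 1e-12)
  expect_true(r$significant)
  # symmetric values -> p = 1
  expect_equal(signflipMeanTest(c(0.3, -0.3, 0.1, -0.1))$p, 1)
  # random cases against the independent oracle
  set.seed(103)
  for (i in 1:10) {
    v <- round(rnorm(sample(4:10, 1)), 2)
    expect_equal(signflipMeanTest(v)$p, signflipOracle(v),
                 tolerance = 1e-12)
  }
  expect_error(signflipMeanTest(0.5), "at least 2")
})

test_that("regression residuals preserve genuine cycle-wise coupling", {
  set.seed(104)
  # white-noise triplets: residual correlation ~ raw correlation
  tabW <- makeCycleTable(50, 6, fs = 100,
    durationFun = function(tr, i) 0.04 + 0.02 * runif(1),
    amplitudeFun = function(tr, i) rlnorm(1))
  raw <- cycleLaggedCorrelation(tabW, 0, scheme = "pooled")$rho
  res <- regressionResidualCorrelation(tabW, scheme = "pooled")$rho
  expect_lt(abs(raw - res), 0.1)
  # exact linear trend across triplets -> degenerate, flagged NA
  tabT <- makeCycleTable(4, 6, fs = 100,
    durationFun = function(tr, i) 0.01 * i,
    amplitudeFun = function(tr, i) 0.01 * i)
  expect_true(is.na(regressionResidualCorrelation(tabT,
                                                  scheme = "pooled")$rho))
  # AR(2): residual lag-0 correlation stays positive, comparable to raw
  rec <- simulateAR(ar2FromEigen(0.97, 50, 2035), 3e5, seed = 105)
  tab <- detectCyclesPhase(rec)
  rawA <- cycleLaggedCorrelation(tab, 0)$rho
  resA <- regressionResidualCorrelation(tab)$rho
  expect_gt(resA, 0.2)
  expect_lt(abs(resA - rawA), 0.3)
})

test_that("autocorrelation of iid cycle values vanishes at all lags", {
  set.seed(106)
  tab <- makeCycleTable(40, 12, fs = 100,
    durationFun = function(tr, i) 0.04 + 0.02 * runif(1),
    amplitudeFun = function(tr, i) rlnorm(1))
  ac <- cycleAutocorrelation(tab, "amplitude", lags = c(-2, -1, 1, 2),
                             scheme = "pooled")
  expect_true(all(abs(ac$rho) < 0.1))
})

test_that("eigen-sweep regression is exact OLS", {
  x <- c(0.9, 0.95, 0.99)
  r <- eigenSweepRegression(x, 2 * x + 1)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_error(eigenSweepRegression(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(eigenSweepRegression(c(1, 2), c(1, 2)), "3 points")
})

test_that("CBAS bins, aligns and interpolates", {
  # identical cycles: one occupied bin, flat amplitude
  tab <- makeCycleTable(5, 6, fs = 1000,
                        durationFun = function(tr, i) 0.010,
                        amplitudeFun = function(tr, i) 2)
  cb <- cbas(tab, gammaPeak = 50)
  occ <- cb[!is.na(cb$mean_amplitude), ]
  expect_identical(nrow(occ), 1L)
  expect_identical(occ$offset_hz, 0)
  expect_equal(occ$mean_amplitude, 2)
  # AR(2): unimodal count distribution with mode within 2 Hz of zero offset
  p <- ar2FromEigen(0.97, 50, 2035)
  rec <- simulateAR(p, 6e5, seed = 107)
  tabA <- detectCyclesPhase(rec)
  sp <- powerSpectrum(rec, 1, "rectangular")
  pk <- sp@frequencies[which.max(sp@power)]
  cbA <- cbas(tabA, pk)
  # duration quantisation makes single 1-Hz bins unreliable; the central
  # tendency of the windowed distribution must still sit at the peak
  fwin <- halfCycles(tabA)$frequency
  fwin <- fwin[abs(fwin - pk) <= 20]
  expect_lt(abs(median(fwin) - pk), 3)
  # ... and the distribution is unimodal-symmetric enough that counts fall
  # off on both sides of the central third of the window
  centralMass <- sum(cbA$count[abs(cbA$offset_hz) <= 7], na.rm = TRUE)
  expect_gt(centralMass, 0.5 * sum(cbA$count, na.rm = TRUE))
  # maximal mean amplitude at or below the Fourier peak
  expect_lte(cbA$offset_hz[which.max(cbA$mean_amplitude)], 0)
  # interior interpolation fills the duration-quantisation comb
  expect_true(any(cbA$interpolated))
})

test_that("variability estimators are consistent and the debias is 2/3", {
  set.seed(108)
  f <- rnorm(1e6, mean = 50, sd = 1)
  expect_equal(frequencyVariability(f, "gaussian_fit"), 1, tolerance = 0.01)
  expect_equal(frequencyVariability(f, "pairs_bessel"), 1, tolerance = 0.01)
  expect_equal(frequencyVariability(f, "triplets_debias"), 1,
               tolerance = 0.01)
  # without the 2/3 debias the triplet statistic overestimates by 3/2
  n <- length(f); mid <- 2:(n - 1)
  rawTriplet <- mean((f[mid] - (f[mid - 1] + f[mid + 1]) / 2)^2)
  expect_equal(rawTriplet, 1.5, tolerance = 0.01)
  # constant input -> zero
  expect_equal(frequencyVariability(rep(40, 100), "gaussian_fit"), 0)
  expect_equal(frequencyVariability(rep(40, 100), "pairs_bessel"), 0)
  expect_equal(frequencyVariability(rep(40, 100), "triplets_debias"), 0)
  expect_error(frequencyVariability(c(1, 2), "triplets_debias"), ">= 3")
})

test_that("pair/triplet estimators ignore slow drift; moment fits do not", {
  set.seed(109)
  n <- 2e5
  f <- rnorm(n, sd = 1) + seq(0, 20, length.out = n)   # 20 Hz linear drift
  expect_equal(frequencyVariability(f, "pairs_bessel"), 1, tolerance = 0.02)
  expect_equal(frequencyVariability(f, "triplets_debias"), 1,
               tolerance = 0.02)
  expect_gt(frequencyVariability(f, "gaussian_fit"), 3)
})

test_that("the histogram least-squares Gaussian fit works on clean bins", {
  set.seed(110)
  f <- rnorm(5e4, mean = 50, sd = 4)
  expect_equal(frequencyVariability(f, "gaussian_ls"), 4, tolerance = 0.1)
})
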