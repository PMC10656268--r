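test_that("study-day threshold averages per-period SDs", {
  mkSd <- function(s) { x <- c(-1, 1, -1, 1); x / sd(x) * s }
  expect_equal(rippleThreshold(list(mkSd(10), mkSd(12)), fs = 1,
                               sdMultiplier = 5, offsetUv = 5,
                               minNremS = 0), 60)
  expect_equal(rippleThreshold(list(mkSd(10)), 1, 5, 5, 0), 55)
  expect_equal(rippleThreshold(list(rep(0, 10)), 1, 5, 5, 0), 5)
  # periods with <= 3 min of NonREM are excluded
  long <- mkSd(10)[rep(1:4, 100)]
  expect_error(rippleThreshold(list(mkSd(10)), fs = 1, minNremS = 180),
               "3 min|180")
})

test_that("ripple detector recovers an isolated tapered burst", {
  fs <- 2500
  set.seed(61)
  bg <- generateBackground(60, fs, 1.5, 2.5)
  bandSd <- sd(bandpassFilter(bg, fs, 100, 300))
  x <- addEvents(bg, fs, "ripple", 30, 150, 60, 10 * bandSd)
  xf <- bandpassFilter(x, fs, 100, 300)
  thr <- rippleThreshold(list(xf), fs, 5, 5, minNremS = 0)
  det <- detectRipples(xf, fs, thr)
  expect_equal(nrow(det), 1)
  # the envelope plateau spans ~45 ms, so the peak can sit anywhere on it
  expect_lt(abs(det$peak_s - 30), 0.03)
  expect_lt(abs(det$duration_ms - 60), 10)
  expect_equal(det$length_class, "SHORT")
  expect_lt(abs(det$mean_freq_hz - 150), 10)
})

test_that("closeness merging follows the 20 ms chronic rule exactly", {
  fs <- 2500
  mk <- function(gapMs) {
    x <- numeric(round(0.5 * fs))
    x <- injectBurst(x, fs, 0.215, 150, 30, 100)
    injectBurst(x, fs, 0.215 + 0.030 + gapMs / 1000, 150, 30, 100)
  }
  expect_equal(nrow(detectRipples(mk(15), fs, 50, 20, 20)), 1)
  expect_equal(nrow(detectRipples(mk(25), fs, 50, 20, 20)), 2)
})

test_that("suprathreshold runs below the minimum duration are dropped", {
  fs <- 2500
  x <- injectBurst(numeric(fs), fs, 0.3, 150, 10, 100)
  expect_equal(nrow(detectRipples(x, fs, 50, 20, 20)), 0)
})

test_that("raising the SD multiplier never increases the event count", {
  fs <- 1000
  set.seed(77)
  bg <- generateBackground(60, fs, 1.5, 2.5)
  x <- addEvents(bg, fs, "ripple", seq(5, 55, by = 5), 150, 60,
                 8 * sd(bandpassFilter(bg, fs, 100, 300)))
  xf <- bandpassFilter(x, fs, 100, 300)
  s <- sd(xf)
  counts <- vapply(c(2, 3, 4, 5, 7, 10, 100), function(m) {
    nrow(detectRipples(xf, fs, m * s + 5))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("emitted ripples satisfy their defining predicates", {
  fs <- 1000
  set.seed(78)
  bg <- generateBackground(60, fs, 1.5, 2.5)
  x <- addEvents(bg, fs, "ripple", seq(5, 55, by = 5), 150, 80,
                 10 * sd(bandpassFilter(bg, fs, 100, 300)))
  xf <- bandpassFilter(x, fs, 100, 300)
  thr <- 5 * sd(xf) + 5
  det <- detectRipples(xf, fs, thr, 20, 20, 0.5)
  expect_gt(nrow(det), 0)
  env <- abs(analyticSignal(xf))
  for (i in seq_len(nrow(det))) {
    expect_gte(det$amplitude_uv[i], thr)                      # crossed it
    expect_equal(det$duration_ms[i],
                 (det$end_s[i] - det$start_s[i]) * 1000)      # definitional
    expect_equal(det$length_class[i],
                 ifelse(det$duration_ms[i] <= 100, "SHORT", "LONG"))
    pk <- round(det$peak_s[i] * fs) + 1
    expect_equal(env[pk], det$amplitude_uv[i], tolerance = 1e-6)
  }
  # no two events closer than the closeness gap
  if (nrow(det) > 1) {
    gaps <- det$start_s[-1] - det$end_s[-nrow(det)]
    expect_true(all(gaps * 1000 >= 0))
  }
})

test_that("events inside blanked intervals are discarded", {
  fs <- 2500
  x <- injectBurst(numeric(2 * fs), fs, 0.5, 150, 60, 100)
  x <- injectBurst(x, fs, 1.5, 150, 60, 100)
  mask <- data.frame(start_s = 1.4, end_s = 1.6)
  det <- detectRipples(x, fs, 50, mask = mask)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$peak_s - 0.5), 0.05)
})

test_that("unfiltered-looking input only warns", {
  fs <- 1000
  set.seed(9)
  raw <- generateBackground(10, fs, 1.5, 2.5)
  expect_warning(detectRipples(raw, fs, 1e6, band = c(100, 300)),
                 "unfiltered")
})

test_that("quiet-wake detection vetoes movement and theta epochs", {
  fs <- 1000
  set.seed(55)
  bg <- generateBackground(90, fs, 1.5, 2.5)
  bandSd <- sd(bandpassFilter(bg, fs, 100, 300))
  # ripples at 20 s (still), 50 s (moving), 80 s (high theta)
  x <- addEvents(bg, fs, "ripple", c(20, 50, 80), 150, 60, 10 * bandSd)
  xf <- bandpassFilter(x, fs, 100, 300)
  thr <- 5 * bandSd + 5
  wake <- data.frame(start_s = c(10, 40, 70), end_s = c(30, 60, 90))
  acc <- matrix(rnorm(90 * fs * 3, sd = 0.02), ncol = 3)
  acc[(45 * fs):(55 * fs), ] <- rnorm(length((45 * fs):(55 * fs)) * 3,
                                      sd = 0.5)
  thetaPower <- data.frame(start_s = c(10, 40, 70), end_s = c(30, 60, 90),
                           power = c(1, 1, 10))
  quietRes <- sqrt(rowSums(matrix(rnorm(fs * 3, sd = 0.02), ncol = 3)^2))
  det <- detectQuietWakeRipples(xf, fs, thr, wake, acc = acc,
                                accBaseline = quietRes,
                                thetaPower = thetaPower, thetaThreshold = 5)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$peak_s - 20), 0.05)
  expect_true(all(det$context == "QUIET_WAKE"))
  # without accelerometer: warning, no movement veto
  expect_warning(
    det2 <- detectQuietWakeRipples(xf, fs, thr, wake,
                                   thetaPower = thetaPower,
                                   thetaThreshold = 5),
    "accelerometer")
  expect_equal(nrow(det2), 2)
})

test_that("spindle detector enforces duration floor and ceiling", {
  fs <- 1000
  set.seed(91)
  bg <- generateBackground(120, fs, 1.5, 2.5)
  bsd <- sd(bandpassFilter(bg, fs, 9, 20))
  # constant-envelope spindle burst: duration measured at the crossings
  x <- injectBurst(bg, fs, 60, 14, 800, 8 * bsd)
  sp <- detectSpindles(bandpassFilter(x, fs, 9, 20), fs)
  hit <- which(abs(sp$peak_s - 60) < 0.45)
  expect_equal(length(hit), 1)
  expect_lt(abs(sp$duration_ms[hit] - 800), 100)
  expect_equal(sp$kind[hit], "SPINDLE")

  # 200 ms burst: below the 0.4 s floor.  Constructed directly as the
  # band-limited input trace, since the 9-20 Hz band-pass itself would
  # ring a 200 ms burst out past the floor.
  set.seed(17)
  x2 <- injectBurst(rnorm(120 * fs, sd = 1), fs, 60, 14, 200, 8)
  sp2 <- detectSpindles(x2, fs)
  expect_false(any(abs(sp2$peak_s - 60) < 0.3))

  # continuous sine: above the 3 s ceiling
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  expect_equal(nrow(detectSpindles(sin(2 * pi * 14 * t) * 50, fs)), 0)
})

test_that("tapered spindles at 8x band SD are recovered", {
  fs <- 1000
  set.seed(92)
  bg <- generateBackground(300, fs, 1.5, 2.5)
  bsd <- sd(bandpassFilter(bg, fs, 9, 20))
  tt <- seq(25, 275, by = 50)
  x <- addEvents(bg, fs, "spindle", tt, 14, 800, 8 * bsd)
  sp <- detectSpindles(bandpassFilter(x, fs, 9, 20), fs)
  hits <- sum(vapply(tt, function(t) any(abs(sp$peak_s - t) < 0.4),
                     logical(1)))
  expect_gte(hits, 5)
})

test_that("delta detector finds the wave and respects thresholds", {
  fs <- 500
  set.seed(93)
  bg <- generateBackground(120, fs, 1.5, 2.5)
  bf <- bandpassFilter(bg, fs, 1, 6)
  x <- addEvents(bg, fs, "delta", 60, 2.5, 400, 6 * sd(bf))
  xf <- bandpassFilter(x, fs, 1, 6)
  de <- detectDeltaWaves(xf, fs)
  j <- which.min(abs(de$peak_s - 60))
  expect_gt(nrow(de), 0)
  expect_lt(abs(de$peak_s[j] - 60), 0.1)
  expect_true(de$start_s[j] < de$peak_s[j] && de$peak_s[j] < de$end_s[j])

  # low-amplitude wave rejected
  x2 <- addEvents(bg, fs, "delta", 60, 2.5, 400, 0.5 * sd(bf))
  de2 <- detectDeltaWaves(bandpassFilter(x2, fs, 1, 6), fs)
  expect_false(any(abs(de2$peak_s - 60) < 0.05 &
                     de2$amplitude_uv > 2 * sd(bf) * 3))
})

test_that("delta false-positive rate on noise is low at 5 SD thresholds", {
  fs <- 200
  rate <- vapply(1:10, function(s) {
    set.seed(400 + s)
    x <- bandpassFilter(rnorm(120 * fs), fs, 1, 6)
    nrow(detectDeltaWaves(x, fs, peakMult = 5, troughMult = 5)) / 120
  }, numeric(1))
  expect_lt(mean(rate), 0.05)
})
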