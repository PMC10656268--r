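test_that("white-noise background has a flat log-log spectrum", {
  fs <- 500
  acc <- NULL
  for (s in 1:10) {
    x <- generateBackground(20, fs, exponent = 0, offset = 1, seed = s)
    ps <- sleepLFP:::welchPSD(x, fs, windowS = 2, overlapS = 0)
    acc <- if (is.null(acc)) ps$power else acc + ps$power
  }
  sel <- ps$frequency >= 1 & ps$frequency <= 100
  fit <- lm(log10(acc[sel] / 10) ~ log10(ps$frequency[sel]))
  expect_lt(abs(coef(fit)[2]), 0.05)
  expect_lt(abs(mean(x)), 1)
})

test_that("1/f^2 background recovers its slope from the periodogram", {
  fs <- 1000
  slopes <- vapply(1:10, function(s) {
    x <- generateBackground(120, fs, exponent = 2, offset = 2, seed = 100 + s)
    ps <- sleepLFP:::welchPSD(x, fs)
    sel <- ps$frequency >= 1 & ps$frequency <= 100
    unname(coef(lm(log10(ps$power[sel]) ~ log10(ps$frequency[sel])))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-2)), 0.1)
})

test_that("background generation is deterministic and validates input", {
  expect_identical(generateBackground(5, 200, 1, 1, seed = 7),
                   generateBackground(5, 200, 1, 1, seed = 7))
  expect_error(generateBackground(-1, 200, 1, 1), "positive")
  expect_error(generateBackground(0.001, 200, 1, 1), "2 samples")
})

test_that("synthEvent honors duration, amplitude and carrier frequency", {
  sp <- eventSpec("ripple", 150, 60, 100, time = 1)
  ev <- synthEvent(sp, 2500)
  expect_lte(abs(length(ev$wave) - 150), 1)
  expect_lt(abs(max(abs(ev$wave)) - 100) / 100, 0.01)

  de <- synthEvent(eventSpec("delta", 2, 400, 300, 1), 500)
  ps <- sleepLFP:::periodogramPSD(de$wave, 500)
  expect_lt(abs(ps$frequency[which.max(ps$power)] - 2), 500 / length(de$wave))

  spw <- synthEvent(eventSpec("spindle", 14, 800, 80, 1), 500)
  ps <- sleepLFP:::periodogramPSD(spw$wave, 500)
  band <- ps$frequency >= 9 & ps$frequency <= 20
  expect_gt(sum(ps$power[band]) / sum(ps$power), 0.8)

  expect_error(synthEvent(eventSpec("ripple", 150, 60, 100, 1), fs = 250),
               "Nyquist")
  expect_error(eventSpec("ripple", 50, 60, 100, 1), "outside admissible")
  expect_error(eventSpec("spindle", 25, 500, 50, 1), "outside admissible")
  expect_error(eventSpec("delta", 2, -5, 50, 1), "durationMs")
})

test_that("recording with no events is pure background with empty truth", {
  cfg <- simConfig(20, 500, stateSchedule = data.frame(state = "NREM",
                                                       duration = 20),
                   seed = 3, soAmplitudeUv = 0)
  rec <- generateRecording(cfg)
  expect_equal(nrow(rec$truth$events), 0)
  bg <- generateBackground(20, 500, 1.5, 2.5, seed = 3)
  expect_equal(channelData(rec$bundle, "HPC"), bg)
})

test_that("coupled pairs realize requested lags within jitter", {
  cfg <- simConfig(600, 500,
                   stateSchedule = data.frame(state = "NREM", duration = 600),
                   couplingSpecs = list(list(lead = "delta", trail = "ripple",
                                             lagMs = 200, jitterMs = 50,
                                             count = 50)),
                   seed = 11)
  rec <- generateRecording(cfg)
  expect_equal(length(rec$truth$coupledTuples), 50)
  ev <- rec$truth$events
  lags <- vapply(rec$truth$coupledTuples, function(tp) {
    (ev$peak_s[tp[2]] - ev$peak_s[tp[1]]) * 1000
  }, numeric(1))
  expect_true(all(lags >= 150 & lags <= 250))
  # ground-truth events are sorted and inside the recording
  expect_true(!is.unsorted(ev$start_s))
  expect_true(all(ev$start_s >= 0 & ev$end_s <= 600))
})

test_that("phase-targeted ripples land around the requested phase", {
  cfg <- simConfig(120, 1000,
                   stateSchedule = data.frame(state = "NREM", duration = 120),
                   phaseSpec = list(soFrequencyHz = 1, targetPhaseDeg = 180,
                                    concentration = 50, count = 100,
                                    soAmplitudeUv = 300),
                   seed = 9)
  rec <- generateRecording(cfg)
  ph <- rec$truth$eventPhases$phase_deg
  expect_equal(length(ph), 100)
  d <- (circMeanDeg(ph) - 180 + 180) %% 360 - 180
  expect_lt(abs(d), 10)
})

test_that("identical configs give bit-identical recordings", {
  cfg <- simConfig(30, 500,
                   stateSchedule = data.frame(state = c("NREM", "REM"),
                                              duration = c(20, 10)),
                   eventSpecs = list(eventSpec("ripple", 150, 60, 100,
                                               "NREM")),
                   seed = 21)
  r1 <- generateRecording(cfg)
  r2 <- generateRecording(cfg)
  expect_identical(r1$bundle@samples, r2$bundle@samples)
  expect_identical(r1$truth$events, r2$truth$events)
})

test_that("overlapping identical-kind requests warn but are both recorded", {
  cfg <- simConfig(10, 500,
                   stateSchedule = data.frame(state = "NREM", duration = 10),
                   eventSpecs = list(
                     eventSpec("ripple", 150, 60, 100, time = 5),
                     eventSpec("ripple", 150, 60, 100, time = 5)),
                   seed = 2)
  expect_warning(rec <- generateRecording(cfg), "identical")
  expect_equal(nrow(rec$truth$events), 2)
})

test_that("accelerometer variance is elevated only during wake", {
  cfg <- simConfig(40, 200,
                   stateSchedule = data.frame(state = c("NREM", "WAKE"),
                                              duration = c(20, 20)),
                   seed = 4)
  rec <- generateRecording(cfg)
  acc <- channelData(rec$bundle, "ACC_X")
  sdSleep <- sd(acc[1:(20 * 200)])
  sdWake <- sd(acc[(20 * 200 + 1):(40 * 200)])
  expect_gt(sdWake / sdSleep, 5)
})

test_that("schedule durations must sum to the recording duration", {
  expect_error(simConfig(10, 100,
                         stateSchedule = data.frame(state = "NREM",
                                                    duration = 9)),
               "sum")
  expect_error(simConfig(10, 100, phaseSpec = list(targetPhaseDeg = 380)),
               "360")
})
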