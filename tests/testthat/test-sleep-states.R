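test_that("architecture worked example: bouts, transitions, exclusion", {
  h <- hypnogram(c(rep("NREM", 10), rep("REM", 5), rep("NREM", 3)),
                 epochS = 1)
  a <- sleepArchitecture(h, minBout = 4)
  tr <- a$transitions
  expect_equal(tr$count[tr$from == "NREM" & tr$to == "REM"], 1)
  expect_equal(tr$count[tr$from == "REM" & tr$to == "NREM"], 1)
  expect_equal(sum(tr$count), 2)
  expect_equal(a$bouts$duration_s, c(10, 5, 3))
  expect_equal(a$bouts$duration_s[a$bouts$included], c(10, 5))
  expect_equal(a$tst, 18)
  # per-state times partition labeled sleep exactly
  expect_equal(sum(a$bouts$duration_s), 18)
})

test_that("all-wake hypnogram reports zero sleep with a flag", {
  a <- sleepArchitecture(hypnogram(rep("WAKE", 100)))
  expect_equal(a$tst, 0)
  expect_true(a$noSleep)
  expect_true(all(a$pctState == 0) || length(a$pctState) == 0)
})

test_that("transition counts match a brute-force label-change scan", {
  set.seed(31)
  st <- sample(c("WAKE", "NREM", "INTERMEDIATE", "REM"), 10000,
               replace = TRUE, prob = c(0.3, 0.4, 0.1, 0.2))
  a <- sleepArchitecture(hypnogram(st))
  changes <- sum(st[-1] != st[-length(st)])
  expect_equal(sum(a$transitions$count), changes)
  # spot-check one cell against a direct scan
  direct <- sum(st[-length(st)] == "NREM" & st[-1] == "REM")
  got <- a$transitions$count[a$transitions$from == "NREM" &
                               a$transitions$to == "REM"]
  expect_equal(got, direct)
})

test_that("binned percentages normalize a partial final bin by itself", {
  # 100 min: bins of 45 min -> 45, 45, 10
  st <- c(rep("NREM", 60 * 60), rep("REM", 40 * 60))
  a <- sleepArchitecture(hypnogram(st), binWidth = 2700)
  b3 <- a$binnedPct[a$binnedPct$bin == 3, ]
  expect_equal(b3$pct[b3$state == "REM"], 100)
  b1 <- a$binnedPct[a$binnedPct$bin == 1, ]
  expect_equal(b1$pct[b1$state == "NREM"], 100)
  b2 <- a$binnedPct[a$binnedPct$bin == 2, ]
  expect_equal(b2$pct[b2$state == "NREM"], 100 * 15 / 45, tolerance = 1e-6)
})

test_that("epoch features identify the dominant band", {
  fs <- 200
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  theta <- signalBundle(cbind(sin(2 * pi * 5 * t), sin(2 * pi * 5 * t)),
                        fs, c("HPC", "PFC"))
  f <- epochFeatures(theta, 10)
  bands <- c("so_power", "delta_power", "theta_power", "low_beta",
             "low_gamma", "high_gamma", "ripple_power")
  vals <- unlist(f[1, paste0("hpc_", bands)])
  expect_equal(names(which.max(vals)), "hpc_theta_power")

  so <- signalBundle(cbind(sin(2 * pi * 0.5 * t), sin(2 * pi * 0.5 * t)),
                     fs, c("HPC", "PFC"))
  f2 <- epochFeatures(so, 10)
  vals2 <- unlist(f2[1, paste0("pfc_", bands)])
  expect_equal(names(which.max(vals2)), "pfc_so_power")
  expect_lt(f2$pfc_theta_so_ratio[1], 1)

  expect_error(epochFeatures(theta, 100), "epoch longer")
})

test_that("white-noise band powers scale with bandwidth", {
  fs <- 400
  set.seed(8)
  sb <- signalBundle(cbind(rnorm(10 * 10 * fs), rnorm(10 * 10 * fs)),
                     fs, c("HPC", "PFC"))
  f <- epochFeatures(sb, 10)
  # mean over 10 epochs; power per Hz should be constant across bands
  dens <- c(mean(f$hpc_delta_power) / 2,    # 1-3 Hz
            mean(f$hpc_theta_power) / 3,    # 3-6 Hz
            mean(f$hpc_low_beta) / 10,      # 10-20 Hz
            mean(f$hpc_low_gamma) / 15,     # 30-45 Hz
            mean(f$hpc_high_gamma) / 25)    # 55-80 Hz
  expect_lt(max(dens) / min(dens), 1.2 / 0.95)
})

test_that("amplitude outlier flagging follows the scaled-MAD rule", {
  f <- data.frame(epoch = 1:100, hpc_amplitude = rep(10, 100))
  expect_false(any(flagArtifactEpochs(f)))

  set.seed(2)
  f2 <- data.frame(epoch = 1:100, hpc_amplitude = 10 + rnorm(100, sd = 0.5))
  out <- c(17, 58)
  f2$hpc_amplitude[out] <- 100
  flags <- flagArtifactEpochs(f2)
  expect_equal(which(flags), out)
})

test_that("classifier separates synthetic NonREM-like and REM-like epochs", {
  sched <- data.frame(state = rep(c("NREM_LIKE", "REM_LIKE"), 10),
                      duration = 10)
  rec <- generateRecording(simConfig(200, 600, stateSchedule = sched,
                                     regime = "acute", seed = 5))
  f <- epochFeatures(rec$bundle, 10)
  hyp <- classifySleepLike(f, seed = 1)
  acc <- mean(states(hyp) == states(rec$truth$hypnogram))
  expect_gte(acc, 0.9)
  # labeling semantics: NonREM-like epochs carry more slow-oscillation power
  soN <- mean(f$pfc_so_power[states(hyp) == "NREM_LIKE"])
  soR <- mean(f$pfc_so_power[states(hyp) == "REM_LIKE"])
  expect_gt(soN, soR)
})

test_that("classifier is stable across seeds and epoch order", {
  # two perfectly separated clouds in feature space
  set.seed(12)
  n <- 40
  mk <- function(so, th) {
    data.frame(hpc_so_power = so + rnorm(n / 2, sd = 0.01),
               pfc_so_power = so + rnorm(n / 2, sd = 0.01),
               hpc_theta_power = th + rnorm(n / 2, sd = 0.01),
               pfc_theta_power = th + rnorm(n / 2, sd = 0.01),
               hpc_amplitude = so * 10 + rnorm(n / 2, sd = 0.01),
               pfc_amplitude = so * 10 + rnorm(n / 2, sd = 0.01))
  }
  f <- cbind(epoch = 1:n, rbind(mk(10, 1), mk(1, 10)))
  attr(f, "epochS") <- 10
  truth <- c(rep("NREM_LIKE", n / 2), rep("REM_LIKE", n / 2))
  for (s in 1:10) {
    hyp <- classifySleepLike(f, seed = s,
                             artifactFlags = rep(FALSE, n))
    expect_identical(states(hyp), truth)
  }
  # permutation invariance up to identical labels
  perm <- sample(n)
  fp <- f[perm, ]
  attr(fp, "epochS") <- 10
  hp <- classifySleepLike(fp, seed = 1, artifactFlags = rep(FALSE, n))
  expect_identical(states(hp), truth[perm])
})

test_that("classifier errors without enough usable epochs", {
  f <- data.frame(epoch = 1:4, hpc_so_power = rnorm(4),
                  hpc_amplitude = rnorm(4))
  attr(f, "epochS") <- 10
  expect_error(classifySleepLike(f, artifactFlags = rep(TRUE, 4)),
               "at least 2")
})
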