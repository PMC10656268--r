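test_that("worked pair examples with inclusive boundaries", {
  de <- data.frame(id = 1, peak_s = 1.000)
  sp <- data.frame(id = 1, peak_s = 1.500)
  ds <- detectPairs(de, sp, couplingWindows()$D_S, "D_S")
  expect_equal(nrow(ds), 1)
  expect_equal(ds$interval_ms, 500)

  rp <- data.frame(id = 1, peak_s = 1.050)
  dr <- detectPairs(de, rp, couplingWindows()$D_R, "D_R")
  expect_equal(nrow(dr), 1)          # 50 ms boundary is inclusive
  expect_equal(dr$interval_ms, 50)

  expect_equal(nrow(detectPairs(de, data.frame(id = 1, peak_s = 1.049),
                                couplingWindows()$D_R)), 0)
  expect_error(detectPairs(de, sp, c(400, 50)), "minimum exceeds")
})

test_that("pair detection equals the all-pairs brute force", {
  set.seed(17)
  for (rep_ in 1:20) {
    n <- sample(50:200, 1)
    lead <- data.frame(id = seq_len(n), peak_s = sort(runif(n, 0, 120)))
    trail <- data.frame(id = seq_len(n), peak_s = sort(runif(n, 0, 120)))
    for (w in couplingWindows()) {
      expect_equal(nrow(detectPairs(lead, trail, w)),
                   brutePairCount(lead$peak_s, trail$peak_s, w))
    }
  }
})

test_that("triplets equal the brute-force triple enumeration", {
  set.seed(18)
  w <- couplingWindows()
  for (rep_ in 1:10) {
    n <- 25
    de <- data.frame(id = seq_len(n), peak_s = sort(runif(n, 0, 30)))
    rp <- data.frame(id = seq_len(n), peak_s = sort(runif(n, 0, 30)))
    sp <- data.frame(id = seq_len(n), peak_s = sort(runif(n, 0, 30)))
    dr <- detectPairs(de, rp, w$D_R, "D_R")
    rs <- detectPairs(rp, sp, w$R_S, "R_S")
    got <- nrow(detectTriplets(dr, rs))
    combos <- expand.grid(d = de$peak_s, r = rp$peak_s, s = sp$peak_s)
    brute <- with(combos, sum(
      (r - d) * 1000 >= w$D_R[1] & (r - d) * 1000 <= w$D_R[2] &
        (s - r) * 1000 >= w$R_S[1] & (s - r) * 1000 <= w$R_S[2]))
    expect_equal(got, brute)
  }
})

test_that("co-occurrence implements both interval conditions", {
  rp <- data.frame(id = 1, start_s = 1.00, end_s = 1.05)
  sp <- data.frame(id = 1, start_s = 0.90, end_s = 1.60)
  expect_equal(nrow(detectCooccurrence(rp, sp)$pairs), 1)  # contained

  rp2 <- data.frame(id = 1, start_s = 0.85, end_s = 0.95)
  expect_equal(nrow(detectCooccurrence(rp2, sp)$pairs), 1) # end inside

  rp3 <- data.frame(id = 1, start_s = 2.0, end_s = 2.1)
  expect_equal(nrow(detectCooccurrence(rp3, sp)$pairs), 0) # disjoint

  # several ripples in one spindle: directional counts differ
  rp4 <- data.frame(id = 1:3, start_s = c(1.0, 1.2, 1.4),
                    end_s = c(1.05, 1.25, 1.45))
  co <- detectCooccurrence(rp4, sp)
  expect_equal(co$nRipplesWithSpindles, 3)
  expect_equal(co$nSpindlesWithRipples, 1)
})

test_that("co-occurrence equals a brute-force interval check", {
  set.seed(19)
  mkIv <- function(n, durLo, durHi) {
    s <- sort(runif(n, 0, 60))
    data.frame(id = seq_len(n), start_s = s,
               end_s = s + runif(n, durLo, durHi))
  }
  for (rep_ in 1:10) {
    rp <- mkIv(50, 0.02, 0.2)
    sp <- mkIv(50, 0.4, 3)
    got <- nrow(detectCooccurrence(rp, sp)$pairs)
    brute <- 0
    for (i in 1:50) for (j in 1:50) {
      r0 <- rp$start_s[i]; r1 <- rp$end_s[i]
      s0 <- sp$start_s[j]; s1 <- sp$end_s[j]
      ins <- function(t, lo, hi) t >= lo && t <= hi
      if ((ins(r0, s0, s1) && ins(r1, s0, s1)) || ins(r0, s0, s1) ||
            ins(r1, s0, s1) || ins(s0, r0, r1) || ins(s1, r0, r1)) {
        brute <- brute + 1
      }
    }
    expect_equal(got, brute)
  }
})

test_that("D-SwR requires both the delta lead and a hosted ripple", {
  de <- data.frame(id = 1, peak_s = 1.0)
  sp <- data.frame(id = 1, peak_s = 1.5, start_s = 1.2, end_s = 2.0)
  rp <- data.frame(id = 1, peak_s = 1.6, start_s = 1.55, end_s = 1.65)
  ds <- detectPairs(de, sp, couplingWindows()$D_S, "D_S")
  co <- detectCooccurrence(rp, sp)
  expect_equal(nrow(detectDSwR(ds, co$pairs)), 1)

  # no ripple in the spindle -> no record
  rpFar <- data.frame(id = 1, peak_s = 9, start_s = 8.9, end_s = 9.1)
  coFar <- detectCooccurrence(rpFar, sp)
  expect_equal(nrow(detectDSwR(ds, coFar$pairs)), 0)
})

test_that("sequence records are invariant to a global time shift", {
  set.seed(20)
  de <- data.frame(id = 1:50, peak_s = sort(runif(50, 0, 60)))
  sp <- data.frame(id = 1:50, peak_s = sort(runif(50, 0, 60)))
  a <- detectPairs(de, sp, couplingWindows()$D_S, "D_S")
  de2 <- transform(de, peak_s = peak_s + 1234.5)
  sp2 <- transform(sp, peak_s = peak_s + 1234.5)
  b <- detectPairs(de2, sp2, couplingWindows()$D_S, "D_S")
  expect_equal(a$lead_id, b$lead_id)
  expect_equal(a$trail_id, b$trail_id)
  expect_equal(a$interval_ms, b$interval_ms, tolerance = 1e-9)
})

test_that("fractions in sequences use set membership", {
  rp <- data.frame(id = 1:10, peak_s = 1:10,
                   length_class = rep(c("SHORT", "LONG"), 5))
  none <- fractionInSequences(rp, list(D_R = data.frame()))
  expect_true(all(none$byClass$fraction_alone == 1))

  # every ripple in some record, some twice (multiplicity must not inflate)
  dr <- data.frame(sequence_type = "D_R", lead_id = 99,
                   trail_id = c(1:10, 1:5), interval_ms = 100,
                   ripple_class = NA)
  all_ <- fractionInSequences(rp, list(D_R = dr))
  expect_true(all(all_$byClass$fraction_alone == 0))
  expect_true(all(all_$byClass$fraction_in_sequence == 1))

  # random membership against a brute-force scan
  set.seed(21)
  ids <- sample(1:10, 4)
  dr2 <- data.frame(sequence_type = "D_R", lead_id = 99, trail_id = ids,
                    interval_ms = 100, ripple_class = NA)
  fr <- fractionInSequences(rp, list(D_R = dr2))
  for (cl in c("SHORT", "LONG")) {
    sel <- rp$length_class == cl
    oracle <- mean(rp$id[sel] %in% ids)
    expect_equal(fr$byClass$fraction_in_sequence[fr$byClass$length_class == cl],
                 oracle)
  }
})

test_that("slow-oscillation phase follows the peak = 0 convention", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  so <- 100 * cos(2 * pi * 1 * t)
  troughs <- seq(10.5, 50.5, by = 2)   # cos minima
  ph <- soPhaseAtEvents(so, fs, troughs)
  expect_true(all(abs(ph$phase_deg - 180) < 2))
  peaks <- seq(10, 50, by = 2)
  ph2 <- soPhaseAtEvents(so, fs, peaks)
  d <- pmin(ph2$phase_deg, 360 - ph2$phase_deg)
  expect_true(all(d < 2))
  expect_warning(soPhaseAtEvents(so, fs, c(10, 1e4)), "outside")
})

test_that("phase readout ignores components above the SO band", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  so <- 100 * cos(2 * pi * 1 * t)
  fast <- 80 * sin(2 * pi * 12 * t)
  peaks <- seq(5.1, 55.1, by = 1.7)
  p1 <- soPhaseAtEvents(so, fs, peaks)$phase_deg
  p2 <- soPhaseAtEvents(so + fast, fs, peaks)$phase_deg
  d <- abs((p2 - p1 + 180) %% 360 - 180)
  expect_true(all(d < 2))
})

test_that("Rayleigh test behaves at both extremes and has power", {
  r <- phaseLockingTest(rep(90, 50))
  expect_equal(r$R, 1)
  expect_lt(r$p, 1e-4)
  expect_equal(r$meanDirectionDeg, 90)

  u <- phaseLockingTest(seq(0, 359, by = 1)[1:360])
  expect_lt(u$R, 1e-10)
  expect_gt(u$p, 0.99)

  expect_error(phaseLockingTest(c(1, 2, 3)), "at least 5")

  # Monte-Carlo power at kappa = 2, n = 200
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    ph <- sleepLFP:::rvonmises(200, pi, 2) * 180 / pi
    phaseLockingTest(ph)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("generator phase spec round-trips through the phase reader", {
  cfg <- simConfig(120, 500,
                   stateSchedule = data.frame(state = "NREM", duration = 120),
                   phaseSpec = list(soFrequencyHz = 1, targetPhaseDeg = 90,
                                    concentration = 60, count = 60,
                                    soAmplitudeUv = 300),
                   seed = 33)
  rec <- generateRecording(cfg)
  ph <- soPhaseAtEvents(channelData(rec$bundle, "PFC"), 500,
                        rec$truth$events$peak_s)
  d <- abs((circMeanDeg(ph$phase_deg) - 90 + 180) %% 360 - 180)
  expect_lt(d, 10)
})
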