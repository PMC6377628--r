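test_that("gating models validate rates and expose stationary Po", {
  m <- gatingModel(kCO = 1, kOC = 3)
  expect_equal(openProbability(m), 0.25)
  b <- gatingModel(kCO = 2, kOC = 2, type = "burst", kC1C2 = 0.1,
                   kC2C1 = 0.05)
  po <- openProbability(b)
  expect_true(po > 0 && po < 1)
  expect_error(gatingModel(kCO = -1, kOC = 1), "> 0")
  expect_error(gatingModel(kCO = 1, kOC = 1, nChannels = 0), "nChannels")
})

test_that("simulation is seed-reproducible and respects the zero-open limit", {
  m <- gatingModel(kCO = 1, kOC = 1)
  t1 <- simulateTrace(m, voltage = -80, duration = 0.5, seed = 7)
  t2 <- simulateTrace(m, voltage = -80, duration = 0.5, seed = 7)
  expect_identical(t1@samples, t2@samples)
  expect_identical(t1@eventTimes, t2@eventTimes)
  t3 <- simulateTrace(m, voltage = -80, duration = 0.5, seed = 8)
  expect_false(identical(t1@samples, t2@samples) &&
               identical(t1@samples, t3@samples))

  # effectively zero opening rate: silent record
  m0 <- gatingModel(kCO = 1e-9, kOC = 1)
  tr0 <- simulateTrace(m0, voltage = -80, duration = 1, seed = 1)
  expect_true(all(tr0@samples == 0))
  expect_equal(channelStats(trueEvents(tr0))$NPo, 0)
  expect_error(simulateTrace(m, voltage = -80, duration = 1e-5, seed = 1),
               "10 sample intervals")
})

test_that("noiseless samples equal open count times unitary current", {
  m <- gatingModel(kCO = 1, kOC = 1, gamma = 20, vRev = 0)
  tr <- simulateTrace(m, voltage = -80, duration = 0.2, seed = 3)
  expect_equal(tr@unitaryAmplitude, 20 * (-80) / 1000)
  expect_equal(tr@samples, tr@statePath * tr@unitaryAmplitude)
})

test_that("a symmetric two-state channel spends half its time open", {
  m <- gatingModel(kCO = 1, kOC = 1)
  tr <- simulateTrace(m, voltage = -80, duration = 60, seed = 2)
  npo <- channelStats(trueEvents(tr))$NPo
  # 3 standard errors of the stationary time-average
  nCycles <- 60 / 0.002
  expect_lt(abs(npo - 0.5), 3 * 0.5 / sqrt(nCycles) * 2)
})

test_that("idealization reconstructs noiseless dwells exactly", {
  dt <- 5e-5
  samp <- c(rep(0, 60), rep(2, 40), rep(0, 100))  # 3 / 2 / 5 ms
  ev <- idealizeTrace(samp, unitaryAmplitude = 2, deadTime = 0, dt = dt)
  expect_identical(ev@levels, c(0L, 1L, 0L))
  expect_equal(ev@durations, c(0.003, 0.002, 0.005))

  # a 50 us blip is below the 100 us dead time and must vanish
  blip <- c(rep(0, 60), rep(2, 1), rep(0, 100))
  evb <- idealizeTrace(blip, unitaryAmplitude = 2, deadTime = 1e-4, dt = dt)
  expect_identical(evb@levels, 0L)
  expect_equal(sum(evb@durations), length(blip) * dt)

  # polarity mismatch is an error
  expect_error(idealizeTrace(-samp, unitaryAmplitude = 2, dt = dt),
               "polarity")
  expect_error(idealizeTrace(samp, unitaryAmplitude = 0, dt = dt), "0")
})

test_that("idealization under noise recovers NPo from the true path", {
  m <- gatingModel(kCO = 0.8, kOC = 0.4, gamma = 20, noiseSd = 0.16)
  tr <- simulateTrace(m, voltage = -100, duration = 20, seed = 5)
  ev <- idealizeTrace(tr, deadTime = 0)
  trueNPo <- mean(tr@statePath)
  est <- channelStats(ev)$NPo
  expect_lt(abs(est - trueNPo) / trueNPo, 0.05)
})

test_that("multi-level records resolve nearest-multiple levels", {
  dt <- 5e-5
  samp <- c(rep(0, 50), rep(2, 50), rep(4, 50), rep(2, 50), rep(0, 50))
  ev <- idealizeTrace(samp, unitaryAmplitude = 2, deadTime = 0, dt = dt)
  expect_identical(ev@levels, c(0L, 1L, 2L, 1L, 0L))
  st <- channelStats(ev, nChannels = 2)
  expect_equal(st$NPo, (50 * 1 + 50 * 2 + 50 * 1) / 250)
  expect_equal(st$Po_per_channel, st$NPo / 2)
})

test_that("dwell statistics follow their definitions", {
  ev <- idealizeTrace(c(rep(0, 20000), rep(1, 20000)), unitaryAmplitude = 1,
                      deadTime = 0, dt = 5e-5)
  st <- channelStats(ev)
  expect_equal(st$NPo, 0.5)
  expect_equal(st$mean_open_time_ms, 1000)
  expect_equal(st$mean_closed_time_ms, 1000)
})

test_that("dead-time filtering biases mean open time upward", {
  # bursting channel with sub-dead-time closures
  b <- gatingModel(kCO = 19.98, kOC = 0.5, type = "burst", kC1C2 = 0.05,
                   kC2C1 = 0.02, gamma = 20)
  tr <- simulateTrace(b, voltage = -80, duration = 8, seed = 9)
  ev0 <- idealizeTrace(tr, deadTime = 0)
  ev1 <- idealizeTrace(tr, deadTime = 1e-4)
  mo0 <- channelStats(ev0)$mean_open_time_ms
  mo1 <- channelStats(ev1)$mean_open_time_ms
  expect_gt(mo1, mo0)
})

test_that("unitary i-V regression recovers conductance and reversal", {
  v <- c(-80, -40, 40, 80)
  iv <- unitaryIV(v, 20 * v / 1000)
  expect_equal(iv$conductance_pS, 20)
  expect_equal(iv$reversal_mV, 0)

  set.seed(3)
  amp <- 15 * (v - 10) / 1000
  ivn <- unitaryIV(v, amp * (1 + rnorm(4, 0, 0.01)))
  expect_lt(abs(ivn$conductance_pS - 15) / 15, 0.05)

  two <- unitaryIV(c(-50, 50), c(-1, 1))
  expect_equal(two$conductance_pS, 20)
  expect_error(unitaryIV(c(10, 10), c(1, 2)), "identical")
  expect_error(unitaryIV(10, 1), ">= 2")
})

test_that("whole-cell current is linear in each factor", {
  expect_equal(wholeCellCurrent(1000, 20, 0.5, 100), 1000)
  expect_equal(wholeCellCurrent(1000, 20, 0, 100), 0)
  base <- wholeCellCurrent(500, 15, 0.3, -60, -90)
  expect_equal(wholeCellCurrent(1000, 15, 0.3, -60, -90), 2 * base)
  expect_equal(wholeCellCurrent(500, 30, 0.3, -60, -90), 2 * base)
  expect_equal(wholeCellCurrent(500, 15, 0.6, -60, -90), 2 * base)
  expect_equal(wholeCellCurrent(500, 15, 0.3, -30, -90), 2 * base)
  expect_error(wholeCellCurrent(1, 20, 1.2, 100), "\\[0, 1\\]")
  expect_equal(foldChange(0.5, 0.05), 10)
  expect_error(foldChange(0.5, 0), "may not be 0")
})

test_that("exponential activation fits recover tau", {
  tm <- seq(0, 0.5, 1e-3)
  fit <- fitActivationTau(tm, 1 - exp(-tm / 0.05))
  expect_equal(fit$tau_ms, 50, tolerance = 1e-6)
  expect_equal(fit$offset, 1, tolerance = 1e-6)
  expect_equal(fit$amplitude, -1, tolerance = 1e-6)
  expect_error(fitActivationTau(tm, rep(1, length(tm))), "no activation")
  expect_error(fitActivationTau(1:5, 1:5), ">= 10")
})
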