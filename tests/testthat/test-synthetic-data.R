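test_that("pure bolus reproduces the scaled unit-bolus response", {
  bm <- bloodModel()
  sch <- AdministrationSchedule(bolusFraction = 1, infusionDuration = 0,
                                totalActivity = 37, scanDuration = 50)
  tg <- seq(0, 50, by = 1 / 60)
  ifs <- makeInputFunctions(sch, bm, tg)
  expect_equal(plasmaParent(ifs), 37 * bloodModelParent(bm)(tg),
               tolerance = 1e-12)
  expect_equal(plasmaMetabolite(ifs), 37 * bloodModelMetabolite(bm)(tg),
               tolerance = 1e-12)
})

test_that("pure infusion of a mono-exponential tracer approaches rate/lambda", {
  lambda <- 0.5
  bm <- bloodModel(parentAmp = 1, parentRate = lambda, kMet = 0,
                   ratioIntercept = 1, ratioSlope = 0)
  sch <- AdministrationSchedule(bolusFraction = 0, infusionDuration = 50,
                                totalActivity = 100, scanDuration = 50)
  ifs <- makeInputFunctions(sch, bm)
  rate <- 100 / 50
  plateau <- rate / lambda      # closed-form ODE steady state
  late <- plasmaParent(ifs)[timeGrid(ifs) >= 20]
  expect_true(all(abs(late / plateau - 1) < 0.01))
})

test_that("bolus+infusion lowers the metabolite-fraction AUC versus pure bolus", {
  bm <- bloodModel()
  tg <- seq(0, 50, by = 1 / 60)
  bi <- makeInputFunctions(AdministrationSchedule(), bm, tg)
  bol <- makeInputFunctions(
    AdministrationSchedule(bolusFraction = 1, infusionDuration = 0,
                           totalActivity = 200, scanDuration = 50), bm, tg)
  fracBI <- 1 - parentFraction(bi)
  fracBol <- 1 - parentFraction(bol)
  expect_lt(pracma::trapz(tg, fracBI), pracma::trapz(tg, fracBol))
})

test_that("non-physical blood-model parameters are rejected", {
  expect_error(bloodModel(parentAmp = c(1, -1), parentRate = c(1, 1)),
               "non-physical")
  expect_error(bloodModel(parentRate = c(0.5, -0.1), parentAmp = c(1, 1)),
               "non-physical")
})

test_that("simulateTac reduces to the one-tissue model when k3=0, vB=0", {
  ifs <- parentOnlyInputs()
  p <- KineticParams(K1 = 0.05, k2 = 0.1, k3 = 0, vB = 0, K1m = 0, k2m = 1)
  tac <- simulateTac(p, ifs)
  oracle <- odeOracle2tc(0.05, 0.1, 0, numeric(0), ifs)
  expected <- frameAverageForTest(timeGrid(ifs), oracle,
                                  frameStart(tac), frameEnd(tac))
  expect_equal(as.numeric(activity(tac)), expected, tolerance = 2e-4)
})

test_that("zero transport gives an identically zero TAC", {
  ifs <- parentOnlyInputs()
  p <- KineticParams(K1 = 0, k2 = 0.1, k3 = 0.02, vB = 0, K1m = 0, k2m = 1)
  expect_true(all(activity(simulateTac(p, ifs)) == 0))
})

test_that("constant plasma: late trapped growth rate matches Ki * Cp", {
  cp <- 25
  ifs <- constantPlasmaInputs(cp = cp, tmax = 120)
  p <- KineticParams(K1 = 0.04, k2 = 0.07, k3 = 0.02, vB = 0,
                     K1m = 0, k2m = 1)
  tac <- simulateTac(p, ifs,
                     frames = list(start = seq(0, 119), end = seq(1, 120)))
  act <- as.numeric(activity(tac))
  lateSlope <- (act[120] - act[110]) / 10       # kBq/mL per min
  expect_equal(lateSlope, trueKi(p) * cp, tolerance = 0.02)
  ## same against the independent ODE oracle
  oracle <- odeOracle2tc(0.04, 0.07, 0.02, numeric(0), ifs)
  expect_equal(max(abs(tac@groundTruth$parentTissue -
                         frameAverageForTest(timeGrid(ifs), oracle,
                                             frameStart(tac), frameEnd(tac)))) /
                 max(oracle), 0, tolerance = 2e-4)
})

test_that("ode-mode task modulation matches the deSolve oracle", {
  ifs <- parentOnlyInputs()
  task <- TaskSchedule()
  delta <- c(0.03, 0.01, 0.02, 0.015)
  p <- KineticParams(K1 = 0.04, k2 = 0.07, k3 = 0.013, vB = 0,
                     K1m = 0, k2m = 1, taskK3Delta = delta)
  tac <- simulateTac(p, ifs, task = task, taskMode = "ode")
  oracle <- odeOracle2tc(0.04, 0.07, 0.013, delta, ifs, task)
  expected <- frameAverageForTest(timeGrid(ifs), oracle,
                                  frameStart(tac), frameEnd(tac))
  expect_equal(as.numeric(activity(tac)), expected, tolerance = 5e-4)
})

test_that("a task delta driving k3 negative is rejected", {
  ifs <- parentOnlyInputs()
  p <- KineticParams(K1 = 0.04, k2 = 0.07, k3 = 0.01, vB = 0,
                     taskK3Delta = c(-0.02, 0, 0, 0))
  expect_error(simulateTac(p, ifs, task = TaskSchedule(), taskMode = "ode"),
               "negative")
  expect_error(simulateTac(p, ifs, task = TaskSchedule(), taskMode = "uptake"),
               "negative")
})

test_that("the reference simulator refuses trapping", {
  ifs <- parentOnlyInputs()
  expect_error(simulateReferenceTac(KineticParams(K1 = 0.06, k2 = 0.05,
                                                  k3 = 0.01), ifs),
               "k3 = 0")
})

test_that("frame averaging conserves integral activity", {
  ifs <- parentOnlyInputs()
  p <- KineticParams(K1 = 0.05, k2 = 0.1, k3 = 0, vB = 0, K1m = 0, k2m = 1)
  tac <- simulateTac(p, ifs)
  fine <- odeOracle2tc(0.05, 0.1, 0, numeric(0), ifs)
  lhs <- sum(as.numeric(activity(tac)) * frameLength(tac))
  rhs <- pracma::trapz(timeGrid(ifs), fine)
  expect_equal(lhs, rhs, tolerance = 1e-5)
})

test_that("the recorded metabolite tissue component matches a convolution oracle", {
  ifs <- fixtureInputs()
  p <- KineticParams(K1 = 0.04, k2 = 0.07, k3 = 0.013, K1m = 0.06,
                     k2m = 0.05)
  tac <- simulateTac(p, ifs)
  ## direct discrete-convolution oracle on a coarser grid
  dt <- 0.05
  tg <- seq(0, 50, by = dt)
  cm <- stats::approx(timeGrid(ifs), plasmaMetabolite(ifs), tg)$y
  oracle <- vapply(seq_along(tg), function(i) {
    tau <- tg[seq_len(i)]
    pracma::trapz(tau, cm[seq_len(i)] * 0.06 * exp(-0.05 * (tg[i] - tau)))
  }, numeric(1))
  expected <- frameAverageForTest(tg, oracle, frameStart(tac), frameEnd(tac))
  relRms <- sqrt(mean((tac@groundTruth$omfdTissue - expected)^2)) /
    max(expected)
  expect_lt(relRms, 0.005)
})

test_that("identical seeds reproduce TACs and trial logs bit for bit", {
  ifs <- fixtureInputs()
  p <- KineticParams(K1 = 0.04, k2 = 0.07, k3 = 0.013)
  t1 <- simulateTac(p, ifs, noiseSd = 0.5, seed = 42L)
  t2 <- simulateTac(p, ifs, noiseSd = 0.5, seed = 42L)
  expect_identical(activity(t1), activity(t2))
  l1 <- simulateMidSession(seed = 7L)
  l2 <- simulateMidSession(seed = 7L)
  expect_identical(l1, l2)
})

test_that("the staircase holds the hit rate near one half", {
  log <- simulateMidSession(nBlocks = 2, trialsPerBlock = 120,
                            manipulationBias = 0, seed = 11L)
  expect_gte(mean(log$hit), 0.40)
  expect_lte(mean(log$hit), 0.60)
})

test_that("deterministic RTs at the limit with zero step give identical outcomes", {
  log <- simulateMidSession(rtFun = function(a) 500, rtSd = 0,
                            initialLimit = 500, staircaseStep = 0,
                            manipulationBias = 0, seed = 1L)
  expect_true(all(log$hit))
})

test_that("strong positive gain-block bias yields net gain in every session", {
  for (seed in 1:5) {
    log <- simulateMidSession(nBlocks = 2, trialsPerBlock = 24,
                              conditions = c("gain", "loss"),
                              manipulationBias = 400, seed = seed)
    gain <- accumulatedBalance(log, by = "condition")[["gain"]]
    loss <- accumulatedBalance(log, by = "condition")[["loss"]]
    expect_gt(gain, 0)
    expect_lt(loss, 0)
  }
})

test_that("trial-log invariants hold: hit iff rt <= limit, balance rules", {
  log <- simulateMidSession(seed = 3L)
  expect_identical(log$hit, log$reaction_time <= log$time_limit)
  gains <- log$amount > 0
  expect_true(all(log$balance_delta[gains & log$hit] == log$amount[gains & log$hit]))
  expect_true(all(log$balance_delta[gains & !log$hit] == 0))
  expect_true(all(log$balance_delta[!gains & log$hit] == 0))
  expect_true(all(log$balance_delta[!gains & !log$hit] == log$amount[!gains & !log$hit]))
})
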