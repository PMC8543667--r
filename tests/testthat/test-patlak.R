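test_that("an exact line is recovered to machine precision", {
  xy <- data.frame(x = seq(5, 50, by = 1), y = 0.01 * seq(5, 50, by = 1) + 0.2,
                   frameMid = seq(5, 50, by = 1))
  fit <- fitKi(xy, tStar = 25)
  expect_equal(fit@Ki, 0.01, tolerance = 1e-12)
  expect_equal(fit@intercept, 0.2, tolerance = 1e-12)
  expect_equal(fit@r2, 1, tolerance = 1e-12)
})

test_that("the transform reduces to closed forms under constant plasma", {
  cp <- 20
  ifs <- constantPlasmaInputs(cp = cp)
  mid <- seq(0.5, 49.5)
  ct <- 0.012 * cp * mid
  xy <- patlakTransform(ct, ifs, frameMid = mid)
  expect_equal(xy$x, mid, tolerance = 1e-9)
  expect_equal(xy$y, 0.012 * mid, tolerance = 1e-9)
  expect_equal(fitKi(xy)@Ki, 0.012, tolerance = 1e-9)
  zero <- patlakTransform(rep(0, 50), ifs, frameMid = mid)
  expect_true(all(zero$y == 0))
  expect_equal(fitKi(zero)@Ki, 0, tolerance = 1e-12)
})

test_that("Patlak slope matches K1*k3/(k2+k3) in the constant-plasma limit", {
  ## asymptotic window of a long acquisition so the free compartment has
  ## fully equilibrated
  ifs <- constantPlasmaInputs(cp = 25, tmax = 300, dt = 0.02)
  p <- KineticParams(K1 = 0.04, k2 = 0.07, k3 = 0.02, vB = 0, K1m = 0,
                     k2m = 1)
  frames <- list(start = seq(0, 299), end = seq(1, 300))
  tac <- simulateTac(p, ifs, frames = frames)
  fit <- fitKi(patlakTransform(tac, ifs), tStar = 150)
  expect_equal(fit@Ki, trueKi(p), tolerance = 0.01)
})

test_that("frame-averaged 50-min acquisitions stay within the discretisation bound", {
  ifs <- fixtureInputs()
  for (ki in c(0.009, 0.012)) {
    p <- KineticParams(K1 = 0.04, k2 = 0.07, k3 = k3ForKi(0.04, 0.07, ki),
                       vB = 0, K1m = 0, k2m = 1)
    tac <- simulateTac(p, ifs)
    fit <- fitKi(patlakTransform(tac, ifs), tStar = 25)
    expect_equal(fit@Ki, ki, tolerance = 0.02)
  }
})

test_that("a reversible tracer gives near-zero slope and intercept K1/k2", {
  ## fast-exchange 1TC tissue fully equilibrated over the fit window
  ifs <- constantPlasmaInputs(cp = 25, tmax = 120)
  p <- KineticParams(K1 = 0.06, k2 = 0.3, k3 = 0, vB = 0, K1m = 0, k2m = 1)
  frames <- list(start = seq(0, 119), end = seq(1, 120))
  tac <- simulateTac(p, ifs, frames = frames)
  fit <- fitKi(patlakTransform(tac, ifs), tStar = 60)
  expect_lt(abs(fit@Ki), 1e-6 * 0.06)
  expect_equal(fit@intercept, 0.06 / 0.3, tolerance = 0.01)
})

test_that("non-positive plasma in the window is refused", {
  tg <- seq(0, 50, by = 0.1)
  ifs <- InputFunctionSet(timeGrid = tg, wholeBlood = rep(1, length(tg)),
                          plasmaParent = rep(0, length(tg)),
                          plasmaMetabolite = rep(0, length(tg)))
  expect_error(patlakTransform(rep(1, 50), ifs, frameMid = seq(0.5, 49.5)),
               "positive")
})

test_that("fewer than three late frames is an error", {
  xy <- data.frame(x = 1:5, y = 1:5, frameMid = c(1, 2, 3, 26, 30))
  expect_error(fitKi(xy, tStar = 25), "fewer than 3")
})

test_that("zero task betas give zero task Ki and scaling cancels", {
  cfg <- fpetConfig(seed = 1L)
  ses <- fixtureSession("default", cfg)
  res <- runQuantification(cfg, ses$tacs, ses$bloodSamples, ses$motion,
                           ses$trialLog)
  gf <- res$glmFits$striatum
  gf0 <- GlmFit(design = gf@design,
                beta = replace(coef(gf), 1:4, 0),
                components = sweep(designMatrix(gf), 2,
                                   replace(coef(gf), 1:4, 0), "*"),
                residuals = gf@response -
                  as.numeric(designMatrix(gf) %*% replace(coef(gf), 1:4, 0)),
                sigma2 = gf@sigma2, response = gf@response)
  expect_true(all(taskKi(gf0, res$inputs, cfg@task) == 0))
  ## joint rescaling of plasma and TAC leaves task Ki unchanged
  ifs2 <- InputFunctionSet(timeGrid = timeGrid(res$inputs),
                           wholeBlood = 2 * wholeBlood(res$inputs),
                           plasmaParent = 2 * plasmaParent(res$inputs),
                           plasmaMetabolite = 2 * plasmaMetabolite(res$inputs))
  gf2 <- GlmFit(design = gf@design, beta = 2 * coef(gf),
                components = 2 * fittedComponents(gf),
                residuals = 2 * gf@residuals, sigma2 = 4 * gf@sigma2,
                response = 2 * gf@response)
  expect_equal(taskKi(gf2, ifs2, cfg@task),
               taskKi(gf, res$inputs, cfg@task), tolerance = 1e-12)
})

test_that("noise-free per-block task Ki is recovered within 2%", {
  cfg <- fpetConfig(seed = 1L)
  ses <- fixtureSession("default", cfg)
  res <- runQuantification(cfg, ses$tacs, ses$bloodSamples, ses$motion,
                           ses$trialLog)
  tki <- taskKi(res$glmFits$striatum, res$inputs, cfg@task)
  truth <- ses$truth$striatum$dKi
  expect_equal(unname(tki), truth, tolerance = 0.02)
})

test_that("beta-conversion and Patlak-difference task Ki agree within 2%", {
  cfg <- fpetConfig(seed = 1L)
  ses <- fixtureSession("default", cfg)
  res <- runQuantification(cfg, ses$tacs, ses$bloodSamples, ses$motion,
                           ses$trialLog)
  a <- taskKi(res$glmFits$striatum, res$inputs, cfg@task)
  b <- patlakDiffTaskKi(res$glmFits$striatum, res$inputs, cfg@task,
                        tStar = cfg@tStar)
  expect_equal(unname(b), unname(a), tolerance = 0.02)
})

test_that("recovered block Ki increases with the generative task delta", {
  cfg <- fpetConfig(seed = 1L)
  deltas <- c(0.004, 0.009, 0.014, 0.019)
  scene <- kineticScene(baselineKi = 0.010, taskDeltaKi = deltas)
  ses <- simulateSession(cfg, scene)
  res <- runQuantification(cfg, ses$tacs, ses$bloodSamples, ses$motion,
                           ses$trialLog)
  tki <- unname(taskKi(res$glmFits$striatum, res$inputs, cfg@task))
  expect_true(all(diff(tki) > 0))
})

test_that("weighted averaging follows the performance-weight rule", {
  ck <- weightAndAverage(c(0.010, 0.016), c("gain", "gain"), 0.009,
                         weights = c(0.8, 0.4))
  expect_equal(unname(ck@KiCondition["gain"]), 0.012, tolerance = 1e-12)
  expect_equal(unname(ck@KiConditionUnweighted["gain"]), 0.013,
               tolerance = 1e-12)
  eq <- weightAndAverage(c(0.010, 0.016), c("gain", "gain"), 0.009,
                         weights = c(0.5, 0.5))
  expect_equal(unname(eq@KiCondition["gain"]), 0.013, tolerance = 1e-12)
  first <- weightAndAverage(c(0.010, 0.016), c("gain", "gain"), 0.009,
                            weights = c(1, 0))
  expect_equal(unname(first@KiCondition["gain"]), 0.010, tolerance = 1e-12)
  expect_error(weightAndAverage(c(0.01, 0.02), c("gain", "gain"), 0.009,
                                weights = c(0, 0)), "all-zero")
})

test_that("percent signal change follows Ki_task/Ki_baseline x 100", {
  expect_equal(percentSignalChange(0.009, 0.009), 100)
  expect_equal(percentSignalChange(0, 0.009), 0)
  expect_equal(percentSignalChange(0.014, 0.009), 1400 / 9)
  expect_equal(round(percentSignalChange(0.014, 0.009), 1), 155.6)
  expect_error(percentSignalChange(0.01, 0), "positive")
})
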