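test_that("the low-pass filter has unit DC gain", {
  x <- rep(7.3, 50)
  expect_equal(lowpassFilter(x, frameLengthMin = 1), x, tolerance = 1e-12)
})

test_that("filter attenuation matches the frequency-response oracle", {
  fl <- 0.25                          # fine frames so a 1-min wave is sampled
  tt <- seq(fl / 2, 50, by = fl)
  measureGain <- function(period) {
    x <- sin(2 * pi * tt / period)
    y <- lowpassFilter(x, cutoffPeriod = 2.5, frameLengthMin = fl)
    ## amplitude via projection on the sinusoid pair, central frames only
    ## (mirror-extension edge transients excluded)
    sel <- tt > 5 & tt < 45
    fit <- lm(y[sel] ~ sin(2 * pi * tt[sel] / period) +
                cos(2 * pi * tt[sel] / period))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  expect_lt(measureGain(1), 0.10)     # 1-min period: >= 90% attenuation
  expect_gt(measureGain(10), 0.95)    # 10-min period: preserved within 5%
  expect_lt(measureGain(10), 1.05)
})

test_that("non-uniform frames cannot be filtered", {
  tac <- TimeActivityCurve(frameStart = c(0, 1, 3), frameEnd = c(1, 3, 6),
                           activity = matrix(1:3, ncol = 1))
  expect_error(lowpassFilter(tac), "uniform")
})

test_that("the baseline regressor is the mean of non-excluded series", {
  act <- cbind(a = 1:5, b = 1:5, c = 1:5)
  tac <- TimeActivityCurve(frameStart = 0:4, frameEnd = 1:5, activity = act)
  expect_equal(buildBaselineRegressor(tac), as.numeric(1:5))
  act2 <- cbind(a = 1:5, b = 11:15)
  tac2 <- TimeActivityCurve(frameStart = 0:4, frameEnd = 1:5, activity = act2)
  expect_equal(buildBaselineRegressor(tac2, exclude = "a"),
               as.numeric(11:15))
  expect_error(buildBaselineRegressor(tac2, exclude = c("a", "b")),
               "no gray-matter series")
  set.seed(1)
  act3 <- matrix(rnorm(50 * 6), 50, 6,
                 dimnames = list(NULL, paste0("g", 1:6)))
  tac3 <- TimeActivityCurve(frameStart = 0:49, frameEnd = 1:50,
                            activity = act3)
  expect_equal(buildBaselineRegressor(tac3, exclude = "g6"),
               rowMeans(act3[, 1:5]))
})

test_that("the motion regressor is PC1 with the documented sign convention", {
  set.seed(2)
  base <- cumsum(rnorm(40))
  m <- matrix(rep(base, 6), ncol = 6)
  s <- motionRegressor(m)
  expect_equal(abs(cor(s, base)), 1, tolerance = 1e-12)
  expect_gt(cor(s, base), 0)          # positive with largest-variance column
  ## eigen-decomposition oracle on independent noise columns
  m2 <- matrix(rnorm(200 * 6), 200, 6)
  s2 <- motionRegressor(m2)
  ev <- eigen(cov(m2))
  oracle <- as.numeric(scale(m2, scale = FALSE) %*% ev$vectors[, 1])
  expect_equal(abs(cor(s2, oracle)), 1, tolerance = 1e-12)
  expect_equal(var(s2), ev$values[1], tolerance = 1e-9)
  expect_warning(z <- motionRegressor(matrix(1, 10, 6)), "constant motion")
  expect_true(all(z == 0))
})

test_that("task ramps have unit slope inside blocks and hold after", {
  frames <- list(start = 0:49, end = 1:50)
  d <- buildGlmDesign(frames, TaskSchedule(), baseline = rep(1, 50))
  X <- designMatrix(d)
  r <- X[, "task2"]                   # block 2: 20-25 min
  mids <- 0:49 + 0.5
  expect_true(all(r[mids < 20] == 0))
  inb <- mids > 20 & mids < 25
  expect_equal(unname(diff(r[inb])), rep(1, sum(inb) - 1))
  expect_true(all(r[mids > 25] == max(r)))
})

test_that("GLM recovers exact coefficients for in-span signals", {
  frames <- list(start = 0:49, end = 1:50)
  base <- 10 + 0.4 * (0:49) - 0.002 * (0:49)^2
  set.seed(3)
  motion <- cumsum(rnorm(50, 0, 0.1))
  d <- buildGlmDesign(frames, TaskSchedule(), base, motion)
  y1 <- fitGlm(base, d)
  expect_equal(unname(coef(y1)), c(0, 0, 0, 0, 1, 0), tolerance = 1e-10)
  y2 <- fitGlm(base + 0.5 * designMatrix(d)[, "task2"], d)
  expect_equal(unname(coef(y2)["task2"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(coef(y2)["baseline"]), 1, tolerance = 1e-10)
})

test_that("OLS equals the normal-equation oracle", {
  frames <- list(start = 0:49, end = 1:50)
  base <- 10 + 0.4 * (0:49)
  set.seed(4)
  motion <- rnorm(50)
  d <- buildGlmDesign(frames, TaskSchedule(), base, motion)
  y <- base + rnorm(50)
  X <- designMatrix(d)
  oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(coef(fitGlm(y, d))), as.numeric(oracle),
               tolerance = 1e-10)
})

test_that("consistently permuting frames leaves the betas unchanged", {
  frames <- list(start = 0:49, end = 1:50)
  base <- 10 + 0.4 * (0:49)
  set.seed(5)
  motion <- rnorm(50)
  d <- buildGlmDesign(frames, TaskSchedule(), base, motion)
  y <- base + 0.3 * designMatrix(d)[, "task1"] + rnorm(50, 0, 0.1)
  b1 <- coef(fitGlm(y, d))
  perm <- sample(50)
  d2 <- GlmDesign(design = designMatrix(d)[perm, ],
                  frameStart = frames$start, frameEnd = frames$end,
                  taskColumns = d@taskColumns, blockMap = d@blockMap,
                  conditionNumber = d@conditionNumber)
  b2 <- coef(fitGlm(y[perm], d2))
  expect_equal(b2, b1, tolerance = 1e-10)
})

test_that("adding baseline multiples to the motion column leaves task and motion betas unchanged", {
  frames <- list(start = 0:49, end = 1:50)
  base <- 10 + 0.4 * (0:49)
  set.seed(6)
  motion <- rnorm(50)
  d <- buildGlmDesign(frames, TaskSchedule(), base, motion)
  y <- base + 0.3 * designMatrix(d)[, "task3"] + 0.2 * motion +
    rnorm(50, 0, 0.1)
  b1 <- coef(fitGlm(y, d))
  d2 <- buildGlmDesign(frames, TaskSchedule(), base, motion + 2.5 * base)
  b2 <- coef(fitGlm(y, d2))
  keep <- c("task1", "task2", "task3", "task4", "motion")
  expect_equal(b2[keep], b1[keep], tolerance = 1e-8)
})

test_that("rank-deficient designs are refused", {
  frames <- list(start = 0:49, end = 1:50)
  base <- rep(1, 50)
  d <- buildGlmDesign(frames, TaskSchedule(), base, motion = rep(2, 50))
  expect_error(fitGlm(rnorm(50), d), "rank-deficient")
})

test_that("block betas carry the sign of the generative task modulation", {
  cfg <- fpetConfig(seed = 1L)
  scene <- kineticScene(baselineKi = 0.010,
                        taskDeltaKi = c(0.014, -0.004, 0.009, -0.002))
  ses <- simulateSession(cfg, scene)
  res <- runQuantification(cfg, ses$tacs, ses$bloodSamples, ses$motion,
                           ses$trialLog)
  betas <- coef(res$glmFits$striatum)[1:4]
  expect_identical(sign(unname(betas)), c(1, -1, 1, -1))
})

test_that("filtering both sides leaves in-span coefficients unchanged", {
  frames <- list(start = 0:49, end = 1:50)
  base <- 10 + 0.4 * (0:49)
  d <- buildGlmDesign(frames, TaskSchedule(), base, motion = NULL)
  y <- base + 0.25 * designMatrix(d)[, "task2"]
  bRaw <- coef(fitGlm(y, d))
  bFil <- coef(fitGlm(y, d, filter = 2.5))
  expect_equal(bFil, bRaw, tolerance = 1e-9)
})
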