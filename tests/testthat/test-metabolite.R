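test_that("the one-tissue fit recovers generator truth within 1%", {
  ifs <- parentOnlyInputs()
  ref <- simulateReferenceTac(KineticParams(K1 = 0.06, k2 = 0.05, k3 = 0,
                                            vB = 0.05, K1m = 0, k2m = 1),
                              ifs)
  fit <- fitReference1TC(ref, ifs, input = "parent", vB = 0.05)
  expect_true(fit@converged)
  expect_equal(fit@K1ref, 0.06, tolerance = 0.01)
  expect_equal(fit@k2ref, 0.05, tolerance = 0.01)
  expect_lt(fit@residRms, 1e-3)
})

test_that("a zero driving input is rejected as degenerate", {
  ifs <- parentOnlyInputs()
  ref <- simulateReferenceTac(KineticParams(K1 = 0.06, k2 = 0.05, k3 = 0,
                                            K1m = 0, k2m = 1), ifs)
  zero <- InputFunctionSet(timeGrid = timeGrid(ifs),
                           wholeBlood = wholeBlood(ifs),
                           plasmaParent = rep(0, length(timeGrid(ifs))),
                           plasmaMetabolite = rep(0, length(timeGrid(ifs))))
  expect_error(fitReference1TC(ref, zero, input = "parent"), "degenerate")
})

test_that("jointly doubling input and TAC leaves the fit unchanged", {
  ifs <- parentOnlyInputs()
  p <- KineticParams(K1 = 0.06, k2 = 0.05, k3 = 0, vB = 0.05, K1m = 0,
                     k2m = 1)
  ref <- simulateReferenceTac(p, ifs)
  fit1 <- fitReference1TC(ref, ifs, input = "parent")
  ifs2 <- InputFunctionSet(timeGrid = timeGrid(ifs),
                           wholeBlood = 2 * wholeBlood(ifs),
                           plasmaParent = 2 * plasmaParent(ifs),
                           plasmaMetabolite = 2 * plasmaMetabolite(ifs))
  ref2 <- TimeActivityCurve(frameStart = frameStart(ref),
                            frameEnd = frameEnd(ref),
                            activity = 2 * activity(ref))
  fit2 <- fitReference1TC(ref2, ifs2, input = "parent")
  expect_equal(fit2@K1ref, fit1@K1ref, tolerance = 1e-4)
  expect_equal(fit2@k2ref, fit1@k2ref, tolerance = 1e-4)
})

test_that("metabolite tissue curve reduces to closed forms", {
  n <- 3001
  tg <- seq(0, 50, length.out = n)
  mkIfs <- function(cm) InputFunctionSet(timeGrid = tg,
                                         wholeBlood = rep(1, n),
                                         plasmaParent = rep(1, n),
                                         plasmaMetabolite = cm)
  fit <- OneTissueFit(K1ref = 0.06, k2ref = 0.3, residRms = 0,
                      converged = TRUE)
  frames <- list(start = 0:49, end = 1:50)
  zero <- estimateOmfdTissue(fit, mkIfs(rep(0, n)), frames)
  expect_true(all(activity(zero) == 0))
  const <- estimateOmfdTissue(fit, mkIfs(rep(4, n)), frames)
  ## approaches c*K1/k2 once equilibrated (k2=0.3 -> by 25 min)
  plateau <- 4 * 0.06 / 0.3
  late <- as.numeric(activity(const))[30:50]
  expect_true(all(abs(late / plateau - 1) < 0.001))
})

test_that("an unconverged fit cannot be used for the metabolite estimate", {
  fit <- OneTissueFit(K1ref = 0.06, k2ref = 0.05, residRms = 0,
                      converged = FALSE)
  expect_error(estimateOmfdTissue(fit, fixtureInputs(),
                                  list(start = 0:49, end = 1:50)),
               "converge")
})

test_that("correction is the identity for a zero metabolite curve", {
  ses <- fixtureSession("default", fpetConfig(seed = 1L))
  frames <- list(start = frameStart(ses$tacs), end = frameEnd(ses$tacs))
  zeroOmfd <- TimeActivityCurve(frameStart = frames$start,
                                frameEnd = frames$end,
                                activity = matrix(0, 50, 1,
                                                  dimnames = list(NULL, "omfd")))
  out <- correctTacs(ses$tacs, zeroOmfd, vB = 0.05)
  expect_equal(activity(out), activity(ses$tacs), tolerance = 1e-15)
})

test_that("a TAC equal to the scaled metabolite curve corrects to zero", {
  frames <- list(start = 0:49, end = 1:50)
  om <- matrix(seq(0, 4.9, by = 0.1), ncol = 1,
               dimnames = list(NULL, "omfd"))
  omfd <- TimeActivityCurve(frameStart = frames$start, frameEnd = frames$end,
                            activity = om)
  tac <- TimeActivityCurve(frameStart = frames$start, frameEnd = frames$end,
                           activity = 0.95 * om)
  out <- correctTacs(tac, omfd, vB = 0.05)
  expect_equal(max(abs(activity(out))), 0, tolerance = 1e-12)
})

test_that("correction is linear in the (TAC, metabolite) pair", {
  frames <- list(start = 0:49, end = 1:50)
  mk <- function(x) TimeActivityCurve(frameStart = frames$start,
                                      frameEnd = frames$end,
                                      activity = matrix(x, ncol = 1,
                                                        dimnames = list(NULL, "r")))
  a1 <- seq(1, 50); a2 <- sqrt(seq(1, 50)); o1 <- seq(0, 4.9, by = 0.1)
  o2 <- rep(1, 50)
  mkO <- function(x) TimeActivityCurve(frameStart = frames$start,
                                       frameEnd = frames$end,
                                       activity = matrix(x, ncol = 1,
                                                         dimnames = list(NULL, "omfd")))
  lhs <- activity(correctTacs(mk(a1 + a2), mkO(o1 + o2), vB = 0.05))
  rhs <- activity(correctTacs(mk(a1), mkO(o1), vB = 0.05)) +
    activity(correctTacs(mk(a2), mkO(o2), vB = 0.05))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("mismatched frame schedules are refused", {
  frames <- list(start = 0:49, end = 1:50)
  omfd <- TimeActivityCurve(frameStart = frames$start + 0.5,
                            frameEnd = frames$end + 0.5,
                            activity = matrix(0, 50, 1,
                                              dimnames = list(NULL, "omfd")))
  tac <- TimeActivityCurve(frameStart = frames$start, frameEnd = frames$end,
                           activity = matrix(1, 50, 1))
  expect_error(correctTacs(tac, omfd), "frame schedule")
})

## full-chain round trip under the assumption-satisfying scene
refFitForSession <- function(ses, cfg) {
  mid <- frameMid(ses$tacs)
  ramps <- vapply(seq_len(nBlocks(cfg@task)), function(j)
    fpetdopa:::rampRegressor(mid, cfg@task@blockOnsets[j],
                             blockEnd(cfg@task)[j]),
    numeric(length(mid)))
  nuis <- cbind(ramps, motionRegressor(ses$motion))
  fitReference1TC(ses$tacs[cfg@referenceRegion], ses$inputs,
                  input = "total", vB = cfg@vB, nuisance = nuis)
}

test_that("the estimated metabolite TAC matches the generator within 2% RMS", {
  cfg <- fpetConfig(seed = 1L)
  ses <- fixtureSession("default", cfg)
  fit <- refFitForSession(ses, cfg)
  omfd <- estimateOmfdTissue(fit, ses$inputs, ses$tacs)
  truth <- ses$truth$striatum$omfdTissue
  relRms <- sqrt(mean((as.numeric(activity(omfd)) - truth)^2)) / max(truth)
  expect_lt(relRms, 0.02)
})

test_that("corrected target TACs recover the pure parent signal within 2% RMS", {
  cfg <- fpetConfig(seed = 1L)
  ses <- fixtureSession("default", cfg)
  fit <- refFitForSession(ses, cfg)
  omfd <- estimateOmfdTissue(fit, ses$inputs, ses$tacs)
  corrected <- removeBloodComponent(correctTacs(ses$tacs, omfd, cfg@vB),
                                    ses$inputs, cfg@vB)
  got <- as.numeric(activity(corrected["striatum"]))
  truth <- ses$truth$striatum$parentTissue
  relRms <- sqrt(mean((got - truth)^2)) / max(truth)
  expect_lt(relRms, 0.02)
})

test_that("violating the uniform-DV assumption degrades recovery monotonically", {
  cfg <- fpetConfig(seed = 1L)
  errs <- vapply(c(1, 1.3, 1.6), function(viol) {
    scene <- kineticScene()
    ## inflate the metabolite transport of the target region only
    scene$striatum@K1m <- scene$striatum@K1m * viol
    ses <- simulateSession(cfg, scene)
    fit <- refFitForSession(ses, cfg)
    omfd <- estimateOmfdTissue(fit, ses$inputs, ses$tacs)
    corrected <- removeBloodComponent(correctTacs(ses$tacs, omfd, cfg@vB),
                                      ses$inputs, cfg@vB)
    got <- as.numeric(activity(corrected["striatum"]))
    truth <- ses$truth$striatum$parentTissue
    sqrt(mean((got - truth)^2)) / max(truth)
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})
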