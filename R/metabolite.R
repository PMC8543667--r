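#' @include blood.R
NULL

## model prediction for the reference fit: frame-averaged
## (1-vB) * [K1 exp(-k2 t) (x) input] + vB * whole blood
ref1tcModel <- function(K1, k2, input, grid, frames, vB, wbFrames) {
  tis <- conv1tc(K1, k2, input, gridStep(grid))
  (1 - vB) * frameAverage(grid, tis, frames$start, frames$end) + vB * wbFrames
}

#' Fit a one-tissue compartment model to the reference-region TAC
#'
#' Nonlinear least squares of \eqn{(1-v_B)[K_1 e^{-k_2 t} \otimes C_{in}] +
#' v_B C_{WB}} against the frame-averaged reference TAC, with multi-start
#' initialisation over a log-uniform parameter box. Task and motion
#' contamination of the reference TAC can be removed jointly with the fit by
#' supplying nuisance regressors: for each candidate (K1, k2) the nuisance
#' coefficients are profiled out by ordinary least squares, so the reported
#' kinetic parameters are adjusted for task effects and movement in one
#' step.
#'
#' @param refTac A single-region \linkS4class{TimeActivityCurve}.
#' @param inputs An \linkS4class{InputFunctionSet}.
#' @param input Which plasma curve drives the model: \code{"total"}
#'   (default; under the equal-distribution-volume assumption the reference
#'   tissue responds to parent + metabolite with a common impulse response)
#'   or \code{"parent"}.
#' @param vB Fixed whole-blood volume fraction (default 0.05).
#' @param nuisance Optional matrix (frames x k) of nuisance regressors
#'   (task ramps, motion) estimated jointly with the fit.
#' @param nStarts Number of multi-start initialisations (deterministic
#'   log-spaced lattice over [0.005, 0.3]^2).
#' @param relTol Relative convergence tolerance of the optimiser.
#' @return A \linkS4class{OneTissueFit}.
#' @examples
#' ifs <- makeInputFunctions()
#' ref <- simulateReferenceTac(KineticParams(K1 = 0.06, k2 = 0.05, k3 = 0), ifs)
#' fitReference1TC(ref, ifs)
#' @export
fitReference1TC <- function(refTac, inputs, input = c("total", "parent"),
                            vB = 0.05, nuisance = NULL, nStarts = 10,
                            relTol = 1e-8) {
  input <- match.arg(input)
  stopIfNot(ncol(activity(refTac)) == 1,
            "refTac must contain exactly one region")
  grid <- timeGrid(inputs)
  drive <- switch(input, total = plasmaParent(inputs) + plasmaMetabolite(inputs),
                  parent = plasmaParent(inputs))
  if (max(drive) <= 0)
    stop("degenerate input: the driving plasma curve is identically zero")
  frames <- list(start = frameStart(refTac), end = frameEnd(refTac))
  wbFrames <- frameAverage(grid, wholeBlood(inputs), frames$start, frames$end)
  y <- as.numeric(activity(refTac))
  qrN <- if (!is.null(nuisance)) {
    stopIfNot(nrow(nuisance) == length(y),
              "nuisance must have one row per frame")
    qr(nuisance)
  } else NULL
  residFun <- function(par) {
    mod <- ref1tcModel(exp(par[1]), exp(par[2]), drive, grid, frames, vB,
                       wbFrames)
    r <- y - mod
    if (!is.null(qrN)) r <- qr.resid(qrN, r)
    r
  }
  ## deterministic multi-start lattice, log-spaced
  box <- exp(seq(log(0.005), log(0.3), length.out = max(2, ceiling(sqrt(nStarts)))))
  starts <- as.matrix(expand.grid(K1 = box, k2 = box))
  starts <- starts[seq_len(min(nrow(starts), max(nStarts, 1))), , drop = FALSE]
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = log(as.numeric(starts[s, ])), fn = residFun,
      control = minpack.lm::nls.lm.control(ftol = relTol, ptol = relTol,
                                           maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("reference one-tissue fit failed to converge from any start")
  K1 <- exp(best$par[1]); k2 <- exp(best$par[2])
  if (!is.finite(K1) || !is.finite(k2) || K1 <= 0 || k2 <= 0)
    stop("reference one-tissue fit returned non-positive parameters")
  r <- residFun(best$par)
  dof <- max(1, length(r) - 2 - if (is.null(qrN)) 0 else ncol(nuisance))
  ## delta-method covariance on the natural scale
  covLog <- tryCatch(solve(crossprod(jacLog(residFun, best$par))) *
                       sum(r^2) / dof,
                     error = function(e) matrix(NA_real_, 2, 2))
  J <- diag(c(K1, k2))
  nb <- if (!is.null(qrN))
    as.numeric(qr.coef(qrN, y - ref1tcModel(K1, k2, drive, grid, frames, vB,
                                            wbFrames)))
  else numeric(0)
  OneTissueFit(K1ref = K1, k2ref = k2, residRms = sqrt(mean(r^2)),
               cov = J %*% covLog %*% J,
               converged = best$info %in% 1:4, nuisanceBeta = nb)
}

## forward-difference jacobian of a residual function at log-scale par
jacLog <- function(fn, par, h = 1e-6) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - r0) / h
  }
  J
}

#' Estimate the 3-OMFD brain signal from the reference fit
#'
#' Convolves the metabolite arterial input function with the impulse
#' response \eqn{K_1^{ref} e^{-k_2^{ref} t}} fitted on the reference region
#' and frame-averages the result to a frame schedule. This rests on the
#' assumption that the 3-OMFD distribution volume is uniform across the
#' brain and equals that of the parent in the reference region.
#'
#' @param fit A converged \linkS4class{OneTissueFit}.
#' @param inputs An \linkS4class{InputFunctionSet}.
#' @param frames Frame schedule (list/data frame with \code{start},
#'   \code{end} in minutes) or a \linkS4class{TimeActivityCurve} to copy it
#'   from.
#' @return A single-region \linkS4class{TimeActivityCurve} named
#'   \code{"omfd"} (tissue concentration, kBq/mL; no blood component).
#' @export
estimateOmfdTissue <- function(fit, inputs, frames) {
  stopIfNot(fit@converged, "the reference fit did not converge")
  if (is(frames, "TimeActivityCurve"))
    frames <- list(start = frameStart(frames), end = frameEnd(frames))
  grid <- timeGrid(inputs)
  tis <- conv1tc(fit@K1ref, fit@k2ref, plasmaMetabolite(inputs),
                 gridStep(grid))
  act <- frameAverage(grid, tis, frames$start, frames$end)
  TimeActivityCurve(frameStart = frames$start, frameEnd = frames$end,
                    activity = matrix(act, ncol = 1,
                                      dimnames = list(NULL, "omfd")))
}

#' Subtract the 3-OMFD component from brain TACs
#'
#' Subtracts \eqn{(1-v_B)} times the estimated metabolite tissue curve from
#' every region. Negative residual values are permitted; their fraction is
#' attached as a QC attribute.
#'
#' @param tacs A \linkS4class{TimeActivityCurve} (any number of regions).
#' @param omfdTac The metabolite tissue TAC from
#'   \code{\link{estimateOmfdTissue}} (same frame schedule).
#' @param vB Whole-blood volume fraction.
#' @return A \linkS4class{TimeActivityCurve}; attribute
#'   \code{"negativeFraction"} holds the fraction of negative corrected
#'   values.
#' @export
correctTacs <- function(tacs, omfdTac, vB = 0.05) {
  stopIfNot(length(frameStart(tacs)) == length(frameStart(omfdTac)) &&
              max(abs(frameStart(tacs) - frameStart(omfdTac))) < 1e-9 &&
              max(abs(frameEnd(tacs) - frameEnd(omfdTac))) < 1e-9,
            "TACs and metabolite TAC must share the frame schedule")
  corrected <- activity(tacs) - (1 - vB) * as.numeric(activity(omfdTac))
  out <- TimeActivityCurve(frameStart = frameStart(tacs),
                           frameEnd = frameEnd(tacs), activity = corrected,
                           groundTruth = tacs@groundTruth)
  attr(out, "negativeFraction") <- mean(corrected < 0)
  out
}

#' Remove the fixed whole-blood component from measured TACs
#'
#' Converts measured curves \eqn{(1-v_B) C_{tissue} + v_B C_{WB}} to tissue
#' concentration by subtracting the frame-averaged whole-blood contribution
#' and dividing by \eqn{1-v_B}.
#'
#' @param tacs A \linkS4class{TimeActivityCurve}.
#' @param inputs An \linkS4class{InputFunctionSet} supplying the whole-blood
#'   curve.
#' @param vB Whole-blood volume fraction.
#' @return A \linkS4class{TimeActivityCurve} of tissue concentration.
#' @export
removeBloodComponent <- function(tacs, inputs, vB = 0.05) {
  wbF <- frameAverage(timeGrid(inputs), wholeBlood(inputs),
                      frameStart(tacs), frameEnd(tacs))
  TimeActivityCurve(frameStart = frameStart(tacs), frameEnd = frameEnd(tacs),
                    activity = (activity(tacs) - vB * wbF) / (1 - vB),
                    groundTruth = tacs@groundTruth)
}
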