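#' @include blood-model.R
NULL

#' Convert between net influx constants and trapping rates
#'
#' For fixed \code{K1} and \code{k2}, \code{k3ForKi} returns the trapping
#' rate giving net influx \eqn{K_i = K_1 k_3/(k_2+k_3)}, and
#' \code{taskK3DeltaForKi} the additive k3 change that raises the implied
#' influx by \code{dKi} above the baseline of \code{params}.
#'
#' @param K1,k2 Rate constants (mL/cm3/min, 1/min).
#' @param Ki Target net influx constant, 1/min; must be < K1.
#' @return k3 in 1/min.
#' @examples
#' k3ForKi(0.04, 0.07, 0.009)
#' @export
k3ForKi <- function(K1, k2, Ki) {
  stopIfNot(all(Ki >= 0) && all(Ki < K1),
            "Ki must lie in [0, K1) for an irreversible two-tissue model")
  k2 * Ki / (K1 - Ki)
}

#' @rdname k3ForKi
#' @param params A \linkS4class{KineticParams} (baseline K1, k2, k3).
#' @param dKi Desired additive change of the net influx constant, 1/min
#'   (vector, one per task block).
#' @export
taskK3DeltaForKi <- function(params, dKi) {
  base <- trueKi(params)
  k3ForKi(params@K1, params@k2, base + dKi) - params@k3
}

## piecewise-constant block index per grid point (1..B, 0 outside blocks)
blockIndexOnGrid <- function(task, grid) {
  idx <- integer(length(grid))
  if (is.null(task)) return(idx)
  for (j in seq_len(nBlocks(task))) {
    on <- task@blockOnsets[j]; off <- on + task@blockDuration
    idx[grid >= on & grid < off] <- j
  }
  idx
}

## solve the task-modulated irreversible 2TC system on the input grid.
## mode "uptake": baseline kinetics plus an additional trapping flux
##   dKi_j * Cp(t) inside block j (instantaneous-equilibration limit of a
##   k3 increase; the model the fPET GLM assumes).
## mode "ode": k3 switches to k3 + delta_j inside block j (full transient).
solve2tc <- function(K1, k2, k3, delta, Cp, grid, task, mode) {
  n <- length(grid)
  dt <- gridStep(grid)
  blk <- blockIndexOnGrid(task, grid)
  B <- if (is.null(task)) 0L else nBlocks(task)
  if (B > 0 && length(delta) == 0) delta <- rep(0, B)
  if (B > 0 && length(delta) != B)
    stop("need one task k3 delta per block")
  if (B > 0 && any(k3 + delta < 0))
    stop("task k3 delta more negative than baseline k3")
  dKi <- if (B > 0 && (k2 + k3 + delta[1]) > 0)
    K1 * (k3 + delta) / (k2 + k3 + delta) - K1 * k3 / (k2 + k3) else numeric(0)
  C1 <- numeric(n); C2 <- numeric(n)
  for (i in 2:n) {
    k3i <- if (mode == "ode" && blk[i] > 0) k3 + delta[blk[i]] else k3
    a <- k2 + k3i
    cbar <- 0.5 * (Cp[i - 1] + Cp[i])
    if (a > 0) {
      e <- exp(-a * dt)
      C1[i] <- C1[i - 1] * e + K1 * cbar * (1 - e) / a
    } else {
      C1[i] <- C1[i - 1] + K1 * cbar * dt
    }
    C2[i] <- C2[i - 1] + k3i * 0.5 * (C1[i - 1] + C1[i]) * dt
    if (mode == "uptake" && blk[i] > 0)
      C2[i] <- C2[i] + dKi[blk[i]] * cbar * dt
  }
  list(free = C1, trapped = C2, dKi = dKi)
}

#' Simulate a tissue time-activity curve
#'
#' Solves the irreversible two-tissue compartment system for the parent
#' tracer (free + trapped), adds a separately solved one-tissue 3-OMFD
#' component driven by the metabolite input, mixes in the whole-blood signal
#' with blood volume fraction \code{vB}, frame-averages over the frame
#' schedule and optionally adds Gaussian noise. The generative ground truth
#' (baseline Ki, per-block task Ki, the metabolite tissue component and the
#' pure parent tissue signal, all frame-averaged) is recorded in the
#' returned object.
#'
#' Task modulation is parameterised by additive k3 changes per block and can
#' be rendered in two modes. \code{"uptake"} (default) adds the implied
#' extra influx \eqn{\Delta K_i \, C_p(t)} to the trapped compartment inside
#' each block: the instantaneous-equilibration limit in which a task block
#' changes the uptake rate by a constant amount, which is exactly the signal
#' model the ramp-and-hold GLM regressor assumes. \code{"ode"} switches k3
#' itself, so the total-activity response develops with the free
#' compartment's relaxation time \eqn{1/(k_2+k_3+\delta)}; see the package
#' vignette for why this lagged response is systematically under-recovered
#' by the GLM.
#'
#' @param params A \linkS4class{KineticParams}.
#' @param inputs An \linkS4class{InputFunctionSet} (uniform grid covering
#'   the frames).
#' @param task A \linkS4class{TaskSchedule} or NULL.
#' @param frames Data frame or list with \code{start}/\code{end} frame times
#'   in minutes; default 60-s frames over the input grid.
#' @param noiseSd Gaussian noise SD, kBq/mL (applied per frame).
#' @param taskMode \code{"uptake"} or \code{"ode"}.
#' @param refParams Reference-region \linkS4class{KineticParams} whose
#'   (K1, k2) fill in missing metabolite kinetics (uniform
#'   distribution-volume assumption); defaults to K1=0.06, k2=0.05.
#' @param region Region name for the output column.
#' @param seed Optional integer; when given, noise is generated from this
#'   seed so the TAC is reproducible bit for bit.
#' @return A \linkS4class{TimeActivityCurve} with one region and ground
#'   truth in \code{@groundTruth}: \code{KiBaseline}, \code{KiBlock}
#'   (baseline + task increment per block), \code{dKi}, \code{omfdTissue},
#'   \code{parentTissue}, \code{noiseSd}, \code{seed}.
#' @examples
#' ifs <- makeInputFunctions()
#' tac <- simulateTac(KineticParams(K1 = 0.04, k2 = 0.07, k3 = 0.02), ifs)
#' tac
#' @export
simulateTac <- function(params, inputs, task = NULL, frames = NULL,
                        noiseSd = 0, taskMode = c("uptake", "ode"),
                        refParams = NULL, region = "region", seed = NULL) {
  taskMode <- match.arg(taskMode)
  validObject(params); validObject(inputs)
  grid <- timeGrid(inputs)
  if (is.null(frames))
    frames <- defaultFrames(max(grid))
  stopIfNot(min(frames$start) >= min(grid) && max(frames$end) <= max(grid),
            "frames must lie within the input-function grid")
  if (!is.null(task))
    stopIfNot(max(blockEnd(task)) <= max(grid) + 1e-9,
              "task blocks must lie within the input-function grid")
  sol <- solve2tc(params@K1, params@k2, params@k3, params@taskK3Delta,
                  plasmaParent(inputs), grid, task, taskMode)
  K1m <- if (is.na(params@K1m)) refDefault(refParams)@K1 else params@K1m
  k2m <- if (is.na(params@k2m)) refDefault(refParams)@k2 else params@k2m
  omfd <- conv1tc(K1m, k2m, plasmaMetabolite(inputs), gridStep(grid))
  tissue <- sol$free + sol$trapped
  meas <- (1 - params@vB) * (tissue + omfd) + params@vB * wholeBlood(inputs)
  act <- frameAverage(grid, meas, frames$start, frames$end)
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    act <- act + stats::rnorm(length(act), 0, noiseSd)
  }
  gt <- list(
    KiBaseline = trueKi(params),
    KiBlock = trueKi(params) + sol$dKi,
    dKi = sol$dKi,
    omfdTissue = frameAverage(grid, omfd, frames$start, frames$end),
    parentTissue = frameAverage(grid, tissue, frames$start, frames$end),
    noiseSd = noiseSd, seed = seed, taskMode = taskMode)
  TimeActivityCurve(frameStart = frames$start, frameEnd = frames$end,
                    activity = matrix(act, ncol = 1,
                                      dimnames = list(NULL, region)),
                    groundTruth = gt)
}

#' Simulate a reference-region (trapping-free) time-activity curve
#'
#' Same as \code{\link{simulateTac}} with trapping disabled: the reference
#' region (occipital cortex) is assumed devoid of specific AADC activity, so
#' k3 must be 0 and no task modulation is allowed.
#'
#' @inheritParams simulateTac
#' @return A \linkS4class{TimeActivityCurve}.
#' @export
simulateReferenceTac <- function(params, inputs, frames = NULL, noiseSd = 0,
                                 region = "occipital", seed = NULL) {
  stopIfNot(params@k3 == 0, "a reference region must have k3 = 0")
  stopIfNot(length(params@taskK3Delta) == 0 || all(params@taskK3Delta == 0),
            "a reference region cannot carry task modulation")
  simulateTac(params, inputs, task = NULL, frames = frames,
              noiseSd = noiseSd, refParams = params, region = region,
              seed = seed)
}

## default: 60-s frames spanning the scan
defaultFrames <- function(scanMinutes, frameSeconds = 60) {
  fl <- frameSeconds / 60
  start <- seq(0, scanMinutes - fl, by = fl)
  list(start = start, end = start + fl)
}

refDefault <- function(refParams) {
  if (is.null(refParams))
    KineticParams(K1 = 0.06, k2 = 0.05, k3 = 0, vB = 0.05)
  else refParams
}
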