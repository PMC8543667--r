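#' @include config.R
NULL

#' Kinetic scene of a synthetic session
#'
#' Region-by-region kinetic parameters of the small synthetic "brain" used
#' for recovery testing: one task-responsive striatal target, a set of
#' gray-matter regions sharing the striatal clearance and trapping rates
#' (scaled transport, so the baseline regressor is shape-matched to the
#' target baseline), and a trapping-free occipital reference region. The
#' 3-OMFD tissue kinetics are uniform and equal to the reference parent
#' kinetics, satisfying the distribution-volume assumptions of the
#' metabolite correction.
#'
#' @param baselineKi Baseline net influx constant of the target, 1/min.
#' @param taskDeltaKi Task-specific increase of the net influx constant per
#'   block, 1/min (recycled over blocks).
#' @param K1,k2 Striatal transport and clearance constants.
#' @param grayScale Transport scaling of the gray-matter regions.
#' @param refK1,refk2 Reference-region constants.
#' @param vB Blood volume fraction.
#' @param task A \linkS4class{TaskSchedule} (used to size taskDeltaKi).
#' @return List of \linkS4class{KineticParams} per region plus the implied
#'   truth (\code{baselineKi}, \code{taskDeltaKi}).
#' @export
kineticScene <- function(baselineKi = 0.009, taskDeltaKi = 0.014,
                         K1 = 0.04, k2 = 0.07,
                         grayScale = c(0.8, 1.1, 0.95, 1.25),
                         refK1 = 0.06, refk2 = 0.05, vB = 0.05,
                         task = TaskSchedule()) {
  B <- nBlocks(task)
  dKi <- rep(taskDeltaKi, length.out = B)
  k3 <- k3ForKi(K1, k2, baselineKi)
  target <- KineticParams(K1 = K1, k2 = k2, k3 = k3, vB = vB,
                          K1m = refK1, k2m = refk2,
                          taskK3Delta = taskK3DeltaForKi(
                            KineticParams(K1 = K1, k2 = k2, k3 = k3, vB = vB),
                            dKi))
  grays <- lapply(grayScale, function(s)
    KineticParams(K1 = s * K1, k2 = k2, k3 = k3, vB = vB,
                  K1m = refK1, k2m = refk2))
  names(grays) <- paste0("gray", seq_along(grayScale))
  ref <- KineticParams(K1 = refK1, k2 = refk2, k3 = 0, vB = vB,
                       K1m = refK1, k2m = refk2)
  c(list(striatum = target), grays, list(occipital = ref),
    list(.truth = list(baselineKi = baselineKi, taskDeltaKi = dKi)))
}

## default arterial sampling schedule: dense during the bolus phase,
## sparser manual samples later (minutes)
defaultBloodSamplingTimes <- function(scanDuration = 50) {
  unique(c(seq(0, 2, by = 2 / 60), seq(2, 5, by = 10 / 60),
           seq(5, 10, by = 0.5), seq(10, scanDuration, by = 1)))
}

#' Simulate a complete synthetic session
#'
#' Generates everything the quantification pipeline consumes, with ground
#' truth recorded: tissue TACs for the target, gray-matter and reference
#' regions; the true input functions and a blood sample table drawn from
#' them on a realistic arterial sampling schedule; a small random-walk
#' motion trace; and an adaptive-staircase MID trial log matched to the
#' task schedule.
#'
#' @param config A \linkS4class{RunConfig}.
#' @param scene A \code{\link{kineticScene}}.
#' @param model A \code{\link{bloodModel}}.
#' @param noiseSd Frame noise SD for the TACs, kBq/mL.
#' @param taskMode Task response mode, see \code{\link{simulateTac}}.
#' @param motionSd Per-frame random-walk step SD of the motion parameters.
#' @param midArgs List of overrides for \code{\link{simulateMidSession}}.
#' @return List with \code{tacs} (\linkS4class{TimeActivityCurve},
#'   all regions, ground truth attached), \code{inputs} (true
#'   \linkS4class{InputFunctionSet}), \code{bloodSamples}, \code{motion},
#'   \code{trialLog}, \code{truth}.
#' @examples
#' ses <- simulateSession(fpetConfig(seed = 1L))
#' ses$tacs
#' @export
simulateSession <- function(config = fpetConfig(), scene = kineticScene(),
                            model = bloodModel(), noiseSd = 0,
                            taskMode = c("uptake", "ode"), motionSd = 0.02,
                            midArgs = list()) {
  taskMode <- match.arg(taskMode)
  validObject(config)
  set.seed(config@seed)
  frames <- configFrames(config)
  inputs <- makeInputFunctions(config@admin, model,
                               seq(0, config@scanDuration, by = 1 / 60))
  truth <- scene$.truth
  regions <- setdiff(names(scene), ".truth")
  refPar <- scene[[config@referenceRegion]]
  tacList <- lapply(regions, function(rg) {
    p <- scene[[rg]]
    if (rg == config@referenceRegion)
      simulateReferenceTac(p, inputs, frames = frames, noiseSd = noiseSd,
                           region = rg)
    else
      simulateTac(p, inputs,
                  task = if (length(p@taskK3Delta)) config@task else NULL,
                  frames = frames, noiseSd = noiseSd, taskMode = taskMode,
                  refParams = refPar, region = rg)
  })
  names(tacList) <- regions
  act <- do.call(cbind, lapply(tacList, activity))
  colnames(act) <- regions
  gt <- lapply(tacList, function(x) x@groundTruth)
  gt$session <- truth
  tacs <- TimeActivityCurve(frameStart = frames$start, frameEnd = frames$end,
                            activity = act, groundTruth = gt)
  st <- defaultBloodSamplingTimes(config@scanDuration)
  bloodSamples <- data.frame(
    time = st,
    whole_blood = interpConst(timeGrid(inputs), wholeBlood(inputs), st),
    plasma = interpConst(timeGrid(inputs),
                         plasmaParent(inputs) + plasmaMetabolite(inputs), st))
  nF <- length(frames$start)
  motion <- matrix(cumsum(stats::rnorm(nF * 6, 0, motionSd)), nF, 6,
                   dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                           "rot_x", "rot_y", "rot_z")))
  midDefaults <- list(nBlocks = nBlocks(config@task),
                      conditions = config@task@blockCondition,
                      seed = config@seed + 1L)
  trialLog <- do.call(simulateMidSession, utils::modifyList(midDefaults, midArgs))
  list(tacs = tacs, inputs = inputs, bloodSamples = bloodSamples,
       motion = motion, trialLog = trialLog, truth = gt)
}

#' Write a simulated session to disk
#'
#' Emits the TAC table, blood table, motion table, trial log and the
#' ground-truth JSON sidecar into a directory.
#'
#' @param session A list from \code{\link{simulateSession}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tacs = writeTacTable(session$tacs, file.path(dir, "tacs.tsv")),
    blood = writeBloodTable(session$bloodSamples, file.path(dir, "blood.tsv")),
    motion = writeMotionTable(session$motion, file.path(dir, "motion.tsv")),
    trials = writeTrialLog(session$trialLog, file.path(dir, "trials.csv")),
    truth = writeGroundTruth(session$truth, file.path(dir, "truth.json")))
  invisible(paths)
}
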