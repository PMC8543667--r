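#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## AdministrationSchedule
## ---------------------------------------------------------------------------

#' Radiotracer administration schedule
#'
#' Describes how the total injected activity is split between an initial
#' bolus and a constant infusion. The protocol modelled throughout the
#' package is bolus + constant infusion at a 20:80 ratio with the infusion
#' running over the whole 50 min scan, which flattens the late parent plasma
#' curve and emphasises the irreversible trapping of 6-FDOPA.
#'
#' @slot bolusFraction Fraction of the activity given as bolus, in [0, 1].
#' @slot infusionDuration Duration of the constant infusion, minutes.
#' @slot totalActivity Total administered activity, arbitrary activity units
#'   (the package works in relative units; absolute calibration cancels in
#'   every derived quantity).
#' @slot scanDuration Scan duration, minutes.
#'
#' @param bolusFraction,infusionDuration,totalActivity,scanDuration See slots.
#' @return An \code{AdministrationSchedule} object.
#' @examples
#' AdministrationSchedule()            # the default 20:80 over 50 min
#' @export AdministrationSchedule
#' @exportClass AdministrationSchedule
AdministrationSchedule <- setClass("AdministrationSchedule",
  slots = c(bolusFraction = "numeric", infusionDuration = "numeric",
            totalActivity = "numeric", scanDuration = "numeric"),
  prototype = prototype(bolusFraction = 0.20, infusionDuration = 50,
                        totalActivity = 200, scanDuration = 50))

setValidity("AdministrationSchedule", function(object) {
  msg <- character()
  if (length(object@bolusFraction) != 1 || is.na(object@bolusFraction) ||
      object@bolusFraction < 0 || object@bolusFraction > 1)
    msg <- c(msg, "bolusFraction must be a single value in [0, 1]")
  if (object@infusionDuration < 0)
    msg <- c(msg, "infusionDuration must be non-negative")
  if (object@infusionDuration > object@scanDuration)
    msg <- c(msg, "infusionDuration must not exceed scanDuration")
  if (object@totalActivity <= 0)
    msg <- c(msg, "totalActivity must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AdministrationSchedule", function(object) {
  cat(sprintf("AdministrationSchedule: %.0f:%.0f bolus:infusion, %g units over %g min (scan %g min)\n",
              100 * object@bolusFraction, 100 * (1 - object@bolusFraction),
              object@totalActivity, object@infusionDuration, object@scanDuration))
})

## ---------------------------------------------------------------------------
## TaskSchedule
## ---------------------------------------------------------------------------

#' Task block schedule
#'
#' Onsets, duration and condition labels of the MID task blocks within the
#' scan. Defaults follow the main-study design: four 5-min blocks at 10, 20,
#' 30 and 40 min, alternating gain and loss. Proof-of-concept acquisitions
#' use three blocks from 20 min with condition \code{"mixed"}.
#'
#' @slot blockOnsets Numeric, block onset times in minutes.
#' @slot blockDuration Numeric scalar, block length in minutes.
#' @slot blockCondition Character, one of \code{"gain"}, \code{"loss"},
#'   \code{"mixed"} per block.
#'
#' @param blockOnsets,blockDuration,blockCondition See slots.
#' @return A \code{TaskSchedule}.
#' @examples
#' TaskSchedule()
#' pocTaskSchedule()
#' @export TaskSchedule
#' @exportClass TaskSchedule
TaskSchedule <- setClass("TaskSchedule",
  slots = c(blockOnsets = "numeric", blockDuration = "numeric",
            blockCondition = "character"),
  prototype = prototype(blockOnsets = c(10, 20, 30, 40), blockDuration = 5,
                        blockCondition = c("gain", "loss", "gain", "loss")))

setValidity("TaskSchedule", function(object) {
  msg <- character()
  on <- object@blockOnsets
  if (length(object@blockDuration) != 1 || object@blockDuration <= 0)
    msg <- c(msg, "blockDuration must be a positive scalar")
  if (is.unsorted(on, strictly = TRUE))
    msg <- c(msg, "blockOnsets must be strictly increasing")
  if (length(on) > 1 && any(diff(on) < object@blockDuration))
    msg <- c(msg, "task blocks must not overlap")
  if (length(object@blockCondition) != length(on))
    msg <- c(msg, "need one condition label per block")
  if (!all(object@blockCondition %in% c("gain", "loss", "mixed")))
    msg <- c(msg, "block conditions must be 'gain', 'loss' or 'mixed'")
  if (length(msg)) msg else TRUE
})

#' @rdname TaskSchedule-class
#' @export
pocTaskSchedule <- function() {
  TaskSchedule(blockOnsets = c(20, 30, 40), blockDuration = 5,
               blockCondition = rep("mixed", 3))
}

#' Number of task blocks
#' @param x A \linkS4class{TaskSchedule}.
#' @return Integer.
#' @export
nBlocks <- function(x) length(x@blockOnsets)

#' Block end times
#' @param x A \linkS4class{TaskSchedule}.
#' @return Numeric vector, minutes.
#' @export
blockEnd <- function(x) x@blockOnsets + x@blockDuration

setMethod("show", "TaskSchedule", function(object) {
  cat(sprintf("TaskSchedule: %d block(s) of %g min\n", nBlocks(object),
              object@blockDuration))
  cat(sprintf("  onsets (min): %s\n", paste(object@blockOnsets, collapse = ", ")))
  cat(sprintf("  conditions  : %s\n", paste(object@blockCondition, collapse = ", ")))
})

## ---------------------------------------------------------------------------
## KineticParams
## ---------------------------------------------------------------------------

#' Compartment-model rate constants for one region
#'
#' Parameters of the irreversible two-tissue compartment model used for
#' 6-FDOPA: plasma-to-tissue transport \code{K1} (mL/cm3/min), tissue
#' clearance \code{k2} (1/min) and irreversible trapping \code{k3} (1/min,
#' the AADC-driven synthesis step). The measured signal is
#' \eqn{(1-v_B)\,C_{tissue} + v_B\,C_{wholeblood}} with blood volume
#' fraction \code{vB}. Task modulation is expressed as an additive change of
#' \code{k3} per task block (\code{taskK3Delta}); see
#' \code{\link{simulateTac}} for the two response modes. The separately
#' simulated 3-OMFD tissue component follows one-tissue kinetics with
#' \code{K1m}/\code{k2m}; \code{NA} (the default) means "same as the
#' reference-region parent kinetics supplied at simulation time".
#'
#' @slot K1 mL/cm3/min.
#' @slot k2 1/min.
#' @slot k3 1/min.
#' @slot vB Blood volume fraction in [0, 1].
#' @slot K1m,k2m One-tissue constants of the metabolite component (NA =
#'   inherit).
#' @slot taskK3Delta Numeric, additive k3 change per task block (1/min);
#'   empty means no task modulation.
#'
#' @param K1,k2,k3,vB,K1m,k2m,taskK3Delta See slots.
#' @return A \code{KineticParams}.
#' @examples
#' p <- KineticParams(K1 = 0.04, k2 = 0.07, k3 = 0.02)
#' trueKi(p)
#' @export KineticParams
#' @exportClass KineticParams
KineticParams <- setClass("KineticParams",
  slots = c(K1 = "numeric", k2 = "numeric", k3 = "numeric", vB = "numeric",
            K1m = "numeric", k2m = "numeric", taskK3Delta = "numeric"),
  prototype = prototype(K1 = 0.04, k2 = 0.07, k3 = 0.02, vB = 0.05,
                        K1m = NA_real_, k2m = NA_real_,
                        taskK3Delta = numeric(0)))

setValidity("KineticParams", function(object) {
  msg <- character()
  for (s in c("K1", "k2", "k3")) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v < 0)
      msg <- c(msg, sprintf("%s must be a single non-negative number", s))
  }
  if (length(object@vB) != 1 || is.na(object@vB) ||
      object@vB < 0 || object@vB > 1)
    msg <- c(msg, "vB must be in [0, 1]")
  if (!is.na(object@K1m) && object@K1m < 0) msg <- c(msg, "K1m must be >= 0")
  if (!is.na(object@k2m) && object@k2m < 0) msg <- c(msg, "k2m must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname trueKi
setMethod("trueKi", "KineticParams", function(x) {
  if (x@k2 + x@k3 == 0) return(0)
  x@K1 * x@k3 / (x@k2 + x@k3)
})

setMethod("show", "KineticParams", function(object) {
  cat(sprintf("KineticParams: K1=%g mL/cm3/min, k2=%g/min, k3=%g/min, vB=%g (Ki=%.4g/min)\n",
              object@K1, object@k2, object@k3, object@vB, trueKi(object)))
  if (length(object@taskK3Delta))
    cat(sprintf("  task k3 deltas (1/min): %s\n",
                paste(signif(object@taskK3Delta, 4), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## TimeActivityCurve
## ---------------------------------------------------------------------------

#' Framed time-activity curves
#'
#' Radioactivity concentration (kBq/mL) per frame for one or more regions,
#' together with the frame schedule (minutes post injection). Simulated TACs
#' carry their generative ground truth in the \code{groundTruth} list.
#'
#' @slot frameStart,frameEnd Numeric, frame boundaries in minutes.
#' @slot activity Matrix (frames x regions), kBq/mL.
#' @slot groundTruth List with generator ground truth (may be empty).
#'
#' @param frameStart,frameEnd,activity,groundTruth See slots.
#' @return A \code{TimeActivityCurve}.
#' @export TimeActivityCurve
#' @exportClass TimeActivityCurve
TimeActivityCurve <- setClass("TimeActivityCurve",
  slots = c(frameStart = "numeric", frameEnd = "numeric",
            activity = "matrix", groundTruth = "list"),
  prototype = prototype(groundTruth = list()))

setValidity("TimeActivityCurve", function(object) {
  msg <- character()
  n <- length(object@frameStart)
  if (length(object@frameEnd) != n)
    msg <- c(msg, "frameStart and frameEnd must have equal length")
  else {
    if (any(object@frameEnd <= object@frameStart))
      msg <- c(msg, "frames must have positive length")
    if (n > 1 && any(object@frameStart[-1] < object@frameEnd[-n]))
      msg <- c(msg, "frames must not overlap and must be ordered")
  }
  if (nrow(object@activity) != n)
    msg <- c(msg, "activity must have one row per frame")
  if (length(msg)) msg else TRUE
})

#' @rdname frame-accessors
setMethod("frameStart", "TimeActivityCurve", function(x) x@frameStart)
#' @rdname frame-accessors
setMethod("frameEnd", "TimeActivityCurve", function(x) x@frameEnd)
#' @rdname frame-accessors
setMethod("frameMid", "TimeActivityCurve",
          function(x) (x@frameStart + x@frameEnd) / 2)
#' @rdname frame-accessors
setMethod("frameLength", "TimeActivityCurve",
          function(x) x@frameEnd - x@frameStart)
#' @rdname activity
setMethod("activity", "TimeActivityCurve", function(x) x@activity)
#' @rdname regionNames
setMethod("regionNames", "TimeActivityCurve", function(x) colnames(x@activity))

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve: %d frame(s) x %d region(s), %g-%g min\n",
              nrow(object@activity), ncol(object@activity),
              min(object@frameStart), max(object@frameEnd)))
  if (!is.null(colnames(object@activity)))
    cat("  regions:", paste(colnames(object@activity), collapse = ", "), "\n")
  if (length(object@groundTruth))
    cat("  ground truth recorded:",
        paste(names(object@groundTruth), collapse = ", "), "\n")
})

#' Subset regions of a TimeActivityCurve
#'
#' @param x A \linkS4class{TimeActivityCurve}.
#' @param i Region names or indices.
#' @param j,...,drop Ignored.
#' @return A \code{TimeActivityCurve} with the selected regions.
#' @export
setMethod("[", "TimeActivityCurve", function(x, i, j, ..., drop = FALSE) {
  TimeActivityCurve(frameStart = x@frameStart, frameEnd = x@frameEnd,
                    activity = x@activity[, i, drop = FALSE],
                    groundTruth = x@groundTruth)
})

## ---------------------------------------------------------------------------
## InputFunctionSet
## ---------------------------------------------------------------------------

#' Arterial input functions on a common time grid
#'
#' Whole-blood, parent (6-FDOPA) plasma and metabolite (3-OMFD) plasma
#' concentration curves. Parent and metabolite sum to total plasma by
#' construction; the parent fraction is \eqn{C_p / (C_p + C_m)}.
#'
#' @slot timeGrid Numeric, strictly increasing, minutes, starting at 0.
#' @slot wholeBlood,plasmaParent,plasmaMetabolite Numeric curves, kBq/mL.
#'
#' @param timeGrid,wholeBlood,plasmaParent,plasmaMetabolite See slots.
#' @return An \code{InputFunctionSet}.
#' @export InputFunctionSet
#' @exportClass InputFunctionSet
InputFunctionSet <- setClass("InputFunctionSet",
  slots = c(timeGrid = "numeric", wholeBlood = "numeric",
            plasmaParent = "numeric", plasmaMetabolite = "numeric"))

setValidity("InputFunctionSet", function(object) {
  msg <- character()
  n <- length(object@timeGrid)
  if (n < 2 || is.unsorted(object@timeGrid, strictly = TRUE))
    msg <- c(msg, "timeGrid must be strictly increasing with >= 2 points")
  if (object@timeGrid[1] < 0) msg <- c(msg, "timeGrid must start at >= 0")
  for (s in c("wholeBlood", "plasmaParent", "plasmaMetabolite")) {
    v <- slot(object, s)
    if (length(v) != n) msg <- c(msg, sprintf("%s must match timeGrid length", s))
    else if (any(v < -1e-9)) msg <- c(msg, sprintf("%s must be non-negative", s))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname timeGrid
setMethod("timeGrid", "InputFunctionSet", function(x) x@timeGrid)
#' @rdname blood-accessors
setMethod("wholeBlood", "InputFunctionSet", function(x) x@wholeBlood)
#' @rdname blood-accessors
setMethod("plasmaParent", "InputFunctionSet", function(x) x@plasmaParent)
#' @rdname blood-accessors
setMethod("plasmaMetabolite", "InputFunctionSet", function(x) x@plasmaMetabolite)
#' @rdname blood-accessors
setMethod("parentFraction", "InputFunctionSet", function(x) {
  tot <- x@plasmaParent + x@plasmaMetabolite
  ifelse(tot > 0, x@plasmaParent / tot, 1)
})

setMethod("show", "InputFunctionSet", function(object) {
  tg <- object@timeGrid
  cat(sprintf("InputFunctionSet: %d points, %g-%g min (step ~%.3g s)\n",
              length(tg), min(tg), max(tg), 60 * stats::median(diff(tg))))
  cat(sprintf("  parent plasma at end: %.3g kBq/mL, parent fraction %.2f\n",
              object@plasmaParent[length(tg)],
              parentFraction(object)[length(tg)]))
})

## ---------------------------------------------------------------------------
## OneTissueFit
## ---------------------------------------------------------------------------

#' Reference-region one-tissue compartment fit
#'
#' @slot K1ref mL/cm3/min.
#' @slot k2ref 1/min.
#' @slot residRms Root-mean-square residual, kBq/mL.
#' @slot cov 2x2 covariance matrix of (K1ref, k2ref).
#' @slot converged Logical.
#' @slot nuisanceBeta Coefficients of the task/motion nuisance regressors
#'   estimated jointly with the fit (empty if none were supplied).
#'
#' @param K1ref,k2ref,residRms,cov,converged,nuisanceBeta See slots.
#' @return A \code{OneTissueFit}.
#' @export OneTissueFit
#' @exportClass OneTissueFit
OneTissueFit <- setClass("OneTissueFit",
  slots = c(K1ref = "numeric", k2ref = "numeric", residRms = "numeric",
            cov = "matrix", converged = "logical", nuisanceBeta = "numeric"),
  prototype = prototype(cov = matrix(NA_real_, 2, 2), converged = FALSE,
                        nuisanceBeta = numeric(0)))

setValidity("OneTissueFit", function(object) {
  msg <- character()
  if (object@K1ref <= 0 || object@k2ref <= 0)
    msg <- c(msg, "K1ref and k2ref must be positive")
  if (!is.finite(object@residRms)) msg <- c(msg, "residRms must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OneTissueFit", function(object) {
  cat(sprintf("OneTissueFit: K1=%.4g mL/cm3/min, k2=%.4g/min (RMS %.3g kBq/mL, %s)\n",
              object@K1ref, object@k2ref, object@residRms,
              if (object@converged) "converged" else "NOT converged"))
})

## ---------------------------------------------------------------------------
## GlmDesign / GlmFit
## ---------------------------------------------------------------------------

#' GLM design matrix for functional PET
#'
#' Columns: one ramp-and-hold regressor per task block (slope exactly 1
#' kBq/mL per frame inside the block, 0 before onset, held at the end-of-
#' block value afterwards), the baseline regressor (the supplied gray-matter
#' average TAC), and one motion regressor (first principal component of the
#' six rigid-body parameters). No orthogonalisation is applied; collinearity
#' is surfaced through the condition number.
#'
#' @slot design Matrix (frames x regressors) with named columns.
#' @slot frameStart,frameEnd Frame schedule, minutes.
#' @slot taskColumns Integer indices of the task regressors.
#' @slot blockMap List mapping each task column to the block indices it
#'   covers (one per column, several for a combined proof-of-concept
#'   regressor).
#' @slot conditionNumber Condition number of the column-scaled design.
#'
#' @param design,frameStart,frameEnd,taskColumns,blockMap,conditionNumber
#'   See slots.
#' @return A \code{GlmDesign}.
#' @seealso \code{\link{buildGlmDesign}}
#' @export GlmDesign
#' @exportClass GlmDesign
GlmDesign <- setClass("GlmDesign",
  slots = c(design = "matrix", frameStart = "numeric", frameEnd = "numeric",
            taskColumns = "integer", blockMap = "list",
            conditionNumber = "numeric"))

setValidity("GlmDesign", function(object) {
  msg <- character()
  if (nrow(object@design) != length(object@frameStart))
    msg <- c(msg, "design must have one row per frame")
  if (is.null(colnames(object@design)))
    msg <- c(msg, "design columns must be named")
  if (any(object@taskColumns > ncol(object@design)))
    msg <- c(msg, "taskColumns out of range")
  if (length(msg)) msg else TRUE
})

#' @rdname designMatrix
setMethod("designMatrix", "GlmDesign", function(x) x@design)

setMethod("show", "GlmDesign", function(object) {
  cat(sprintf("GlmDesign: %d frames x %d regressors (%s); condition number %.3g\n",
              nrow(object@design), ncol(object@design),
              paste(colnames(object@design), collapse = ", "),
              object@conditionNumber))
})

#' Ordinary least-squares fit of a functional-PET GLM
#'
#' @slot design The \linkS4class{GlmDesign} used.
#' @slot beta Named coefficients: kBq/mL per frame for task columns,
#'   dimensionless for the baseline column, arbitrary units for motion.
#' @slot components Matrix of reconstructed per-column components
#'   (design column x beta), kBq/mL.
#' @slot residuals Numeric, kBq/mL.
#' @slot sigma2 Residual variance.
#' @slot response The (filtered) TAC that was fitted.
#'
#' @param design,beta,components,residuals,sigma2,response See slots.
#' @return A \code{GlmFit}.
#' @export GlmFit
#' @exportClass GlmFit
GlmFit <- setClass("GlmFit",
  slots = c(design = "GlmDesign", beta = "numeric", components = "matrix",
            residuals = "numeric", sigma2 = "numeric", response = "numeric"))

setValidity("GlmFit", function(object) {
  ## reconstruction identity: design %*% beta + residuals == response
  rec <- as.numeric(object@design@design %*% object@beta) + object@residuals
  if (max(abs(rec - object@response)) >
      1e-6 * max(1, max(abs(object@response))))
    return("reconstruction identity violated: design x beta + residuals != response")
  TRUE
})

#' @rdname designMatrix
setMethod("designMatrix", "GlmFit", function(x) x@design@design)
#' @rdname fittedComponents
setMethod("fittedComponents", "GlmFit", function(x) x@components)

#' @export
#' @rdname GlmFit-class
#' @param object A \code{GlmFit}.
#' @param ... Ignored.
setMethod("coef", "GlmFit", function(object, ...) object@beta)

setMethod("show", "GlmFit", function(object) {
  cat("GlmFit:\n")
  print(signif(object@beta, 4))
  cat(sprintf("  residual SD %.3g kBq/mL\n", sqrt(object@sigma2)))
})

## ---------------------------------------------------------------------------
## PatlakResult / ConditionKi
## ---------------------------------------------------------------------------

#' Gjedde-Patlak fit result
#'
#' @slot Ki Net influx constant (slope), 1/min.
#' @slot intercept Dimensionless intercept (apparent distribution volume).
#' @slot tStar Start of the linear fit window, minutes.
#' @slot nPoints Number of frames in the fit.
#' @slot r2 Coefficient of determination of the linear fit.
#'
#' @param Ki,intercept,tStar,nPoints,r2 See slots.
#' @return A \code{PatlakResult}.
#' @export PatlakResult
#' @exportClass PatlakResult
PatlakResult <- setClass("PatlakResult",
  slots = c(Ki = "numeric", intercept = "numeric", tStar = "numeric",
            nPoints = "integer", r2 = "numeric"))

setValidity("PatlakResult", function(object) {
  if (object@nPoints < 3L) return("a Patlak fit needs at least 3 points")
  TRUE
})

setMethod("show", "PatlakResult", function(object) {
  cat(sprintf("PatlakResult: Ki=%.4g/min, intercept=%.3g (t*=%g min, n=%d, R2=%.4f)\n",
              object@Ki, object@intercept, object@tStar, object@nPoints,
              object@r2))
})

#' Condition-level net influx constants and percent signal change
#'
#' Baseline and per-block task-specific net influx constants together with
#' the performance weights, weighted and unweighted condition averages, and
#' percent signal change from baseline
#' (\eqn{PSC = K_{i,task}/K_{i,baseline} \times 100}).
#'
#' @slot KiBaseline 1/min.
#' @slot KiBlock Per-block task Ki, 1/min.
#' @slot weights Performance weights per block, in [0, 1].
#' @slot conditions Condition label per block.
#' @slot KiCondition Named numeric (per condition), performance-weighted.
#' @slot KiConditionUnweighted Named numeric, plain means.
#' @slot PSC,PSCUnweighted Named numeric, percent.
#'
#' @param KiBaseline,KiBlock,weights,conditions,KiCondition,
#'   KiConditionUnweighted,PSC,PSCUnweighted See slots.
#' @return A \code{ConditionKi}.
#' @export ConditionKi
#' @exportClass ConditionKi
ConditionKi <- setClass("ConditionKi",
  slots = c(KiBaseline = "numeric", KiBlock = "numeric", weights = "numeric",
            conditions = "character", KiCondition = "numeric",
            KiConditionUnweighted = "numeric", PSC = "numeric",
            PSCUnweighted = "numeric"))

setValidity("ConditionKi", function(object) {
  msg <- character()
  if (length(object@KiBlock) != length(object@weights) ||
      length(object@KiBlock) != length(object@conditions))
    msg <- c(msg, "KiBlock, weights and conditions must align")
  if (any(object@weights < 0 | object@weights > 1))
    msg <- c(msg, "weights must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConditionKi", function(object) {
  cat(sprintf("ConditionKi: baseline Ki=%.4g/min\n", object@KiBaseline))
  for (cc in names(object@KiCondition))
    cat(sprintf("  %s: Ki=%.4g/min (unweighted %.4g), PSC=%.1f%%\n", cc,
                object@KiCondition[cc], object@KiConditionUnweighted[cc],
                object@PSC[cc]))
})
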