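#' @include utils.R
NULL

#' Parametric unit-bolus blood model
#'
#' Describes the plasma response to a unit bolus of tracer: the parent
#' (6-FDOPA) plasma concentration is a sum of decaying exponentials,
#' \eqn{p(t) = \sum_i A_i e^{-\lambda_i t}}, and the metabolite (3-OMFD)
#' appears by first-order conversion from the parent with formation rate
#' \code{kMet} and slow elimination \code{lambdaMet}:
#' \eqn{m(t) = k_{met} \int_0^t p(s) e^{-\lambda_m (t-s)} ds}. Total plasma
#' is \eqn{p + m}; whole blood is total plasma divided by the
#' plasma-to-whole-blood ratio line \code{ratioIntercept + ratioSlope * t}.
#'
#' The defaults give a parent plasma curve that is near-flat over the second
#' half of a 50-min scan under the 20:80 bolus + infusion protocol, and a
#' unit-bolus 3-OMFD fraction that rises sigmoidally to roughly 0.6 by
#' 50 min, in line with published bolus FDOPA metabolite data under
#' carbidopa pretreatment.
#'
#' @param parentAmp Amplitudes \eqn{A_i}, kBq/mL per unit activity.
#' @param parentRate Decay rates \eqn{\lambda_i}, 1/min (same length).
#' @param kMet Parent-to-metabolite formation rate, 1/min.
#' @param lambdaMet Metabolite elimination rate, 1/min.
#' @param ratioIntercept,ratioSlope Plasma/whole-blood ratio line
#'   (dimensionless, 1/min).
#' @return A list of class \code{"BloodModel"}.
#' @examples
#' bm <- bloodModel()
#' curve(bloodModelParent(bm)(x), 0, 50, xlab = "min", ylab = "parent, unit bolus")
#' @export
bloodModel <- function(parentAmp = c(6, 1.0, 0.30),
                       parentRate = c(3.0, 0.35, 0.12),
                       kMet = 0.012, lambdaMet = 0.006,
                       ratioIntercept = 1.0, ratioSlope = 0.004) {
  if (length(parentAmp) != length(parentRate))
    stop("parentAmp and parentRate must have equal length")
  if (any(parentAmp < 0) || any(parentRate <= 0) || kMet < 0 || lambdaMet < 0)
    stop("non-physical blood model: amplitudes/rates must be non-negative")
  structure(list(parentAmp = parentAmp, parentRate = parentRate,
                 kMet = kMet, lambdaMet = lambdaMet,
                 ratioIntercept = ratioIntercept, ratioSlope = ratioSlope),
            class = "BloodModel")
}

#' @rdname bloodModel
#' @param model A \code{"BloodModel"}.
#' @return \code{bloodModelParent}/\code{bloodModelMetabolite} return the
#'   unit-bolus parent/metabolite plasma response as a function of time
#'   (minutes); \code{bolusParentFraction} the unit-bolus 3-OMFD fraction
#'   \eqn{m/(p+m)}.
#' @export
bloodModelParent <- function(model) {
  force(model)
  function(t) {
    as.numeric(colSums(model$parentAmp * exp(-outer(model$parentRate, t))))
  }
}

#' @rdname bloodModel
#' @export
bloodModelMetabolite <- function(model) {
  force(model)
  function(t) {
    out <- 0
    for (i in seq_along(model$parentAmp)) {
      li <- model$parentRate[i]; lm <- model$lambdaMet
      out <- out + model$kMet * model$parentAmp[i] *
        (exp(-lm * t) - exp(-li * t)) / (li - lm)
    }
    out
  }
}

#' @rdname bloodModel
#' @export
bolusParentFraction <- function(model) {
  p <- bloodModelParent(model); m <- bloodModelMetabolite(model)
  function(t) {
    pv <- p(t); mv <- m(t); tot <- pv + mv
    ifelse(tot > 0, mv / tot, 0)
  }
}

## superpose a unit-bolus response under a bolus+infusion administration:
## bolus part is the scaled response, infusion part the running-trapezoid
## convolution of the response with the constant administration rate.
superposeBI <- function(responseFun, schedule, timeGrid) {
  h <- responseFun(timeGrid)
  out <- schedule@bolusFraction * schedule@totalActivity * h
  infFrac <- 1 - schedule@bolusFraction
  if (infFrac > 0 && schedule@infusionDuration > 0) {
    rate <- infFrac * schedule@totalActivity / schedule@infusionDuration
    dt <- gridStep(timeGrid)
    conv <- rate * dt * (cumsum(h) - (h + h[1]) / 2)
    if (max(timeGrid) > schedule@infusionDuration) {
      ## infusion stops: subtract a delayed copy of the same convolution
      shifted <- interpConst(timeGrid + schedule@infusionDuration, conv, timeGrid)
      shifted[timeGrid <= schedule@infusionDuration] <- 0
      conv <- conv - shifted
    }
    out <- out + conv
  }
  out
}

#' Generate noise-free input functions for an administration schedule
#'
#' Builds whole-blood, parent-plasma and metabolite-plasma curves as the
#' superposition of the administration rate function (bolus + constant
#' infusion) with the parametric unit-bolus responses of a
#' \code{\link{bloodModel}}. Parent and metabolite sum to total plasma on
#' the grid; under bolus + infusion the late parent curve approaches a
#' plateau.
#'
#' @param schedule An \linkS4class{AdministrationSchedule}.
#' @param model A \code{\link{bloodModel}}.
#' @param timeGrid Uniform, strictly increasing time grid starting at 0,
#'   minutes. Default: 1-s steps over the scan.
#' @return An \linkS4class{InputFunctionSet}.
#' @examples
#' ifs <- makeInputFunctions(AdministrationSchedule(), bloodModel())
#' plot(timeGrid(ifs), plasmaParent(ifs), type = "l",
#'      xlab = "min", ylab = "kBq/mL")
#' @export
makeInputFunctions <- function(schedule = AdministrationSchedule(),
                               model = bloodModel(),
                               timeGrid = NULL) {
  validObject(schedule)
  if (is.null(timeGrid))
    timeGrid <- seq(0, schedule@scanDuration, by = 1 / 60)
  stopIfNot(timeGrid[1] == 0 && !is.unsorted(timeGrid, strictly = TRUE),
            "timeGrid must be strictly increasing and start at 0")
  Cp <- superposeBI(bloodModelParent(model), schedule, timeGrid)
  Cm <- superposeBI(bloodModelMetabolite(model), schedule, timeGrid)
  ratio <- pmax(model$ratioIntercept + model$ratioSlope * timeGrid, 1e-6)
  InputFunctionSet(timeGrid = timeGrid, wholeBlood = (Cp + Cm) / ratio,
                   plasmaParent = Cp, plasmaMetabolite = Cm)
}
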