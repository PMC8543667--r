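#' @include synthetic-mid.R
NULL

#' Fit the plasma-to-whole-blood ratio line
#'
#' Per-sample plasma/whole-blood ratios are fitted with a linear function of
#' time by ordinary least squares (ratio-space regression). Evaluation of
#' the fitted line is clamped at zero.
#'
#' @param samples Data frame with columns \code{time} (minutes),
#'   \code{whole_blood} and \code{plasma} (kBq/mL), e.g. from
#'   \code{\link{readBloodTable}}.
#' @return A list of class \code{"PlasmaRatioFit"} with elements
#'   \code{intercept}, \code{slope} (1/min) and \code{fn}, the clamped
#'   evaluation function r(t).
#' @examples
#' s <- data.frame(time = c(0, 50), whole_blood = c(10, 10),
#'                 plasma = c(10, 12))
#' fitPlasmaRatio(s)$slope   # 0.004/min
#' @export
fitPlasmaRatio <- function(samples) {
  ok <- samples$whole_blood > 0
  if (sum(ok) < 2)
    stop("need at least 2 samples with positive whole-blood activity")
  ratio <- samples$plasma[ok] / samples$whole_blood[ok]
  t <- samples$time[ok]
  cf <- stats::coef(stats::lm(ratio ~ t))
  a <- unname(cf[1]); b <- unname(cf[2])
  structure(list(intercept = a, slope = b,
                 fn = function(time) pmax(0, a + b * time)),
            class = "PlasmaRatioFit")
}

#' @export
print.PlasmaRatioFit <- function(x, ...) {
  cat(sprintf("PlasmaRatioFit: r(t) = %.4g + %.4g * t [1/min], clamped at 0\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Adapt a bolus metabolite-fraction curve to bolus + infusion
#'
#' The literature 3-OMFD fraction is measured after a pure bolus. Under
#' bolus + constant infusion the plasma is a superposition of boluses, so
#' the metabolite fraction is obtained by superposing total and metabolite
#' bolus responses separately: the B+I total is the administration-rate
#' convolution of the unit-bolus total response, the B+I metabolite the same
#' convolution of \code{fBolus * total response}, and the adapted fraction
#' their ratio. The relative change in the area under the fraction curve is
#' reported as a percent reduction.
#'
#' @param fBolus The bolus metabolite fraction, either a function of time
#'   (minutes) or a data frame with \code{time} and \code{fraction}
#'   (linearly interpolated); values must lie in [0, 1].
#' @param schedule An \linkS4class{AdministrationSchedule}.
#' @param timeGrid Uniform evaluation grid, minutes, starting at 0.
#' @param totalBolus Unit-bolus total plasma response: function of time or
#'   data frame (\code{time}, \code{value}). Defaults to the total response
#'   of \code{\link{bloodModel}()}. The fraction adaptation only depends on
#'   its shape, not its scale.
#' @return List with \code{fBI} (adapted fraction on the grid), \code{fn}
#'   (interpolating function), \code{aucReductionPct} (percent reduction of
#'   the fraction AUC relative to the pure bolus) and \code{timeGrid}.
#' @examples
#' ad <- adaptMetaboliteFraction(bolusParentFraction(bloodModel()),
#'                               AdministrationSchedule(),
#'                               seq(0, 50, by = 1/60))
#' ad$aucReductionPct
#' @export
adaptMetaboliteFraction <- function(fBolus, schedule = AdministrationSchedule(),
                                    timeGrid = seq(0, 50, by = 1 / 60),
                                    totalBolus = NULL) {
  fb <- asTimeFunction(fBolus, "fraction")
  fbv <- fb(timeGrid)
  if (any(fbv < -1e-9 | fbv > 1 + 1e-9))
    stop("bolus metabolite fraction must lie in [0, 1]")
  if (is.null(totalBolus)) {
    bm <- bloodModel()
    p <- bloodModelParent(bm); m <- bloodModelMetabolite(bm)
    totalFun <- function(t) p(t) + m(t)
  } else totalFun <- asTimeFunction(totalBolus, "value")
  metFun <- function(t) fb(t) * totalFun(t)
  totBI <- superposeBI(totalFun, schedule, timeGrid)
  metBI <- superposeBI(metFun, schedule, timeGrid)
  fBI <- ifelse(totBI > 0, metBI / totBI, 0)
  aucB <- pracma::trapz(timeGrid, fbv)
  aucBI <- pracma::trapz(timeGrid, fBI)
  list(fBI = fBI,
       fn = function(time) interpConst(timeGrid, fBI, time),
       aucReductionPct = 100 * (1 - aucBI / aucB),
       timeGrid = timeGrid)
}

asTimeFunction <- function(obj, valueCol) {
  if (is.function(obj)) return(obj)
  if (is.data.frame(obj)) {
    stopIfNot(all(c("time", valueCol) %in% names(obj)),
              sprintf("data frame must have columns 'time' and '%s'", valueCol))
    return(function(t) interpConst(obj$time, obj[[valueCol]], t))
  }
  stop("expected a function or a data frame")
}

#' Assemble parent and metabolite input functions from blood samples
#'
#' The whole-blood curve is linearly interpolated onto the time grid
#' (constant extrapolation after the last sample), multiplied by the fitted
#' plasma-to-whole-blood ratio to give total plasma, and split into parent
#' and metabolite with the adapted 3-OMFD fraction: parent = total x
#' (1 - fBI), metabolite = total x fBI.
#'
#' @param samples Blood sample data frame (\code{time} minutes,
#'   \code{whole_blood}, \code{plasma} in kBq/mL).
#' @param ratioFit A \code{"PlasmaRatioFit"} from \code{\link{fitPlasmaRatio}}.
#' @param fBI Adapted metabolite fraction: function of time, or the list
#'   returned by \code{\link{adaptMetaboliteFraction}}.
#' @param timeGrid Output grid, minutes, starting at 0.
#' @param maxExtrapolation Largest allowed gap (minutes) between the last
#'   sample and the end of the grid.
#' @return An \linkS4class{InputFunctionSet}.
#' @export
assembleInputFunctions <- function(samples, ratioFit, fBI,
                                   timeGrid = seq(0, 50, by = 1 / 60),
                                   maxExtrapolation = 5) {
  if (max(timeGrid) > max(samples$time) + maxExtrapolation)
    stop(sprintf("time grid extends %.1f min beyond the last blood sample (allowed: %g)",
                 max(timeGrid) - max(samples$time), maxExtrapolation))
  fn <- if (is.function(fBI)) fBI else fBI$fn
  wb <- interpConst(samples$time, samples$whole_blood, timeGrid)
  total <- wb * ratioFit$fn(timeGrid)
  f <- pmin(pmax(fn(timeGrid), 0), 1)
  InputFunctionSet(timeGrid = timeGrid, wholeBlood = wb,
                   plasmaParent = total * (1 - f),
                   plasmaMetabolite = total * f)
}
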