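#' @include glm.R
NULL

#' Gjedde-Patlak transformation
#'
#' Maps a tissue curve and the parent plasma input to the Patlak
#' coordinates: normalised time \eqn{x(t) = \int_0^t C_p d\tau / C_p(t)}
#' (minutes) and normalised tissue \eqn{y(t) = C_T(t)/C_p(t)}
#' (dimensionless), both evaluated at frame midpoints. For an irreversibly
#' trapped tracer y becomes linear in x with slope Ki once the reversible
#' compartments have equilibrated.
#'
#' @param tissue Numeric per-frame tissue curve (kBq/mL), or a
#'   single-region \linkS4class{TimeActivityCurve}.
#' @param inputs An \linkS4class{InputFunctionSet} (plasma integral by
#'   trapezoid on its grid).
#' @param frameMid Frame midpoints (minutes); taken from \code{tissue} when
#'   it is a TAC.
#' @return Data frame with columns \code{x}, \code{y}, \code{frameMid}.
#' @export
patlakTransform <- function(tissue, inputs, frameMid = NULL) {
  if (is(tissue, "TimeActivityCurve")) {
    stopIfNot(ncol(activity(tissue)) == 1, "one region at a time")
    frameMid <- frameMid(tissue)
    tissue <- as.numeric(activity(tissue))
  }
  stopIfNot(!is.null(frameMid), "frameMid is required for numeric input")
  grid <- timeGrid(inputs)
  Cp <- plasmaParent(inputs)
  CpMid <- interpConst(grid, Cp, frameMid)
  if (any(CpMid <= 0))
    stop("parent plasma must be positive at all frame midpoints")
  intCp <- cumtrapzv(grid, Cp)
  data.frame(x = interpConst(grid, intCp, frameMid) / CpMid,
             y = tissue / CpMid, frameMid = frameMid)
}

#' Fit the net influx constant from Patlak coordinates
#'
#' Ordinary least squares of y on x over the frames whose midpoint is at or
#' after \code{tStar} (inclusive).
#'
#' @param xy Data frame from \code{\link{patlakTransform}}.
#' @param tStar Start of the linear window, minutes (default 25, half of
#'   the 50-min scan).
#' @return A \linkS4class{PatlakResult}.
#' @examples
#' xy <- data.frame(x = 1:30, y = 0.01 * (1:30) + 0.2, frameMid = 21:50)
#' fitKi(xy)
#' @export
fitKi <- function(xy, tStar = 25) {
  sel <- xy$frameMid >= tStar
  if (sum(sel) < 3)
    stop("fewer than 3 frames at or after t*")
  fit <- stats::lm(y ~ x, data = xy[sel, ])
  cf <- stats::coef(fit)
  ss <- sum((xy$y[sel] - mean(xy$y[sel]))^2)
  r2 <- if (ss > 0) 1 - sum(stats::resid(fit)^2) / ss else 1
  PatlakResult(Ki = unname(cf[2]), intercept = unname(cf[1]), tStar = tStar,
               nPoints = as.integer(sum(sel)), r2 = r2)
}

## mean parent plasma over a block
blockMeanCp <- function(inputs, onset, offset) {
  grid <- timeGrid(inputs)
  sel <- grid >= onset & grid <= offset
  mean(plasmaParent(inputs)[sel])
}

#' Task-specific net influx constants from GLM coefficients
#'
#' Converts each fitted task-ramp coefficient (kBq/mL per frame) into a net
#' influx constant by dividing by the frame length and the mean parent
#' plasma concentration over the corresponding block(s):
#' \eqn{K_{i,j} = \beta_j / (\Delta t \, \bar{C}_{p,j})}. For a combined
#' (proof-of-concept) task regressor the mean plasma over all blocks is
#' used.
#'
#' @param glmFit A \linkS4class{GlmFit}.
#' @param inputs An \linkS4class{InputFunctionSet}.
#' @param task The \linkS4class{TaskSchedule} the design was built from.
#' @return Named numeric vector, one task Ki (1/min) per task regressor.
#' @export
taskKi <- function(glmFit, inputs, task) {
  des <- glmFit@design
  fl <- gridStep((des@frameStart + des@frameEnd) / 2)
  vapply(seq_along(des@taskColumns), function(k) {
    col <- des@taskColumns[k]
    blocks <- des@blockMap[[colnames(des@design)[col]]]
    cpb <- mean(vapply(blocks, function(j)
      blockMeanCp(inputs, task@blockOnsets[j], blockEnd(task)[j]),
      numeric(1)))
    if (cpb <= 0) stop("non-positive mean parent plasma over a task block")
    unname(glmFit@beta[col]) / (fl * cpb)
  }, numeric(1)) |>
    stats::setNames(colnames(des@design)[des@taskColumns])
}

#' Task-specific Ki via the Patlak-difference construction
#'
#' Cross-check for \code{\link{taskKi}}: for each task regressor, the
#' fitted block uptake rate is extended over the whole scan (a global ramp
#' of \eqn{\beta_j} kBq/mL per frame added to the baseline component, i.e.
#' the counterfactual of the task condition being sustained), and the task
#' Ki is the Patlak slope of that curve minus the slope of the baseline
#' component alone. Under the model both routes coincide.
#'
#' @inheritParams taskKi
#' @param tStar Patlak window start, minutes.
#' @return Named numeric vector of task Ki (1/min).
#' @export
patlakDiffTaskKi <- function(glmFit, inputs, task, tStar = 25) {
  des <- glmFit@design
  mid <- (des@frameStart + des@frameEnd) / 2
  base <- glmFit@components[, "baseline"]
  slopeOf <- function(curve)
    fitKi(patlakTransform(curve, inputs, frameMid = mid), tStar = tStar)@Ki
  s0 <- slopeOf(base)
  globalRamp <- seq_along(mid) - 0.5      # 1 kBq/mL per frame over the scan
  out <- vapply(des@taskColumns, function(col) {
    slopeOf(base + glmFit@beta[col] * globalRamp) - s0
  }, numeric(1))
  stats::setNames(out, colnames(des@design)[des@taskColumns])
}

#' Baseline net influx constant from the GLM baseline component
#'
#' Applies the Patlak plot to the reconstructed baseline component
#' (baseline regressor times its coefficient) of a fitted GLM.
#'
#' @inheritParams patlakDiffTaskKi
#' @return A \linkS4class{PatlakResult}.
#' @export
baselineKi <- function(glmFit, inputs, tStar = 25) {
  des <- glmFit@design
  mid <- (des@frameStart + des@frameEnd) / 2
  fitKi(patlakTransform(glmFit@components[, "baseline"], inputs,
                        frameMid = mid), tStar = tStar)
}

#' Performance-weighted condition averages and percent signal change
#'
#' Averages per-block task Ki into condition-specific values using the
#' task-performance weights (actual gain over possible gain for gain
#' blocks; loss avoided over maximum avoidable for loss blocks):
#' \eqn{K_i^{cond} = \sum w_j K_{i,j} / \sum w_j}. The unweighted variant
#' and percent signal change from baseline are included.
#'
#' @param kiBlocks Numeric, task Ki per block (1/min).
#' @param conditions Condition label per block (\code{"gain"}/\code{"loss"}
#'   or \code{"mixed"}).
#' @param kiBaseline Baseline Ki (1/min).
#' @param weights Per-block weights in [0, 1], from
#'   \code{\link{performanceWeights}}; NULL for equal weights.
#' @return A \linkS4class{ConditionKi}.
#' @examples
#' weightAndAverage(c(0.010, 0.016), c("gain", "gain"), 0.009,
#'                  weights = c(0.8, 0.4))
#' @export
weightAndAverage <- function(kiBlocks, conditions, kiBaseline,
                             weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(kiBlocks))
  stopIfNot(length(kiBlocks) == length(conditions) &&
              length(kiBlocks) == length(weights),
            "kiBlocks, conditions and weights must align")
  conds <- unique(conditions)
  wavg <- uavg <- stats::setNames(numeric(length(conds)), conds)
  for (cc in conds) {
    sel <- conditions == cc
    if (sum(weights[sel]) <= 0)
      stop(sprintf("all-zero weights in condition '%s'", cc))
    wavg[cc] <- sum(weights[sel] * kiBlocks[sel]) / sum(weights[sel])
    uavg[cc] <- mean(kiBlocks[sel])
  }
  ConditionKi(KiBaseline = kiBaseline, KiBlock = kiBlocks,
              weights = weights, conditions = conditions,
              KiCondition = wavg, KiConditionUnweighted = uavg,
              PSC = percentSignalChange(wavg, kiBaseline),
              PSCUnweighted = percentSignalChange(uavg, kiBaseline))
}

#' Percent signal change from baseline
#'
#' \eqn{PSC = K_{i,task} / K_{i,baseline} \times 100}.
#'
#' @param kiTask Task-specific Ki (1/min), scalar or vector.
#' @param kiBaseline Baseline Ki (1/min), positive.
#' @return Percent, same shape as \code{kiTask}.
#' @examples
#' percentSignalChange(0.014, 0.009)
#' @export
percentSignalChange <- function(kiTask, kiBaseline) {
  if (kiBaseline <= 0) stop("baseline Ki must be positive for PSC")
  kiTask / kiBaseline * 100
}
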