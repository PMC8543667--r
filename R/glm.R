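#' @include metabolite.R
NULL

#' Zero-phase temporal low-pass filter
#'
#' Attenuates fast temporal components of a framed signal. The filter is
#' realised in the frequency domain after even (mirror) extension, giving
#' zero phase shift and no wrap-around of the strongly trending PET signal.
#' The amplitude response is a raised cosine: unity below
#' \eqn{0.3 f_c}, zero above the upper transition edge, and exactly
#' half-power (\eqn{1/\sqrt{2}}) at the cutoff frequency
#' \eqn{f_c = 1/\mathrm{cutoffPeriod}}. DC gain is exactly 1.
#'
#' @param x Numeric vector, or a single/multi-region
#'   \linkS4class{TimeActivityCurve} with uniform frames.
#' @param cutoffPeriod Cutoff period, minutes (default 2.5: components with
#'   shorter periods are suppressed).
#' @param frameLengthMin Frame length in minutes (taken from the TAC when
#'   \code{x} is one).
#' @return Filtered object of the same type as \code{x}.
#' @examples
#' lowpassFilter(rep(5, 50), frameLengthMin = 1)  # constant is unchanged
#' @export
lowpassFilter <- function(x, cutoffPeriod = 2.5, frameLengthMin = NULL) {
  if (is(x, "TimeActivityCurve")) {
    fl <- frameLength(x)
    if (max(fl) - min(fl) > 1e-9)
      stop("low-pass filtering requires a uniform frame schedule")
    act <- apply(activity(x), 2, lowpassFilter,
                 cutoffPeriod = cutoffPeriod, frameLengthMin = fl[1])
    act <- matrix(act, nrow = nrow(activity(x)),
                  dimnames = dimnames(activity(x)))
    return(TimeActivityCurve(frameStart = frameStart(x),
                             frameEnd = frameEnd(x), activity = act,
                             groundTruth = x@groundTruth))
  }
  stopIfNot(!is.null(frameLengthMin), "frameLengthMin is required for vectors")
  n <- length(x)
  if (n < 4) return(x)
  ext <- c(x, rev(x))                     # even extension, period 2n
  H <- filterGain(fftFreq(2 * n, frameLengthMin), 1 / cutoffPeriod)
  Re(stats::fft(stats::fft(ext) * H, inverse = TRUE))[seq_len(n)] / (2 * n)
}

## two-sided frequency axis (cycles/min) of an n-point FFT at spacing dt
fftFreq <- function(n, dt) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k / (n * dt)
}

## raised-cosine amplitude response with half-power at fc
filterGain <- function(f, fc) {
  f1 <- 0.3 * fc
  theta <- acos(sqrt(2) - 1)              # H(fc) = 1/sqrt(2)
  f2 <- f1 + (fc - f1) * pi / theta
  af <- abs(f)
  H <- numeric(length(f))
  H[af <= f1] <- 1
  tr <- af > f1 & af < f2
  H[tr] <- 0.5 * (1 + cos(pi * (af[tr] - f1) / (f2 - f1)))
  H
}

#' Build the baseline regressor from gray-matter TACs
#'
#' The baseline time course is the unweighted mean of all gray-matter
#' series, excluding task-responsive regions (in the imaging experiment this
#' exclusion comes from an independent activation map; here it is an
#' explicit label list).
#'
#' @param tacs A multi-region \linkS4class{TimeActivityCurve} (gray-matter
#'   set).
#' @param exclude Character vector of region names to exclude.
#' @return Numeric baseline regressor (kBq/mL per frame).
#' @export
buildBaselineRegressor <- function(tacs, exclude = character(0)) {
  keep <- setdiff(regionNames(tacs), exclude)
  if (length(keep) == 0)
    stop("no gray-matter series left after exclusion")
  rowMeans(activity(tacs)[, keep, drop = FALSE])
}

#' Summarise six motion parameters into one regressor
#'
#' Returns the first principal component scores of the column-centered
#' motion-parameter matrix. The sign is fixed so that the regressor
#' correlates positively with the motion column of largest variance. With
#' zero motion variance a zero regressor is returned with a warning.
#'
#' @param motion Matrix or data frame, frames x 6 (three translations, three
#'   rotations; units irrelevant, the GLM scales it).
#' @return Numeric vector of PC1 scores.
#' @export
motionRegressor <- function(motion) {
  motion <- as.matrix(motion)
  stopIfNot(nrow(motion) >= 2, "need at least 2 frames of motion parameters")
  v <- apply(motion, 2, stats::var)
  if (all(v < .Machine$double.eps)) {
    warning("constant motion parameters: returning a zero regressor")
    return(numeric(nrow(motion)))
  }
  pc <- stats::prcomp(motion, center = TRUE, scale. = FALSE)
  s <- pc$x[, 1]
  ref <- motion[, which.max(v)]
  if (stats::cor(s, ref) < 0) s <- -s
  as.numeric(s)
}

## frame-averaged ramp-and-hold regressor for frames covering blocks:
## slope 1 kBq/mL per frame inside the block (frame-average convention:
## the i-th in-block frame takes value i - 0.5), 0 before, held after.
rampRegressor <- function(frameMid, onset, offset) {
  v <- numeric(length(frameMid))
  inb <- frameMid > onset & frameMid < offset
  nIn <- sum(inb)
  v[inb] <- seq_len(nIn) - 0.5
  v[frameMid >= offset] <- nIn
  v
}

#' Build the functional-PET GLM design
#'
#' One ramp-and-hold regressor per task block (slope exactly 1 kBq/mL per
#' frame inside the block, constant outside), the baseline regressor, and
#' the motion regressor. For proof-of-concept sessions a single task
#' regressor covering all blocks can be requested. Columns are entered
#' as-is (no orthogonalisation); the condition number of the column-scaled
#' design is recorded.
#'
#' @param tacOrFrames A \linkS4class{TimeActivityCurve} or a list with
#'   \code{start}/\code{end} frame times (minutes).
#' @param task A \linkS4class{TaskSchedule}.
#' @param baseline Numeric baseline regressor (one value per frame).
#' @param motion Numeric motion regressor (one value per frame), or NULL to
#'   omit the column.
#' @param combineTask Logical; sum all block ramps into a single task
#'   regressor (proof-of-concept design).
#' @return A \linkS4class{GlmDesign}.
#' @export
buildGlmDesign <- function(tacOrFrames, task, baseline, motion = NULL,
                           combineTask = FALSE) {
  if (is(tacOrFrames, "TimeActivityCurve"))
    frames <- list(start = frameStart(tacOrFrames), end = frameEnd(tacOrFrames))
  else frames <- tacOrFrames
  mid <- (frames$start + frames$end) / 2
  B <- nBlocks(task)
  ramps <- vapply(seq_len(B), function(j)
    rampRegressor(mid, task@blockOnsets[j], blockEnd(task)[j]),
    numeric(length(mid)))
  if (combineTask) {
    X <- cbind(task = rowSums(ramps))
    blockMap <- list(task = seq_len(B))
  } else {
    colnames(ramps) <- paste0("task", seq_len(B))
    X <- ramps
    blockMap <- as.list(stats::setNames(seq_len(B), colnames(ramps)))
  }
  stopIfNot(length(baseline) == length(mid),
            "baseline regressor must have one value per frame")
  X <- cbind(X, baseline = baseline)
  if (!is.null(motion)) {
    stopIfNot(length(motion) == length(mid),
              "motion regressor must have one value per frame")
    X <- cbind(X, motion = motion)
  }
  taskCols <- seq_len(ncol(X) - 1 - !is.null(motion))
  sc <- apply(X, 2, function(cc) if (max(abs(cc)) > 0) max(abs(cc)) else 1)
  kap <- kappa(sweep(X, 2, sc, "/"), exact = TRUE)
  GlmDesign(design = X, frameStart = frames$start, frameEnd = frames$end,
            taskColumns = as.integer(taskCols), blockMap = blockMap,
            conditionNumber = kap)
}

#' Fit the functional-PET GLM by ordinary least squares
#'
#' Separates a TAC into per-block task, baseline and motion components.
#' When a filter is supplied, the same zero-phase low-pass operator is
#' applied to the response and to every design column before the fit, so
#' that filtering does not bias coefficients of signals generated by the
#' design; the returned components are reconstructed from the unfiltered
#' design columns.
#'
#' @param tac Single-region \linkS4class{TimeActivityCurve} or numeric
#'   vector.
#' @param design A \linkS4class{GlmDesign}.
#' @param filter \code{NULL}, or the cutoff period in minutes to apply
#'   \code{\link{lowpassFilter}} to both sides of the regression.
#' @return A \linkS4class{GlmFit}.
#' @examples
#' frames <- list(start = 0:49, end = 1:50)
#' task <- TaskSchedule()
#' base <- 10 + 0.5 * (0:49)
#' d <- buildGlmDesign(frames, task, base)
#' y <- base + 0.5 * designMatrix(d)[, "task2"]
#' coef(fitGlm(y, d))
#' @export
fitGlm <- function(tac, design, filter = NULL) {
  y <- if (is(tac, "TimeActivityCurve")) {
    stopIfNot(ncol(activity(tac)) == 1, "fitGlm expects a single region")
    as.numeric(activity(tac))
  } else as.numeric(tac)
  X <- design@design
  stopIfNot(length(y) == nrow(X), "TAC and design disagree in frame count")
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design matrix")
  if (!is.null(filter)) {
    fl <- gridStep((design@frameStart + design@frameEnd) / 2)
    yF <- lowpassFilter(y, cutoffPeriod = filter, frameLengthMin = fl)
    XF <- apply(X, 2, lowpassFilter, cutoffPeriod = filter,
                frameLengthMin = fl)
  } else { yF <- y; XF <- X }
  qrX <- qr(XF)
  beta <- stats::setNames(as.numeric(qr.coef(qrX, yF)), colnames(X))
  residFit <- as.numeric(yF - XF %*% beta)
  comps <- sweep(X, 2, beta, "*")
  ## reconstruction residual against the stored (unfiltered) design keeps
  ## the identity design %*% beta + residuals == response exact
  GlmFit(design = design, beta = beta, components = comps,
         residuals = as.numeric(yF - X %*% beta),
         sigma2 = sum(residFit^2) / max(1, length(y) - ncol(X)),
         response = yF)
}
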