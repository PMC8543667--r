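#' @include synthetic-tac.R
NULL

#' Simulate an adaptive-staircase monetary incentive delay session
#'
#' Reproduces the task logic used during scanning: on every trial a cue
#' announces a signed amount (positive = potential gain, negative =
#' potential loss) and the subject must respond before an individually
#' adapted time limit. The limit follows a one-up/one-down staircase (after
#' a hit it is shortened by \code{staircaseStep} ms, after a miss
#' lengthened), which holds the hit probability near 0.5. To separate the
#' two monetary conditions, a limit bias is injected at the beginning and at
#' the middle of each block: \code{+manipulationBias} ms in gain blocks
#' (responding becomes easy, gains are realised) and \code{-manipulationBias}
#' in loss blocks (losses are realised). \code{"mixed"} blocks get the
#' positive bias in their first half and the negative bias in the second.
#'
#' Outcome rules: a hit on a gain cue pays \code{+amount}; a miss pays 0; a
#' hit on a loss cue avoids the loss (0); a miss costs \code{-|amount|}.
#'
#' @param rtFun Function mapping a signed amount (currency units) to the
#'   mean reaction time in ms (the subject model).
#' @param rtSd Trial-to-trial Gaussian RT standard deviation, ms.
#' @param nBlocks Number of task blocks.
#' @param trialsPerBlock Trials per block; must be even (the manipulation
#'   switches or is refreshed at the block middle).
#' @param amounts Signed amount levels, currency units; each block presents
#'   a shuffled whole number of repetitions of this set.
#' @param conditions Condition label per block (\code{"gain"},
#'   \code{"loss"}, \code{"mixed"}); default alternates gain/loss.
#' @param initialLimit Starting time limit, ms (the individually determined
#'   initial reaction time).
#' @param staircaseStep Staircase step, ms per trial.
#' @param manipulationBias Limit bias applied at the start and middle of
#'   each block, ms; 0 disables the manipulation.
#' @param seed Integer seed; the log is fully replayable from it.
#' @return A data frame (trial log) with columns \code{trial_index},
#'   \code{block}, \code{condition}, \code{amount}, \code{time_limit},
#'   \code{reaction_time}, \code{hit}, \code{balance_delta}.
#' @examples
#' log <- simulateMidSession(seed = 1)
#' mean(log$hit)
#' @export
simulateMidSession <- function(rtFun = function(amount) 500 - 2 * amount,
                               rtSd = 80, nBlocks = 4, trialsPerBlock = 24,
                               amounts = c(-3, -2, -1, 1, 2, 3),
                               conditions = NULL,
                               initialLimit = 500, staircaseStep = 15,
                               manipulationBias = 120, seed = NULL) {
  if (trialsPerBlock %% 2 != 0)
    stop("trialsPerBlock must be even: the manipulation switches at the block middle")
  if (trialsPerBlock %% length(amounts) != 0)
    stop("trialsPerBlock must be a multiple of the number of amount levels")
  if (is.null(conditions))
    conditions <- rep(c("gain", "loss"), length.out = nBlocks)
  stopIfNot(length(conditions) == nBlocks,
            "need one condition label per block")
  stopIfNot(all(conditions %in% c("gain", "loss", "mixed")),
            "conditions must be 'gain', 'loss' or 'mixed'")
  if (!is.null(seed)) set.seed(seed)
  limit <- initialLimit
  rows <- vector("list", nBlocks * trialsPerBlock)
  k <- 0L
  for (b in seq_len(nBlocks)) {
    amt <- sample(rep(amounts, trialsPerBlock / length(amounts)))
    for (i in seq_len(trialsPerBlock)) {
      half2 <- i > trialsPerBlock / 2
      if (i == 1L || i == trialsPerBlock / 2 + 1L) {
        bias <- switch(conditions[b],
                       gain = manipulationBias,
                       loss = -manipulationBias,
                       mixed = if (half2) -manipulationBias else manipulationBias)
        limit <- limit + bias
      }
      rt <- max(1, rtFun(amt[i]) + stats::rnorm(1, 0, rtSd))
      hit <- rt <= limit
      delta <- if (amt[i] > 0) {
        if (hit) amt[i] else 0
      } else {
        if (hit) 0 else amt[i]
      }
      k <- k + 1L
      rows[[k]] <- data.frame(trial_index = k, block = b,
                              condition = conditions[b], amount = amt[i],
                              time_limit = limit, reaction_time = rt,
                              hit = hit, balance_delta = delta)
      limit <- limit + if (hit) -staircaseStep else staircaseStep
    }
  }
  do.call(rbind, rows)
}

#' Accumulated balance of a trial log
#'
#' Sums the per-trial balance changes, overall or per condition.
#'
#' @param trialLog A trial log from \code{\link{simulateMidSession}} (or
#'   read with \code{\link{readTrialLog}}).
#' @param by \code{"total"}, \code{"condition"} or \code{"block"}.
#' @return Numeric (named for grouped summaries), currency units.
#' @export
accumulatedBalance <- function(trialLog, by = c("total", "condition", "block")) {
  by <- match.arg(by)
  switch(by,
         total = sum(trialLog$balance_delta),
         condition = tapply(trialLog$balance_delta, trialLog$condition, sum),
         block = tapply(trialLog$balance_delta, trialLog$block, sum))
}

#' Task-performance weights per block
#'
#' Implements the performance weighting used when averaging per-block net
#' influx constants: for gain blocks the weight is actual gain divided by
#' the maximum possible gain; for loss blocks the amount of loss avoided
#' divided by the maximum avoidable loss. Mixed blocks combine both rules
#' (realised-plus-avoided over total at stake).
#'
#' @param trialLog A trial log from \code{\link{simulateMidSession}}.
#' @return Numeric vector of weights in [0, 1], one per block.
#' @export
performanceWeights <- function(trialLog) {
  blocks <- sort(unique(trialLog$block))
  vapply(blocks, function(b) {
    tl <- trialLog[trialLog$block == b, ]
    gains <- tl$amount > 0
    won <- sum(tl$amount[gains & tl$hit])
    possible <- sum(tl$amount[gains])
    avoided <- sum(-tl$amount[!gains & tl$hit])
    avoidable <- sum(-tl$amount[!gains])
    cond <- tl$condition[1]
    num <- switch(cond, gain = won, loss = avoided, mixed = won + avoided)
    den <- switch(cond, gain = possible, loss = avoidable,
                  mixed = possible + avoidable)
    if (den <= 0) stop("block without any money at stake for its condition")
    num / den
  }, numeric(1))
}
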