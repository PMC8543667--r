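#' @include synthetic-session.R
NULL

#' Run the full quantification pipeline
#'
#' Ties together the analysis chain for one session: assemble parent and
#' metabolite input functions from the blood samples; fit the one-tissue
#' model on the reference region with task/motion nuisance terms; estimate
#' and subtract the 3-OMFD brain component and the fixed whole-blood
#' component; build the GLM design (task ramps, gray-matter baseline,
#' motion PC1) and fit each target region with the zero-phase low-pass
#' filter applied to both sides; convert the separated components to net
#' influx constants (task Ki from the ramp coefficients, baseline Ki from
#' the Patlak plot of the baseline component); weight blocks by task
#' performance and report condition Ki and percent signal change.
#'
#' @param config A \linkS4class{RunConfig}.
#' @param tacs Multi-region \linkS4class{TimeActivityCurve} (or a TAC table
#'   path) containing the target, gray and reference regions.
#' @param bloodSamples Blood sample data frame (or table path).
#' @param motion Frames x 6 motion-parameter matrix (or table path).
#' @param trialLog MID trial log (or CSV path); NULL gives equal condition
#'   weights.
#' @param fBolus Literature bolus 3-OMFD fraction curve (function or data
#'   frame with \code{time}, \code{fraction}); default: the package blood
#'   model's unit-bolus fraction.
#' @param totalBolus Unit-bolus total plasma response used to adapt the
#'   fraction to bolus + infusion (function or data frame); default: the
#'   package blood model.
#' @return List of class \code{"FpetResults"}: \code{table} (one row per
#'   target region), \code{conditionKi} (list of
#'   \linkS4class{ConditionKi}), \code{glmFits}, \code{referenceFit},
#'   \code{inputs}, \code{qc}, \code{provenance}.
#' @examples
#' ses <- simulateSession(fpetConfig(seed = 1L))
#' res <- runQuantification(fpetConfig(seed = 1L), ses$tacs,
#'                          ses$bloodSamples, ses$motion, ses$trialLog)
#' res$table
#' @export
runQuantification <- function(config, tacs, bloodSamples, motion,
                              trialLog = NULL, fBolus = NULL,
                              totalBolus = NULL) {
  validObject(config)
  if (is.character(tacs)) tacs <- readTacTable(tacs)
  if (is.character(bloodSamples)) bloodSamples <- readBloodTable(bloodSamples)
  if (is.character(motion)) motion <- readMotionTable(motion)
  if (is.character(trialLog)) trialLog <- readTrialLog(trialLog)
  need <- c(config@targetRegions, config@referenceRegion, config@grayRegions)
  missing <- setdiff(need, regionNames(tacs))
  if (length(missing))
    stop("TACs lack required regions: ", paste(missing, collapse = ", "))

  ## --- blood: ratio fit, metabolite-fraction adaptation, assembly -------
  grid <- seq(0, config@scanDuration, by = 1 / 60)
  ratioFit <- fitPlasmaRatio(bloodSamples)
  if (is.null(fBolus)) fBolus <- bolusParentFraction(bloodModel())
  adapted <- adaptMetaboliteFraction(fBolus, config@admin, grid,
                                     totalBolus = totalBolus)
  inputs <- assembleInputFunctions(bloodSamples, ratioFit, adapted, grid)

  ## --- reference fit with task/motion nuisance --------------------------
  frames <- list(start = frameStart(tacs), end = frameEnd(tacs))
  mid <- (frames$start + frames$end) / 2
  motionPc <- motionRegressor(motion)
  B <- nBlocks(config@task)
  ramps <- vapply(seq_len(B), function(j)
    rampRegressor(mid, config@task@blockOnsets[j], blockEnd(config@task)[j]),
    numeric(length(mid)))
  if (config@combineTask) ramps <- matrix(rowSums(ramps), ncol = 1)
  nuisance <- cbind(ramps, motionPc)
  refFit <- fitReference1TC(tacs[config@referenceRegion], inputs,
                            input = "total", vB = config@vB,
                            nuisance = nuisance)

  ## --- metabolite and blood correction ----------------------------------
  omfd <- estimateOmfdTissue(refFit, inputs, frames)
  corrected <- removeBloodComponent(correctTacs(tacs, omfd, config@vB),
                                    inputs, config@vB)
  negFrac <- attr(correctTacs(tacs, omfd, config@vB), "negativeFraction")

  ## --- GLM and influx constants -----------------------------------------
  baseReg <- buildBaselineRegressor(corrected[config@grayRegions],
                                    exclude = config@excludeFromBaseline)
  design <- buildGlmDesign(frames, config@task, baseReg, motionPc,
                           combineTask = config@combineTask)
  weights <- if (!is.null(trialLog)) performanceWeights(trialLog) else NULL
  conditions <- config@task@blockCondition
  glmFits <- list(); condKi <- list(); rows <- list()
  for (rg in config@targetRegions) {
    gf <- fitGlm(corrected[rg], design, filter = config@filterCutoff)
    tki <- taskKi(gf, inputs, config@task)
    bki <- baselineKi(gf, inputs, tStar = config@tStar)
    if (config@combineTask) {
      ck <- weightAndAverage(unname(tki), "mixed", bki@Ki,
                             weights = if (is.null(weights)) NULL
                                       else mean(weights))
    } else {
      ck <- weightAndAverage(unname(tki), conditions, bki@Ki,
                             weights = weights)
    }
    glmFits[[rg]] <- gf; condKi[[rg]] <- ck
    row <- data.frame(region = rg, Ki_baseline = bki@Ki,
                      patlak_r2 = bki@r2, check.names = FALSE)
    for (cc in names(ck@KiCondition)) {
      row[[paste0("Ki_", cc)]] <- ck@KiCondition[[cc]]
      row[[paste0("Ki_", cc, "_unweighted")]] <- ck@KiConditionUnweighted[[cc]]
      row[[paste0("PSC_", cc)]] <- ck@PSC[[cc]]
    }
    if (all(c("gain", "loss") %in% names(ck@KiCondition))) {
      row$Ki_gain_minus_loss <- ck@KiCondition[["gain"]] - ck@KiCondition[["loss"]]
      row$PSC_gain_minus_loss <- ck@PSC[["gain"]] - ck@PSC[["loss"]]
    }
    rows[[rg]] <- row
  }
  qc <- list(referenceFit = c(K1 = refFit@K1ref, k2 = refFit@k2ref,
                              residRms = refFit@residRms),
             designConditionNumber = design@conditionNumber,
             negativeCorrectedFraction = negFrac,
             metaboliteAucReductionPct = adapted$aucReductionPct,
             plasmaRatio = c(intercept = ratioFit$intercept,
                             slope = ratioFit$slope),
             blockWeights = weights)
  prov <- list(configHash = configHash(config), seed = config@seed,
               package = as.character(utils::packageVersion("fpetdopa")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  structure(list(table = do.call(rbind, rows), conditionKi = condKi,
                 glmFits = glmFits, referenceFit = refFit, inputs = inputs,
                 design = design, qc = qc, provenance = prov),
            class = "FpetResults")
}

#' @export
print.FpetResults <- function(x, ...) {
  cat("fPET quantification results\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("reference fit: K1=%.4g, k2=%.4g (RMS %.3g kBq/mL)\n",
              x$qc$referenceFit["K1"], x$qc$referenceFit["k2"],
              x$qc$referenceFit["residRms"]))
  invisible(x)
}

#' Behavioral analysis of MID trial logs
#'
#' Mean-centers reaction times within blocks, fits the stepwise polynomial
#' RT-versus-amount model pooled across subjects, summarises accumulated
#' gain and loss per subject, and (when a group factor is given) runs the
#' Holm-corrected group tests on accumulated amounts.
#'
#' @param trialLogs A single trial log, or a named list of per-subject
#'   trial logs.
#' @param groups Optional named character vector mapping subject names to
#'   group labels (e.g. \code{c(s1 = "men", s2 = "women")}).
#' @param entryAlpha Entry threshold of the stepwise fit.
#' @return List with \code{model} (the pooled \code{"RtModel"}),
#'   \code{subjectModels} (per-subject OLS refits of the selected terms),
#'   \code{balance} (per subject x condition), \code{tests} (group tests or
#'   NULL).
#' @export
behaviorAnalysis <- function(trialLogs, groups = NULL, entryAlpha = 0.05) {
  if (is.data.frame(trialLogs)) trialLogs <- list(subject1 = trialLogs)
  logs <- lapply(names(trialLogs), function(s) {
    tl <- normalizeRt(trialLogs[[s]]); tl$subject <- s; tl
  })
  pooled <- do.call(rbind, logs)
  model <- stepwisePolyfit(pooled$amount, pooled$rt_centered, entryAlpha)
  terms <- c(linear = "a", quadratic = "a2")[model$included]
  subjectModels <- lapply(logs, function(tl) {
    dat <- data.frame(rt = tl$rt_centered, a = tl$amount, a2 = tl$amount^2)
    f <- stats::reformulate(if (length(terms)) terms else "1",
                            response = "rt")
    stats::coef(stats::lm(f, data = dat))
  })
  names(subjectModels) <- names(trialLogs)
  balance <- do.call(rbind, lapply(seq_along(logs), function(i)
    data.frame(subject = names(trialLogs)[i],
               t(accumulatedBalance(logs[[i]], by = "condition")))))
  tests <- NULL
  if (!is.null(groups) && "gain" %in% names(balance)) {
    byGroup <- split(balance$gain, groups[balance$subject])
    tests <- groupTests(byGroup)
  }
  list(model = model, subjectModels = subjectModels, balance = balance,
       tests = tests)
}
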