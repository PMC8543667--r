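#' @include patlak.R
NULL

#' Mean-center reaction times within blocks
#'
#' Because the adaptive staircase shifts absolute reaction times over the
#' session, RTs are normalised by subtracting the mean reaction time of the
#' block each trial belongs to.
#'
#' @param trialLog Trial log with columns \code{block} and
#'   \code{reaction_time} (and optionally \code{subject}, in which case
#'   centering is within subject x block).
#' @return The trial log with an added column \code{rt_centered} (ms).
#' @export
normalizeRt <- function(trialLog) {
  stopIfNot(all(c("block", "reaction_time") %in% names(trialLog)),
            "trial log must have 'block' and 'reaction_time' columns")
  key <- if ("subject" %in% names(trialLog))
    interaction(trialLog$subject, trialLog$block, drop = TRUE)
  else factor(trialLog$block)
  if (any(tabulate(key) == 0) || nrow(trialLog) == 0)
    stop("empty block in trial log")
  means <- stats::ave(trialLog$reaction_time, key)
  trialLog$rt_centered <- trialLog$reaction_time - means
  trialLog
}

#' Stepwise polynomial model of reaction time versus amount
#'
#' Forward selection over the linear and quadratic amount terms: starting
#' from the intercept-only model, the candidate term with the smallest
#' p-value is entered while that p-value is below \code{entryAlpha}; the
#' final model is refitted by OLS with all selected terms. Used to model
#' the relation between (mean-centered) reaction time and the monetary
#' amount at stake.
#'
#' @param amount Signed amounts, currency units.
#' @param rt Mean-centered reaction times, ms.
#' @param entryAlpha Entry threshold for the forward step (default 0.05).
#' @return A list of class \code{"RtModel"}: \code{coefficients} (named
#'   \code{intercept}, \code{linear}, \code{quadratic}; NA when not
#'   selected), \code{included} (character), \code{pValues} (entry p-values
#'   of the selected terms and the final p-values of all terms in the full
#'   model), and \code{fit}, the final \code{lm}.
#' @examples
#' a <- rep(c(-3, -2, -1, 1, 2, 3), 20)
#' m <- stepwisePolyfit(a, 4.31 - 0.95 * a - 1.16 * a^2)
#' m$included
#' @export
stepwisePolyfit <- function(amount, rt, entryAlpha = 0.05) {
  stopIfNot(length(amount) == length(rt), "amount and rt must align")
  if (length(unique(amount)) < 3)
    stop("need at least 3 distinct amount levels")
  dat <- data.frame(rt = rt, a = amount, a2 = amount^2)
  candidates <- c(linear = "a", quadratic = "a2")
  included <- character(0)
  entryP <- c(linear = NA_real_, quadratic = NA_real_)
  sst <- sum((rt - mean(rt))^2)
  repeat {
    remaining <- setdiff(candidates, included)
    if (!length(remaining)) break
    ## numerically perfect fit: the current model already explains the data
    cur <- stats::lm(stats::reformulate(if (length(included)) included
                                        else "1", response = "rt"),
                     data = dat)
    if (sum(stats::resid(cur)^2) <= 1e-16 * max(sst, .Machine$double.eps))
      break
    ps <- vapply(remaining, function(term) {
      f <- stats::reformulate(c(included, term), response = "rt")
      fit <- stats::lm(f, data = dat)
      p <- suppressWarnings(stats::coef(summary(fit))[term, "Pr(>|t|)"])
      if (!is.finite(p)) 1 else p
    }, numeric(1))
    best <- names(ps)[which.min(ps)]
    if (min(ps) >= entryAlpha) break
    included <- c(included, best)
    entryP[names(candidates)[candidates == best]] <- min(ps)
  }
  finalForm <- stats::reformulate(if (length(included)) included else "1",
                                  response = "rt")
  fit <- stats::lm(finalForm, data = dat)
  cf <- stats::coef(fit)
  coefs <- c(intercept = unname(cf["(Intercept)"]),
             linear = if ("a" %in% included) unname(cf["a"]) else NA_real_,
             quadratic = if ("a2" %in% included) unname(cf["a2"]) else NA_real_)
  ## final p-values of all candidate terms in the full two-term model
  full <- stats::lm(rt ~ a + a2, data = dat)
  fullP <- suppressWarnings(stats::coef(summary(full))[, "Pr(>|t|)"])
  structure(list(coefficients = coefs,
                 included = names(candidates)[candidates %in% included],
                 pValues = list(entry = entryP,
                                full = c(linear = unname(fullP["a"]),
                                         quadratic = unname(fullP["a2"]))),
                 fit = fit),
            class = "RtModel")
}

#' @export
print.RtModel <- function(x, ...) {
  cat("RtModel (stepwise polynomial, RT vs amount):\n")
  cat("  included:", if (length(x$included)) paste(x$included, collapse = ", ")
      else "none (intercept only)", "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Holm step-down adjustment
#'
#' Thin wrapper around \code{stats::p.adjust(method = "holm")} kept as the
#' single place the package's declared test families are corrected.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same order as \code{p}.
#' @export
holmAdjust <- function(p) stats::p.adjust(p, method = "holm")

#' Group tests with Holm correction
#'
#' One-sample t-tests against zero per group and, for exactly two groups,
#' the independent-samples t-test of the group difference; all two-sided,
#' Holm-adjusted as one family. Groups whose values are all identical are
#' handled by an exact-equality fast path (t = 0, p = 1 when the common
#' value equals the null).
#'
#' @param values Named list of numeric vectors, one per group.
#' @param mu Null value for the one-sample tests.
#' @param betweenGroups Logical, include the two-sample comparison.
#' @return Data frame with columns \code{test}, \code{estimate}, \code{t},
#'   \code{df}, \code{p}, \code{pHolm}.
#' @examples
#' groupTests(list(men = c(4.2, 4.0, 4.5), women = c(5.6, 5.2, 6.1)))
#' @export
groupTests <- function(values, mu = 0, betweenGroups = TRUE) {
  stopIfNot(is.list(values) && length(values) >= 1 &&
              !is.null(names(values)), "values must be a named list")
  rows <- list()
  oneSample <- function(x, nm) {
    if (length(x) > 1 && stats::sd(x) == 0) {
      est <- mean(x)
      data.frame(test = paste0(nm, " vs ", mu), estimate = est,
                 t = if (est == mu) 0 else Inf * sign(est - mu),
                 df = length(x) - 1, p = as.numeric(est == mu))
    } else {
      tt <- stats::t.test(x, mu = mu)
      data.frame(test = paste0(nm, " vs ", mu),
                 estimate = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }
  }
  for (nm in names(values)) rows[[length(rows) + 1]] <- oneSample(values[[nm]], nm)
  if (betweenGroups && length(values) == 2) {
    x <- values[[1]]; y <- values[[2]]
    if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
      est <- mean(x) - mean(y)
      rows[[length(rows) + 1]] <- data.frame(
        test = paste(names(values), collapse = " vs "), estimate = est,
        t = if (est == 0) 0 else Inf * sign(est),
        df = length(x) + length(y) - 2, p = as.numeric(est == 0))
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        test = paste(names(values), collapse = " vs "),
        estimate = unname(diff(rev(tt$estimate))),
        t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$pHolm <- holmAdjust(out$p)
  rownames(out) <- NULL
  out
}

#' Spearman correlation with exact permutation p-value for small n
#'
#' Rank correlation between a behavioral model term and a task-specific Ki
#' across subjects. For n of at most 9 the two-sided p-value is computed by
#' complete enumeration of all n! orderings (valid with ties through
#' average ranks); for larger n the t approximation is used.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @return List with \code{rho}, \code{p}, \code{n} and \code{method}.
#' @examples
#' kiBehaviorCorrelation(1:5, c(2, 1, 4, 3, 5))
#' @export
kiBehaviorCorrelation <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must be paired")
  n <- length(x)
  stopIfNot(n >= 4, "need at least 4 paired observations")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- permutationsMatrix(n)
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- as.numeric(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

## all permutations of 1..n as a matrix (n! x n); n <= 9
permutationsMatrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutationsMatrix(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
  }
  out
}
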