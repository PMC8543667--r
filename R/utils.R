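#' @include AllClasses.R
NULL

## internal numeric helpers shared across modules

## running trapezoid integral of y over x, same length as x
cumtrapzv <- function(x, y) {
  as.numeric(pracma::cumtrapz(x, y))
}

## linear interpolation with constant extrapolation on both sides
interpConst <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

## frame-average a curve sampled on `grid` over [start, end] frames.
## Trapezoid quadrature within each frame; grid must cover the frames.
frameAverage <- function(grid, values, frameStart, frameEnd) {
  if (min(grid) > min(frameStart) + 1e-9 || max(grid) < max(frameEnd) - 1e-9)
    stop("frames extend beyond the sampling grid")
  ## fast path: frame boundaries on grid points -> differences of the
  ## running trapezoid integral (vectorised, exact trapezoid quadrature)
  bounds <- c(frameStart, frameEnd)
  idx <- findInterval(bounds + 1e-9, grid)
  if (all(abs(grid[idx] - bounds) < 1e-9)) {
    I <- cumtrapzv(grid, values)
    nf <- length(frameStart)
    return((I[idx[nf + seq_len(nf)]] - I[idx[seq_len(nf)]]) /
             (frameEnd - frameStart))
  }
  vapply(seq_along(frameStart), function(f) {
    a <- frameStart[f]; b <- frameEnd[f]
    inside <- grid > a & grid < b
    xs <- c(a, grid[inside], b)
    ys <- c(interpConst(grid, values, a), values[inside],
            interpConst(grid, values, b))
    pracma::trapz(xs, ys) / (b - a)
  }, numeric(1))
}

## one-tissue response K1*exp(-k2 t) convolved with input on a uniform grid;
## exact exponential update assuming the input is linear between grid points
## (trapezoid-in-step). Used both by the simulator and the metabolite fit.
conv1tc <- function(K1, k2, input, dt) {
  n <- length(input)
  out <- numeric(n)
  if (K1 == 0 || n < 2) return(out)
  if (k2 <= 0) { # pure integrator: running trapezoid of the input
    out <- K1 * dt * (cumsum(input) - (input + input[1]) / 2)
    return(out)
  }
  e <- exp(-k2 * dt)
  g <- (1 - e) / k2
  cbar <- 0.5 * (input[-n] + input[-1])
  ## linear recurrence out[i] = e * out[i-1] + K1 * g * cbar[i]
  out[-1] <- stats::filter(K1 * g * cbar, e, method = "recursive")
  out
}

## uniform-grid check
gridStep <- function(grid) {
  d <- diff(grid)
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("a uniform time grid is required here")
  mean(d)
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
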