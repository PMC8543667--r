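# shared fixtures, computed once per test run

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

fixtureInputs <- function() {
  cachedFixture("inputs", makeInputFunctions())
}

# input set with constant parent plasma (metabolite-free, bloodless)
constantPlasmaInputs <- function(cp = 30, tmax = 50, dt = 1 / 60) {
  tg <- seq(0, tmax, by = dt)
  InputFunctionSet(timeGrid = tg, wholeBlood = rep(cp, length(tg)),
                   plasmaParent = rep(cp, length(tg)),
                   plasmaMetabolite = rep(0, length(tg)))
}

# metabolite-free inputs from the default blood model (for parent-only fits)
parentOnlyInputs <- function() {
  cachedFixture("parentOnly", {
    ifs <- makeInputFunctions(model = bloodModel(kMet = 0))
    ifs
  })
}

fixtureSession <- function(key = "default", ...) {
  cachedFixture(paste0("session_", key), simulateSession(...))
}

defaultScene <- function(...) kineticScene(...)

# independent ODE oracle for the 2TC system (piecewise-constant k3),
# solved with deSolve at tight tolerances on the input grid
odeOracle2tc <- function(K1, k2, k3, delta, inputs, task = NULL) {
  grid <- timeGrid(inputs)
  cpf <- stats::approxfun(grid, plasmaParent(inputs), rule = 2)
  B <- if (is.null(task)) 0 else nBlocks(task)
  k3fun <- function(t) {
    if (B == 0) return(k3)
    for (j in seq_len(B)) {
      if (t >= task@blockOnsets[j] && t < blockEnd(task)[j])
        return(k3 + delta[j])
    }
    k3
  }
  rhs <- function(t, y, parms) {
    k3t <- k3fun(t)
    list(c(K1 * cpf(t) - (k2 + k3t) * y[1], k3t * y[1]))
  }
  ev <- if (B > 0) sort(c(task@blockOnsets, blockEnd(task))) else NULL
  out <- deSolve::lsoda(c(C1 = 0, C2 = 0), grid, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12, events = NULL,
                        maxsteps = 50000)
  rowSums(out[, c("C1", "C2")])
}

# independent frame-average oracle (trapezoid over each frame interval)
frameAverageForTest <- function(grid, values, frameStart, frameEnd) {
  vapply(seq_along(frameStart), function(f) {
    a <- frameStart[f]; b <- frameEnd[f]
    inside <- grid > a & grid < b
    xs <- c(a, grid[inside], b)
    ys <- stats::approx(grid, values, xs, rule = 2)$y
    pracma::trapz(xs, ys) / (b - a)
  }, numeric(1))
}
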