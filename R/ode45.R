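#' Adaptive Dormand-Prince 5(4) integration onto a fixed output grid
#'
#' Integrates `dy/dt = f(t, y)` with an embedded Runge-Kutta 5(4) pair
#' (Dormand-Prince coefficients), adaptive step-size control on a mixed
#' absolute/relative error norm, and cubic Hermite dense output sampled on
#' the user-supplied grid. This is the single numerical engine behind every
#' simulation in the package; entry-time diagnostics are threshold crossings,
#' so the default tolerances are deliberately tight.
#'
#' @param f derivative function `f(t, y)` returning a numeric vector of
#'   `length(y0)`.
#' @param y0 numeric vector of initial values at `times[1]`.
#' @param times strictly increasing numeric output grid. Integration runs
#'   from `times[1]` to `times[length(times)]`.
#' @param rtol,atol relative and absolute local error tolerances (both > 0).
#' @param hInit initial step size.
#' @param hMax largest step the controller may take.
#' @param hMin smallest step before the integration is abandoned; a collapse
#'   below this is reported as an error together with the failure time.
#'
#' @return A list with `times` (the grid), `states` (matrix, one row per grid
#'   time, named after `y0` when it has names) and `steps` (number of
#'   accepted steps).
#' @examples
#' sol <- odeRK45(function(t, y) -y, 1, seq(0, 5, by = 0.1))
#' max(abs(sol$states[, 1] - exp(-sol$times)))
#' @export
odeRK45 <- function(f, y0, times, rtol = 1e-8, atol = 1e-10,
                    hInit = 1e-4, hMax = Inf, hMin = 1e-12) {
  stopifnot(is.function(f), is.numeric(y0), length(y0) >= 1)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("'times' must be a strictly increasing grid with at least 2 points")
  }
  if (rtol <= 0 || atol <= 0) stop("solver tolerances must be positive")

  # Dormand-Prince 5(4) tableau
  c2 <- 1 / 5; c3 <- 3 / 10; c4 <- 4 / 5; c5 <- 8 / 9
  a21 <- 1 / 5
  a31 <- 3 / 40; a32 <- 9 / 40
  a41 <- 44 / 45; a42 <- -56 / 15; a43 <- 32 / 9
  a51 <- 19372 / 6561; a52 <- -25360 / 2187; a53 <- 64448 / 6561
  a54 <- -212 / 729
  a61 <- 9017 / 3168; a62 <- -355 / 33; a63 <- 46732 / 5247
  a64 <- 49 / 176; a65 <- -5103 / 18656
  b1 <- 35 / 384; b3 <- 500 / 1113; b4 <- 125 / 192
  b5 <- -2187 / 6784; b6 <- 11 / 84
  e1 <- 71 / 57600; e3 <- -71 / 16695; e4 <- 71 / 1920
  e5 <- -17253 / 339200; e6 <- 22 / 525; e7 <- -1 / 40
  # dense-output coefficients of the 4th-order continuous extension
  d1 <- -12715105075 / 11282082432; d3 <- 87487479700 / 32700410799
  d4 <- -10690763975 / 1880347072; d5 <- 701980252875 / 199316789632
  d6 <- -1453857185 / 822651844; d7 <- 69997945 / 29380423

  t0 <- times[1]; t1 <- times[length(times)]
  n <- length(y0); ng <- length(times)
  out <- matrix(NA_real_, ng, n)
  colnames(out) <- names(y0)
  out[1, ] <- y0
  gi <- 2L

  t <- t0; y <- as.numeric(y0)
  k1 <- f(t, y)
  if (length(k1) != n) stop("f(t, y) must return length(y0) derivatives")
  h <- min(hInit, hMax, t1 - t0)
  nstep <- 0L

  while (t < t1) {
    if (t + h > t1) h <- t1 - t
    k2 <- f(t + c2 * h, y + h * a21 * k1)
    k3 <- f(t + c3 * h, y + h * (a31 * k1 + a32 * k2))
    k4 <- f(t + c4 * h, y + h * (a41 * k1 + a42 * k2 + a43 * k3))
    k5 <- f(t + c5 * h, y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4))
    k6 <- f(t + h, y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 +
                              a65 * k5))
    ynew <- y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6)
    k7 <- f(t + h, ynew)
    err <- h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7)
    sc <- atol + rtol * pmax(abs(y), abs(ynew))
    enorm <- sqrt(mean((err / sc)^2))

    if (!is.finite(enorm)) {
      stop(sprintf("non-finite state encountered at t = %g", t))
    }
    if (enorm <= 1) {
      # accepted: fill grid points inside (t, t + h] with the 4th-order
      # continuous extension of the pair (quartic in the step fraction)
      if (gi <= ng && times[gi] <= t + h + 1e-12 * max(1, abs(t))) {
        dy <- ynew - y
        r3 <- h * k1 - dy
        r4 <- dy - h * k7 - r3
        r5 <- h * (d1 * k1 + d3 * k3 + d4 * k4 + d5 * k5 + d6 * k6 + d7 * k7)
        while (gi <= ng && times[gi] <= t + h + 1e-12 * max(1, abs(t))) {
          s <- (times[gi] - t) / h
          out[gi, ] <- y + s * (dy + (1 - s) * (r3 + s * (r4 + (1 - s) * r5)))
          gi <- gi + 1L
        }
      }
      t <- t + h; y <- ynew; k1 <- k7
      nstep <- nstep + 1L
    }
    h <- h * min(5, max(0.2, 0.9 * enorm^(-0.2)))
    h <- min(h, hMax)
    if (h < hMin) {
      stop(sprintf("step size collapse (h = %g) at t = %g", h, t))
    }
  }
  if (gi <= ng) out[ng, ] <- y  # guard against roundoff at the right end
  list(times = times, states = out, steps = nstep)
}
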