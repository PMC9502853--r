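#' Observer gain set
#'
#' Bundles the four tunables of the robust adaptive observer: the rate-like
#' correction gain `omega` (1/time), the dead-zone half-width `epsilon`
#' (units of the measured state), the convergence gain `k` (dimensionless)
#' and the adaptation gain `gamma`. All must be strictly positive.
#'
#' @param omega correction gain (> 0), 1/time.
#' @param epsilon dead-zone half-width (> 0), units of the measured state.
#'   This is also the half-width of the convergence band of the measured-state
#'   error.
#' @param k convergence gain (> 0).
#' @param gamma adaptation gain (> 0) driving the update of the adaptive
#'   parameter.
#' @return An object of class `observerGains`.
#' @examples
#' observerGains(omega = 8.56, epsilon = 0.0015, k = 40, gamma = 100)
#' @export
observerGains <- function(omega, epsilon, k, gamma) {
  for (nm in c("omega", "epsilon", "k", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive number", nm))
    }
  }
  structure(list(omega = omega, epsilon = epsilon, k = k, gamma = gamma),
            class = "observerGains")
}

#' @export
print.observerGains <- function(x, ...) {
  cat(sprintf(
    "observer gains: omega = %g, epsilon = %g, k = %g, gamma = %g\n",
    x$omega, x$epsilon, x$k, x$gamma))
  invisible(x)
}

#' Observer state
#'
#' The evolving state of the observer: the estimate of the measured state,
#' the estimate of the unknown state, and the adaptive parameter. The
#' adaptive parameter is non-decreasing along any trajectory (its update law
#' is nonnegative), so a negative initial value is rejected.
#'
#' @param x1Hat estimate of the measured state.
#' @param x2Hat estimate of the unknown state.
#' @param thetaHat adaptive parameter (>= 0).
#' @return An object of class `observerState`.
#' @export
observerState <- function(x1Hat = 0, x2Hat = 0, thetaHat = 0) {
  stopifnot(is.numeric(x1Hat), length(x1Hat) == 1,
            is.numeric(x2Hat), length(x2Hat) == 1,
            is.numeric(thetaHat), length(thetaHat) == 1)
  if (thetaHat < 0) stop("'thetaHat' must be nonnegative")
  structure(list(x1Hat = x1Hat, x2Hat = x2Hat, thetaHat = thetaHat),
            class = "observerState")
}

#' Instantaneous plant signals
#'
#' The signals a plant must expose to the observer at a time instant: the
#' measured state `x1`, the known model terms `h1` (in the measured-state
#' dynamics) and `h2` (in the unknown-state dynamics), and the known gain `b`
#' multiplying the unknown state. `b` must be nonzero (bounded away from
#' zero along trajectories).
#'
#' @param x1 measured state value.
#' @param h1 known term of the measured-state dynamics.
#' @param h2 known term of the unknown-state dynamics.
#' @param b known gain of the unknown state in the measured-state dynamics
#'   (nonzero).
#' @return An object of class `plantSignals`.
#' @export
plantSignals <- function(x1, h1 = 0, h2 = 0, b = 1) {
  stopifnot(is.numeric(x1), is.numeric(h1), is.numeric(h2), is.numeric(b))
  if (!is.finite(b) || b == 0) {
    stop("'b' must be nonzero: the unknown-state gain must be bounded away from zero")
  }
  structure(list(x1 = x1, h1 = h1, h2 = h2, b = b), class = "plantSignals")
}

#' Dead-zone operator
#'
#' Continuous piecewise-linear map that is zero on `[-epsilon, epsilon]` and
#' has slope 1 outside. Applied to the measured-state observer error it
#' freezes correction and adaptation inside the error band, preventing
#' chattering on small errors.
#'
#' @param x1Err measured-state observer error (estimate minus measurement);
#'   vectorized.
#' @param epsilon band half-width (> 0).
#' @return Dead-zoned error, same length as `x1Err`.
#' @examples
#' deadzone(c(-0.002, 0, 0.002), epsilon = 0.0015)
#' @export
deadzone <- function(x1Err, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop("'epsilon' must be a single positive number")
  }
  sign(x1Err) * pmax(abs(x1Err) - epsilon, 0)
}

#' Saturation operator
#'
#' Continuous companion of [deadzone()]: linear with slope `1/epsilon` on
#' `[-epsilon, epsilon]` and clamped to +/-1 outside. It scales the adaptive
#' correction term of the observer.
#'
#' @inheritParams deadzone
#' @return Saturated signal in `[-1, 1]`, same length as `x1Err`.
#' @examples
#' saturation(c(-0.003, 0.00075, 0.003), epsilon = 0.0015)
#' @export
saturation <- function(x1Err, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop("'epsilon' must be a single positive number")
  }
  pmin(pmax(x1Err / epsilon, -1), 1)
}

#' Observer time derivatives
#'
#' Right-hand side of the robust adaptive observer. With measured-state error
#' `e1 = x1Hat - x1`, combined gain `K = k + 1/(4 omega)`, dead-zoned error
#' `psi = deadzone(e1, epsilon)` and saturation `sat = saturation(e1,
#' epsilon)`:
#' \deqn{d\hat{x}_1/dt = b \hat{x}_2 - |b| (\omega e_1 + K \psi +
#'   sat \cdot \hat\theta) + h_1}
#' \deqn{d\hat{x}_2/dt = -b \omega (K \psi + sat \cdot \hat\theta) + h_2}
#' \deqn{d\hat\theta/dt = \gamma |b| |\psi| \ge 0}
#' Note the asymmetry: the measured-state correction is scaled by `|b|`, the
#' unknown-state correction by `b` itself (its sign orients the correction).
#' Inside the dead zone the derivatives reduce to the nominal model.
#'
#' @param state an [observerState()].
#' @param signals a [plantSignals()] (scalar signals).
#' @param gains an [observerGains()].
#' @return Named numeric vector `c(x1Hat = , x2Hat = , thetaHat = )` of time
#'   derivatives.
#' @examples
#' observerDerivatives(observerState(1, 0, 0),
#'                     plantSignals(x1 = 1 - 0.003, b = 1),
#'                     observerGains(1, 0.0015, 1, 1))
#' @export
observerDerivatives <- function(state, signals, gains) {
  stopifnot(inherits(state, "observerState"),
            inherits(signals, "plantSignals"),
            inherits(gains, "observerGains"))
  b <- signals$b
  if (b == 0) stop("'b' is zero: unknown-state gain must be bounded away from zero")
  ab <- abs(b)
  e1 <- state$x1Hat - signals$x1
  K <- gains$k + 1 / (4 * gains$omega)
  psi <- deadzone(e1, gains$epsilon)
  sat <- saturation(e1, gains$epsilon)
  c(x1Hat = b * state$x2Hat -
      ab * (gains$omega * e1 + K * psi + sat * state$thetaHat) + signals$h1,
    x2Hat = -b * gains$omega * (K * psi + sat * state$thetaHat) + signals$h2,
    thetaHat = gains$gamma * ab * abs(psi))
}

#' Linear-interpolation signal source from sampled data
#'
#' Adapter turning pre-sampled plant signals into the callable signal source
#' consumed by [integrateObserver()]. Intended for data-driven use where the
#' plant is only available as a time series; for simulation studies prefer
#' co-simulation ([runCoupled()]), which avoids interpolation artifacts.
#'
#' @param data data.frame with columns `t`, `x1`, `b` and optionally `h1`,
#'   `h2` (missing known terms default to 0).
#' @return A function of time returning `list(x1, h1, h2, b)`.
#' @export
signalInterpolator <- function(data) {
  need <- c("t", "x1", "b")
  if (!all(need %in% names(data))) {
    stop("'data' must contain columns t, x1, b")
  }
  tt <- data$t
  if (any(diff(tt) <= 0)) stop("'data$t' must be strictly increasing")
  h1 <- if ("h1" %in% names(data)) data$h1 else rep(0, length(tt))
  h2 <- if ("h2" %in% names(data)) data$h2 else rep(0, length(tt))
  fx1 <- stats::approxfun(tt, data$x1, rule = 2)
  fh1 <- stats::approxfun(tt, h1, rule = 2)
  fh2 <- stats::approxfun(tt, h2, rule = 2)
  fb <- stats::approxfun(tt, data$b, rule = 2)
  function(t) list(x1 = fx1(t), h1 = fh1(t), h2 = fh2(t), b = fb(t))
}

#' Integrate the observer against a signal source
#'
#' Solves the observer equations over a time span, with plant signals
#' evaluated inside the integrator. The signal source is a function of time
#' returning `list(x1, h1, h2, b)` (see [signalInterpolator()] for the
#' sampled-data adapter). The sign of `b` must not flip along the run (the
#' convergence analysis assumes a fixed sign); a flip stops the integration
#' output with an error.
#'
#' @param signals function of time returning `list(x1, h1, h2, b)`.
#' @param gains an [observerGains()].
#' @param tSpan numeric length-2 interval `c(t0, t1)`.
#' @param initial an [observerState()], or `NULL` for the default
#'   `x1Hat = x1(t0)`, `x2Hat = 0`, `thetaHat = 0`.
#' @param gridStep uniform output grid step.
#' @param rtol,atol solver tolerances, see [odeRK45()].
#' @param thetaWarn warn if the adaptive parameter exceeds this threshold
#'   (runaway adaptation); `Inf` disables.
#' @return data.frame with columns `t`, `x1`, `x1_hat`, `x2_hat`,
#'   `theta_hat`, `x1_err`, `b`.
#' @export
integrateObserver <- function(signals, gains, tSpan, initial = NULL,
                              gridStep = 0.001, rtol = 1e-8, atol = 1e-10,
                              thetaWarn = Inf) {
  stopifnot(is.function(signals), inherits(gains, "observerGains"),
            is.numeric(tSpan), length(tSpan) == 2, tSpan[2] > tSpan[1])
  s0 <- signals(tSpan[1])
  if (is.null(initial)) initial <- observerState(x1Hat = s0$x1)
  stopifnot(inherits(initial, "observerState"))

  K <- gains$k + 1 / (4 * gains$omega)
  om <- gains$omega; eps <- gains$epsilon; gam <- gains$gamma
  f <- function(t, y) {
    sg <- signals(t)
    b <- sg$b; ab <- abs(b)
    e1 <- y[1] - sg$x1
    psi <- if (e1 >= eps) e1 - eps else if (e1 <= -eps) e1 + eps else 0
    sat <- if (e1 >= eps) 1 else if (e1 <= -eps) -1 else e1 / eps
    c(b * y[2] - ab * (om * e1 + K * psi + sat * y[3]) + sg$h1,
      -b * om * (K * psi + sat * y[3]) + sg$h2,
      gam * ab * abs(psi))
  }
  times <- seq(tSpan[1], tSpan[2], by = gridStep)
  sol <- odeRK45(f, c(initial$x1Hat, initial$x2Hat, initial$thetaHat),
                 times, rtol = rtol, atol = atol)
  x1 <- vapply(times, function(t) signals(t)$x1, numeric(1))
  bser <- vapply(times, function(t) signals(t)$b, numeric(1))
  if (min(bser) < 0 && max(bser) > 0) {
    stop("sign of 'b' flips along the trajectory; the convergence analysis assumes a fixed sign")
  }
  th <- sol$states[, 3]
  if (is.finite(thetaWarn) && max(th) > thetaWarn) {
    warning(sprintf("adaptive parameter reached %.4g (> thetaWarn = %g): possible runaway adaptation",
                    max(th), thetaWarn))
  }
  data.frame(t = times, x1 = x1, x1_hat = sol$states[, 1],
             x2_hat = sol$states[, 2], theta_hat = th,
             x1_err = sol$states[, 1] - x1, b = bser)
}
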