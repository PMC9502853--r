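#' Synthetic second-order plant
#'
#' A minimal configurable plant in observer canonical form, used for
#' controlled verification studies: `dx1/dt = h1(t) + b x2 + delta1(t)`,
#' `dx2/dt = h2(t) + delta2(t)`. The truth is known by construction, so
#' estimation errors and disturbance ratios are exact.
#'
#' @param b constant nonzero unknown-state gain.
#' @param x10,x20 true initial states.
#' @param h1,h2 known model terms, functions of time (default 0).
#' @param delta1,delta2 disturbance terms, functions of time (default 0).
#' @param label plant label used in reports.
#' @return An object of class `syntheticPlant`.
#' @examples
#' syntheticPlant(b = 1, x20 = 0.5)   # constant unknown state
#' @export
syntheticPlant <- function(b = 1, x10 = 0, x20 = 0,
                           h1 = function(t) 0, h2 = function(t) 0,
                           delta1 = function(t) 0, delta2 = function(t) 0,
                           label = "synthetic") {
  stopifnot(is.numeric(b), length(b) == 1, is.finite(b))
  if (b == 0) stop("'b' must be nonzero")
  stopifnot(is.function(h1), is.function(h2),
            is.function(delta1), is.function(delta2))
  structure(list(b = b, x10 = x10, x20 = x20, h1 = h1, h2 = h2,
                 delta1 = delta1, delta2 = delta2, label = label),
            class = "syntheticPlant")
}

#' Reference observer gains for the bioreactor examples
#'
#' The gain sets used in the two worked examples: dead-zone half-width
#' 0.0015, convergence gain 40, adaptation gain 100, and correction gain
#' 8.56 (uptake-rate sensor) or 9.12 (growth-rate sensor) — the rounded
#' minimizers of the convergence-region half-width for the respective
#' disturbance bounds.
#'
#' @param example `"uptake"` or `"growth"`.
#' @return An [observerGains()].
#' @export
defaultGains <- function(example = c("uptake", "growth")) {
  example <- match.arg(example)
  omega <- switch(example, uptake = 8.56, growth = 9.12)
  observerGains(omega = omega, epsilon = 0.0015, k = 40, gamma = 100)
}

#' Co-simulate plant and observer
#'
#' Integrates the plant and the observer jointly as one augmented system
#' (the observer reads the instantaneous plant state, not an interpolated
#' series). For the Droop examples the plant is the three-state bioreactor
#' and the casting follows the selected example; initial conditions default
#' to the reference runs (plant `x = 0.1, s = 0.01, q = 0.06`; observer
#' `x1Hat = 0.1, x2Hat = 0, thetaHat = 0`). A [syntheticPlant()] may be
#' passed instead of an example name.
#'
#' @param example `"uptake"`, `"growth"`, or a [syntheticPlant()].
#' @param gains an [observerGains()]; defaults to [defaultGains()] for the
#'   named examples (mandatory for synthetic plants).
#' @param params a [droopParameters()] (named examples only).
#' @param tEnd horizon, d.
#' @param gridStep uniform output grid step, d.
#' @param initialObserver an [observerState()], or `NULL` for the example
#'   default (`x1Hat = 0.1` for the Droop examples, `x1Hat = x1(t0)` for
#'   synthetic plants).
#' @param rtol,atol solver tolerances.
#' @return A data.frame of class `observerTrajectory` with the time grid,
#'   plant truth, observer estimates, errors `x1_err`, `x2_err`, the
#'   combined error `z = x2_err - sigma omega x1_err`, the dead-zoned error
#'   `psi_x1`, the gain signal `b` and the disturbance ratios. Attributes:
#'   `gains`, `sigma`, `label`, and `params` for the Droop examples.
#' @examples
#' traj <- runCoupled(syntheticPlant(b = 1, x20 = 0.3),
#'                    observerGains(2, 0.01, 5, 10), tEnd = 5,
#'                    gridStep = 0.01)
#' tail(traj[, c("t", "x2", "x2_hat")], 3)
#' @export
runCoupled <- function(example = c("uptake", "growth"), gains = NULL,
                       params = droopParameters(), tEnd = 20,
                       gridStep = 0.001, initialObserver = NULL,
                       rtol = 1e-8, atol = 1e-10) {
  if (inherits(example, "syntheticPlant")) {
    if (is.null(gains)) stop("'gains' must be supplied for a synthetic plant")
    return(runCoupledSynthetic(example, gains, tEnd, gridStep,
                               initialObserver, rtol, atol))
  }
  example <- match.arg(example)
  if (is.null(gains)) gains <- defaultGains(example)
  stopifnot(inherits(gains, "observerGains"),
            inherits(params, "droopParameters"))
  if (is.null(initialObserver)) initialObserver <- observerState(x1Hat = 0.1)
  p <- params
  om <- gains$omega; eps <- gains$epsilon; gam <- gains$gamma
  K <- gains$k + 1 / (4 * om)
  uptake <- example == "uptake"

  f <- function(t, y) {
    x <- y[1]; s <- max(y[2], 0); q <- y[3]
    mu <- max(0, p$mu_m * (1 - p$Q0 / q))
    rho <- p$rho_m * s / (s + p$K_s)
    on <- if (p$continuous_phase == "before_switch") t < p$D_switch_time
          else t >= p$D_switch_time
    D <- if (on) p$D_amplitude * (1 + sin(2 * pi * t / p$tau_D)) else 0
    si <- p$s_in_bar +
      p$feed_uncertainty_fraction * p$s_in_bar * sin(2 * pi * t / p$tau_si)
    if (uptake) {
      x1 <- s; b <- -x; h1 <- (p$s_in_bar - s) * D
    } else {
      x1 <- x; b <- x; h1 <- -D * x
    }
    ab <- abs(b)
    e1 <- y[4] - x1
    psi <- if (e1 >= eps) e1 - eps else if (e1 <= -eps) e1 + eps else 0
    sat <- if (e1 >= eps) 1 else if (e1 <= -eps) -1 else e1 / eps
    c(mu * x - D * x,
      -rho * x + D * (si - s),
      rho - mu * q,
      b * y[5] - ab * (om * e1 + K * psi + sat * y[6]) + h1,
      -b * om * (K * psi + sat * y[6]),
      gam * ab * abs(psi))
  }
  times <- seq(0, tEnd, by = gridStep)
  y0 <- c(p$x0, p$s0, p$q0, initialObserver$x1Hat, initialObserver$x2Hat,
          initialObserver$thetaHat)
  sol <- odeRK45(f, y0, times, rtol = rtol, atol = atol)

  x <- sol$states[, 1]; s <- pmax(sol$states[, 2], 0); q <- sol$states[, 3]
  mu <- growthRate(q, p); rho <- uptakeRate(s, p)
  D <- dilutionRate(times, p)
  s_in <- p$s_in_bar + feedUncertainty(times, p)
  if (uptake) {
    x1 <- s; x2 <- rho; b <- -x; sigma <- -1L
    ds <- -rho * x + D * (s_in - s)
    delta1 <- D * feedUncertainty(times, p)
    delta2 <- p$rho_m * p$K_s / (s + p$K_s)^2 * ds
  } else {
    x1 <- x; x2 <- mu; b <- x; sigma <- 1L
    dq <- rho - mu * q
    delta1 <- rep(0, length(times))
    delta2 <- ifelse(mu > 0, p$mu_m * p$Q0 / q^2 * dq, 0)
  }
  x1_hat <- sol$states[, 4]; x2_hat <- sol$states[, 5]
  x1_err <- x1_hat - x1; x2_err <- x2_hat - x2
  out <- data.frame(
    t = times, x = x, s = s, q = q, mu = mu, rho = rho, D = D, s_in = s_in,
    x1 = x1, x2 = x2, x1_hat = x1_hat, x2_hat = x2_hat,
    theta_hat = sol$states[, 6], x1_err = x1_err, x2_err = x2_err,
    b = b, z = x2_err - sigma * om * x1_err,
    psi_x1 = deadzone(x1_err, eps),
    delta1_over_b = delta1 / b, delta2_over_b = delta2 / b)
  attr(out, "gains") <- gains
  attr(out, "sigma") <- sigma
  attr(out, "label") <- example
  attr(out, "params") <- p
  class(out) <- c("observerTrajectory", class(out))
  out
}

runCoupledSynthetic <- function(plant, gains, tEnd, gridStep,
                                initialObserver, rtol, atol) {
  stopifnot(inherits(gains, "observerGains"))
  if (is.null(initialObserver)) {
    initialObserver <- observerState(x1Hat = plant$x10)
  }
  b <- plant$b; ab <- abs(b); sigma <- as.integer(sign(b))
  om <- gains$omega; eps <- gains$epsilon; gam <- gains$gamma
  K <- gains$k + 1 / (4 * om)
  f <- function(t, y) {
    e1 <- y[3] - y[1]
    psi <- if (e1 >= eps) e1 - eps else if (e1 <= -eps) e1 + eps else 0
    sat <- if (e1 >= eps) 1 else if (e1 <= -eps) -1 else e1 / eps
    c(plant$h1(t) + b * y[2] + plant$delta1(t),
      plant$h2(t) + plant$delta2(t),
      b * y[4] - ab * (om * e1 + K * psi + sat * y[5]) + plant$h1(t),
      -b * om * (K * psi + sat * y[5]) + plant$h2(t),
      gam * ab * abs(psi))
  }
  times <- seq(0, tEnd, by = gridStep)
  y0 <- c(plant$x10, plant$x20, initialObserver$x1Hat,
          initialObserver$x2Hat, initialObserver$thetaHat)
  sol <- odeRK45(f, y0, times, rtol = rtol, atol = atol)
  x1 <- sol$states[, 1]; x2 <- sol$states[, 2]
  x1_hat <- sol$states[, 3]; x2_hat <- sol$states[, 4]
  x1_err <- x1_hat - x1; x2_err <- x2_hat - x2
  out <- data.frame(
    t = times, x1 = x1, x2 = x2, x1_hat = x1_hat, x2_hat = x2_hat,
    theta_hat = sol$states[, 5], x1_err = x1_err, x2_err = x2_err,
    b = b, z = x2_err - sigma * om * x1_err,
    psi_x1 = deadzone(x1_err, eps),
    delta1_over_b = vapply(times, plant$delta1, numeric(1)) / b,
    delta2_over_b = vapply(times, plant$delta2, numeric(1)) / b)
  attr(out, "gains") <- gains
  attr(out, "sigma") <- sigma
  attr(out, "label") <- plant$label
  class(out) <- c("observerTrajectory", class(out))
  out
}

#' Estimate disturbance bounds from a casting trajectory
#'
#' Step two of the gain-setting algorithm: the disturbance bounds are read
#' off a simulation of the plant model as trajectory suprema,
#' `d1 = sup |delta1/b|`, `d2 = sup |delta2/b|`, together with
#' `bMin = inf |b|`. The window may be restricted with `from` (e.g. to
#' exclude a start-up transient caused by arbitrary simulation initial
#' conditions); the default is the full run, which is what the convergence
#' theory requires.
#'
#' @param plant a `secondOrderPlant` (see [castUptakeSubsystem()],
#'   [castGrowthSubsystem()]) or any data.frame with columns `t`,
#'   `delta1_over_b`, `delta2_over_b`, `b`.
#' @param from lower end of the evaluation window (default: start of run).
#' @param digits decimals for the rounded report block.
#' @return A [disturbanceBounds()] with an additional `rounded` field.
#' @export
estimateDisturbanceBounds <- function(plant, from = -Inf, digits = 2) {
  d <- if (inherits(plant, "secondOrderPlant")) plant$data else plant
  need <- c("t", "delta1_over_b", "delta2_over_b", "b")
  if (!is.data.frame(d) || !all(need %in% names(d)) || nrow(d) == 0) {
    stop("'plant' must carry a non-empty trajectory with columns ",
         paste(need, collapse = ", "))
  }
  w <- d$t >= from
  if (!any(w)) stop("'from' is beyond the end of the trajectory")
  out <- disturbanceBounds(d1 = max(abs(d$delta1_over_b[w])),
                           d2 = max(abs(d$delta2_over_b[w])),
                           bMin = min(abs(d$b[w])))
  out$rounded <- list(d1 = round(out$d1, digits), d2 = round(out$d2, digits))
  out
}

#' Band entry time of an error series
#'
#' The time after which an error series stays inside a band of given
#' half-width: the last grid time at which `|error| > band`. If the series
#' never leaves the band the start time is returned.
#'
#' @param time strictly increasing time grid (at least 2 samples).
#' @param error error series on the grid.
#' @param band band half-width (> 0).
#' @return An object of class `entryTimeReport` with `entryTime`, `band`,
#'   and `fractionInsideAfter` (1 by construction, on the grid).
#' @examples
#' t <- seq(0, 10, 0.01)
#' entryTime(t, 0.01 * exp(-t), 0.0015)$entryTime  # ~ log(0.01/0.0015)
#' @export
entryTime <- function(time, error, band) {
  if (length(time) < 2 || length(error) != length(time)) {
    stop("'time' and 'error' must have equal length >= 2")
  }
  if (any(diff(time) <= 0)) stop("'time' must be strictly increasing")
  if (!is.numeric(band) || length(band) != 1 || band <= 0) {
    stop("'band' must be a single positive half-width")
  }
  outside <- which(abs(error) > band)
  et <- if (length(outside)) time[max(outside)] else time[1]
  after <- time > et
  structure(list(entryTime = et, band = band,
                 fractionInsideAfter =
                   if (any(after)) mean(abs(error[after]) <= band) else 1),
            class = "entryTimeReport")
}

#' @export
print.entryTimeReport <- function(x, ...) {
  cat(sprintf("band +/-%g entered at t = %g (fraction inside after: %g)\n",
              x$band, x$entryTime, x$fractionInsideAfter))
  invisible(x)
}

# convergence spec of a finished run: delta limits from estimated bounds,
# psiZ0 from the initial combined error, decay rate from inf|b|
specFromRun <- function(traj, bounds = NULL, gains = attr(traj, "gains")) {
  stopifnot(inherits(traj, "observerTrajectory"))
  if (is.null(bounds)) bounds <- estimateDisturbanceBounds(traj)
  if (is.na(bounds$bMin)) bounds$bMin <- min(abs(traj$b))
  convergenceSpec(bounds, gains, z0 = traj$z[1])
}

#' Verify the transient envelope along a run
#'
#' Checks that the unknown-state error never exceeds the transient envelope
#' after the measured-state error has entered its band, and never exceeds the
#' asymptotic half-width after its own entry time. Truth must be available
#' (`x2_err` on the trajectory).
#'
#' @param traj an [runCoupled()] trajectory.
#' @param spec a [convergenceSpec()]; default is built from the run itself
#'   (estimated bounds, measured initial combined error).
#' @param from start of the envelope check; defaults to the measured-state
#'   entry time.
#' @param tol additive slack for solver/finite-grid error.
#' @return list with `violationsEnvelope`, `violationsBand` (counts),
#'   `maxRelViolation`, `from`, `x2EntryTime`, and the `spec` used.
#' @export
verifyEnvelope <- function(traj, spec = NULL, from = NULL, tol = 1e-6) {
  stopifnot(inherits(traj, "observerTrajectory"))
  gains <- attr(traj, "gains")
  if (is.null(spec)) spec <- specFromRun(traj)
  if (is.null(from)) {
    from <- entryTime(traj$t, traj$x1_err, gains$epsilon)$entryTime
  }
  env <- transientEnvelope(traj$t, traj$t[1], spec)
  w <- traj$t > from  # strictly after: at the exit sample |x1_err| still exceeds the band
  excess <- abs(traj$x2_err[w]) - env[w]
  et2 <- entryTime(traj$t, traj$x2_err, spec$fW)$entryTime
  wb <- traj$t > et2
  excessBand <- abs(traj$x2_err[wb]) - spec$fW
  list(violationsEnvelope = sum(excess > tol),
       violationsBand = sum(excessBand > tol),
       maxRelViolation = max(c(excess / env[w], -Inf)) ,
       from = from, x2EntryTime = et2, spec = spec)
}

#' Verify the Lyapunov decrease condition along a run
#'
#' Numerically checks the dissipation inequality of the convergence analysis:
#' the overall Lyapunov function `V = Vz + Vx1 + Vtheta` (quadratic forms of
#' the shifted dead-zoned combined error, the dead-zoned measured-state
#' error, and the adaptation mismatch) must satisfy
#' `dV/dt <= -k bMin psi_x1^2` along the run, and the combined-error part
#' alone `dVz/dt <= -2 omega |b| Vz`. Derivatives are central finite
#' differences on the output grid, so kink-adjacent samples carry
#' discretization slack; the report gives the fraction of grid points
#' satisfying each inequality.
#'
#' The unknown constant bound of the adaptation analysis is not observable;
#' for verification it is instantiated as the trajectory supremum of
#' `|-(psi_z - z) - delta1/b|` plus a tie-break.
#'
#' @param traj an [runCoupled()] trajectory with truth and disturbances.
#' @param spec a [convergenceSpec()]; default built from the run.
#' @param gains the gains of the run (default: trajectory attribute).
#' @param bMin lower bound on `|b|` (default: trajectory infimum).
#' @param tol additive finite-difference slack.
#' @return list with `fractionOverall`, `fractionVz`, `theta`, `maxSlack`
#'   (largest violation of the overall inequality), and the series needed to
#'   reproduce the check (`V`, `Vz`, `dissipation`).
#' @export
verifyLyapunov <- function(traj, spec = NULL, gains = attr(traj, "gains"),
                           bMin = NULL, tol = 1e-6) {
  stopifnot(inherits(traj, "observerTrajectory"))
  if (is.null(spec)) spec <- specFromRun(traj)
  if (is.null(bMin)) bMin <- min(abs(traj$b))
  psi_z <- psiZ(traj$z, spec$deltaMin, spec$deltaMax)
  delta_zt <- psi_z - traj$z
  theta <- max(abs(-delta_zt - traj$delta1_over_b)) + 1e-9
  Vz <- psi_z^2 / 2
  Vx1 <- traj$psi_x1^2 / 2
  Vth <- (traj$theta_hat - theta)^2 / (2 * gains$gamma)
  V <- Vz + Vx1 + Vth
  n <- length(V)
  h <- traj$t[2] - traj$t[1]
  mid <- 2:(n - 1)
  dV <- (V[mid + 1] - V[mid - 1]) / (2 * h)
  rhs <- -gains$k * bMin * traj$psi_x1[mid]^2
  okOverall <- dV <= rhs + tol
  dVz <- (Vz[mid + 1] - Vz[mid - 1]) / (2 * h)
  rhsZ <- -2 * gains$omega * abs(traj$b[mid]) * Vz[mid]
  okZ <- dVz <= rhsZ + tol
  list(fractionOverall = mean(okOverall),
       fractionVz = mean(okZ),
       theta = theta,
       maxSlack = max(dV - rhs),
       V = V, Vz = Vz,
       dissipation = rhs)
}
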