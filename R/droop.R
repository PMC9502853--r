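#' Droop model parameters
#'
#' Parameter set for the Droop model of microalgae growth in a
#' photobioreactor, where growth is driven by the internal nitrogen quota
#' rather than directly by the external substrate. Defaults are the reference
#' culture: maximal uptake rate 0.03 mgN/(mgC d), half-saturation 0.001
#' mgN/L, maximal growth rate 0.5 1/d, minimal quota 0.045 mgN/mgC, nominal
#' feed 0.05 mgN/L, and a forcing schedule with a sinusoidal dilution rate of
#' period 8 d during the continuous phase and a 10% sinusoidal feed
#' uncertainty of period 3 d.
#'
#' The reactor runs continuously (sinusoidal dilution) before the switch time
#' and in batch (`D = 0`) after it; `continuous_phase = "after_switch"`
#' selects the opposite reading (batch start-up), retained for sensitivity
#' analysis.
#'
#' @param rho_m maximal specific uptake rate, mgN/(mgC d).
#' @param K_s uptake half-saturation constant, mgN/L.
#' @param mu_m maximal specific growth rate, 1/d.
#' @param Q0 minimal cell quota, mgN/mgC.
#' @param s_in_bar nominal fed substrate concentration, mgN/L.
#' @param tau_D dilution-rate period, d.
#' @param tau_si feed-uncertainty period, d.
#' @param D_switch_time continuous-to-batch switch time, d.
#' @param D_amplitude dilution base level, 1/d (peak is twice this).
#' @param feed_uncertainty_fraction relative amplitude of the feed
#'   uncertainty.
#' @param continuous_phase `"before_switch"` (default) or `"after_switch"`;
#'   which side of the switch has the sinusoidal dilution.
#' @param x0,s0,q0 initial biomass (mgC/L), substrate (mgN/L) and quota
#'   (mgN/mgC).
#' @return An object of class `droopParameters`.
#' @export
droopParameters <- function(rho_m = 0.03, K_s = 0.001, mu_m = 0.5,
                            Q0 = 0.045, s_in_bar = 0.05, tau_D = 8,
                            tau_si = 3, D_switch_time = 6,
                            D_amplitude = 0.25,
                            feed_uncertainty_fraction = 0.1,
                            continuous_phase = c("before_switch",
                                                 "after_switch"),
                            x0 = 0.1, s0 = 0.01, q0 = 0.06) {
  continuous_phase <- match.arg(continuous_phase)
  num <- list(rho_m = rho_m, K_s = K_s, mu_m = mu_m, Q0 = Q0,
              s_in_bar = s_in_bar, tau_D = tau_D, tau_si = tau_si,
              D_switch_time = D_switch_time, D_amplitude = D_amplitude,
              feed_uncertainty_fraction = feed_uncertainty_fraction,
              x0 = x0, s0 = s0, q0 = q0)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop(sprintf("'%s' must be a single nonnegative number", nm))
    }
  }
  if (Q0 <= 0) stop("'Q0' must be positive")
  if (tau_D <= 0 || tau_si <= 0) stop("forcing periods must be positive")
  structure(c(num, list(continuous_phase = continuous_phase)),
            class = "droopParameters")
}

#' Specific growth rate from the cell quota
#'
#' Droop kinetics: `mu(q) = max(0, mu_m (1 - Q0/q))`. Zero at or below the
#' minimal quota, approaching `mu_m` as the quota grows.
#'
#' @param q cell quota, mgN/mgC (> 0); vectorized.
#' @param params a [droopParameters()].
#' @return specific growth rate, 1/d.
#' @examples
#' growthRate(0.09, droopParameters())  # 0.25
#' @export
growthRate <- function(q, params = droopParameters()) {
  stopifnot(inherits(params, "droopParameters"))
  if (any(q <= 0)) stop("'q' must be positive")
  pmax(0, params$mu_m * (1 - params$Q0 / q))
}

#' Specific substrate uptake rate
#'
#' Monod form `rho(s) = rho_m s / (s + K_s)`, in `[0, rho_m)`.
#'
#' @param s substrate concentration, mgN/L (>= 0); vectorized.
#' @inheritParams growthRate
#' @return specific uptake rate, mgN/(mgC d).
#' @examples
#' uptakeRate(0.001, droopParameters())  # rho_m / 2
#' @export
uptakeRate <- function(s, params = droopParameters()) {
  stopifnot(inherits(params, "droopParameters"))
  if (any(s < 0)) stop("'s' must be nonnegative")
  params$rho_m * s / (s + params$K_s)
}

#' Dilution rate schedule
#'
#' `D(t) = D_amplitude (1 + sin(2 pi t / tau_D))` during the continuous
#' phase and 0 during the batch phase; the continuous phase is the side of
#' `D_switch_time` selected by `params$continuous_phase`.
#'
#' @param t time, d (>= 0); vectorized.
#' @inheritParams growthRate
#' @return dilution rate, 1/d, in `[0, 2 D_amplitude]`.
#' @export
dilutionRate <- function(t, params = droopParameters()) {
  stopifnot(inherits(params, "droopParameters"))
  on <- if (params$continuous_phase == "before_switch") {
    t < params$D_switch_time
  } else {
    t >= params$D_switch_time
  }
  ifelse(on, params$D_amplitude * (1 + sin(2 * pi * t / params$tau_D)), 0)
}

#' Feed-concentration uncertainty
#'
#' Sinusoidal uncertainty on the fed substrate concentration:
#' `delta_si(t) = feed_uncertainty_fraction * s_in_bar * sin(2 pi t /
#' tau_si)`. The actual feed is `s_in_bar + delta_si`; the observer only
#' knows `s_in_bar`.
#'
#' @inheritParams dilutionRate
#' @return feed uncertainty, mgN/L.
#' @export
feedUncertainty <- function(t, params = droopParameters()) {
  stopifnot(inherits(params, "droopParameters"))
  params$feed_uncertainty_fraction * params$s_in_bar *
    sin(2 * pi * t / params$tau_si)
}

#' Droop model time derivatives
#'
#' Right-hand side of the three-state Droop model:
#' `dx/dt = mu x - D x`, `ds/dt = -rho x + D (si - s)`,
#' `dq/dt = rho - mu q`, with `si = s_in_bar + delta_si(t)`. In batch
#' (`D = 0`, no feed uncertainty) total nitrogen `s + q x` is conserved.
#'
#' @param state named list or vector with `x` (> 0), `s` (>= 0), `q` (> 0).
#' @param t time, d.
#' @inheritParams growthRate
#' @return named numeric vector `c(x = , s = , q = )` of derivatives.
#' @export
droopDerivatives <- function(state, t, params = droopParameters()) {
  stopifnot(inherits(params, "droopParameters"))
  x <- state[["x"]]; s <- state[["s"]]; q <- state[["q"]]
  if (!is.finite(x) || x <= 0) stop("'x' must be positive")
  if (!is.finite(s) || s < 0) stop("'s' must be nonnegative")
  if (!is.finite(q) || q <= 0) stop("'q' must be positive")
  mu <- growthRate(q, params)
  rho <- uptakeRate(s, params)
  D <- dilutionRate(t, params)
  si <- params$s_in_bar + feedUncertainty(t, params)
  c(x = mu * x - D * x,
    s = -rho * x + D * (si - s),
    q = rho - mu * q)
}

#' Simulate the Droop bioreactor
#'
#' Integrates the Droop model from its initial conditions on a uniform output
#' grid and returns the trajectory with derived signals (growth and uptake
#' rates, dilution, feed). The substrate may graze zero during batch
#' exhaustion; it is clamped at zero at the solver level to within
#' tolerance-sized excursions.
#'
#' @inheritParams growthRate
#' @param tEnd simulation horizon, d.
#' @param gridStep uniform output grid step, d.
#' @param rtol,atol solver tolerances, see [odeRK45()].
#' @return A data.frame of class `droopTrajectory` with columns `t`, `x`,
#'   `s`, `q`, `mu`, `rho`, `D`, `s_in`, `ds`, `dq` and the parameters in
#'   attribute `"params"`.
#' @examples
#' traj <- simulateDroop(tEnd = 2, gridStep = 0.01)
#' head(traj)
#' @export
simulateDroop <- function(params = droopParameters(), tEnd = 20,
                          gridStep = 0.001, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "droopParameters"), tEnd > 0, gridStep > 0)
  p <- params
  f <- function(t, y) {
    x <- y[1]; s <- max(y[2], 0); q <- y[3]
    mu <- max(0, p$mu_m * (1 - p$Q0 / q))
    rho <- p$rho_m * s / (s + p$K_s)
    on <- if (p$continuous_phase == "before_switch") t < p$D_switch_time
          else t >= p$D_switch_time
    D <- if (on) p$D_amplitude * (1 + sin(2 * pi * t / p$tau_D)) else 0
    si <- p$s_in_bar +
      p$feed_uncertainty_fraction * p$s_in_bar * sin(2 * pi * t / p$tau_si)
    c(mu * x - D * x, -rho * x + D * (si - s), rho - mu * q)
  }
  times <- seq(0, tEnd, by = gridStep)
  sol <- odeRK45(f, c(p$x0, p$s0, p$q0), times, rtol = rtol, atol = atol)
  x <- sol$states[, 1]
  s <- pmax(sol$states[, 2], 0)  # clamp tolerance-sized excursions
  q <- sol$states[, 3]
  mu <- growthRate(q, p)
  rho <- uptakeRate(s, p)
  D <- dilutionRate(times, p)
  s_in <- p$s_in_bar + feedUncertainty(times, p)
  out <- data.frame(t = times, x = x, s = s, q = q, mu = mu, rho = rho,
                    D = D, s_in = s_in,
                    ds = -rho * x + D * (s_in - s),
                    dq = rho - mu * q)
  attr(out, "params") <- p
  class(out) <- c("droopTrajectory", class(out))
  out
}

# shared scaffolding for the two second-order castings
newSecondOrderPlant <- function(data, sigma, label, params) {
  if (min(abs(data$b)) <= 0) {
    stop("|b| reaches zero along the trajectory: the unknown-state gain must be bounded away from zero")
  }
  if (min(data$b) < 0 && max(data$b) > 0) {
    stop("sign of 'b' flips along the trajectory")
  }
  sig <- signalInterpolator(data)
  structure(list(data = data, sigma = sigma, label = label,
                 params = params, signals = sig),
            class = "secondOrderPlant")
}

#' @export
print.secondOrderPlant <- function(x, ...) {
  cat(sprintf(
    "second-order plant casting '%s': %d samples on [%g, %g], sigma = %+d\n",
    x$label, nrow(x$data), min(x$data$t), max(x$data$t), x$sigma))
  cat(sprintf("  sup|delta1/b| = %.4g, sup|delta2/b| = %.4g, min|b| = %.4g\n",
              max(abs(x$data$delta1_over_b)),
              max(abs(x$data$delta2_over_b)), min(abs(x$data$b))))
  invisible(x)
}

#' Cast the substrate balance as a second-order plant (uptake-rate sensor)
#'
#' Substrate-uptake casting: the measured state is the substrate
#' concentration, the unknown state is the specific uptake rate, and
#' `b = -x` (biomass, sign fixed negative). The known term is the nominal
#' feed exchange `h1 = (s_in_bar - s) D`; the disturbances are the feed
#' uncertainty `delta1 = D delta_si` and the uptake-rate drift
#' `delta2 = d rho/dt`, evaluated analytically by the chain rule
#' `rho_m K_s/(s + K_s)^2 ds/dt` so that bound estimation is robust to the
#' output grid.
#'
#' @param traj a [simulateDroop()] trajectory.
#' @param params the parameters of the trajectory (defaults to its
#'   attribute).
#' @return An object of class `secondOrderPlant` whose `data` carries `t`,
#'   `x1`, `h1`, `h2`, `b`, `x2` (truth), `delta1`, `delta2`,
#'   `delta1_over_b`, `delta2_over_b`.
#' @export
castUptakeSubsystem <- function(traj, params = attr(traj, "params")) {
  stopifnot(inherits(traj, "droopTrajectory"),
            inherits(params, "droopParameters"))
  drho <- params$rho_m * params$K_s / (traj$s + params$K_s)^2 * traj$ds
  delta1 <- traj$D * feedUncertainty(traj$t, params)
  b <- -traj$x
  d <- data.frame(t = traj$t, x1 = traj$s,
                  h1 = (params$s_in_bar - traj$s) * traj$D,
                  h2 = 0, b = b, x2 = traj$rho,
                  delta1 = delta1, delta2 = drho,
                  delta1_over_b = delta1 / b, delta2_over_b = drho / b)
  newSecondOrderPlant(d, sigma = -1L, label = "uptake", params = params)
}

#' Cast the biomass balance as a second-order plant (growth-rate sensor)
#'
#' Growth-rate casting: the measured state is the biomass concentration, the
#' unknown state is the specific growth rate, and `b = x` (sign fixed
#' positive). The known term is the wash-out `h1 = -D x`; there is no
#' measured-state disturbance (`delta1 = 0`) and the unknown-state
#' disturbance is the growth-rate drift `delta2 = d mu/dt`, analytically
#' `mu_m Q0 / q^2 dq/dt` where the growth rate is positive and 0 on the
#' clipped branch.
#'
#' @inheritParams castUptakeSubsystem
#' @return An object of class `secondOrderPlant`; see
#'   [castUptakeSubsystem()] for the `data` columns.
#' @export
castGrowthSubsystem <- function(traj, params = attr(traj, "params")) {
  stopifnot(inherits(traj, "droopTrajectory"),
            inherits(params, "droopParameters"))
  dmu <- ifelse(traj$mu > 0,
                params$mu_m * params$Q0 / traj$q^2 * traj$dq, 0)
  d <- data.frame(t = traj$t, x1 = traj$x, h1 = -traj$D * traj$x,
                  h2 = 0, b = traj$x, x2 = traj$mu,
                  delta1 = 0, delta2 = dmu,
                  delta1_over_b = 0, delta2_over_b = dmu / traj$x)
  newSecondOrderPlant(d, sigma = 1L, label = "growth", params = params)
}
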