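#' Disturbance bounds for observer tuning
#'
#' The three quantities all tuning analytics consume: `d1`, a bound on the
#' disturbance-to-gain ratio entering the measured-state error dynamics;
#' `d2`, a bound on the ratio entering the unknown-state error dynamics; and
#' `bMin`, a positive lower bound on `|b|`. In practice they are obtained by
#' simulating the plant model and taking suprema (see
#' [estimateDisturbanceBounds()]).
#'
#' @param d1 bound on the measured-state disturbance ratio (>= 0), units of
#'   the unknown state.
#' @param d2 bound on the unknown-state disturbance ratio (> 0), units of the
#'   unknown state per time.
#' @param bMin positive lower bound on `|b|`.
#' @return An object of class `disturbanceBounds`.
#' @examples
#' disturbanceBounds(d1 = 0.04, d2 = 0.11, bMin = 0.05)
#' @export
disturbanceBounds <- function(d1, d2, bMin = NA_real_) {
  stopifnot(is.numeric(d1), length(d1) == 1,
            is.numeric(d2), length(d2) == 1)
  if (d1 < 0) stop("'d1' must be nonnegative")
  if (d2 < 0) stop("'d2' must be nonnegative")
  if (!is.na(bMin) && (!is.numeric(bMin) || bMin <= 0)) {
    stop("'bMin' must be positive")
  }
  structure(list(d1 = d1, d2 = d2, bMin = bMin), class = "disturbanceBounds")
}

#' @export
print.disturbanceBounds <- function(x, digits = 4, ...) {
  cat(sprintf("disturbance bounds: d1 = %.*g, d2 = %.*g, bMin = %.*g\n",
              digits, x$d1, digits, x$d2, digits, x$bMin))
  invisible(x)
}

#' Half-width of the unknown-state convergence region
#'
#' The asymptotic half-width of the band the unknown-state estimation error
#' converges into, as a function of the correction gain:
#' \deqn{f_w(\omega) = d_2/\omega + d_1 + \omega \epsilon.}
#' It diverges as `omega -> 0+` (vertical asymptote) and as `omega -> Inf`,
#' always exceeds `d1`, and for `d2 > 0` is strictly convex with an interior
#' minimum (see [fwMinimum()]).
#'
#' @param omega correction gain(s), strictly positive; vectorized.
#' @param bounds a [disturbanceBounds()].
#' @param epsilon dead-zone half-width (> 0).
#' @return `fw` value(s), same length as `omega`.
#' @examples
#' fwWidth(8.564, disturbanceBounds(0.04, 0.11), 0.0015)
#' @export
fwWidth <- function(omega, bounds, epsilon) {
  stopifnot(inherits(bounds, "disturbanceBounds"),
            is.numeric(epsilon), length(epsilon) == 1, epsilon > 0)
  if (!is.numeric(omega) || any(omega <= 0)) {
    stop("'omega' must be strictly positive (fw has a vertical asymptote at omega = 0)")
  }
  bounds$d2 / omega + bounds$d1 + omega * epsilon
}

#' Minimum of the convergence-region half-width
#'
#' Closed-form coordinates of the interior minimum of [fwWidth()]:
#' \deqn{\omega^* = \sqrt{d_2/\epsilon}, \qquad
#'   f_w^* = 2\sqrt{d_2 \epsilon} + d_1,}
#' equivalently `fw* = 2 d2 / omega* + d1`. When `d1 = 0` this reduces to
#' `fw* = 2 sqrt(d2 epsilon)`. The degenerate case `d2 = 0` has no interior
#' minimum (`fw` is then increasing in `omega`) and is reported as a distinct
#' condition.
#'
#' @inheritParams fwWidth
#' @return list with `omegaStar` and `fwStar`.
#' @examples
#' fwMinimum(disturbanceBounds(0.04, 0.11), 0.0015)  # omega* = 8.564
#' @export
fwMinimum <- function(bounds, epsilon) {
  stopifnot(inherits(bounds, "disturbanceBounds"),
            is.numeric(epsilon), length(epsilon) == 1, epsilon > 0)
  if (bounds$d2 == 0) {
    stop("d2 = 0: fw is monotone increasing in omega and has no interior minimum")
  }
  omegaStar <- sqrt(bounds$d2 / epsilon)
  list(omegaStar = omegaStar,
       fwStar = 2 * sqrt(bounds$d2 * epsilon) + bounds$d1)
}

#' Qualitative properties of the half-width curve on a gain grid
#'
#' Checks, on a strictly positive sorted grid, the analytic properties of
#' [fwWidth()]: positivity and the `fw > d1` lower bound, the
#' decreasing/increasing split around the closed-form minimizer, agreement of
#' the grid argmin with the closed form, and (for `d2 > 0`) convexity via
#' second differences.
#'
#' @inheritParams fwWidth
#' @param omegaGrid strictly positive, strictly increasing numeric grid.
#' @return list with the `fw` values, logical flags (`positive`,
#'   `aboveD1`, `unimodal`, `convex`), the grid argmin `omegaArgmin` and the
#'   closed-form minimizer `omegaStar` (`NA` when `d2 = 0`).
#' @export
fwProperties <- function(bounds, epsilon, omegaGrid) {
  stopifnot(is.numeric(omegaGrid), length(omegaGrid) >= 3)
  if (any(omegaGrid <= 0) || any(diff(omegaGrid) <= 0)) {
    stop("'omegaGrid' must be strictly positive and strictly increasing")
  }
  fw <- fwWidth(omegaGrid, bounds, epsilon)
  i <- which.min(fw)
  d2pos <- bounds$d2 > 0
  omegaStar <- if (d2pos) sqrt(bounds$d2 / epsilon) else NA_real_
  before <- if (i > 1) all(diff(fw[seq_len(i)]) <= 0) else TRUE
  after <- if (i < length(fw)) all(diff(fw[i:length(fw)]) >= 0) else TRUE
  list(omega = omegaGrid, fw = fw,
       positive = all(fw > 0),
       aboveD1 = all(fw > bounds$d1),
       unimodal = before && after,
       convex = !d2pos || all(diff(fw, differences = 2) > 0),
       omegaArgmin = omegaGrid[i],
       omegaStar = omegaStar,
       monotoneIncreasing = !d2pos && all(diff(fw) > 0))
}

#' Shifted dead zone for the combined error coordinate
#'
#' Dead-zone map for the combined error `z`: zero on the open band
#' `(-deltaMax, -deltaMin)` (the interval spanned by the negated disturbance
#' limits), and shifted-linear outside, `z + deltaMin` on the upper branch
#' and `z + deltaMax` on the lower. Used to seed the transient envelope and
#' in the Lyapunov verification.
#'
#' @param z combined error value(s); vectorized.
#' @param deltaMin lower disturbance limit (<= 0).
#' @param deltaMax upper disturbance limit (>= 0).
#' @return The shifted dead-zoned value(s).
#' @examples
#' psiZ(c(-0.15, 0, 0.15), deltaMin = -0.1, deltaMax = 0.1)
#' @export
psiZ <- function(z, deltaMin, deltaMax) {
  stopifnot(is.numeric(deltaMin), length(deltaMin) == 1,
            is.numeric(deltaMax), length(deltaMax) == 1)
  if (deltaMin > 0 || deltaMax < 0) {
    stop("'deltaMin' must be <= 0 and 'deltaMax' >= 0")
  }
  ifelse(z >= -deltaMin, z + deltaMin,
         ifelse(z <= -deltaMax, z + deltaMax, 0))
}

#' Convergence specification
#'
#' Assembles the constants of the convergence analysis for one observer run:
#' the symmetric disturbance limits `deltaMax = d2/omega + d1 = -deltaMin`,
#' the asymptotic half-width `fW = deltaMax + omega epsilon`, the exponential
#' decay rate `omega * bMin` of the transient term, and the initial value
#' `psiZ0` of the shifted dead-zoned combined error.
#'
#' @param bounds a [disturbanceBounds()] with finite `bMin`.
#' @param gains an [observerGains()].
#' @param psiZ0 initial shifted dead-zoned combined error. Supply directly,
#'   or via `z0` (truth-based verification mode).
#' @param z0 initial combined error `x2_err(t0) - sigma * omega * x1_err(t0)`;
#'   used to compute `psiZ0` when that is not given.
#' @return An object of class `convergenceSpec` with fields `fW`, `omega`,
#'   `epsilon`, `deltaMin`, `deltaMax`, `psiZ0`, `decayRate`.
#' @export
convergenceSpec <- function(bounds, gains, psiZ0 = NULL, z0 = NULL) {
  stopifnot(inherits(bounds, "disturbanceBounds"),
            inherits(gains, "observerGains"))
  if (is.na(bounds$bMin)) stop("'bounds$bMin' is required for the decay rate")
  deltaMax <- bounds$d2 / gains$omega + bounds$d1
  deltaMin <- -deltaMax
  if (is.null(psiZ0)) {
    if (is.null(z0)) stop("supply either 'psiZ0' or 'z0'")
    psiZ0 <- psiZ(z0, deltaMin, deltaMax)
  }
  structure(list(
    fW = deltaMax + gains$omega * gains$epsilon,
    omega = gains$omega, epsilon = gains$epsilon,
    deltaMin = deltaMin, deltaMax = deltaMax,
    psiZ0 = psiZ0, decayRate = gains$omega * bounds$bMin),
    class = "convergenceSpec")
}

#' @export
print.convergenceSpec <- function(x, ...) {
  cat(sprintf(
    paste0("convergence spec: fW = %.4g, omega = %.4g, epsilon = %.4g,\n",
           "  delta limits [%.4g, %.4g], psiZ0 = %.4g, decay rate = %.4g\n"),
    x$fW, x$omega, x$epsilon, x$deltaMin, x$deltaMax, x$psiZ0, x$decayRate))
  invisible(x)
}

#' Transient envelope of the unknown-state error
#'
#' Time-dependent upper bound on the magnitude of the unknown-state error,
#' valid once the measured-state error has entered its band:
#' \deqn{|\bar{x}_2(t)| \le |\psi_{z0}| e^{-\omega b_{min} (t - t_0)} +
#'   \max\{-\delta_{min}, \delta_{max}\} + \omega\epsilon.}
#' Non-increasing in `t`; its limit as `t -> Inf` is the asymptotic
#' half-width `fW` of the convergence region.
#'
#' @param t evaluation time(s), `>= t0`; vectorized.
#' @param t0 initial time of the run.
#' @param spec a [convergenceSpec()].
#' @return Envelope value(s).
#' @export
transientEnvelope <- function(t, t0, spec) {
  stopifnot(inherits(spec, "convergenceSpec"))
  if (any(t < t0)) stop("'t' must be >= 't0'")
  abs(spec$psiZ0) * exp(-spec$decayRate * (t - t0)) +
    max(-spec$deltaMin, spec$deltaMax) + spec$omega * spec$epsilon
}

#' Set the observer gains from disturbance bounds
#'
#' The gain-setting pipeline: given disturbance bounds and a dead-zone
#' half-width, resolve the correction gain (default: the closed-form
#' minimizer of the convergence-region half-width), adopt user values for the
#' convergence and adaptation gains, and assemble the convergence
#' specification and the half-width curve. The defaults `k = 40`,
#' `gamma = 100` are the reference choices of the worked bioreactor examples
#' ("high" values giving fast measured-state convergence and adaptation);
#' both are freely overridable.
#'
#' @param bounds a [disturbanceBounds()].
#' @param epsilon dead-zone half-width (> 0). Small values shrink the
#'   convergence region but steepen the saturation slope, forcing smaller
#'   integration steps; a message flags values below `1e-4`.
#' @param k convergence gain.
#' @param gamma adaptation gain.
#' @param omega `"at_minimum"` (default) to use the closed-form minimizer, or
#'   an explicit positive value.
#' @param psiZ0 optional initial shifted combined error for the envelope
#'   (default 0 when unknown).
#' @param curvePointsPerDecade resolution of the emitted half-width curve
#'   (log grid spanning `[omega*/100, 100 omega*]`).
#' @return An object of class `tuningReport`: fields `omegaStar`, `fwStar`,
#'   `gains`, `curve` (data.frame `omega`, `f_w`), `spec`
#'   (a [convergenceSpec()], when `bMin` is known), `bounds`, `epsilon`.
#' @examples
#' tuneParameters(disturbanceBounds(0.04, 0.11, bMin = 0.05), 0.0015)
#' @export
tuneParameters <- function(bounds, epsilon, k = 40, gamma = 100,
                           omega = "at_minimum", psiZ0 = 0,
                           curvePointsPerDecade = 400) {
  stopifnot(inherits(bounds, "disturbanceBounds"),
            is.numeric(epsilon), length(epsilon) == 1, epsilon > 0)
  if (epsilon < 1e-4) {
    message("very small epsilon: the saturation slope 1/epsilon is steep; ",
            "expect smaller integration steps")
  }
  mn <- fwMinimum(bounds, epsilon)
  if (identical(omega, "at_minimum")) {
    omegaUse <- mn$omegaStar
  } else {
    if (!is.numeric(omega) || length(omega) != 1 || omega <= 0) {
      stop("'omega' must be \"at_minimum\" or a single positive value")
    }
    omegaUse <- omega
  }
  gains <- observerGains(omega = omegaUse, epsilon = epsilon,
                         k = k, gamma = gamma)
  ndec <- 4  # [omega*/100, 100*omega*]
  grid <- mn$omegaStar / 100 *
    10^(seq(0, ndec, length.out = ndec * curvePointsPerDecade + 1))
  curve <- data.frame(omega = grid, f_w = fwWidth(grid, bounds, epsilon))
  spec <- if (!is.na(bounds$bMin)) {
    convergenceSpec(bounds, gains, psiZ0 = psiZ0)
  } else NULL
  structure(list(omegaStar = mn$omegaStar, fwStar = mn$fwStar,
                 gains = gains, curve = curve, spec = spec,
                 bounds = bounds, epsilon = epsilon),
            class = "tuningReport")
}

#' @export
print.tuningReport <- function(x, ...) {
  cat(sprintf("tuning report: omega* = %.4g, fw* = %.4g (epsilon = %g)\n",
              x$omegaStar, x$fwStar, x$epsilon))
  print(x$gains)
  if (!is.null(x$spec)) print(x$spec)
  cat(sprintf("fw curve: %d samples over [%.3g, %.3g]\n",
              nrow(x$curve), min(x$curve$omega), max(x$curve$omega)))
  invisible(x)
}
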