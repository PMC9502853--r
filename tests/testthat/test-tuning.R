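test_that("half-width formula matches direct arithmetic and the reference case", {
  b1 <- disturbanceBounds(d1 = 0.04, d2 = 0.11)
  expect_equal(fwWidth(8.564, b1, 0.0015), 0.0657, tolerance = 5e-4 / 0.0657)
  expect_equal(fwWidth(1, disturbanceBounds(0, 0), 0.002), 0.002)
  expect_equal(fwWidth(1, b1, 0.0015), 0.1515)
  # vectorized over omega
  expect_equal(fwWidth(c(1, 2), b1, 0.0015),
               c(0.1515, 0.11 / 2 + 0.04 + 2 * 0.0015))
  expect_error(fwWidth(0, b1, 0.0015), "asymptote")
  expect_error(fwWidth(-3, b1, 0.0015), "asymptote")
})

test_that("closed-form minimum reproduces the reference gains and lies on the curve", {
  m1 <- fwMinimum(disturbanceBounds(0.04, 0.11), 0.0015)
  # exact value is sqrt(0.11/0.0015) = 8.56349, printed as 8.564 in the
  # reference (a final-digit rounding slip); agree to within one printed ulp
  expect_lt(abs(m1$omegaStar - 8.564), 1e-3)
  expect_equal(m1$omegaStar, sqrt(0.11 / 0.0015))
  expect_equal(round(m1$fwStar, 4), 0.0657)

  m2 <- fwMinimum(disturbanceBounds(0, 0.125), 0.0015)
  expect_equal(round(m2$omegaStar, 3), 9.129)
  # d1 = 0 special case: fw* = 2 sqrt(d2 epsilon)
  expect_equal(m2$fwStar, 2 * sqrt(0.125 * 0.0015))

  # the minimum lies on the curve
  expect_equal(fwWidth(m1$omegaStar, disturbanceBounds(0.04, 0.11), 0.0015),
               m1$fwStar)
  expect_error(fwMinimum(disturbanceBounds(0.1, 0), 0.0015), "no interior minimum")
})

test_that("closed-form minimum agrees with a brute-force grid search (100 random draws)", {
  set.seed(1)
  for (i in 1:100) {
    d1 <- stats::runif(1, 0, 0.5)
    d2 <- stats::runif(1, 1e-3, 2)
    eps <- stats::runif(1, 1e-4, 0.1)
    b <- disturbanceBounds(d1, d2)
    m <- fwMinimum(b, eps)
    # independent oracle: log-grid search over the raw formula, refined once
    # around the coarse argmin to resolve the flat minimum
    grid <- exp(seq(log(m$omegaStar / 50), log(m$omegaStar * 50),
                    length.out = 4000))
    fw <- d2 / grid + d1 + grid * eps
    j <- which.min(fw)
    expect_lt(abs(log(grid[j] / m$omegaStar)), diff(log(grid[1:2])) * 1.5)
    fine <- exp(seq(log(grid[max(1, j - 2)]), log(grid[min(4000, j + 2)]),
                    length.out = 4001))
    fwFine <- d2 / fine + d1 + fine * eps
    expect_lt(abs(min(fwFine) - m$fwStar) / m$fwStar, 1e-10)
    # relation between the minimum value and the minimizer
    expect_lt(abs(m$fwStar - 0 - d1 - 2 * d2 / m$omegaStar), 1e-12)
  }
})

test_that("half-width curve is convex with the documented asymptote and bounds", {
  b <- disturbanceBounds(0.04, 0.11)
  grid <- exp(seq(log(0.01), log(1000), length.out = 2000))
  pr <- fwProperties(b, 0.0015, grid)
  expect_true(pr$positive)
  expect_true(pr$aboveD1)
  expect_true(pr$unimodal)
  expect_true(pr$convex)
  expect_equal(pr$omegaArgmin, pr$omegaStar, tolerance = 0.01)
  # asymptote probe: fw near omega = 0 dwarfs the minimum
  expect_gt(fwWidth(1e-6, b, 0.0015) / fwWidth(pr$omegaStar, b, 0.0015), 1e4)

  # degenerate d2 = 0: monotone increasing, no minimum reported
  pr0 <- fwProperties(disturbanceBounds(0.04, 0), 0.0015, grid)
  expect_true(pr0$monotoneIncreasing)
  expect_true(is.na(pr0$omegaStar))
})

test_that("minimum half-width grows with epsilon and d1; minimizer ignores d1", {
  eps <- c(5e-4, 1e-3, 2e-3, 5e-3)
  fws <- vapply(eps, function(e) fwMinimum(disturbanceBounds(0.02, 0.3), e)$fwStar,
                numeric(1))
  expect_true(all(diff(fws) > 0))
  d1s <- c(0, 0.01, 0.05, 0.2)
  res <- lapply(d1s, function(d) fwMinimum(disturbanceBounds(d, 0.3), 1e-3))
  expect_true(all(diff(vapply(res, `[[`, numeric(1), "fwStar")) > 0))
  expect_equal(length(unique(vapply(res, `[[`, numeric(1), "omegaStar"))), 1L)
})

test_that("shifted dead zone for the combined error has the stated branches", {
  expect_identical(psiZ(0, -0.1, 0.1), 0)
  expect_equal(psiZ(0.15, -0.1, 0.1), 0.05)
  expect_equal(psiZ(-0.15, -0.1, 0.1), -0.05)
  # continuity at both edges
  expect_equal(psiZ(0.1, -0.1, 0.1), 0)
  expect_equal(psiZ(-0.1, -0.1, 0.1), 0)
  # asymmetric band
  expect_equal(psiZ(c(-0.3, 0, 0.3), -0.2, 0.05), c(-0.25, 0, 0.1))
  expect_error(psiZ(0, 0.1, 0.2), "deltaMin")
})

test_that("transient envelope decays to the asymptotic half-width", {
  bounds <- disturbanceBounds(0.04, 0.11, bMin = 1)
  g <- observerGains(8.564, 0.0015, 40, 100)
  sp <- convergenceSpec(bounds, g, psiZ0 = 0.1)
  # at t = t0 the exponential equals 1
  expect_equal(transientEnvelope(0, 0, sp),
               0.1 + sp$deltaMax + g$omega * g$epsilon)
  # the t -> Inf limit is the half-width of the convergence region
  expect_equal(transientEnvelope(1e6, 0, sp), fwWidth(g$omega, bounds, g$epsilon))
  # excess above the limit halves every ln(2)/decayRate
  hl <- log(2) / sp$decayRate
  ex <- function(t) transientEnvelope(t, 0, sp) - transientEnvelope(1e6, 0, sp)
  expect_equal(ex(hl), 0.05)
  expect_equal(ex(2 * hl), 0.025)
  expect_error(transientEnvelope(-1, 0, sp), ">=")
})

test_that("gain-setting pipeline reproduces the two reference gain sets", {
  tr1 <- tuneParameters(disturbanceBounds(0.04, 0.11, bMin = 0.05), 0.0015)
  expect_equal(tr1$gains$omega, 8.56, tolerance = 0.01 / 8.56)
  expect_equal(tr1$fwStar, 0.0657, tolerance = 5e-4 / 0.0657)
  expect_equal(tr1$gains$k, 40)
  expect_equal(tr1$gains$gamma, 100)
  # symmetric disturbance limits
  expect_equal(tr1$spec$deltaMax, 0.11 / tr1$gains$omega + 0.04)
  expect_equal(tr1$spec$deltaMin, -tr1$spec$deltaMax)

  tr2 <- tuneParameters(disturbanceBounds(0, 0.125, bMin = 0.05), 0.0015)
  expect_equal(tr2$gains$omega, 9.12, tolerance = 0.01 / 9.12)

  # explicit omega = omega* is identical to the default resolution
  tr1b <- tuneParameters(disturbanceBounds(0.04, 0.11, bMin = 0.05), 0.0015,
                         omega = tr1$omegaStar)
  expect_equal(tr1b$gains, tr1$gains)
  expect_equal(tr1b$curve, tr1$curve)

  # curve spans [omega*/100, 100 omega*] on a log grid
  expect_equal(range(tr1$curve$omega),
               c(tr1$omegaStar / 100, tr1$omegaStar * 100))
  expect_error(tuneParameters(disturbanceBounds(0, 0.1), 0.0015, omega = -2),
               "positive")
})
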