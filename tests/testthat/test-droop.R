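test_that("growth and uptake kinetics match their closed forms", {
  p <- droopParameters()
  expect_equal(growthRate(0.045, p), 0)         # at the minimal quota
  expect_equal(growthRate(0.09, p), 0.25)
  expect_equal(growthRate(0.02, p), 0)          # clipped below the quota
  expect_error(growthRate(0, p), "positive")

  expect_equal(uptakeRate(0, p), 0)
  expect_equal(uptakeRate(0.001, p), 0.015)     # half-saturation
  expect_equal(uptakeRate(0.01, p), 0.03 * 0.01 / 0.011)
  expect_true(all(uptakeRate(seq(0, 10, 0.5), p) < p$rho_m))
  expect_error(uptakeRate(-0.1, p), "nonnegative")
})

test_that("dilution schedule: sinusoidal continuous phase, batch after the switch", {
  p <- droopParameters()
  expect_equal(dilutionRate(0, p), 0.25)
  expect_equal(dilutionRate(2, p), 0.5)                     # sin peak
  expect_equal(dilutionRate(3, p), 0.25 * (1 + sin(2 * pi * 3 / 8)))
  expect_equal(dilutionRate(c(6, 8, 10, 15), p), rep(0, 4)) # batch phase
  tg <- seq(0, 20, 0.01)
  expect_true(all(dilutionRate(tg, p) >= 0 &
                    dilutionRate(tg, p) <= 2 * p$D_amplitude))

  # alternative reading (batch start-up), kept for sensitivity analysis
  pa <- droopParameters(continuous_phase = "after_switch")
  expect_equal(dilutionRate(3, pa), 0)
  expect_equal(dilutionRate(8, pa), 0.25)   # sin(2*pi) = 0
  expect_equal(dilutionRate(10, pa), 0.5)   # sin(2.5*pi) = 1
})

test_that("feed uncertainty is a 3-day sinusoid of amplitude 0.005", {
  p <- droopParameters()
  expect_equal(feedUncertainty(0, p), 0)
  expect_equal(feedUncertainty(0.75, p), 0.005)   # quarter period
  expect_equal(feedUncertainty(1.5, p), 0, tolerance = 1e-12)
})

test_that("model derivatives match hand evaluation and conserve batch nitrogen", {
  # batch configuration isolates the kinetics from the forcing
  pb <- droopParameters(D_amplitude = 0, feed_uncertainty_fraction = 0)
  d0 <- droopDerivatives(list(x = 0.1, s = 0.01, q = 0.06), t = 0, params = pb)
  expect_equal(unname(d0["x"]), 0.0125)
  expect_equal(unname(d0["s"]), -0.03 * 0.01 / 0.011 * 0.1)
  expect_equal(unname(d0["q"]), 0.03 * 0.01 / 0.011 - 0.125 * 0.06)

  # equilibrium: no substrate, quota at the minimum
  de <- droopDerivatives(list(x = 0.5, s = 0, q = 0.045), t = 1, params = pb)
  expect_equal(unname(de), c(0, 0, 0))

  # total nitrogen s + q x is conserved in batch: d(s + qx)/dt = 0
  set.seed(11)
  for (i in 1:10) {
    st <- list(x = stats::runif(1, 0.05, 2), s = stats::runif(1, 0, 0.05),
               q = stats::runif(1, 0.046, 0.2))
    d <- droopDerivatives(st, t = stats::runif(1, 0, 10), params = pb)
    expect_equal(unname(d["s"] + st$q * d["x"] + st$x * d["q"]), 0)
  }

  # with dilution on, the feed term enters the substrate balance
  p <- droopParameters()
  dd <- droopDerivatives(list(x = 0.1, s = 0.01, q = 0.06), t = 0, params = p)
  expect_equal(unname(dd["s"]), -0.03 * 0.01 / 0.011 * 0.1 + 0.25 * (0.05 - 0.01))
  expect_error(droopDerivatives(list(x = -1, s = 0, q = 0.05), 0, p), "positive")
})

test_that("simulated batch culture conserves nitrogen to 1e-6 relative over 6 d", {
  pb <- droopParameters(D_amplitude = 0, feed_uncertainty_fraction = 0)
  tr <- simulateDroop(pb, tEnd = 6, gridStep = 0.01)
  n_tot <- tr$s + tr$q * tr$x
  expect_lt(max(abs(n_tot - n_tot[1])) / n_tot[1], 1e-6)
})

test_that("reference 20 d trajectory stays positive with rates in range", {
  tr <- refDroop()
  expect_true(all(tr$x > 0))
  expect_true(all(tr$s >= 0))
  expect_true(all(tr$q > 0))
  expect_true(all(tr$rho >= 0 & tr$rho <= attr(tr, "params")$rho_m))
  expect_true(all(tr$mu >= 0 & tr$mu <= attr(tr, "params")$mu_m))
})

test_that("analytic disturbance drifts match finite differences of the rates", {
  tr <- refDroop()
  up <- castUptakeSubsystem(tr)
  gr <- castGrowthSubsystem(tr)
  h <- tr$t[2] - tr$t[1]
  mid <- 2:(nrow(tr) - 1)
  fd_rho <- (tr$rho[mid + 1] - tr$rho[mid - 1]) / (2 * h)
  fd_mu <- (tr$mu[mid + 1] - tr$mu[mid - 1]) / (2 * h)
  expect_lt(max(abs(up$data$delta2[mid] - fd_rho)), 1e-4)
  expect_lt(max(abs(gr$data$delta2[mid] - fd_mu)), 1e-4)
})

test_that("castings have fixed gain signs and the stated disturbance structure", {
  tr <- refDroop()
  up <- castUptakeSubsystem(tr)
  expect_identical(up$sigma, -1L)
  expect_true(all(up$data$b < 0))
  expect_equal(up$data$x1, tr$s)
  expect_equal(up$data$x2, tr$rho)
  # no feed disturbance while the reactor is in batch
  expect_true(all(up$data$delta1[tr$D == 0] == 0))

  gr <- castGrowthSubsystem(tr)
  expect_identical(gr$sigma, 1L)
  expect_true(all(gr$data$b > 0))
  expect_true(all(gr$data$delta1_over_b == 0))

  # clipped growth branch: no drift while mu = 0
  plow <- droopParameters(q0 = 0.040, D_amplitude = 0,
                          feed_uncertainty_fraction = 0)
  trlow <- simulateDroop(plow, tEnd = 2, gridStep = 0.01)
  expect_true(any(trlow$mu == 0))
  grlow <- castGrowthSubsystem(trlow)
  expect_true(all(grlow$data$delta2[trlow$mu == 0] == 0))

  # a biomass wash-out violates the bounded-gain assumption
  fake <- refDroop()[1:10, ]
  fake$x[5] <- 0
  attr(fake, "params") <- attr(refDroop(), "params")
  class(fake) <- class(refDroop())
  expect_error(castUptakeSubsystem(fake), "zero")
})
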