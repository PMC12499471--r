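test_that("nucleation rate evaluates the power law", {
  expect_equal(nucleation_rate(rate_model(1, 2), 3), 9)
  expect_equal(nucleation_rate(rate_model(5, 3.7), 0), 0)
  # hand evaluation: 5e-2 * 10^7.2
  expect_equal(nucleation_rate(rate_model(5e-2, 7.2), 10), 5e-2 * 10^7.2)
  expect_true(all(diff(nucleation_rate(rate_model(2, 1.5), 1:10)) > 0))
  expect_error(nucleation_rate(rate_model(1, 2), -1), ">= 0")
  expect_error(rate_model(-1, 2), "gamma")
  expect_error(rate_model(1, -2), "n")
})

test_that("ramp survival has the closed Weibull form", {
  m0 <- rate_model(1, 0); p0 <- protocol(1, 1)
  expect_equal(ramp_survival(m0, p0, 0), 1)
  # n = 0 reduces to an exponential: survival 1/2 at delta_T = ln 2
  expect_equal(ramp_survival(m0, p0, log(2)), 0.5)
  m <- droplet_model(); p <- droplet_protocol()
  expect_equal(ramp_survival(m, p, 0), 1)
  dT <- seq(0, 15, by = 0.5)
  chi <- ramp_survival(m, p, dT)
  expect_true(all(diff(chi) <= 0))
})

test_that("closed-form survival equals the quadrature of the rate integral", {
  withr::local_seed(11)
  for (i in 1:10) {
    m <- rate_model(10^stats::runif(1, -4, 0), stats::runif(1, 0, 10))
    p <- protocol(10^stats::runif(1, -2, 0), 10^stats::runif(1, -6, -2))
    dT <- stats::runif(1, 0.5, 2) * weib_scale(m, p)
    q <- stats::integrate(function(x) nucleation_rate(m, x), 0, dT,
                          rel.tol = 1e-12)$value
    expect_equal(ramp_survival(m, p, dT), exp(-p$S / p$k * q),
                 tolerance = 1e-10)
  }
})

test_that("log(-log survival) is linear in log delta_T with slope n + 1", {
  m <- droplet_model(); p <- droplet_protocol()
  a <- 2; b <- 9
  slope <- log(log(ramp_survival(m, p, b)) / log(ramp_survival(m, p, a))) /
    log(b / a)
  expect_equal(slope, m$n + 1, tolerance = 1e-10)
})

test_that("mean supercooling matches its closed form and scalings", {
  # n = 0: exponential mean k / (gamma S), Gamma(2) = 1
  m0 <- rate_model(0.4, 0)
  expect_equal(mean_supercooling(m0, protocol(2, 5)), 2 / (0.4 * 5))
  # n = 1: doubling S shrinks the mean by sqrt(2)
  m1 <- rate_model(0.3, 1)
  expect_equal(mean_supercooling(m1, protocol(1, 1)) /
                 mean_supercooling(m1, protocol(1, 2)), sqrt(2))
  # increasing in k, decreasing in gamma and S
  m <- droplet_model()
  expect_gt(mean_supercooling(m, protocol(0.2, 1e-5)),
            mean_supercooling(m, protocol(0.1, 1e-5)))
  expect_gt(mean_supercooling(m, protocol(0.1, 1e-5)),
            mean_supercooling(m, protocol(0.1, 1e-4)))
})

test_that("mean supercooling equals the integral of the survival curve", {
  withr::local_seed(21)
  for (i in 1:10) {
    m <- rate_model(10^stats::runif(1, -4, 0), stats::runif(1, 0, 10))
    p <- protocol(10^stats::runif(1, -2, 0), 10^stats::runif(1, -6, -2))
    lam <- weib_scale(m, p)
    mu_quad <- lam * stats::integrate(
      function(u) exp(-u^(m$n + 1)), 0, Inf, rel.tol = 1e-12)$value
    expect_equal(mean_supercooling(m, p), mu_quad, tolerance = 1e-8)
  }
})

test_that("isothermal time is the reciprocal hazard", {
  m <- rate_model(1, 2)
  expect_equal(isothermal_time(m, S = 0.5, delta_T = 2), 0.5)
  expect_equal(isothermal_time(m, S = 1, delta_T = 2),
               2 * isothermal_time(m, S = 2, delta_T = 2))
  expect_true(all(diff(isothermal_time(m, 1, c(1, 2, 4, 8))) < 0))
  # no nucleation at zero supercooling: distinguished Inf, not an error
  expect_identical(isothermal_time(m, 1, 0), Inf)
})

test_that("freezing probability is the memoryless exponential first passage", {
  m <- droplet_model()
  expect_equal(freezing_probability(m, 1e-3, 5, 0), 0)
  # probability at the mean waiting time is 1 - 1/e
  tmean <- isothermal_time(m, 1e-3, 5)
  expect_equal(freezing_probability(m, 1e-3, 5, tmean), 1 - exp(-1))
  # memorylessness: (1 - P(t1 + t2)) = (1 - P(t1)) (1 - P(t2))
  S2 <- 1e-6; dT2 <- 3          # hazard S*J ~ 6.6e-3 /s, mean ~150 s
  t1 <- 30; t2 <- 110
  expect_equal(
    1 - freezing_probability(m, S2, dT2, t1 + t2),
    (1 - freezing_probability(m, S2, dT2, t1)) *
      (1 - freezing_probability(m, S2, dT2, t2)),
    tolerance = 1e-12)
  expect_true(all(diff(freezing_probability(m, S2, dT2,
                                            c(0, 50, 150, 500))) > 0))
})

test_that("scale-up prediction evaluates the model at the target protocol", {
  m <- droplet_model(); small <- droplet_protocol()
  same <- predict_scaleup(m, small)
  expect_equal(same$mean_delta_T, mean_supercooling(m, small))
  # n = 1: quadrupling the area halves the expected supercooling
  m1 <- rate_model(0.2, 1)
  p1 <- protocol(0.1, 1e-4); p4 <- protocol(0.1, 4e-4)
  expect_equal(predict_scaleup(m1, p1)$mean_delta_T /
                 predict_scaleup(m1, p4)$mean_delta_T, 2)
  # survival curve is attached and consistent with ramp_survival
  big <- predict_scaleup(m, protocol(0.1, 6e-3))
  expect_equal(big$survival$survival,
               ramp_survival(m, protocol(0.1, 6e-3), big$survival$delta_T))
})
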