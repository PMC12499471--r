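test_that("with n fixed at 0 the MLE is the closed-form moment estimator", {
  m0 <- rate_model(0.5, 0); p <- protocol(0.2, 2)
  a <- generate_assay(m0, p, n_cycles = 200, seed = 15)
  fit <- fit_rate_model(a, fix_n = 0)
  expect_equal(fit$model$gamma, p$k / (p$S * mean(a$delta_T)),
               tolerance = 1e-6)
  expect_equal(fit$model$n, 0)
})

test_that("the MLE agrees with survreg's Weibull fit (independent oracle)", {
  m <- droplet_model(); p <- droplet_protocol()
  a <- generate_assay(m, p, n_cycles = 300, floor = 7.5, seed = 16)
  expect_gt(sum(a$censored), 0)
  fit <- fit_rate_model(a)
  sr <- survival::survreg(
    survival::Surv(a$delta_T, !a$censored) ~ 1, dist = "weibull")
  shape_sr <- 1 / sr$scale
  scale_sr <- exp(unname(stats::coef(sr)[1]))
  expect_equal(fit$model$n + 1, shape_sr, tolerance = 1e-4)
  expect_equal(weib_scale(fit$model, p), scale_sr, tolerance = 1e-5)
})

test_that("primary MLE and secondary log-log route agree on clean data", {
  m <- droplet_model(); p <- droplet_protocol()
  a <- generate_assay(m, p, n_cycles = 2000, seed = 17)
  fit <- fit_rate_model(a)
  ll <- fit_rate_loglog(a)
  expect_lt(abs(ll$n - fit$model$n) / fit$model$n, 0.10)
  expect_lt(abs(weib_scale(rate_model(ll$gamma, ll$n), p) -
                  weib_scale(fit$model, p)) / weib_scale(fit$model, p), 0.02)
  expect_gt(ll$r_squared, 0.95)
  # and both sit near the generating parameters
  expect_lt(abs(fit$model$n - m$n) / m$n, 0.15)
  expect_lt(abs(weib_scale(fit$model, p) - weib_scale(m, p)) /
              weib_scale(m, p), 0.02)
})

test_that("the fitted model reproduces the sample mean (self-consistency)", {
  m <- droplet_model(); p <- droplet_protocol()
  a <- generate_assay(m, p, n_cycles = 500, seed = 18)
  fit <- fit_rate_model(a)
  se <- stats::sd(a$delta_T) / sqrt(nrow(a))
  expect_lt(abs(mean_supercooling(fit$model, p) - mean(a$delta_T)), 3 * se)
})

test_that("degenerate and unusable assays fail loudly", {
  p <- droplet_protocol()
  same <- freezing_assay(data.frame(delta_T = rep(5, 40), censored = FALSE), p)
  expect_error(fit_rate_model(same), "degenerate")
  all_cens <- freezing_assay(data.frame(delta_T = rep(8, 20), censored = TRUE),
                             p)
  expect_error(fit_rate_model(all_cens), "uncensored")
  tiny <- freezing_assay(data.frame(delta_T = c(4, 5, 5.5, 6, 7),
                                    censored = FALSE), p)
  expect_warning(fit_rate_model(tiny), "fewer than 10")
})

test_that("tidy and glance expose estimates, intervals and fit diagnostics", {
  a <- generate_assay(droplet_model(), droplet_protocol(), seed = 19)
  fit <- fit_rate_model(a)
  td <- tidy(fit)
  expect_equal(td$term, c("gamma", "n"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$nobs, 100)
  expect_true(gl$converged)
  expect_equal(gl$mean_delta_T,
               mean_supercooling(fit$model, assay_protocol(a)))
})

test_that("end-to-end: simulate, fit, and predict at a larger scale", {
  m <- droplet_model(); small <- droplet_protocol()
  large <- protocol(k = small$k, S = 100 * small$S)
  withr::local_seed(20)
  hits <- 0
  for (i in 1:10) {
    a <- generate_assay(m, small, n_cycles = 100)
    fit <- fit_rate_model(a)
    pred <- predict_scaleup(fit, large)
    mc <- mean(sample_ramp_freezing(m, large, 2000))
    # prediction uncertainty via the delta method on (log gamma, log(n+1))
    grad <- numeric_grad(function(phi) {
      mm <- rate_model(exp(phi[1]), exp(phi[2]) - 1)
      mean_supercooling(mm, large)
    }, c(log(fit$model$gamma), log(fit$model$n + 1)))
    se_pred <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
    if (abs(pred$mean_delta_T - mc) < 1.96 * se_pred + 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
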