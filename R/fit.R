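#' Fit the power-law nucleation rate to a freezing assay
#'
#' Maximum-likelihood estimation of `gamma` and `n` in
#' `J(dT) = gamma * dT^n` from per-cycle supercooling observations. Under the
#' linear-ramp Poisson model the uncensored supercooling degrees are Weibull
#' with shape `n + 1` and scale `(k (n+1) / (S gamma))^(1/(n+1))`; cycles that
#' reached the ramp floor unfrozen contribute their survival factor. The
#' likelihood is maximised in the unconstrained parameters
#' `(log gamma, log(n + 1))`: `gamma` has a closed-form profile maximiser, and
#' the profile in `log(n + 1)` is optimised numerically starting from the
#' log-log regression estimate (see [fit_rate_loglog()]). Standard errors come
#' from the observed information at the optimum.
#'
#' @param assay A [freezing_assay()] with at least 10 uncensored cycles (a
#'   smaller assay fits but with a warning).
#' @param fix_n Optional: hold the exponent fixed at this value and estimate
#'   only `gamma` (closed form).
#' @param n_max Upper bound for the exponent search (default 100). Hitting it
#'   is reported as non-convergence.
#'
#' @return An object of class `rate_fit`: a list with elements `model` (the
#'   fitted [rate_model()]), `se` (standard errors for `gamma` and `n`),
#'   `vcov` (covariance of `(log gamma, log(n+1))`), `logLik`, `n_obs`,
#'   `n_censored`, `converged`, and `protocol`. Supports [tidy()], [glance()],
#'   `autoplot()` and [predict_scaleup()].
#' @examples
#' a <- generate_assay(rate_model(1e-3, 8), seed = 7)
#' fit <- fit_rate_model(a)
#' tidy(fit)
#' @export
fit_rate_model <- function(assay, fix_n = NULL, n_max = 100) {
  stopifnot(inherits(assay, "freezing_assay"))
  p <- assay_protocol(assay)
  unc <- assay$delta_T[!assay$censored]
  n_unc <- length(unc)
  if (n_unc < 1) stop("no uncensored cycles; nothing to fit", call. = FALSE)
  if (n_unc < 10) {
    warning("fewer than 10 uncensored cycles; estimates will be unstable",
            call. = FALSE)
  }
  if (stats::sd(log(unc)) < 1e-12 && is.null(fix_n)) {
    stop(paste("degenerate assay: all uncensored supercooling degrees are",
               "identical; the exponent is unidentifiable"), call. = FALSE)
  }

  # negative log-likelihood in phi = (log gamma, a = log(n + 1))
  nll <- function(phi) {
    g <- exp(phi[1]); s <- exp(phi[2])  # s = n + 1
    -(n_unc * (log(p$S) + phi[1] - log(p$k)) +
        (s - 1) * sum(log(unc)) -
        (p$S * g) / (p$k * s) * sum(assay$delta_T^s))
  }
  # closed-form profile maximiser of gamma at fixed shape s
  gamma_hat <- function(s) {
    n_unc * p$k * s / (p$S * sum(assay$delta_T^s))
  }

  if (!is.null(fix_n)) {
    if (fix_n < 0) stop("`fix_n` must be >= 0", call. = FALSE)
    s <- fix_n + 1
    g <- gamma_hat(s)
    se_lg <- 1 / sqrt(n_unc)  # observed information for log gamma is n_unc
    fit <- list(
      model = rate_model(g, fix_n),
      se = c(gamma = g * se_lg, n = 0),
      vcov = matrix(c(se_lg^2, 0, 0, 0), 2, 2,
                    dimnames = list(c("log_gamma", "log_n1"),
                                    c("log_gamma", "log_n1"))),
      logLik = -nll(c(log(g), log(s))),
      n_obs = nrow(assay), n_censored = sum(assay$censored),
      converged = TRUE, fixed_n = TRUE, protocol = p
    )
    class(fit) <- "rate_fit"
    return(fit)
  }

  # start from the secondary log-log regression route
  start <- tryCatch({
    ll <- fit_rate_loglog(assay)
    c(log(ll$gamma), log(ll$n + 1))
  }, error = function(e) c(log(gamma_hat(2)), log(2)))
  start[2] <- min(max(start[2], log(1 + 1e-6)), log(n_max + 1) - 0.1)

  prof_nll <- function(a) nll(c(log(gamma_hat(exp(a))), a))
  opt1 <- stats::optimize(prof_nll, lower = 0, upper = log(n_max + 1))
  opt2 <- stats::optim(start, nll, method = "BFGS",
                       control = list(reltol = 1e-12, maxit = 500))
  a_hat <- if (opt1$objective <= opt2$value) opt1$minimum else opt2$par[2]
  phi <- c(log(gamma_hat(exp(a_hat))), a_hat)
  # polish jointly
  opt <- stats::optim(phi, nll, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  if (opt$value < nll(phi)) phi <- opt$par

  s_hat <- exp(phi[2])
  if (s_hat > n_max) {
    stop(sprintf(paste("fit did not converge: exponent estimate hit the",
                       "search bound (n = %.1f); the assay may be degenerate"),
                 s_hat - 1), call. = FALSE)
  }
  H <- stats::optimHess(phi, nll)
  vc <- tryCatch(solve(H), error = function(e) {
    stop("fit did not converge: singular observed information", call. = FALSE)
  })
  if (any(diag(vc) <= 0)) {
    stop("fit did not converge: non-positive-definite information",
         call. = FALSE)
  }
  dimnames(vc) <- list(c("log_gamma", "log_n1"), c("log_gamma", "log_n1"))
  g_hat <- exp(phi[1]); n_hat <- s_hat - 1
  fit <- list(
    model = rate_model(g_hat, n_hat),
    se = c(gamma = g_hat * sqrt(vc[1, 1]), n = s_hat * sqrt(vc[2, 2])),
    vcov = vc,
    logLik = -nll(phi),
    n_obs = nrow(assay), n_censored = sum(assay$censored),
    converged = TRUE, fixed_n = FALSE, protocol = p
  )
  class(fit) <- "rate_fit"
  fit
}

#' Log-log regression fit of the nucleation rate (secondary route)
#'
#' The graphical route: under the ramp model `-log(chi)` is a power function
#' of the supercooling degree with exponent `n + 1`, so
#' `log(-log chi)` regressed on `log dT` over the product-limit survival
#' curve recovers the rate parameters. Survival at each event is taken at the
#' step midpoint so the final (zero-survival) step remains usable. Provided as
#' an independent cross-check of [fit_rate_model()] and as its starting value.
#'
#' @param assay A [freezing_assay()].
#' @return A list with elements `gamma`, `n`, `r_squared`.
#' @export
fit_rate_loglog <- function(assay) {
  stopifnot(inherits(assay, "freezing_assay"))
  p <- assay_protocol(assay)
  km <- empirical_survival(assay)
  km <- km[km$n_event > 0, ]
  chi_prev <- c(1, km$survival[-nrow(km)])
  chi_mid <- (chi_prev + km$survival) / 2
  keep <- chi_mid > 0 & chi_mid < 1 & km$delta_T > 0
  if (sum(keep) < 3) {
    stop("too few distinct freezing events for the log-log fit", call. = FALSE)
  }
  x <- log(km$delta_T[keep])
  y <- log(-log(chi_mid[keep]))
  ls <- stats::lm.fit(cbind(1, x), y)
  slope <- ls$coefficients[2]
  if (!is.finite(slope) || slope <= 0) {
    stop("log-log fit failed: non-positive slope", call. = FALSE)
  }
  n <- unname(slope - 1)
  # intercept = log(S gamma / (k (n+1)))
  gamma <- unname(exp(ls$coefficients[1]) * p$k * slope / p$S)
  r2 <- 1 - sum(ls$residuals^2) / sum((y - mean(y))^2)
  list(gamma = gamma, n = n, r_squared = r2)
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit> power-law nucleation rate, Weibull/censoring MLE\n")
  cat(sprintf("  gamma = %.4g +/- %.3g %s\n", x$model$gamma, x$se[["gamma"]],
              rate_units(x$model)))
  cat(sprintf("  n     = %.4g +/- %.3g\n", x$model$n, x$se[["n"]]))
  cat(sprintf("  logLik = %.3f on %d cycles (%d censored)\n",
              x$logLik, x$n_obs, x$n_censored))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted nucleation rate model
#'
#' One row per parameter with estimate, standard error and Wald confidence
#' interval. Intervals are built on the unconstrained scale
#' (`log gamma`, `log(n + 1)`) and back-transformed, so they respect the
#' parameter domains.
#'
#' @param x A [fit_rate_model()] result.
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy rate_fit
#' @export
tidy.rate_fit <- function(x, conf.level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  lg <- log(x$model$gamma); a <- log(x$model$n + 1)
  se_lg <- sqrt(x$vcov[1, 1]); se_a <- sqrt(x$vcov[2, 2])
  tibble::tibble(
    term = c("gamma", "n"),
    estimate = c(x$model$gamma, x$model$n),
    std.error = c(x$se[["gamma"]], x$se[["n"]]),
    conf.low = c(exp(lg - z * se_lg), exp(a - z * se_a) - 1),
    conf.high = c(exp(lg + z * se_lg), exp(a + z * se_a) - 1)
  )
}

#' Glance at a fitted nucleation rate model
#'
#' @param x A [fit_rate_model()] result.
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `nobs`, `n_censored`,
#'   `converged`, and the predicted mean supercooling at the assay protocol.
#' @method glance rate_fit
#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik,
    nobs = x$n_obs,
    n_censored = x$n_censored,
    converged = x$converged,
    mean_delta_T = mean_supercooling(x$model, x$protocol)
  )
}
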