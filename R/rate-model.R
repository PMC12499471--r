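#' Power-law nucleation rate model
#'
#' The empirical surface nucleation rate `J(dT) = gamma * dT^n` (events per
#' square metre per second at supercooling `dT` kelvin). `gamma` and `n` are
#' empirical parameters of the nucleating interface; note that the units of
#' `gamma` depend on `n` (m^-2 s^-1 K^-n), so the two are always stored and
#' printed together.
#'
#' @param gamma Rate prefactor (events m^-2 s^-1 K^-n), > 0.
#' @param n Power-law exponent (dimensionless), >= 0.
#'
#' @return An object of class `rate_model`.
#' @examples
#' rate_model(gamma = 1e-3, n = 8)
#' @export
rate_model <- function(gamma, n) {
  if (!is.finite(gamma) || gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  if (!is.finite(n) || n < 0) stop("`n` must be >= 0", call. = FALSE)
  structure(list(gamma = gamma, n = n), class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> J(dT) = gamma * dT^n with gamma = %g %s, n = %g\n",
              x$gamma, rate_units(x), x$n))
  invisible(x)
}

rate_units <- function(model) sprintf("m^-2 s^-1 K^-%g", model$n)

#' Cooling/holding protocol
#'
#' Protocol metadata for a freezing assay or a preservation scenario: the
#' linear cooling-ramp rate, the nucleating surface area of the container, and
#' optionally an isothermal hold temperature for storage-phase prediction.
#'
#' @param k Cooling rate (K s^-1), > 0.
#' @param S Nucleating surface area (m^2), > 0.
#' @param T_hold Optional isothermal hold temperature (degrees C).
#'
#' @return An object of class `protocol`.
#' @examples
#' protocol(k = 0.1, S = 1e-5)          # 6 C/min droplet assay
#' protocol(k = 0.1, S = 6e-3, T_hold = -4)
#' @export
protocol <- function(k, S, T_hold = NULL) {
  if (!is.finite(k) || k <= 0) stop("`k` must be > 0", call. = FALSE)
  if (!is.finite(S) || S <= 0) stop("`S` must be > 0", call. = FALSE)
  structure(list(k = k, S = S, T_hold = T_hold), class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> k = %g K/s, S = %g m^2%s\n", x$k, x$S,
              if (is.null(x$T_hold)) "" else sprintf(", T_hold = %g C", x$T_hold)))
  invisible(x)
}

#' Nucleation rate at a given supercooling
#'
#' Evaluates `J(dT) = gamma * dT^n`.
#'
#' @param model A [rate_model()].
#' @param delta_T Supercooling degree (K), >= 0. Vectorised.
#' @return Rate in events m^-2 s^-1.
#' @examples
#' nucleation_rate(rate_model(1e-3, 8), 5)
#' @export
nucleation_rate <- function(model, delta_T) {
  stopifnot(inherits(model, "rate_model"))
  if (any(!is.finite(delta_T)) || any(delta_T < 0)) {
    stop("`delta_T` must be finite and >= 0", call. = FALSE)
  }
  model$gamma * delta_T^model$n
}

# Weibull scale of the ramp supercooling distribution:
# shape = n + 1, scale = (k (n+1) / (S gamma))^(1/(n+1))
ramp_weibull_scale <- function(model, protocol) {
  s <- model$n + 1
  (protocol$k * s / (protocol$S * model$gamma))^(1 / s)
}

#' Survival under a linear cooling ramp
#'
#' Probability that a sample remains unfrozen on reaching supercooling
#' `delta_T` under a linear ramp at rate `k` with nucleating area `S`, from
#' the non-homogeneous Poisson model:
#' `chi(dT) = exp(-(S * gamma) / (k * (n + 1)) * dT^(n + 1))`.
#' This is a Weibull survival function with shape `n + 1`.
#'
#' @param model A [rate_model()].
#' @param protocol A [protocol()].
#' @param delta_T Supercooling degree (K), >= 0. Vectorised.
#' @return Survival probability in \[0, 1\].
#' @examples
#' m <- rate_model(1e-3, 8); p <- protocol(0.1, 1e-5)
#' ramp_survival(m, p, c(0, 5, 8, 12))
#' @export
ramp_survival <- function(model, protocol, delta_T) {
  stopifnot(inherits(model, "rate_model"), inherits(protocol, "protocol"))
  if (any(!is.finite(delta_T)) || any(delta_T < 0)) {
    stop("`delta_T` must be finite and >= 0", call. = FALSE)
  }
  s <- model$n + 1
  exp(-(protocol$S * model$gamma) / (protocol$k * s) * delta_T^s)
}

#' Expected supercooling degree under a cooling ramp
#'
#' Mean of the supercooling distribution implied by [ramp_survival()]:
#' `(k * (n + 1) / (gamma * S))^(1/(n + 1)) * Gamma((n + 2) / (n + 1))`.
#' Decreases with surface area and with the rate prefactor, and grows with the
#' cooling rate — the analytic bridge from small-sample assays to large
#' preservers.
#'
#' @inheritParams ramp_survival
#' @return Expected supercooling in K.
#' @examples
#' mean_supercooling(rate_model(1e-3, 8), protocol(0.1, 1e-5))
#' @export
mean_supercooling <- function(model, protocol) {
  stopifnot(inherits(model, "rate_model"), inherits(protocol, "protocol"))
  s <- model$n + 1
  ramp_weibull_scale(model, protocol) * gamma((s + 1) / s)
}

#' Expected isothermal preservation time
#'
#' Mean waiting time to the first nucleation event while holding at a constant
#' supercooling: `t = 1 / (S * J(dT))`. At `delta_T = 0` the rate vanishes
#' (for `n > 0`) and the expected time is reported as `Inf` (no nucleation),
#' not as an error.
#'
#' @param model A [rate_model()].
#' @param S Nucleating surface area (m^2).
#' @param delta_T Hold supercooling (K), >= 0. Vectorised.
#' @return Expected time in seconds (possibly `Inf`).
#' @examples
#' isothermal_time(rate_model(1e-3, 8), S = 6e-3, delta_T = 4)
#' @export
isothermal_time <- function(model, S, delta_T) {
  stopifnot(inherits(model, "rate_model"))
  if (any(S <= 0)) stop("`S` must be > 0", call. = FALSE)
  if (any(delta_T < 0)) stop("`delta_T` must be >= 0", call. = FALSE)
  J <- nucleation_rate(model, delta_T)
  ifelse(J > 0, 1 / (S * J), Inf)
}

#' Freezing probability over an isothermal hold
#'
#' Probability that at least one nucleation event occurs within `t_hold`
#' seconds while holding at constant supercooling `delta_T`:
#' `P = 1 - exp(-S * J(dT) * t_hold)`. This is the constant-hazard
#' (exponential first-passage) consequence of the power-law rate at fixed
#' temperature; the hazard `S * J` does not depend on elapsed time, so holds
#' are memoryless.
#'
#' @param model A [rate_model()].
#' @param S Nucleating surface area (m^2).
#' @param delta_T Hold supercooling (K), >= 0.
#' @param t_hold Hold duration (s), >= 0. Vectorised with `delta_T`.
#' @return Freezing probability in \[0, 1\].
#' @examples
#' freezing_probability(rate_model(1e-3, 8), S = 6e-3, delta_T = 4,
#'                      t_hold = 48 * 3600)
#' @export
freezing_probability <- function(model, S, delta_T, t_hold) {
  stopifnot(inherits(model, "rate_model"))
  if (any(S <= 0)) stop("`S` must be > 0", call. = FALSE)
  if (any(t_hold < 0)) stop("`t_hold` must be >= 0", call. = FALSE)
  1 - exp(-S * nucleation_rate(model, delta_T) * t_hold)
}

#' Predict supercooling performance at a different scale
#'
#' Evaluates the fitted rate model at a new protocol (typically a much larger
#' preserver): the expected supercooling degree and the full predictive ramp
#' survival curve at the new surface area and cooling rate.
#'
#' @param model A [rate_model()] (or a [fit_rate_model()] result, whose model
#'   is used).
#' @param protocol The target [protocol()].
#' @param delta_T Optional supercooling grid for the survival curve; default
#'   spans 0 to ~4x the predicted mean.
#'
#' @return A list of class `scaleup_prediction` with elements
#'   `mean_delta_T` (K) and `survival` (a tibble `delta_T`, `survival`).
#' @examples
#' m <- rate_model(1e-3, 8)
#' predict_scaleup(m, protocol(0.1, 6e-3))
#' @export
predict_scaleup <- function(model, protocol, delta_T = NULL) {
  if (inherits(model, "rate_fit")) model <- model$model
  stopifnot(inherits(model, "rate_model"), inherits(protocol, "protocol"))
  mu <- mean_supercooling(model, protocol)
  if (is.null(delta_T)) delta_T <- seq(0, 4 * mu, length.out = 201)
  structure(
    list(
      mean_delta_T = mu,
      survival = tibble::tibble(
        delta_T = delta_T,
        survival = ramp_survival(model, protocol, delta_T)
      ),
      protocol = protocol,
      model = model
    ),
    class = "scaleup_prediction"
  )
}

#' @export
print.scaleup_prediction <- function(x, ...) {
  cat(sprintf(
    "<scaleup_prediction> S = %g m^2, k = %g K/s: expected supercooling %.3f K\n",
    x$protocol$S, x$protocol$k, x$mean_delta_T))
  invisible(x)
}
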