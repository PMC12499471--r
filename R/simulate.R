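#' Sample supercooling degrees under a linear cooling ramp
#'
#' Draws first-nucleation supercooling degrees for repeated cooling cycles by
#' inverse-CDF sampling of the ramp survival distribution:
#' `dT = scale * (-log(U))^(1/(n+1))` with `U ~ Uniform(0, 1)` and
#' `scale = (k (n+1) / (S gamma))^(1/(n+1))` — an exact draw from the Weibull
#' law implied by the non-homogeneous Poisson model.
#'
#' @param model A [rate_model()].
#' @param protocol A [protocol()].
#' @param n_cycles Number of cooling cycles to simulate.
#' @param seed Optional integer seed; identical seeds give identical draws and
#'   the caller's RNG state is left untouched.
#'
#' @return Numeric vector of supercooling degrees (K), length `n_cycles`.
#' @examples
#' sample_ramp_freezing(rate_model(1e-3, 8), protocol(0.1, 1e-5),
#'                      n_cycles = 5, seed = 1)
#' @export
sample_ramp_freezing <- function(model, protocol, n_cycles, seed = NULL) {
  stopifnot(inherits(model, "rate_model"), inherits(protocol, "protocol"))
  if (n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  s <- model$n + 1
  draw <- function() {
    ramp_weibull_scale(model, protocol) *
      (-log(stats::runif(n_cycles)))^(1 / s)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Sample isothermal waiting times to nucleation
#'
#' Draws times to the first nucleation event while holding at a constant
#' supercooling. The hazard `S * J(dT)` is constant in time, so waiting times
#' are exponential with mean [isothermal_time()].
#'
#' @param model A [rate_model()].
#' @param S Nucleating surface area (m^2).
#' @param delta_T Hold supercooling (K), > 0.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#'
#' @return Numeric vector of waiting times (s).
#' @examples
#' sample_isothermal_freezing(rate_model(1e-3, 8), S = 6e-3, delta_T = 4,
#'                            n = 5, seed = 1)
#' @export
sample_isothermal_freezing <- function(model, S, delta_T, n, seed = NULL) {
  stopifnot(inherits(model, "rate_model"))
  if (delta_T <= 0) stop("`delta_T` must be > 0", call. = FALSE)
  draw <- function() stats::rexp(n, rate = S * nucleation_rate(model, delta_T))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Synthesise a thermocouple temperature trace
#'
#' Builds the temperature log a thermocouple would record during one cooling
#' cycle: a linear ramp from the start temperature at rate `k` with additive
#' iid Gaussian sensor noise, and — if a nucleation time is given — an
#' instantaneous recalescence jump to the latent-heat plateau (0 degrees C by
#' default) that holds for the rest of the trace.
#'
#' @param k Cooling rate (K s^-1).
#' @param duration Trace length (s).
#' @param nucleation_time Time of the nucleation event (s), or `NULL` for a
#'   cycle that never froze.
#' @param T_start Start temperature (degrees C); default 0 (ramp enters the
#'   supercooled regime immediately).
#' @param sample_rate Sampling rate (Hz).
#' @param noise_sd Sensor noise standard deviation (K).
#' @param plateau Post-nucleation plateau temperature (degrees C).
#' @param seed Optional integer seed for the noise.
#'
#' @return A tibble of class `temperature_trace` with columns `time_s`,
#'   `temp_C`.
#' @examples
#' synth_trace(k = 0.1, duration = 120, nucleation_time = 80, seed = 1)
#' @export
synth_trace <- function(k, duration, nucleation_time = NULL, T_start = 0,
                        sample_rate = 10, noise_sd = 0.05, plateau = 0,
                        seed = NULL) {
  if (k <= 0 || duration <= 0 || sample_rate <= 0 || noise_sd < 0) {
    stop("`k`, `duration`, `sample_rate` must be > 0 and `noise_sd` >= 0",
         call. = FALSE)
  }
  if (!is.null(nucleation_time) &&
      (nucleation_time < 0 || nucleation_time > duration)) {
    stop("`nucleation_time` must lie within the trace duration", call. = FALSE)
  }
  t <- seq(0, duration, by = 1 / sample_rate)
  temp <- T_start - k * t
  if (!is.null(nucleation_time)) {
    temp[t >= nucleation_time] <- plateau
  }
  add_noise <- function() temp + stats::rnorm(length(t), sd = noise_sd)
  temp <- if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
  out <- tibble::tibble(time_s = t, temp_C = temp)
  class(out) <- c("temperature_trace", class(out))
  out
}

#' Simulate a complete freezing assay
#'
#' Runs [sample_ramp_freezing()] for `n_cycles` cooling cycles and packages
#' the outcomes as a [freezing_assay()], right-censoring any cycle whose
#' nucleation supercooling would exceed the ramp floor (the deepest
#' supercooling the ramp reaches). Defaults mirror a droplet-scale assay:
#' 100 cycles cooled at 6 degrees C per minute.
#'
#' @param model A [rate_model()].
#' @param protocol A [protocol()]; default `protocol(k = 0.1, S = 1e-5)`.
#' @param n_cycles Number of cycles (default 100).
#' @param floor Ramp-floor supercooling (K); cycles still unfrozen there are
#'   censored. Default `Inf` (every cycle freezes, as in a ramp run to
#'   nucleation).
#' @param seed Optional integer seed.
#'
#' @return A [freezing_assay()] tibble.
#' @examples
#' generate_assay(rate_model(1e-3, 8), seed = 42)
#' @export
generate_assay <- function(model, protocol = supercoolr::protocol(0.1, 1e-5),
                           n_cycles = 100, floor = Inf, seed = NULL) {
  if (floor <= 0) stop("`floor` must be > 0", call. = FALSE)
  dt <- sample_ramp_freezing(model, protocol, n_cycles, seed = seed)
  cens <- dt > floor
  freezing_assay(
    data.frame(
      cycle = seq_len(n_cycles),
      delta_T = ifelse(cens, floor, dt),
      censored = cens
    ),
    protocol
  )
}

# Independent slow oracle: event-driven hazard-increment sampler for the ramp.
# Steps the ramp in increments dt and fires with probability S*J(k*t)*dt per
# step. Used in tests to cross-check the inverse-CDF sampler; not exported.
sample_ramp_time_stepping <- function(model, protocol, n_cycles, dt = 1e-3,
                                      dT_max = NULL, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, sample_ramp_time_stepping(model, protocol, n_cycles, dt = dt,
                                      dT_max = dT_max)))
  }
  if (is.null(dT_max)) {
    dT_max <- 10 * ramp_weibull_scale(model, protocol)
  }
  dT_grid <- seq(0, dT_max, by = protocol$k * dt)
  p_step <- pmin(1, protocol$S * nucleation_rate(model, dT_grid) * dt)
  vapply(seq_len(n_cycles), function(i) {
    fired <- which(stats::runif(length(p_step)) < p_step)
    if (length(fired) == 0) dT_max else dT_grid[fired[1]]
  }, numeric(1))
}
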