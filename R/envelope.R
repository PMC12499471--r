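#' Deepest safe hold temperature for a preservation scenario
#'
#' Inverts [freezing_probability()] for the supercooling degree: the hold
#' temperature at which the probability of freezing within `duration` equals
#' the accepted `risk`,
#' `dT = (-log(1 - risk) / (S * gamma * duration))^(1/n)`.
#' Longer durations and larger containers force a warmer (smaller
#' supercooling) hold. For `n = 0` the freezing probability does not depend on
#' temperature, so no finite solution exists and `NA` is returned with a
#' warning.
#'
#' @param model A [rate_model()] (or [fit_rate_model()] result).
#' @param S Nucleating surface area (m^2).
#' @param duration Hold duration (s). Vectorised.
#' @param risk Accepted freezing probability, in (0, 1).
#' @param melting_point Melting temperature (degrees C) the supercooling is
#'   referenced to. Default 0.
#' @param delta_T_cap Cap on the allowed supercooling (K); solutions beyond it
#'   (e.g. as `risk` approaches 1) are clipped with a warning. Default 273.15.
#'
#' @return Hold temperature in degrees C (negative for supercooled holds).
#' @examples
#' safe_temperature(rate_model(1e-3, 8), S = 6e-3,
#'                  duration = 7 * 24 * 3600, risk = 0.05)
#' @export
safe_temperature <- function(model, S, duration, risk,
                             melting_point = 0, delta_T_cap = 273.15) {
  if (inherits(model, "rate_fit")) model <- model$model
  stopifnot(inherits(model, "rate_model"))
  if (any(risk <= 0) || any(risk >= 1)) {
    stop("`risk` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(S <= 0) || any(duration <= 0)) {
    stop("`S` and `duration` must be > 0", call. = FALSE)
  }
  if (model$n == 0) {
    warning(paste("exponent n = 0: freezing probability is independent of",
                  "temperature, no finite safe temperature exists"),
            call. = FALSE)
    return(rep(NA_real_, max(length(duration), length(S))))
  }
  dT <- (-log(1 - risk) / (S * model$gamma * duration))^(1 / model$n)
  if (any(dT > delta_T_cap)) {
    warning(sprintf(
      "allowed supercooling exceeds the %g K cap for some inputs; clipped",
      delta_T_cap), call. = FALSE)
    dT <- pmin(dT, delta_T_cap)
  }
  melting_point - dT
}

#' Preservation envelope table
#'
#' Tabulates, for each labelled container area and hold duration, the deepest
#' hold temperature compatible with the accepted freezing risk, and — if a
#' hold temperature is supplied — the freezing probability of holding at that
#' temperature for the duration. Rows are sorted by area then duration, so the
#' table reads as a preservation envelope (safe temperature shrinking toward
#' the melting point as containers grow and holds lengthen).
#'
#' @param model A [rate_model()] (or [fit_rate_model()] result).
#' @param areas Named numeric vector of container surface areas (m^2); names
#'   label the rows (e.g. organ or container names).
#' @param durations Numeric vector of hold durations (s).
#' @param risk Accepted freezing probability in (0, 1); default 0.05.
#' @param hold_temp_C Optional hold temperature (degrees C) at which to also
#'   report the freezing probability over each duration.
#' @inheritParams safe_temperature
#'
#' @return A tibble with columns `label`, `area_m2`, `duration_s`,
#'   `safe_temp_C`, `delta_T_K`, and `freeze_prob_at_hold` when
#'   `hold_temp_C` is given.
#' @examples
#' envelope_table(rate_model(1e-3, 8),
#'                areas = c(droplet = 1e-5, container = 6e-3),
#'                durations = c(24, 72, 168) * 3600, hold_temp_C = -4)
#' @export
envelope_table <- function(model, areas, durations, risk = 0.05,
                           hold_temp_C = NULL, melting_point = 0,
                           delta_T_cap = 273.15) {
  if (inherits(model, "rate_fit")) model <- model$model
  stopifnot(inherits(model, "rate_model"))
  if (is.null(names(areas))) {
    names(areas) <- paste0("area_", seq_along(areas))
  }
  if (any(areas <= 0) || any(durations <= 0)) {
    stop("`areas` and `durations` must be > 0", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    label = names(areas),
    duration_s = sort(durations)
  )
  grid$area_m2 <- unname(areas[grid$label])
  grid <- grid[order(grid$area_m2, grid$duration_s), ]
  grid$safe_temp_C <- safe_temperature(
    model, S = grid$area_m2, duration = grid$duration_s, risk = risk,
    melting_point = melting_point, delta_T_cap = delta_T_cap)
  grid$delta_T_K <- melting_point - grid$safe_temp_C
  if (!is.null(hold_temp_C)) {
    grid$freeze_prob_at_hold <- freezing_probability(
      model, S = grid$area_m2, delta_T = melting_point - hold_temp_C,
      t_hold = grid$duration_s)
  }
  tibble::as_tibble(grid[, c("label", "area_m2", "duration_s", "safe_temp_C",
                             "delta_T_K",
                             if (!is.null(hold_temp_C)) "freeze_prob_at_hold")])
}
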