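#' Construct a freezing assay
#'
#' A freezing assay is a tibble with one row per cooling cycle — the observed
#' supercooling degree at nucleation, or, for cycles that reached the ramp
#' floor unfrozen, the floor supercooling with a right-censoring flag — plus
#' the protocol (cooling rate, surface area) attached as an attribute.
#'
#' @param data A data frame with columns `delta_T` (K) and `censored`
#'   (logical or 0/1). A `cycle` column is added if absent.
#' @param protocol A [protocol()] describing the assay.
#'
#' @return A tibble of class `freezing_assay` with columns `cycle`,
#'   `delta_T`, `censored` and attribute `protocol`.
#' @examples
#' freezing_assay(data.frame(delta_T = c(5.2, 6.1, 7.3), censored = FALSE),
#'                protocol(0.1, 1e-5))
#' @export
freezing_assay <- function(data, protocol) {
  stopifnot(is.data.frame(data), inherits(protocol, "protocol"))
  if (!all(c("delta_T", "censored") %in% names(data))) {
    stop("`data` needs columns `delta_T` and `censored`", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out$censored <- as.logical(out$censored)
  if (!"cycle" %in% names(out)) out$cycle <- seq_len(nrow(out))
  out <- out[, c("cycle", "delta_T", "censored")]
  bad <- which(!out$censored &
                 (!is.finite(out$delta_T) | out$delta_T <= 0))
  bad <- c(bad, which(is.na(out$censored)))
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid assay rows (uncensored delta_T must be finite and > 0): %s",
      paste(sort(unique(bad)), collapse = ", ")), call. = FALSE)
  }
  attr(out, "protocol") <- protocol
  class(out) <- c("freezing_assay", class(out))
  out
}

#' Protocol attached to a freezing assay
#' @param assay A [freezing_assay()].
#' @return The [protocol()] object.
#' @export
assay_protocol <- function(assay) {
  p <- attr(assay, "protocol")
  if (is.null(p)) stop("assay carries no protocol", call. = FALSE)
  p
}

#' @export
print.freezing_assay <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf("<freezing_assay> %d cycles (%d censored), k = %g K/s, S = %g m^2\n",
              nrow(x), sum(x$censored), p$k, p$S))
  NextMethod()
}

#' Empirical survival curve of a freezing assay
#'
#' Product-limit (Kaplan-Meier) estimate of the probability of remaining
#' unfrozen as a function of supercooling degree, treating ramp-floor
#' unfrozen cycles as right-censored. With no censoring this reduces to
#' `1 - ECDF` of the observed supercooling degrees.
#'
#' @param assay A [freezing_assay()] (or a data frame with `delta_T`,
#'   `censored` columns).
#' @return A tibble of class `survival_curve` with columns `delta_T`,
#'   `survival`, `n_risk`, `n_event`.
#' @examples
#' a <- freezing_assay(data.frame(delta_T = 1:4, censored = FALSE),
#'                     protocol(0.1, 1e-5))
#' empirical_survival(a)
#' @export
empirical_survival <- function(assay) {
  stopifnot(is.data.frame(assay))
  if (all(assay$censored)) {
    stop("all cycles are censored; the survival curve never leaves 1",
         call. = FALSE)
  }
  fit <- survival::survfit(
    survival::Surv(assay$delta_T, !assay$censored) ~ 1)
  out <- tibble::tibble(
    delta_T = fit$time,
    survival = fit$surv,
    n_risk = fit$n.risk,
    n_event = fit$n.event
  )
  class(out) <- c("survival_curve", class(out))
  out
}
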