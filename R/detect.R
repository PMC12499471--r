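#' Detect a nucleation event in a thermocouple trace
#'
#' Scans forward temperature differences over a short window; the first rise
#' exceeding `jump_threshold` marks the recalescence (latent-heat) jump. To be
#' robust against sensor noise the scan runs on a lightly smoothed copy of the
#' trace (centred running mean of `smooth` samples), and the event time is
#' then localised on the raw trace as the largest single-step rise near the
#' flagged window. The supercooling degree is the melting point minus the
#' pre-jump minimum of the smoothed trace, so the detector also handles traces
#' that plateau slightly below 0 degrees C (freezing-point-depressed
#' solutions) and traces with a constant sensor offset (the offset shifts the
#' reported supercooling, never the detection).
#'
#' @param trace A data frame with columns `time_s` (strictly increasing) and
#'   `temp_C`, at least 2 samples.
#' @param jump_threshold Minimum rise (K) over the window that counts as a
#'   recalescence jump. Default 1 K.
#' @param window Number of samples spanned by the forward difference.
#'   Default 3.
#' @param smooth Width (samples, made odd) of the centred running mean used
#'   for scanning and for the pre-jump minimum. Default 5; use 1 for no
#'   smoothing.
#' @param melting_point Reference melting temperature (degrees C) for the
#'   supercooling degree. Default 0 (pure water).
#'
#' @return A one-row tibble with columns `event` (logical), `time_s` (jump
#'   time, NA if none), `delta_T` (supercooling degree, K; NA if none) and
#'   `min_temp_C` (pre-jump trace minimum, or overall minimum if none).
#' @examples
#' tr <- synth_trace(k = 0.1, duration = 150, nucleation_time = 120, seed = 1)
#' detect_nucleation(tr)
#' @export
detect_nucleation <- function(trace, jump_threshold = 1, window = 3,
                              smooth = 5, melting_point = 0) {
  validate_trace(trace)
  if (jump_threshold <= 0) stop("`jump_threshold` must be > 0", call. = FALSE)
  if (smooth < 1) stop("`smooth` must be >= 1", call. = FALSE)
  n <- nrow(trace)
  if (n <= window) stop("trace shorter than the detection window", call. = FALSE)
  temp <- trace$temp_C
  sm <- running_mean(temp, smooth)
  rise <- sm[(1 + window):n] - sm[1:(n - window)]
  hit <- which(rise > jump_threshold)
  if (length(hit) == 0) {
    return(tibble::tibble(event = FALSE, time_s = NA_real_,
                          delta_T = NA_real_, min_temp_C = min(sm)))
  }
  # localise on the raw trace: biggest single-step rise near the flagged window
  i0 <- hit[1]
  lo <- max(1, i0 - smooth)
  hi <- min(n - 1, i0 + window + smooth)
  d <- temp[(lo + 1):(hi + 1)] - temp[lo:hi]
  j <- lo + which.max(d) - 1        # jump between raw samples j and j + 1
  pre_min <- min(sm[1:j])
  tibble::tibble(
    event = TRUE,
    time_s = trace$time_s[j + 1],
    delta_T = melting_point - pre_min,
    min_temp_C = pre_min
  )
}

# centred running mean; edges fall back to the raw values
running_mean <- function(x, width) {
  width <- as.integer(width)
  if (width %% 2 == 0) width <- width + 1L
  if (width <= 1 || length(x) < width) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

validate_trace <- function(trace) {
  if (!is.data.frame(trace) ||
      !all(c("time_s", "temp_C") %in% names(trace))) {
    stop("trace must be a data frame with columns `time_s`, `temp_C`",
         call. = FALSE)
  }
  if (nrow(trace) < 2) stop("trace needs at least 2 samples", call. = FALSE)
  if (any(diff(trace$time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  invisible(trace)
}

#' Convert a batch of temperature traces into a freezing assay
#'
#' Runs [detect_nucleation()] on each trace: detected events become
#' uncensored assay rows at their measured supercooling degree; traces with
#' no recalescence jump become right-censored rows at the deepest supercooling
#' the trace reached.
#'
#' @param traces A list of trace data frames (see [detect_nucleation()]).
#' @param protocol The assay [protocol()].
#' @inheritParams detect_nucleation
#'
#' @return A [freezing_assay()] with one row per trace.
#' @examples
#' trs <- lapply(1:3, function(i)
#'   synth_trace(k = 0.1, duration = 150, nucleation_time = 60 + 20 * i,
#'               seed = i))
#' traces_to_assay(trs, protocol(0.1, 1e-5))
#' @export
traces_to_assay <- function(traces, protocol, jump_threshold = 1, window = 3,
                            smooth = 5, melting_point = 0) {
  if (!is.list(traces) || length(traces) == 0) {
    stop("`traces` must be a non-empty list of trace data frames",
         call. = FALSE)
  }
  rows <- purrr::imap(traces, function(tr, i) {
    ev <- tryCatch(
      detect_nucleation(tr, jump_threshold = jump_threshold, window = window,
                        smooth = smooth, melting_point = melting_point),
      error = function(e) {
        stop(sprintf("trace %s: %s", i, conditionMessage(e)), call. = FALSE)
      })
    if (ev$event) {
      tibble::tibble(delta_T = ev$delta_T, censored = FALSE)
    } else {
      tibble::tibble(delta_T = melting_point - ev$min_temp_C, censored = TRUE)
    }
  })
  freezing_assay(dplyr::bind_rows(rows), protocol)
}
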