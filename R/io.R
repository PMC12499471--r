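#' Read a freezing assay from CSV
#'
#' Expects columns `cycle_id`, `delta_T_K`, `censored` (0/1) and protocol
#' metadata as comment header lines `# k_K_per_s=<value>` and
#' `# S_m2=<value>`. Rows failing validation (missing values, non-positive
#' uncensored supercooling) are reported with their row numbers.
#'
#' @param path Path to the CSV file.
#' @return A [freezing_assay()].
#' @export
read_assay <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- parse_header_meta(hdr)
  for (key in c("k_K_per_s", "S_m2")) {
    if (is.na(meta[key])) {
      stop(sprintf("assay file lacks the `# %s=` header line", key),
           call. = FALSE)
    }
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  need <- c("cycle_id", "delta_T_K", "censored")
  if (!all(need %in% names(df))) {
    stop(sprintf("assay file needs columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(is.na(df$delta_T_K) | is.na(df$censored) |
                 !df$censored %in% c(0, 1, TRUE, FALSE))
  if (length(bad) > 0) {
    stop(sprintf("invalid assay rows: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  freezing_assay(
    data.frame(cycle = df$cycle_id, delta_T = df$delta_T_K,
               censored = as.logical(df$censored)),
    protocol(k = meta[["k_K_per_s"]], S = meta[["S_m2"]])
  )
}

parse_header_meta <- function(hdr) {
  keys <- c("k_K_per_s", "S_m2")
  out <- stats::setNames(rep(NA_real_, length(keys)), keys)
  for (key in keys) {
    m <- grep(sprintf("^#\\s*%s\\s*=", key), hdr, value = TRUE)
    if (length(m) > 0) {
      out[key] <- as.numeric(sub(".*=\\s*", "", m[1]))
    }
  }
  out
}

#' Write a freezing assay to CSV
#'
#' Inverse of [read_assay()]: protocol metadata as `#` header lines, then
#' `cycle_id`, `delta_T_K`, `censored` columns.
#'
#' @param assay A [freezing_assay()].
#' @param path Output path.
#' @param provenance Optional named character vector written as extra `#`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_assay <- function(assay, path, provenance = NULL) {
  stopifnot(inherits(assay, "freezing_assay"))
  p <- assay_protocol(assay)
  hdr <- c(sprintf("# k_K_per_s=%.15g", p$k), sprintf("# S_m2=%.15g", p$S))
  if (!is.null(provenance)) {
    hdr <- c(hdr, sprintf("# %s=%s", names(provenance), provenance))
  }
  body <- data.frame(cycle_id = assay$cycle, delta_T_K = assay$delta_T,
                     censored = as.integer(assay$censored))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(body, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a thermocouple trace from CSV
#'
#' Two-column CSV `time_s`, `temp_C` (comment lines beginning `#` are
#' ignored).
#'
#' @param path Path to the CSV file.
#' @return A `temperature_trace` tibble.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("time_s", "temp_C") %in% names(df))) {
    stop("trace file needs columns `time_s`, `temp_C`", call. = FALSE)
  }
  out <- tibble::as_tibble(df[, c("time_s", "temp_C")])
  validate_trace(out)
  class(out) <- c("temperature_trace", class(out))
  out
}

#' Write a thermocouple trace to CSV
#' @param trace A trace data frame (`time_s`, `temp_C`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  utils::write.csv(as.data.frame(trace[, c("time_s", "temp_C")]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a rate model (or fit) as YAML
#'
#' Writes `gamma`, `n`, the units string for `gamma` (which depends on `n`),
#' and — for fitted models — standard errors and fit diagnostics.
#'
#' @param model A [rate_model()] or [fit_rate_model()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_model <- function(model, path) {
  x <- if (inherits(model, "rate_fit")) {
    list(gamma = model$model$gamma, n = model$model$n,
         gamma_units = rate_units(model$model),
         se = list(gamma = unname(model$se[["gamma"]]),
                   n = unname(model$se[["n"]])),
         logLik = model$logLik, n_obs = model$n_obs,
         n_censored = model$n_censored)
  } else {
    stopifnot(inherits(model, "rate_model"))
    list(gamma = model$gamma, n = model$n, gamma_units = rate_units(model))
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a rate model from YAML
#' @param path Path written by [write_rate_model()].
#' @return A [rate_model()].
#' @export
read_rate_model <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$gamma) || is.null(x$n)) {
    stop("model file needs `gamma` and `n` fields", call. = FALSE)
  }
  rate_model(x$gamma, x$n)
}

#' Read a CNT configuration block from YAML
#'
#' Reads a `cnt:` block with keys `gamma_wi`, `T_m`, `rho_i`, `L_f`, `L_max`,
#' `theta_0` (SI units; `theta_0` in degrees). Missing thermophysical keys
#' fall back to the [thermo_params()] defaults.
#'
#' @param path Path to the YAML config file.
#' @return A list with elements `thermo` ([thermo_params()]) and `patch`
#'   ([patch_geometry()]).
#' @export
read_cnt_config <- function(path) {
  x <- yaml::read_yaml(path)
  cnt <- if (!is.null(x$cnt)) x$cnt else x
  defaults <- thermo_params()
  th <- thermo_params(
    gamma_wi = cnt$gamma_wi %||% defaults$gamma_wi,
    T_m = cnt$T_m %||% defaults$T_m,
    rho_i = cnt$rho_i %||% defaults$rho_i,
    L_f = cnt$L_f %||% defaults$L_f
  )
  if (is.null(cnt$L_max) || is.null(cnt$theta_0)) {
    stop("cnt config needs `L_max` and `theta_0`", call. = FALSE)
  }
  list(thermo = th, patch = patch_geometry(cnt$L_max, cnt$theta_0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
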