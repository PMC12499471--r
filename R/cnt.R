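#' Thermophysical constants of the water/ice system
#'
#' Bundle of the constants entering the Gibbs-Thomson critical radius and the
#' homogeneous nucleation barrier. Defaults are conventional literature values
#' for pure water; all are overridable for solutions or alternative parameter
#' sets.
#'
#' @param gamma_wi Water-ice interfacial tension (J m^-2).
#' @param T_m Equilibrium melting temperature (K).
#' @param rho_i Ice density (kg m^-3).
#' @param L_f Specific latent heat of fusion (J kg^-1).
#'
#' @return An object of class `thermo_params`.
#' @examples
#' thermo_params()
#' thermo_params(gamma_wi = 0.028)
#' @export
thermo_params <- function(gamma_wi = 0.030, T_m = 273.15, rho_i = 917,
                          L_f = 3.34e5) {
  vals <- c(gamma_wi = gamma_wi, T_m = T_m, rho_i = rho_i, L_f = L_f)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thermophysical parameters must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params>\n")
  cat(sprintf("  gamma_wi: %g J/m^2\n  T_m: %g K\n  rho_i: %g kg/m^3\n  L_f: %g J/kg\n",
              x$gamma_wi, x$T_m, x$rho_i, x$L_f))
  invisible(x)
}

#' Nucleation-patch geometry
#'
#' Geometry of the nano-confined nucleation patch: the maximum diameter of the
#' circular area available for ice nucleation and the intrinsic ice contact
#' angle of the patch material.
#'
#' @param L_max Maximum diameter of the nucleation patch (m).
#' @param theta_0 Intrinsic ice contact angle on the patch material (degrees),
#'   in (0, 180).
#'
#' @return An object of class `patch_geometry`.
#' @examples
#' patch_geometry(L_max = 2.1e-9, theta_0 = 100)
#' @export
patch_geometry <- function(L_max, theta_0) {
  if (!is.finite(L_max) || L_max <= 0) {
    stop("`L_max` must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(theta_0) || theta_0 <= 0 || theta_0 >= 180) {
    stop("`theta_0` must lie strictly between 0 and 180 degrees", call. = FALSE)
  }
  structure(list(L_max = L_max, theta_0 = theta_0), class = "patch_geometry")
}

#' @export
print.patch_geometry <- function(x, ...) {
  cat(sprintf("<patch_geometry> L_max = %g m, theta_0 = %g deg\n",
              x$L_max, x$theta_0))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Critical ice nucleation radius (Gibbs-Thomson)
#'
#' Radius of the critical ice nucleus at a given supercooling,
#' `R_c = 2 * gamma_wi * T_m / (rho_i * L_f * delta_T)`. The radius diverges as
#' the supercooling vanishes and shrinks hyperbolically as it deepens.
#'
#' @param delta_T Supercooling degree (K), strictly positive. Vectorised.
#' @param thermo A [thermo_params()] object.
#'
#' @return Critical radius in metres, same length as `delta_T`.
#' @examples
#' critical_radius(30)            # ~1.8 nm at 30 K supercooling
#' critical_radius(c(1, 10, 30))
#' @export
critical_radius <- function(delta_T, thermo = thermo_params()) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (any(!is.finite(delta_T)) || any(delta_T <= 0)) {
    stop("`delta_T` must be finite and strictly positive", call. = FALSE)
  }
  2 * thermo$gamma_wi * thermo$T_m / (thermo$rho_i * thermo$L_f * delta_T)
}

#' Spherical-cap shape factor
#'
#' The classical heterogeneous-nucleation barrier reduction
#' `f(m) = (2 + m) * (1 - m)^2 / 4` for a spherical-cap nucleus whose contact
#' angle has cosine `m`. Equals the ratio of the cap volume to the full sphere
#' volume; `f(-1) = 1` (non-wetting, homogeneous barrier) and `f(1) = 0`
#' (perfect wetting, no barrier).
#'
#' @param m Cosine of the contact angle, in \[-1, 1\]. Vectorised.
#' @return Barrier ratio in \[0, 1\].
#' @examples
#' cap_shape_factor(cos(pi * 100 / 180))  # ~0.629 for a 100 degree angle
#' @export
cap_shape_factor <- function(m) {
  if (any(!is.finite(m)) || any(abs(m) > 1)) {
    stop("`m` must lie in [-1, 1]", call. = FALSE)
  }
  (2 + m) * (1 - m)^2 / 4
}

#' Contact angle of a rim-pinned ice nucleus
#'
#' When the nucleation patch is smaller than the footprint of the free critical
#' cap, the nucleus is pinned at the patch rim and its contact angle is forced
#' onto the obtuse branch `theta_i = 180 - asin(L / (2 * R_c))` degrees. The
#' angle grows toward 180 degrees as the patch shrinks (the zero-size effect)
#' and meets the intrinsic angle continuously at `L = 2 * R_c * sin(theta_0)`
#' for obtuse `theta_0`.
#'
#' @param L Patch diameter (m), with `0 < L < 2 * R_c`.
#' @param R_c Critical radius (m).
#' @return Contact angle in degrees, in (90, 180\].
#' @examples
#' confined_contact_angle(1e-9, 1e-9)  # L = R_c gives 150 degrees
#' @export
confined_contact_angle <- function(L, R_c) {
  if (any(R_c <= 0)) stop("`R_c` must be > 0", call. = FALSE)
  if (any(L <= 0) || any(L >= 2 * R_c)) {
    stop("confined regime requires 0 < L < 2 * R_c", call. = FALSE)
  }
  180 - rad2deg(asin(L / (2 * R_c)))
}

#' Nucleation barrier ratio on a confined patch
#'
#' Ratio of the heterogeneous free-energy barrier on a finite patch to the
#' homogeneous barrier, as a function of the normalised patch size
#' `x = L_max / (2 * R_c)`. Piecewise: for `x >= sin(theta_0)` the nucleus is a
#' free spherical cap and the ratio is `cap_shape_factor(cos(theta_0))`; for
#' `x < sin(theta_0)` the nucleus is pinned at the rim and the ratio is
#' `cap_shape_factor(cos(theta_i))` with the obtuse [confined_contact_angle()].
#' The ratio approaches 1 (homogeneous nucleation) as the patch vanishes.
#'
#' @param patch A [patch_geometry()] object.
#' @param R_c Critical radius (m). Vectorised.
#' @return Barrier ratio in (0, 1\].
#' @examples
#' p <- patch_geometry(2.1e-9, 100)
#' barrier_ratio(p, critical_radius(c(5, 15, 30)))
#' @export
barrier_ratio <- function(patch, R_c) {
  stopifnot(inherits(patch, "patch_geometry"))
  if (any(!is.finite(R_c)) || any(R_c <= 0)) {
    stop("`R_c` must be finite and > 0", call. = FALSE)
  }
  barrier_ratio_x(patch$L_max / (2 * R_c), patch$theta_0)
}

# core on the normalised size x = L/(2 R_c); cos(theta_i) = -sqrt(1 - x^2)
barrier_ratio_x <- function(x, theta_0) {
  s0 <- sin(deg2rad(theta_0))
  m0 <- cos(deg2rad(theta_0))
  ifelse(x >= s0,
         cap_shape_factor(m0),
         cap_shape_factor(-sqrt(pmax(0, 1 - x^2))))
}

#' Maximum nucleation radius supported by a patch
#'
#' The largest critical-nucleus radius a patch can host as an unpinned cap:
#' `R_max = L_max / (2 * sin(theta_0))`. Nuclei with `R_c > R_max` are pinned
#' and face an elevated barrier; a surface whose `R_max` lies below the
#' critical radius at every working supercooling behaves quasi-homogeneously.
#'
#' @param patch A [patch_geometry()] object.
#' @return Radius in metres.
#' @examples
#' max_nucleation_radius(patch_geometry(2.1e-9, 100))  # ~1.07e-9 m
#' @export
max_nucleation_radius <- function(patch) {
  stopifnot(inherits(patch, "patch_geometry"))
  s0 <- sin(deg2rad(patch$theta_0))
  if (s0 == 0) stop("sin(theta_0) must be nonzero", call. = FALSE)
  patch$L_max / (2 * s0)
}

#' Homogeneous nucleation barrier
#'
#' Absolute free-energy barrier for homogeneous ice nucleation,
#' `16 * pi * gamma^3 / (3 * dg_v^2)` with the volumetric driving force
#' `dg_v = rho_i * L_f * delta_T / T_m`. Exposed so absolute barriers can be
#' reported; the patch-size analysis works with ratios.
#'
#' @inheritParams critical_radius
#' @return Barrier in joules, same length as `delta_T`.
#' @export
homogeneous_barrier <- function(delta_T, thermo = thermo_params()) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (any(delta_T <= 0)) stop("`delta_T` must be > 0", call. = FALSE)
  dgv <- thermo$rho_i * thermo$L_f * delta_T / thermo$T_m
  16 * pi * thermo$gamma_wi^3 / (3 * dgv^2)
}

#' Confined-patch nucleation curve over a supercooling range
#'
#' Tabulates the critical radius, normalised patch size and barrier ratio on a
#' grid of supercooling degrees, reproducing the critical-radius and
#' barrier-transition curves for a given patch.
#'
#' @param patch A [patch_geometry()] object.
#' @param thermo A [thermo_params()] object.
#' @param delta_T Supercooling grid (K); default 0.1 to 30 K.
#'
#' @return A tibble with columns `delta_T`, `R_c`, `L_over_2Rc`,
#'   `barrier_ratio`.
#' @examples
#' cnt_curve(patch_geometry(2.1e-9, 100))
#' @export
cnt_curve <- function(patch, thermo = thermo_params(),
                      delta_T = seq(0.1, 30, by = 0.1)) {
  Rc <- critical_radius(delta_T, thermo)
  tibble::tibble(
    delta_T = delta_T,
    R_c = Rc,
    L_over_2Rc = patch$L_max / (2 * Rc),
    barrier_ratio = barrier_ratio(patch, Rc)
  )
}
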