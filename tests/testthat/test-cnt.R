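test_that("critical radius follows the Gibbs-Thomson hyperbola", {
  th <- thermo_params(gamma_wi = 0.030, T_m = 273.15, rho_i = 917,
                      L_f = 3.34e5)
  # hand evaluation: 2 * 0.030 * 273.15 / (917 * 3.34e5 * 30)
  expect_equal(critical_radius(30, th), 1.7837e-9, tolerance = 1e-4)
  # R_c is proportional to 1/delta_T
  expect_equal(critical_radius(15, th), 2 * critical_radius(30, th))
  dT <- c(0.5, 1, 3, 10, 30)
  expect_equal(critical_radius(dT, th) * dT,
               rep(critical_radius(1, th), length(dT)))
  # strictly decreasing, diverging near zero supercooling
  expect_true(all(diff(critical_radius(dT, th)) < 0))
  expect_gt(critical_radius(1e-12, th), 1)
  expect_error(critical_radius(0, th), "positive")
  expect_error(critical_radius(-1, th), "positive")
})

test_that("cap shape factor matches the spherical-cap volume fraction", {
  expect_equal(cap_shape_factor(-1), 1)
  expect_equal(cap_shape_factor(1), 0)
  # hand evaluation of (2 + m)(1 - m)^2 / 4 at m = cos(100 deg)
  expect_equal(cap_shape_factor(cos(100 * pi / 180)), 0.62891,
               tolerance = 1e-4)
  m <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(cap_shape_factor(m)) < 0))
  expect_error(cap_shape_factor(1.01), "\\[-1, 1\\]")
  # geometric identity: cap volume / sphere volume by direct quadrature
  for (theta in c(30, 100, 150) * pi / 180) {
    vol <- stats::integrate(function(z) pi * (1 - z^2), cos(theta), 1,
                            rel.tol = 1e-12)$value
    expect_equal(cap_shape_factor(cos(theta)), vol / (4 * pi / 3),
                 tolerance = 1e-9)
  }
})

test_that("confined contact angle sits on the obtuse branch", {
  Rc <- 2e-9
  # vanishing patch: angle tends to 180 degrees (homogeneous limit)
  expect_equal(confined_contact_angle(1e-15, Rc), 180, tolerance = 1e-4)
  # L = R_c: arcsin(1/2) = 30 degrees, so theta_i = 150
  expect_equal(confined_contact_angle(Rc, Rc), 150)
  # continuity with the unconfined regime at L = 2 R_c sin(theta_0)
  theta0 <- 100
  L_star <- 2 * Rc * sin(theta0 * pi / 180)
  expect_equal(confined_contact_angle(L_star, Rc), theta0)
  expect_error(confined_contact_angle(2 * Rc, Rc), "confined regime")
})

test_that("barrier ratio is piecewise, continuous at the transition, monotone", {
  patch <- patch_geometry(2.1e-9, 100)
  s0 <- sin(100 * pi / 180)
  # deep confinement: homogeneous barrier
  Rc_deep <- patch$L_max / (2 * 1e-6)     # L/(2Rc) = 1e-6
  expect_lt(abs(barrier_ratio(patch, Rc_deep) - 1), 1e-3)
  # unconfined branch equals the free spherical-cap factor
  Rc_free <- patch$L_max / (2 * 0.99)     # L/(2Rc) = 0.99 >= sin(100 deg)
  expect_equal(barrier_ratio(patch, Rc_free),
               cap_shape_factor(cos(100 * pi / 180)))
  # non-increasing in L_max at fixed R_c, i.e. non-decreasing in R_c at
  # fixed L: sweep the normalised size via R_c
  x <- 10^seq(-3, log10(2), length.out = 400)
  ratio <- barrier_ratio(patch, patch$L_max / (2 * x))
  expect_true(all(diff(ratio) <= 1e-15))
  # flat beyond the transition, strictly rising below it
  expect_equal(stats::sd(ratio[x >= s0]), 0)
  expect_true(all(diff(ratio[x < s0 * 0.999]) < 0))
})

test_that("both barrier branches agree at the transition across obtuse angles", {
  Rc <- 1.5e-9
  for (theta0 in seq(91, 179, by = 1)) {
    L_star <- 2 * Rc * sin(theta0 * pi / 180)
    unconfined <- cap_shape_factor(cos(theta0 * pi / 180))
    confined <- cap_shape_factor(
      cos(confined_contact_angle(L_star, Rc) * pi / 180))
    expect_lt(abs(confined - unconfined) / unconfined, 1e-12)
  }
})

test_that("barrier ratio limits hold for arbitrary intrinsic angles", {
  for (theta0 in c(95, 120, 150, 179)) {
    patch <- patch_geometry(1e-9, theta0)
    expect_lt(abs(barrier_ratio(patch, patch$L_max / (2 * 1e-8)) - 1), 1e-6)
    expect_equal(barrier_ratio(patch, patch$L_max / (2 * 1.5)),
                 cap_shape_factor(cos(theta0 * pi / 180)))
  }
})

test_that("maximum nucleation radius matches the patch geometry", {
  # the printed patch: 2.1 nm diameter, 100 degree intrinsic angle
  p <- patch_geometry(2.1e-9, 100)
  expect_equal(max_nucleation_radius(p), 2.1e-9 / (2 * sin(100 * pi / 180)))
  expect_equal(round(max_nucleation_radius(p) * 1e9, 1), 1.1)
  expect_equal(max_nucleation_radius(patch_geometry(3e-9, 90)), 1.5e-9)
  expect_error(patch_geometry(0, 100), "L_max")
  expect_error(patch_geometry(1e-9, 180), "theta_0")
})

test_that("critical radii exceed the patch's maximum radius over 0-30 K", {
  # the central geometric claim: the confined patch cannot host a critical
  # nucleus anywhere in the working supercooling range
  p <- patch_geometry(2.1e-9, 100)
  dT <- seq(0.01, 30, length.out = 500)
  expect_true(all(critical_radius(dT) > max_nucleation_radius(p)))
})

test_that("cnt_curve tabulates radius, normalised size and barrier together", {
  p <- patch_geometry(2.1e-9, 100)
  tab <- cnt_curve(p, delta_T = seq(1, 30, by = 1))
  expect_s3_class(tab, "tbl_df")
  expect_named(tab, c("delta_T", "R_c", "L_over_2Rc", "barrier_ratio"))
  expect_equal(tab$R_c, critical_radius(tab$delta_T))
  expect_equal(tab$L_over_2Rc, p$L_max / (2 * tab$R_c))
  expect_true(all(tab$barrier_ratio > 0 & tab$barrier_ratio <= 1))
})

test_that("homogeneous barrier scales as 1/delta_T^2", {
  expect_equal(homogeneous_barrier(10) / homogeneous_barrier(20), 4)
  expect_gt(homogeneous_barrier(30), 0)
})
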