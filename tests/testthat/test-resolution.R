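test_that("axis profiles are unit peak and reproduce the sinc closed form", {
  fld <- strip_model_field(semi_disk, ref_train, 1, "as_printed_linear",
                           window_um = 2, samples = 401)
  px <- axis_profile(fld, "x")
  expect_equal(max(px$magnitude), 1)
  expect_equal(px$magnitude[1], 1)  # peak at the origin
  k <- 2 * pi / ref_train$wavelength_um
  u <- k * px$r_um / ref_train$f_objective_um
  sinc <- ifelse(u == 0, 1e4, abs(sin(1e4 * u) / u)) / 1e4
  expect_equal(px$magnitude, sinc, tolerance = 1e-10)
})

test_that("first dark rings recover closed-form zeros to 0.5%", {
  lamf <- ref_train$wavelength_um * ref_train$f_objective_um
  # rectangle 2b x b: sinc zeros at lambda f / 2b (x) and lambda f / b (y)
  rect <- strip_model_field(semi_disk, ref_train, 1, "as_printed_linear",
                            window_um = 1.2, samples = 961)
  rings <- first_dark_ring(rect)
  expect_equal(rings$x0_um, lamf / 2e4, tolerance = 0.005)
  expect_equal(rings$y0_um, lamf / 1e4, tolerance = 0.005)

  # full circular aperture: Airy minimum at 1.22 lambda f / 2b
  airy <- fraunhofer_axis_profile(aperture_spec(10, 0, "full"), ref_train,
                                  "x", r_max = 0.7, samples = 1401)
  expect_equal(first_dark_ring(airy)$r0_um, 1.22 * lamf / 2e4,
               tolerance = 0.005)
})

test_that("a window that stops before the first minimum errors", {
  p <- fraunhofer_axis_profile(ref_aperture, ref_train, "y", r_max = 0.4,
                               samples = 301)
  expect_error(first_dark_ring(p), "window too small")
})

test_that("side-lobe SNR matches the sinc closed form and decays with tau", {
  rect <- strip_model_field(semi_disk, ref_train, 1, "as_printed_linear",
                            window_um = 2, samples = 641)
  # first sinc side lobe: |sin(u)/u| at u = 4.49341, amplitude 0.21723
  expect_equal(snr_db(rect), 20 * log10(1 / 0.21723), tolerance = 0.01)

  snrs <- vapply(c(0, 0.5, 0.9), function(tv) {
    snr_db(fraunhofer_field(aperture_spec(10, tv * 10), ref_train,
                            window_um = 2, samples = 161))
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))

  flat <- depthsense:::new_field_grid(
    seq(-2, 2, length.out = 41), seq(-2, 2, length.out = 41),
    outer(exp(-seq(-2, 2, length.out = 41)^2),
          exp(-seq(-2, 2, length.out = 41)^2)) + 0i,
    model = "synthetic", train = ref_train, aperture = semi_disk,
    normalization = "unit_peak")
  expect_error(snr_db(flat), "no secondary maximum")
})

test_that("the two models agree on the y-axis dark ring of the design stop", {
  oracle <- fraunhofer_axis_profile(ref_aperture, ref_train, "y",
                                    r_max = 1.2, samples = 1201)
  y_oracle <- first_dark_ring(oracle)$r0_um
  strip <- strip_model_field(ref_aperture, ref_train, 800, "circular_chord",
                             x_um = 0, y_um = seq(0, 1.2, length.out = 1201))
  prof <- structure(list(r_um = strip$y_um,
                         magnitude = abs(strip$amplitude[1, ]) /
                           max(abs(strip$amplitude[1, ])),
                         axis = "y", model = "strip",
                         aperture = ref_aperture),
                    class = "axis_profile")
  y_strip <- first_dark_ring(prof)$r0_um
  expect_equal(y_strip, y_oracle, tolerance = 0.01)
})

test_that("the dark ring is elongated along the symmetry axis", {
  for (tv in c(0, 0.5, 0.9)) {
    ap <- aperture_spec(10, tv * 10)
    x0 <- first_dark_ring(fraunhofer_axis_profile(ap, ref_train, "x",
                                                  r_max = 0.8,
                                                  samples = 801))$r0_um
    y0 <- first_dark_ring(fraunhofer_axis_profile(ap, ref_train, "y",
                                                  r_max = 1.6,
                                                  samples = 801))$r0_um
    expect_gt(y0, x0)
    expect_gt(y0 / x0, 1.6)
    expect_lt(y0 / x0, 2.8)
  }
})

test_that("tau sweep tables have the expected structure and x-axis trend", {
  sw <- tau_sweep(10, ref_train, tau = c(0, 0.3, 0.6), model = "strip",
                  n_strips = 200, rule = "as_printed_linear",
                  snr_samples = 81, axis_samples = 801)
  expect_equal(names(sw), c("tau", "x0_um", "y0_um", "snr_db"))
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$x0_um) < 0))
  expect_true(all(diff(sw$snr_db) < 0))
})

test_that("the resolution report chains dark ring, triangulation and DOF", {
  rep <- resolution_report(ref_field, ref_train, ref_ray)
  expect_equal(rep$delta_z_um, rep$delta_r_um / ref_ray$tan_theta,
               tolerance = 1e-12)
  expect_equal(rep$dtot_um, depth_of_field(ref_train), tolerance = 1e-12)
  expect_equal(rep$ratio_dz_to_dof, rep$delta_z_um / rep$dtot_um,
               tolerance = 1e-12)
  # grazing geometry: tan(theta) -> infinity collapses delta_z to 0
  grazing <- structure(list(theta_rad = pi / 2 - 1e-9, tan_theta = 1e9),
                       class = "ray_geometry")
  expect_lt(resolution_report(ref_field, ref_train, grazing)$delta_z_um,
            1e-8)
})
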