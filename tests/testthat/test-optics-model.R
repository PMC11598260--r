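test_that("marginal-ray angle follows sin(theta) = NA/n", {
  expect_equal(ref_ray$tan_theta, 0.75 / sqrt(1 - 0.75^2), tolerance = 1e-12)
  expect_equal(ref_ray$theta_rad, asin(0.75), tolerance = 1e-12)

  axial <- marginal_ray_angle(optical_train(na = 0))
  expect_equal(axial$theta_rad, 0)
  expect_equal(axial$tan_theta, 0)

  diag45 <- marginal_ray_angle(optical_train(na = sqrt(2) / 2))
  expect_equal(diag45$tan_theta, 1, tolerance = 1e-12)

  expect_error(optical_train(na = 1.1, medium_index = 1), "NA")
  oil <- optical_train(na = 1.1, medium_index = 1.33)
  expect_lt(marginal_ray_angle(oil)$theta_rad, pi / 2)
})

test_that("spot radius on the detector is the similar-triangles chain", {
  # independent construction: object-plane radius r = z tan(theta), then
  # relay magnification R = r f_I / f_O
  z <- 100
  r_obj <- z * ref_ray$tan_theta
  expect_equal(spot_radius_on_detector(z, ref_train, ref_ray),
               r_obj * 20, tolerance = 1e-12)
  expect_equal(spot_radius_on_detector(100, ref_train, ref_ray),
               2267.787, tolerance = 1e-6)
  expect_equal(spot_radius_on_detector(0, ref_train, ref_ray), 0)
  # the 610 nm axial step maps to about 2.5 detector pixels
  expect_equal(spot_radius_on_detector(0.610, ref_train, ref_ray) /
                 ref_train$pixel_pitch_um, 2.515, tolerance = 1e-3)
})

test_that("radius inversion round-trips and is linear in z", {
  zs <- seq(-200, 200, by = 12.5)
  r <- spot_radius_on_detector(zs, ref_train, ref_ray)
  back <- defocus_from_radius(r, sign(zs), ref_train, ref_ray)
  expect_equal(back, zs, tolerance = 1e-9)
  expect_equal(spot_radius_on_detector(2 * zs, ref_train, ref_ray),
               2 * r, tolerance = 1e-12)
  expect_equal(defocus_from_radius(4535.574, 1, ref_train, ref_ray), 200,
               tolerance = 1e-4)
  expect_equal(defocus_from_radius(0, 0, ref_train, ref_ray), 0)
  expect_error(defocus_from_radius(10, 1, optical_train(na = 0)),
               "invalid configuration")
})

test_that("pixel counts demagnify to object-plane distances", {
  expect_equal(object_plane_radius_from_pixels(2.5, ref_train), 0.6875)
  expect_equal(object_plane_radius_from_pixels(0, ref_train), 0)
  expect_equal(object_plane_radius_from_pixels(5, ref_train), 1.375)
})

test_that("focusing accuracy and detector sensitivity are consistent", {
  expect_equal(focusing_accuracy(0.68, ref_ray), 0.5997, tolerance = 1e-4)
  expect_equal(focusing_accuracy(0.688, ref_ray), 0.6068, tolerance = 1e-4)
  ray45 <- marginal_ray_angle(optical_train(na = sqrt(2) / 2))
  expect_equal(focusing_accuracy(1, ray45), 1, tolerance = 1e-12)
  expect_error(focusing_accuracy(1, marginal_ray_angle(optical_train(na = 0))),
               "invalid configuration")

  # the two sensitivity routes agree when delta_z = delta_r / tan(theta)
  dr <- c(0.3, 0.68, 1.2)
  dz <- focusing_accuracy(dr, ref_ray)
  expect_equal(detector_sensitivity(ref_train, ref_ray, delta_z_um = dz),
               detector_sensitivity(ref_train, ref_ray, delta_r_um = dr),
               tolerance = 1e-12)
  expect_equal(detector_sensitivity(ref_train, ref_ray, delta_z_um = 0.60),
               13.607, tolerance = 1e-4)
  # 0.688 um on the sample is 2.5 pixels on the detector
  expect_equal(detector_sensitivity(ref_train, ref_ray, delta_r_um = 0.688) /
                 ref_train$pixel_pitch_um, 2.5, tolerance = 2e-3)
  expect_equal(detector_sensitivity(ref_train, ref_ray, delta_z_um = 0), 0)
  expect_error(detector_sensitivity(ref_train, ref_ray), "exactly one")
  # identity delta_z (f_I/f_O) tan(theta) / delta_R = 1
  expect_equal(dz * image_scale(ref_train) * ref_ray$tan_theta /
                 detector_sensitivity(ref_train, ref_ray, delta_z_um = dz),
               rep(1, 3), tolerance = 1e-12)
})

test_that("focusing range scales with detector size and imaging focal length", {
  z1 <- focusing_range(ref_train, ref_ray)
  expect_equal(z1, defocus_from_radius((1088 / 2) * 5.5, 1, ref_train,
                                       ref_ray))
  tr2 <- optical_train(f_imaging_mm = 400)
  expect_equal(focusing_range(tr2, marginal_ray_angle(tr2)), z1 / 2,
               tolerance = 1e-12)
  tr0 <- optical_train(detector_px = c(0, 0))
  expect_equal(focusing_range(tr0, ref_ray), 0)
  tr_big <- optical_train(detector_px = c(2048, 2176))
  expect_equal(focusing_range(tr_big, ref_ray), 2 * z1, tolerance = 1e-12)
})

test_that("depth of field combines the wave and detector terms", {
  expect_equal(depth_of_field(ref_train), 1.578889, tolerance = 1e-6)
  expect_equal(depth_of_field(ref_train, e_um = 0), 0.785 / 0.75^2,
               tolerance = 1e-12)
  vis <- optical_train(wavelength_nm = 550)
  expect_equal(depth_of_field(vis, e_um = 0), 0.977778, tolerance = 1e-6)
})
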