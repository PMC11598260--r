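test_that("N = 1 strip field collapses to the 2b x b rectangle closed form", {
  fld <- strip_model_field(semi_disk, ref_train, n_strips = 1,
                           rule = "as_printed_linear",
                           window_um = 2, samples = 201)
  closed <- rect_field_magnitude(fld$x_um, fld$y_um, 1e4,
                                 ref_train$wavelength_um,
                                 ref_train$f_objective_um)
  expect_equal(abs(fld$amplitude), closed, tolerance = 1e-12)
  # identical under the chord rule only at N = 1 center phase, magnitude-wise
  fld2 <- strip_model_field(semi_disk, ref_train, n_strips = 1,
                            rule = "circular_chord",
                            window_um = 2, samples = 201)
  expect_false(isTRUE(all.equal(abs(fld2$amplitude), closed,
                                tolerance = 1e-6)))
})

test_that("zero obscuration reproduces the semi-circular accumulation exactly", {
  # independent direct evaluation of the semi-circular sum on a small grid
  n_strips <- 64
  xs <- seq(-1.5, 1.5, length.out = 41)
  ys <- xs
  lam <- ref_train$wavelength_um
  f <- ref_train$f_objective_um
  k <- 2 * pi / lam
  b <- 1e4
  h <- b / n_strips
  direct <- matrix(0 + 0i, length(xs), length(ys))
  for (ix in seq_along(xs)) {
    ux <- k * xs[ix] / f
    for (iy in seq_along(ys)) {
      uy <- k * ys[iy] / f
      acc <- 0 + 0i
      for (n in 0:(n_strips - 1)) {
        w <- b * (n_strips - n) / n_strips
        sx <- if (ux == 0) w else sin(w * ux) / ux
        acc <- acc + sx * exp(-2i * pi * ys[iy] * n * h / (lam * f))
      }
      ypre <- if (uy == 0) h else 2 * sin(uy * b / (2 * n_strips)) / uy
      direct[ix, iy] <- ypre * acc
    }
  }
  fld <- strip_model_field(semi_disk, ref_train, n_strips = n_strips,
                          rule = "as_printed_linear", x_um = xs, y_um = ys,
                          normalization = "raw")
  expect_equal(fld$amplitude, direct, tolerance = 1e-12)
})

test_that("field magnitudes carry the inversion symmetry |E(-x,-y)| = |E(x,y)|", {
  for (fld in list(strip_model_field(ref_aperture, ref_train, 200,
                                     window_um = 2, samples = 81),
                   fraunhofer_field(ref_aperture, ref_train, window_um = 2,
                                    samples = 81, mask_samples = 1024))) {
    m <- abs(fld$amplitude)
    expect_equal(m, m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))],
                 tolerance = 1e-9)
  }
})

test_that("the accumulation converges with N and approaches the mask oracle", {
  conv <- convergence_profile(ref_aperture, ref_train,
                              c(1, 10, 100, 1000), "circular_chord",
                              window_um = 3, samples = 121)
  expect_equal(conv$n_strips, c(1, 10, 100, 1000))
  expect_true(all(diff(conv$sup_deviation) <= 1e-12))
  expect_gt(conv$sup_deviation[1], conv$sup_deviation[3])
  expect_lt(conv$sup_deviation[3], 0.01)
  expect_equal(conv$sup_deviation[4], 0)

  grid <- seq(-3, 3, length.out = 121)
  chord <- strip_model_field(ref_aperture, ref_train, 1000, "circular_chord",
                             x_um = grid, y_um = grid)
  oracle <- fraunhofer_field(ref_aperture, ref_train, x_um = grid,
                             y_um = grid, mask_samples = 2048)
  expect_lt(max(abs(abs(chord$amplitude) - abs(oracle$amplitude))), 0.02)
})

test_that("the padded-FFT transform conserves energy and flags aliasing", {
  full <- fraunhofer_full_transform(semi_disk, ref_train,
                                    mask_samples = 512, pad_factor = 4)
  expect_equal(attr(full, "energy_spectrum"), attr(full, "energy_aperture"),
               tolerance = 1e-9)
  expect_equal(sort(c(length(full$x_um), length(full$y_um))),
               c(2048L, 2048L))
})

test_that("focal windows beyond the alias-free zone are rejected", {
  expect_error(fraunhofer_field(ref_aperture, ref_train, window_um = 120,
                                samples = 33, mask_samples = 1024),
               "sampling error")
})

test_that("feature coordinates contract as 1/b (wavelength-geometry scaling)", {
  tr <- ref_train
  get_rings <- function(b_mm) {
    ap <- aperture_spec(b_mm, 0.8 * b_mm)
    sc <- 10 / b_mm
    c(first_dark_ring(fraunhofer_axis_profile(ap, tr, "x", r_max = 1.2 * sc,
                                              samples = 1201))$r0_um,
      first_dark_ring(fraunhofer_axis_profile(ap, tr, "y", r_max = 2.4 * sc,
                                              samples = 1201))$r0_um)
  }
  r5 <- get_rings(5)
  r15 <- get_rings(15)
  expect_equal(r5 / r15, c(3, 3), tolerance = 0.01)
})
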