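#' Stack of reflective surfaces
#'
#' Axial positions of the reflective surfaces of a transparent sample,
#' signed relative to the objective focal plane (positive = farther from the
#' objective), with relative reflectivities.
#'
#' @param z_um signed surface offsets (micrometres), at least one.
#' @param reflectivity relative weights in `[0, 1]`, recycled to the number
#'   of surfaces; must not sum to zero.
#' @return An object of class `surface_stack`.
#' @examples
#' surface_stack(c(-30, 0, 40))
#' @export
surface_stack <- function(z_um, reflectivity = 1) {
  if (!length(z_um) || any(!is.finite(z_um)))
    stop("need at least one finite surface offset")
  reflectivity <- rep_len(reflectivity, length(z_um))
  if (any(reflectivity < 0) || any(reflectivity > 1) || sum(reflectivity) <= 0)
    stop("reflectivities must lie in [0, 1] and not all be zero")
  structure(list(z_um = as.numeric(z_um), reflectivity = reflectivity),
            class = "surface_stack")
}

#' @export
print.surface_stack <- function(x, ...) {
  cat(sprintf("<surface_stack> %d surfaces at z = %s um\n", length(x$z_um),
              paste(x$z_um, collapse = ", ")))
  invisible(x)
}

new_detector_image <- function(pixels, train, photon_scale, read_sigma, seed,
                               quantized, clipped, bit_depth = 16L) {
  structure(list(pixels = pixels, pitch_um = train$pixel_pitch_um,
                 bit_depth = bit_depth, photon_scale = photon_scale,
                 read_sigma = read_sigma, seed = seed,
                 quantized = quantized, clipped = clipped),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("<detector_image> %d x %d px @ %g um, %s, max %g counts\n",
              nrow(x$pixels), ncol(x$pixels), x$pitch_um,
              if (x$quantized) sprintf("%d-bit", x$bit_depth) else
                "noiseless (expected counts)", max(x$pixels)))
  invisible(x)
}

#' @export
plot.detector_image <- function(x, ...) {
  image(seq_len(nrow(x$pixels)), seq_len(ncol(x$pixels)),
        x$pixels, col = gray.colors(256), xlab = "x (px)", ylab = "y (px)",
        useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

# pixel-centre coordinates (um), frame centre at 0
pixel_coords <- function(train) {
  w <- train$detector_px[1]
  h <- train$detector_px[2]
  list(x = (seq_len(w) - 0.5 - w / 2) * train$pixel_pitch_um,
       y = (seq_len(h) - 0.5 - h / 2) * train$pixel_pitch_um)
}

run_with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Poisson shot noise + Gaussian read noise + quantization, seed-deterministic
apply_detector_noise <- function(expected, read_sigma, seed, bit_depth = 16L) {
  if (is.null(seed)) return(list(pixels = expected, quantized = FALSE))
  counts <- run_with_seed(seed, {
    n <- length(expected)
    rpois(n, lambda = as.vector(expected)) + rnorm(n, 0, read_sigma)
  })
  counts <- matrix(pmin(pmax(round(counts), 0), 2^bit_depth - 1),
                   nrow(expected), ncol(expected))
  list(pixels = counts, quantized = TRUE)
}

bilinear_at <- function(x, y, z, qx, qy) {
  nx <- length(x); ny <- length(y)
  ix <- findInterval(qx, x, all.inside = TRUE)
  iy <- findInterval(qy, y, all.inside = TRUE)
  tx <- (qx - x[ix]) / (x[ix + 1] - x[ix])
  ty <- (qy - y[iy]) / (y[iy + 1] - y[iy])
  inside <- qx >= x[1] & qx <= x[nx] & qy >= y[1] & qy <= y[ny]
  v <- z[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    z[cbind(ix + 1, iy)] * tx * (1 - ty) +
    z[cbind(ix, iy + 1)] * (1 - tx) * ty +
    z[cbind(ix + 1, iy + 1)] * tx * ty
  v[!inside] <- 0
  v
}

#' Pixelated point-spread kernel of the focused spot
#'
#' Magnifies a computed focal-plane field to the detector plane by
#' `f_I / f_O`, takes the intensity `|E|^2`, and resamples it onto the pixel
#' grid by `supersample`-fold supersampling and binning. The result is a
#' small odd-sized matrix normalized to unit sum, used as the focused-spot
#' image and as the blur kernel of defocused rings.
#'
#' @param field a `field_grid` of the design aperture (object-plane
#'   coordinates).
#' @param train an [optical_train()].
#' @param supersample subsamples per pixel and axis.
#' @param extent_px kernel half-extent in pixels (kernel is
#'   `(2 extent + 1)^2`).
#' @return A numeric matrix with `sum = 1`.
#' @export
focused_kernel <- function(field, train, supersample = 4, extent_px = 15) {
  m <- image_scale(train)
  pitch <- train$pixel_pitch_um
  offs <- -extent_px:extent_px
  sub <- ((seq_len(supersample) - 0.5) / supersample) - 0.5
  fine <- as.vector(outer(sub * pitch, offs * pitch, "+"))  # detector um
  intensity <- abs(field$amplitude)^2
  qx <- rep(fine, times = length(fine))
  qy <- rep(fine, each = length(fine))
  v <- bilinear_at(field$x_um, field$y_um, intensity, qx / m, qy / m)
  fine_mat <- matrix(v, length(fine), length(fine))
  k <- length(offs)
  idx <- rep(seq_len(k), each = supersample)
  binned <- rowsum(fine_mat, idx)
  binned <- t(rowsum(t(binned), idx))
  binned / sum(binned)
}

embed_kernel <- function(train, kernel) {
  w <- train$detector_px[1]; h <- train$detector_px[2]
  frame <- matrix(0, w, h)
  e <- (nrow(kernel) - 1) / 2
  cx <- w %/% 2; cy <- h %/% 2
  rows <- (cx - e):(cx + e)
  cols <- (cy - e):(cy + e)
  ok_r <- rows >= 1 & rows <= w
  ok_c <- cols >= 1 & cols <= h
  frame[rows[ok_r], cols[ok_c]] <- kernel[ok_r, ok_c]
  frame
}

# anti-aliased expected-count frame of a defocused half-ring (no noise)
expected_ring_frame <- function(z_um, train, ray, aperture, kernel) {
  pc <- pixel_coords(train)
  pitch <- train$pixel_pitch_um
  r_outer <- spot_radius_on_detector(z_um, train, ray)
  r_inner <- aperture$tau * r_outer
  sgn <- sign(z_um)
  half_w <- (train$detector_px[1] / 2) * pitch
  half_h <- (train$detector_px[2] / 2) * pitch
  if (r_inner > sqrt(half_w^2 + half_h^2))
    stop(sprintf("defocus %g um is out of range: the ring misses the detector entirely",
                 z_um))
  clipped <- r_outer > half_w || r_outer > half_h
  if (clipped)
    warning(sprintf("defocus %g um: ring radius %.0f um exceeds the detector; spot clipped",
                    z_um, r_outer))
  rx <- matrix(pc$x, length(pc$x), length(pc$y))
  ry <- matrix(pc$y, length(pc$x), length(pc$y), byrow = TRUE)
  r <- sqrt(rx^2 + ry^2)
  cov <- pmin(pmax((r_outer - r) / pitch + 0.5, 0), 1) *
    pmin(pmax((r - r_inner) / pitch + 0.5, 0), 1) *
    pmin(pmax(sgn * ry / pitch + 0.5, 0), 1)
  ideal_px <- (pi / 2) * (r_outer^2 - r_inner^2) / pitch^2
  frame <- cov / ideal_px
  if (!is.null(kernel)) {
    frame <- EBImage::imageData(EBImage::filter2(EBImage::Image(frame), kernel,
                                                 boundary = 0))
    frame[frame < 0] <- 0  # FFT convolution ringing
  }
  list(frame = frame, clipped = clipped)
}

#' Render the focused diffraction spot on the detector
#'
#' Places the pixelated focused-spot kernel (see [focused_kernel()]) at the
#' frame centre, scales it to `photon_scale * reflectivity` expected photons
#' and, when a `seed` is given, draws Poisson shot noise plus Gaussian read
#' noise and quantizes to the detector bit depth. Without a seed the
#' noiseless expected-count frame is returned. A `photon_scale` of 0 means
#' no exposure: the frame is all zero.
#'
#' @param field a `field_grid` of the aperture's focused pattern.
#' @param train an [optical_train()].
#' @param photon_scale expected photon count collected from a unit-
#'   reflectivity surface.
#' @param read_sigma Gaussian read-noise standard deviation (counts).
#' @param seed integer seed for the noise draw; `NULL` for a noiseless
#'   frame.
#' @param reflectivity surface weight in `[0, 1]`.
#' @param kernel optional precomputed [focused_kernel()] (saves recomputing
#'   it across frames).
#' @param supersample,extent_px forwarded to [focused_kernel()].
#' @return A `detector_image`.
#' @export
render_focused_spot <- function(field, train, photon_scale = 2e7,
                                read_sigma = 2, seed = NULL, reflectivity = 1,
                                kernel = NULL, supersample = 4,
                                extent_px = 15) {
  if (is.null(kernel))
    kernel <- focused_kernel(field, train, supersample, extent_px)
  expected <- if (photon_scale > 0)
    embed_kernel(train, kernel) * photon_scale * reflectivity
  else matrix(0, train$detector_px[1], train$detector_px[2])
  noisy <- apply_detector_noise(expected, read_sigma,
                                if (photon_scale > 0) seed else NULL)
  new_detector_image(noisy$pixels, train, photon_scale, read_sigma, seed,
                     noisy$quantized, clipped = FALSE)
}

#' Render a defocused half-ring spot on the detector
#'
#' A reflective surface at defocus `z` images as a geometric half-annulus of
#' outer radius `R(z) = |z| (f_I/f_O) tan(theta)` and inner radius
#' `tau R(z)`, opening toward +y for `z > 0` and -y for `z < 0`, uniformly
#' filled and convolved with the focused-spot kernel. Edges are anti-aliased
#' with single-pixel box coverage. At `z = 0` the render degenerates to
#' [render_focused_spot()]. Rings larger than the detector are clipped with
#' a warning; a ring whose inner radius exceeds the detector half-diagonal
#' (nothing would land) is an error.
#'
#' @param z_um signed defocus (micrometres).
#' @param train an [optical_train()].
#' @param ray a [marginal_ray_angle()] geometry.
#' @param aperture an [aperture_spec()] (supplies the obscuration ratio).
#' @param field field used to build the kernel when `kernel` is `NULL`; if
#'   both are `NULL` the oracle field of `aperture` is computed.
#' @inheritParams render_focused_spot
#' @return A `detector_image`.
#' @export
render_defocused_ring <- function(z_um, train, ray = marginal_ray_angle(train),
                                  aperture = aperture_spec(),
                                  field = NULL, kernel = NULL,
                                  photon_scale = 2e7, read_sigma = 2,
                                  seed = NULL, reflectivity = 1) {
  if (is.null(kernel)) {
    if (is.null(field)) field <- fraunhofer_field(aperture, train)
    kernel <- focused_kernel(field, train)
  }
  if (z_um == 0)
    return(render_focused_spot(field, train, photon_scale, read_sigma, seed,
                               reflectivity, kernel = kernel))
  ring <- expected_ring_frame(z_um, train, ray, aperture, kernel)
  expected <- if (photon_scale > 0)
    ring$frame * photon_scale * reflectivity
  else matrix(0, train$detector_px[1], train$detector_px[2])
  noisy <- apply_detector_noise(expected, read_sigma,
                                if (photon_scale > 0) seed else NULL)
  new_detector_image(noisy$pixels, train, photon_scale, read_sigma, seed,
                     noisy$quantized, clipped = ring$clipped)
}

#' Render a multi-surface detector frame
#'
#' Superposes the per-surface renders of a [surface_stack()] -- the focused
#' surface contributes the central spot, the others half-rings -- weighted
#' by reflectivity, then applies a single noise draw to the summed expected
#' counts.
#'
#' @param stack a [surface_stack()].
#' @inheritParams render_defocused_ring
#' @return A `detector_image`.
#' @examples
#' \dontrun{
#' tr <- optical_train()
#' frame <- render_surface_stack(surface_stack(c(-30, 0, 40)), tr, seed = 1)
#' }
#' @export
render_surface_stack <- function(stack, train,
                                 ray = marginal_ray_angle(train),
                                 aperture = aperture_spec(),
                                 field = NULL, kernel = NULL,
                                 photon_scale = 2e7, read_sigma = 2,
                                 seed = NULL) {
  if (is.null(kernel)) {
    if (is.null(field)) field <- fraunhofer_field(aperture, train)
    kernel <- focused_kernel(field, train)
  }
  expected <- matrix(0, train$detector_px[1], train$detector_px[2])
  clipped <- FALSE
  for (i in seq_along(stack$z_um)) {
    if (stack$reflectivity[i] == 0) next
    part <- if (stack$z_um[i] == 0) {
      embed_kernel(train, kernel)
    } else {
      ring <- expected_ring_frame(stack$z_um[i], train, ray, aperture, kernel)
      clipped <- clipped || ring$clipped
      ring$frame
    }
    expected <- expected + part * stack$reflectivity[i]
  }
  expected <- expected * photon_scale
  noisy <- apply_detector_noise(expected, read_sigma,
                                if (photon_scale > 0) seed else NULL)
  new_detector_image(noisy$pixels, train, photon_scale, read_sigma, seed,
                     noisy$quantized, clipped)
}
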