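#' Optical train of the depth-sensing channel
#'
#' Bundles the unit-carrying configuration of the system: microscope
#' objective and imaging-lens focal lengths, laser wavelength, numerical
#' aperture, immersion-medium index, objective magnification, the
#' half-aperture of the expanded incident beam, and the detector geometry.
#' All lengths are converted to micrometres internally; arguments state their
#' units in their names.
#'
#' @param f_objective_mm objective focal length (mm).
#' @param f_imaging_mm imaging-lens focal length (mm).
#' @param wavelength_nm laser wavelength (nm).
#' @param na numerical aperture of the objective.
#' @param medium_index refractive index of the medium between sample and
#'   objective front element (1 for air).
#' @param magnification transverse magnification of the objective.
#' @param beam_half_aperture_mm half-aperture of the expanded incident beam
#'   (mm).
#' @param pixel_pitch_um detector pixel pitch (micrometres).
#' @param detector_px detector size in pixels, `c(width, height)`.
#'
#' @return An object of class `optical_train`.
#' @examples
#' tr <- optical_train()
#' image_scale(tr)  # lateral magnification f_I / f_O
#' @export
optical_train <- function(f_objective_mm = 10, f_imaging_mm = 200,
                          wavelength_nm = 785, na = 0.75, medium_index = 1,
                          magnification = 20, beam_half_aperture_mm = 10,
                          pixel_pitch_um = 5.5, detector_px = c(2048L, 1088L)) {
  lengths <- c(f_objective_mm, f_imaging_mm, wavelength_nm,
               beam_half_aperture_mm, pixel_pitch_um)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all lengths of an optical train must be finite and positive")
  if (!is.finite(na) || na < 0 || na >= medium_index)
    stop("numerical aperture must satisfy 0 <= NA < medium index")
  if (length(detector_px) != 2 || any(detector_px < 0))
    stop("detector_px must be c(width, height) in pixels, both >= 0")
  structure(list(
    f_objective_um = f_objective_mm * 1e3,
    f_imaging_um = f_imaging_mm * 1e3,
    wavelength_um = wavelength_nm * 1e-3,
    na = na,
    medium_index = medium_index,
    magnification = magnification,
    beam_half_aperture_um = beam_half_aperture_mm * 1e3,
    pixel_pitch_um = pixel_pitch_um,
    detector_px = as.integer(detector_px)
  ), class = "optical_train")
}

#' @export
print.optical_train <- function(x, ...) {
  cat("<optical_train>\n")
  cat(sprintf("  objective f = %g mm, imaging f = %g mm (scale %gx)\n",
              x$f_objective_um / 1e3, x$f_imaging_um / 1e3, image_scale(x)))
  cat(sprintf("  wavelength %g nm, NA %g (n = %g), magnification %gx\n",
              x$wavelength_um * 1e3, x$na, x$medium_index, x$magnification))
  cat(sprintf("  detector %d x %d px @ %g um\n",
              x$detector_px[1], x$detector_px[2], x$pixel_pitch_um))
  invisible(x)
}

#' Lateral image scale of the relay
#'
#' The imaging-to-objective focal-length ratio `f_I / f_O`, i.e. the lateral
#' magnification from the object (sample) plane to the detector plane.
#'
#' @param train an [optical_train()].
#' @return Dimensionless scalar.
#' @export
image_scale <- function(train) train$f_imaging_um / train$f_objective_um

#' Marginal-ray angle of the objective
#'
#' The triangulation relations use the incidence angle theta of the outermost
#' focused ray, fixed here as the marginal ray of the objective:
#' `sin(theta) = NA / n`. Its tangent is the sensitivity of the detector ring
#' radius to defocus.
#'
#' @param train an [optical_train()].
#' @return An object of class `ray_geometry` with elements `theta_rad` and
#'   `tan_theta`.
#' @examples
#' ray <- marginal_ray_angle(optical_train())
#' ray$tan_theta  # 1.1339 for NA 0.75 in air
#' @export
marginal_ray_angle <- function(train) {
  s <- train$na / train$medium_index
  if (s >= 1) stop("invalid configuration: NA must be smaller than the medium index")
  theta <- asin(s)
  structure(list(theta_rad = theta, tan_theta = s / sqrt(1 - s^2)),
            class = "ray_geometry")
}

#' @export
print.ray_geometry <- function(x, ...) {
  cat(sprintf("<ray_geometry> theta = %.4f rad (%.2f deg), tan theta = %.5f\n",
              x$theta_rad, x$theta_rad * 180 / pi, x$tan_theta))
  invisible(x)
}

#' Detector spot radius for a given defocus
#'
#' A reflective surface a signed distance `z` from the objective's focal
#' plane images as a half-ring of outer radius `R = |z| (f_I/f_O) tan(theta)`
#' on the detector; the sign of `z` is carried by the ring's opening
#' direction, not by `R`.
#'
#' @param defocus_um signed defocus z (micrometres).
#' @param train an [optical_train()].
#' @param ray a [marginal_ray_angle()] geometry.
#' @return Ring outer radius on the detector (micrometres, >= 0).
#' @export
spot_radius_on_detector <- function(defocus_um, train,
                                    ray = marginal_ray_angle(train)) {
  stopifnot(all(is.finite(defocus_um)))
  abs(defocus_um) * image_scale(train) * ray$tan_theta
}

#' Defocus from a measured ring radius
#'
#' Inverts the linear radius--defocus relation:
#' `z = sign * R * f_O / (f_I tan(theta))`.
#'
#' @param radius_um measured outer ring radius on the detector (micrometres,
#'   >= 0).
#' @param orientation_sign +1 for a ring opening toward +y (surface beyond
#'   the focal plane), -1 for the opposite, 0 for a focused spot.
#' @inheritParams spot_radius_on_detector
#' @return Signed defocus z (micrometres).
#' @export
defocus_from_radius <- function(radius_um, orientation_sign, train,
                                ray = marginal_ray_angle(train)) {
  stopifnot(all(radius_um >= 0), all(orientation_sign %in% c(-1, 0, 1)))
  if (ray$tan_theta <= 0)
    stop("invalid configuration: tan(theta) must be positive to invert the radius relation")
  orientation_sign * radius_um / (image_scale(train) * ray$tan_theta)
}

#' Object-plane radius corresponding to a pixel count
#'
#' Converts a distance measured in detector pixels to object-plane
#' micrometres by demagnifying through the relay:
#' `n_px * pitch * f_O / f_I`.
#'
#' @param n_pixels distance in detector pixels (>= 0).
#' @param train an [optical_train()].
#' @return Object-plane distance (micrometres).
#' @examples
#' object_plane_radius_from_pixels(2.5, optical_train())  # 0.6875 um
#' @export
object_plane_radius_from_pixels <- function(n_pixels, train) {
  stopifnot(all(n_pixels >= 0))
  n_pixels * train$pixel_pitch_um / image_scale(train)
}

#' Focusing accuracy from lateral resolution
#'
#' The smallest axial separation of reflective surfaces the channel can
#' distinguish: `delta_z = delta_r / tan(theta)`, with `delta_r` the lateral
#' (Rayleigh) resolution on the sample.
#'
#' @param delta_r_um lateral resolution (micrometres, > 0).
#' @param ray a [marginal_ray_angle()] geometry.
#' @return Focusing accuracy delta_z (micrometres).
#' @export
focusing_accuracy <- function(delta_r_um, ray) {
  stopifnot(all(delta_r_um > 0))
  if (ray$tan_theta == 0)
    stop("invalid configuration: tan(theta) = 0 gives no depth sensitivity")
  delta_r_um / ray$tan_theta
}

#' Detector-plane sensitivity of the channel
#'
#' The detector-plane resolution element `delta_R`, computed either from the
#' focusing accuracy (`delta_R = (f_I/f_O) tan(theta) delta_z`) or from the
#' lateral resolution (`delta_R = (f_I/f_O) delta_r`). The two routes agree
#' when `delta_z = delta_r / tan(theta)`.
#'
#' @inheritParams spot_radius_on_detector
#' @param delta_z_um focusing accuracy (micrometres); give exactly one of
#'   `delta_z_um` / `delta_r_um`.
#' @param delta_r_um lateral resolution (micrometres).
#' @return delta_R on the detector (micrometres).
#' @export
detector_sensitivity <- function(train, ray = marginal_ray_angle(train),
                                 delta_z_um = NULL, delta_r_um = NULL) {
  if (is.null(delta_z_um) == is.null(delta_r_um))
    stop("give exactly one of delta_z_um or delta_r_um")
  if (!is.null(delta_z_um)) {
    stopifnot(all(delta_z_um >= 0))
    image_scale(train) * ray$tan_theta * delta_z_um
  } else {
    stopifnot(all(delta_r_um >= 0))
    image_scale(train) * delta_r_um
  }
}

#' Focusing range of the channel
#'
#' The largest defocus whose half-ring is guaranteed to stay on the detector.
#' The half-ring is displaced to one side along its opening axis (y), so the
#' limiting detector dimension is the half-extent along that axis:
#' `z_max = R_max f_O / (f_I tan(theta))` with
#' `R_max = (height/2) * pitch`. The range grows with detector size and
#' shrinks as the imaging focal length grows.
#'
#' @inheritParams spot_radius_on_detector
#' @return `z_max` (micrometres); the usable range is `[-z_max, +z_max]`.
#' @export
focusing_range <- function(train, ray = marginal_ray_angle(train)) {
  r_max <- (train$detector_px[2] / 2) * train$pixel_pitch_um
  if (r_max == 0) return(0)
  defocus_from_radius(r_max, 1, train, ray)
}

#' Depth of field of the objective
#'
#' Total depth of field of an infinity-corrected objective,
#' `d_tot = lambda n / NA^2 + n e / (M NA)`, combining the wave-optical term
#' and the detector (geometric) term. `e` is the smallest distance the
#' detector array resolves; it defaults to half the pixel pitch.
#'
#' @param train an [optical_train()].
#' @param e_um detector resolution element (micrometres); default
#'   `pixel_pitch_um / 2`.
#' @return Depth of field (micrometres).
#' @examples
#' depth_of_field(optical_train())  # 1.579 um for 20x/0.75 at 785 nm
#' @export
depth_of_field <- function(train, e_um = NULL) {
  if (is.null(e_um)) e_um <- train$pixel_pitch_um / 2
  stopifnot(e_um >= 0)
  n <- train$medium_index
  train$wavelength_um * n / train$na^2 +
    n * e_um / (train$magnification * train$na)
}
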