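# Shared fixtures: the reference design of the depth-sensing channel.
# Heavier objects (oracle field, spot kernel) are built once per run.

ref_train <- optical_train()
ref_ray <- marginal_ray_angle(ref_train)
ref_aperture <- aperture_spec(10, 8)
semi_disk <- aperture_spec(10, 0)

# oracle focused field of the design aperture (object-plane window +-5 um)
ref_field <- fraunhofer_field(ref_aperture, ref_train,
                              window_um = 5, samples = 257)
ref_kernel <- focused_kernel(ref_field, ref_train)

# closed-form magnitude of the 2b x b rectangle field (unit peak), used as
# the independent oracle for the N = 1 strip collapse and the sinc metrics
rect_field_magnitude <- function(x_um, y_um, b_um, lambda_um, f_um) {
  k <- 2 * pi / lambda_um
  sx <- vapply(x_um, function(x) {
    u <- k * x / f_um
    if (u == 0) b_um else sin(b_um * u) / u
  }, numeric(1))
  sy <- vapply(y_um, function(y) {
    u <- k * y / f_um
    if (u == 0) b_um else 2 * sin(b_um * u / 2) / u
  }, numeric(1))
  m <- abs(outer(sx, sy))
  m / max(m)
}
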