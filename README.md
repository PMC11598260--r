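# depthsense

Depth sensing of multi-layer reflective surfaces by semi-annular aperture
diffraction.

## The problem

Transparent biological samples present several reflective interfaces to a
microscope (coverslip, channel, slide), and a conventional autofocus
sensor cannot tell which one it is locked onto. An active depth-sensing
channel solves this by illuminating the sample through a **semi-annular
diaphragm** (a half-ring of outer radius *b*, inner radius *a*): a surface
in the objective's focal plane returns a compact spot at the camera's
centre, while a surface at signed defocus *z* returns a **half-ring** of
outer radius

```
R = |z| * (f_I / f_O) * tan(theta),      sin(theta) = NA / n
```

whose opening direction (toward +y or -y) encodes the sign of *z*. One
frame therefore depth-tags every reflective surface simultaneously. The
smallest axial separation two surfaces may have and still be told apart
follows from the Rayleigh criterion, `delta_z = delta_r / tan(theta)`,
with `delta_r` the first dark-ring radius of the focused diffraction
pattern along its symmetry (y) axis.

`depthsense` is an R implementation of the complete computational chain:

* **optics**: unit-safe configuration and all closed-form triangulation
  relations (`optical_train()`, `spot_radius_on_detector()`,
  `defocus_from_radius()`, `focusing_accuracy()`, `depth_of_field()`,
  `focusing_range()`);
* **diffraction**: the far field of semi-circular / semi-annular
  diaphragms, both by the N-strip accumulation model
  (`strip_model_field()`, either the literal linear half-width rule or
  true circle chords) and by an independent exact-mask transform oracle
  (`fraunhofer_field()`, `fraunhofer_axis_profile()`);
* **metrics**: dark-ring positions, side-lobe SNR, obscuration-ratio
  sweeps and the system resolution report (`first_dark_ring()`,
  `snr_db()`, `tau_sweep()`, `resolution_report()`);
* **synthetic frames**: pixelated, noisy detector images of focused
  spots, defocused half-rings and multi-surface stacks
  (`render_focused_spot()`, `render_defocused_ring()`,
  `render_surface_stack()`);
* **depth recovery**: spot/ring detection, radius and orientation
  estimation, inversion to per-surface depth, and resolvability checks
  (`segment_spots()`, `estimate_depths()`, `check_resolvability()`).

A thin command-line wrapper (`inst/cli/depthsense`) exposes the pipeline
as `simulate-field`, `tables`, `report`, `render`, `render-stack` and
`analyze` subcommands.

## Worked example

The reference design: b = 10 mm / a = 8 mm diaphragm, 10 mm objective,
200 mm imaging lens, 785 nm, NA 0.75, 5.5 um pixels (2048 x 1088).

```r
library(depthsense)

train    <- optical_train()          # the reference design
ray      <- marginal_ray_angle(train)
aperture <- aperture_spec(10, 8)

# resolution of the channel from the exact diffraction pattern
field <- fraunhofer_field(aperture, train)
resolution_report(field, train, ray)
#> <resolution_report>
#>   lateral resolution  delta_r = 0.7801 um
#>   focusing accuracy   delta_z = 0.6880 um
#>   depth of field      d_tot   = 1.5789 um
#>   delta_z / d_tot             = 0.436

# render a three-surface sample (one coverslip on two coverslips,
# focused on the middle surface) and recover the depths from the frame
kern  <- focused_kernel(field, train)
frame <- render_surface_stack(surface_stack(c(-30, 0, 40)), train, ray,
                              aperture, kernel = kern, seed = 1)
est <- estimate_depths(segment_spots(frame), train, ray, aperture)
est
#>        z_um outer_radius_um orientation_sign pixel_count
#> 1 -30.02020       680.79407               -1        9815
#> 2   0.00000        58.33631                0         843
#> 3  39.99231       906.94043                1       15342

check_resolvability(est, resolution_report(field, train, ray), train, ray)
#> <depth_resolvability> delta_z = 0.688 um, pixel-equivalent = 0.243 um (rayleigh_dz limits)
#>    z_lo_um  z_hi_um separation_um resolvable
#> 1 -30.0202  0.00000      30.02020       TRUE
#> 2   0.0000 39.99231      39.99231       TRUE
```

Reading the output: the focused surface is the centred spot (orientation
0); the surface 30 um *before* the focal plane images as a half-ring of
radius 681 um opening toward -y, the surface 40 um *beyond* it as a ring
of radius 907 um opening toward +y. Inverting `R = z (f_I/f_O)
tan(theta)` recovers the depths to ~0.02 um at the default photon budget.
The lateral resolution of the channel — the first amplitude minimum of the
half-annulus pattern along its symmetry axis — computes to 0.78 um, an
axial (interlayer) resolution of 0.69 um, about two fifths of the
objective's 1.58 um depth of field.

The diffraction-table sweep behind the aperture design trade-off
(smaller central lobe vs. rising side lobes as the obscuration ratio
grows) is one call:

```r
tau_sweep(b_mm = 10, train, tau = seq(0, 0.9, by = 0.1))
```

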