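---
title: "Semi-annular aperture depth sensing: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-annular aperture depth sensing: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthsense)
```

## The measurement principle

Transparent biological preparations present several reflective interfaces
to a microscope — the upper coverslip, a microfluidic channel, the slide —
and a focus sensor that cannot tell them apart will servo onto the wrong
one. The channel modelled here illuminates the sample through a
*semi-annular* diaphragm (a half-ring of outer radius $b$ and inner radius
$a$, obscuration ratio $\tau = a/b$), focused by the objective and
re-imaged onto a camera after reflection. Geometry does the depth tagging:

* a surface in the focal plane returns a compact diffraction spot at the
  frame centre;
* a surface a signed distance $z$ from the focal plane returns a
  *half-ring* of outer radius
  $$R = |z| \, \frac{f_I}{f_O} \tan\theta,$$
  where $f_O$ and $f_I$ are the objective and imaging focal lengths and
  $\theta$ is the marginal-ray angle, $\sin\theta = \mathrm{NA}/n$. The
  ring opens toward $+y$ for $z > 0$ and $-y$ for $z < 0$, so one frame
  reads out position *and* sign for every surface at once.

Inverting the linear relation gives per-surface depth; the smallest axial
separation two surfaces may have and still be told apart is set by the
Rayleigh criterion through the lateral resolution $\delta r$ of the
illumination spot, $\delta z = \delta r / \tan\theta$, with the detector
pixel pitch as a secondary floor.

The reference configuration used throughout (and shipped as
`default_run_config()`) is: $b = 10$ mm, $a = 8$ mm, $f_O = 10$ mm
(a 20x objective), $f_I = 200$ mm, $\lambda = 785$ nm, NA 0.75 in air,
5.5 um pixels on a 2048 x 1088 sensor.

## Why the marginal ray

The triangulation angle $\theta$ is not an independent design parameter
here: it is fixed to the objective's marginal ray,
$\sin\theta = \mathrm{NA}/n$. With NA 0.75 in air this gives
$\tan\theta = 1.1339$, and the chain
$\delta z = \delta r/\tan\theta$ then converts every lateral-resolution
number consistently into its axial counterpart (0.68 um $\to$ 0.60 um,
0.688 um $\to$ 0.607 um). This identification is an assumption of the
model — a system whose annular beam under-fills the pupil would have a
shallower cone and a proportionally worse $\delta z$.

## Two diffraction models, one oracle

The far field of an asymmetric aperture has no closed form, so the
package computes it twice, by different routes:

1. **Strip accumulation** (`strip_model_field()`). The half-aperture is
   sliced into $N$ horizontal strips of height $b/N$; each strip is a
   rectangle whose far field is a phased sinc, and the total field is the
   phased sum. Two half-width rules are provided. The
   `as_printed_linear` rule shrinks the outer half-width *linearly*,
   $w_n = b(N-n)/N$ (and the inner obscuration as $a - (b/N)n$); this is
   the accumulation formula in its literal printed form. The
   `circular_chord` rule (default) uses the true circle chords
   $w_n = \sqrt{b^2 - y_n^2}$ at the strip centres. Both collapse to the
   $2b \times b$ rectangle at $N = 1$ and converge for $N \gtrsim 100$;
   only the chord rule converges to the physically exact pattern. The
   linear rule is retained because the published table values for this
   kind of system derive from it; its first x-axis zero sits at
   $\lambda f / b$, a factor ~1.6 from the chord/oracle position, which
   matters when comparing against published numbers.
2. **Direct mask transform** (`fraunhofer_field()`,
   `fraunhofer_axis_profile()`). The aperture is rasterized (binary
   transmittance, at least 64 samples across the open annulus) and the
   Fraunhofer integral is evaluated exactly at the requested focal-plane
   points as dense matrix products. This serves as the independent
   physical oracle for every metric: it involves no strip approximation
   at all. A padded-FFT variant (`fraunhofer_full_transform()`) keeps the
   classical Parseval/aliasing bookkeeping available.

The uniform incident amplitude and the global complex prefactor
($A e^{jkf}/(j\lambda f) \cdot e^{jk(x^2+y^2)/2f}$) are carried
symbolically and never enter magnitude metrics; every metric is taken on
the unit-peak $|E|$. Removable singularities ($\sin(\alpha u)/u$ at
$u = 0$) are evaluated by their limits, not by epsilon offsets. Default
focal-plane windows are $\pm 5$ um with the origin on the grid (odd
sample counts); aperture-plane coordinates are mm, focal-plane
coordinates um, and $k = 2\pi/\lambda$ with everything converted to um
internally.

## Dark rings, SNR, and what "first zero" means here

Along its symmetry ($y$) axis the half-aperture field has no true zeros:
the "dark ring" is a pronounced local minimum. `first_dark_ring()`
therefore reports the first *strict local minimum* of $|E|$ below a
qualifying fraction of the peak (default 0.25), refined by three-point
parabolic interpolation. The qualifying fraction matters: at obscuration
ratios 0.8–0.9 the genuine first dip bottoms out at 0.21–0.22 of peak,
so a 0.20 cutoff would skip the physical first ring of the design
aperture and jump to the second minimum; 0.25 keeps every first dip in
the design range $\tau \in [0, 0.9]$ while still rejecting shallow
shoulder wiggles. Where profiles do have true zeros (rectangle sinc,
full-circle Airy) the same machinery recovers them to better than 0.5%.

For the reference design ($b = 10$, $a = 8$ mm) the exact transform puts
the first y-axis minimum at **0.778 um** — this is the number
`scripts/acceptance.R` recomputes, and via the marginal ray it implies a
focusing accuracy of 0.69 um. Published treatments of this configuration
quote a smaller lateral resolution (0.68 um); that figure is not
reproduced by either the literal strip formula (0.872 um) or the exact
transform (0.778 um), and no dark-ring convention we tried (intensity
versus amplitude minima, detilted real-part zero crossings,
threshold-crossing variants) yields it from the stated geometry. The
package reports what the stated model computes.

`snr_db()` quantifies side-lobe noise as
$20\log_{10}$(peak / largest secondary local maximum) of the unit-peak
2-D magnitude (strict 8-neighbour maxima). The convention is deliberately
isolated behind one function: no published definition is available for
this system, and other reasonable conventions (intensity ratios, 1-D
scans) shift the absolute dB values while preserving the trend with
$\tau$.

`tau_sweep()` tabulates $X_0$, $Y_0$ and SNR against $\tau$, by default
under the oracle model. Two empirical notes, both visible in the test
suite: the x-axis ring and the SNR shrink essentially monotonically with
$\tau$, but the y-axis first minimum **does not** — under the exact
transform it first moves *outward* by ~6% (peaking near $\tau \approx
0.4$) before contracting, with a corresponding non-monotone step in the
SNR near $\tau = 0.1$. The often-stated claim that the whole pattern
contracts monotonically as the obscuration grows holds for $X_0$ only.
Feature positions scale exactly as $1/b$ at fixed $\tau$ (pure Fourier
geometry), and $Y_0/X_0$ stays between 1.85 and 2.4 across the design
range — the "about twice" elongation that makes the y-axis the
resolution-limiting direction.

## The synthetic detector frames

`render_focused_spot()`, `render_defocused_ring()` and
`render_surface_stack()` emulate the camera frames of the physical
channel:

* the focused spot is the computed $|E|^2$ magnified by $f_I/f_O$,
  resampled to the pixel grid by 4x supersampling and binning
  (`focused_kernel()`), and placed at the frame centre;
* a defocused surface is rendered geometrically: a uniformly filled
  half-annulus between $\tau R(z)$ and $R(z)$, opening along
  $\mathrm{sign}(z)\,y$, with single-pixel anti-aliased edges
  (analytically — the box-filter limit of supersampling, at a fraction
  of the cost), convolved with the focused-spot kernel;
* a surface stack is the reflectivity-weighted sum of per-surface
  renders followed by *one* noise draw: Poisson shot noise at the
  configured photon budget plus Gaussian read noise, quantized to 16
  bits. Every draw is seed-deterministic and leaves the caller's RNG
  state untouched; omitting the seed returns the noiseless expected
  counts unquantized.

Defaults: photon budget $2 \times 10^7$ photons per unit-reflectivity
surface and read noise $\sigma = 2$ counts. The budget is chosen so that
the dimmest in-scope ring ($|z| = 200$ um, spread over $\sim 4 \times
10^5$ pixels) still sits ~25 read-noise sigmas above background, as
frames from a laser-illuminated channel do. The geometric ring model
follows from neglecting the ring thickness in the triangulation (the
same approximation the closed-form relations make); it does not model
coherent speckle, interference between surface reflections, aberrations,
or the radial intensity structure a defocused wave would really have —
the fill is declared uniform. Consequently, passing round-trip tests
demonstrates the *estimator chain* is unbiased under the stated model,
not that a physical instrument achieves these errors.

## Recovering depths from a frame

`segment_spots()` thresholds a frame at the larger of 1% of the frame
maximum (capped at sensor saturation) and a robust background floor
(median plus 5 background sigmas, with sigma taken from the upper-decile
spread so that quantized, mostly-zero backgrounds do not defeat it),
closes single-pixel gaps morphologically so shot noise cannot fragment a
dim ring, and labels connected components. Components smaller than 50
pixels are discarded as speckle. Per component it reports the
intensity-weighted centroid, the ring-opening orientation (sign of the
centroid's y-offset; "focused" below one pixel), and two radius
statistics:

* the intensity-weighted 95th-percentile radial extent about the frame
  centre — simple and robust, but biased low by the annular fill
  (analytically, the 95th percentile of a uniformly filled half-annulus
  sits at $R\sqrt{0.95 + 0.05\tau^2}$, ~1% low at $\tau = 0.8$) and
  biased by the blur skirt;
* the *edge radius*: the steepest-descent (inflection) point of the
  azimuthally averaged radial intensity profile. Because the blur kernel
  is symmetric, the inflection of the smeared outer step stays at the
  true outer radius, independent of brightness, of partial clipping at
  the detector boundary, and of the blur width.

`estimate_depths()` prefers the edge radius (falling back to the
fill-debiased percentile), inverts the triangulation, and merges arcs of
one clipped ring that the detector boundary cut into separate
components. On the synthetic frames this chain recovers $z \in \pm[25,
200]$ um to ~0.03 um at default noise and ring radii to under 0.1 pixel
noiselessly — comfortably inside the 1-pixel tolerance the estimators
are documented for. `check_resolvability()` then labels adjacent
surface pairs with the active constraint: for the reference design the
Rayleigh bound (0.69 um from the computed ring; 0.607 um if one adopts
the published 0.688 um ring radius) dominates the pixel-equivalent
distance (0.243 um).

Dynamic range is the known failure mode of segmentation: a frame
containing both a saturated focused spot and a ring dimmer than ~1% of
saturation (that is $|z| \gtrsim 150$ um at the default budget) will
drop the ring. Single-surface frames have no such limit, because the
threshold then tracks the ring's own peak.

## Focusing range and depth of field

`focusing_range()` reports the largest defocus whose ring is guaranteed
uncut: the limiting dimension is the detector half-extent along the ring
*opening* axis (the half-height, 2992 um), giving $\pm 131.9$ um for the
reference train. Rings beyond that render clipped-with-warning up to the
half-diagonal; the round-trip suite deliberately exercises $\pm 200$ um
to show the estimator still works on cut rings. A quoted range of
$\pm 200$ um for this geometry is consistent only with the half-*width*
(5632 um along x), i.e. with ignoring the displacement of the ring along
its opening axis.

`depth_of_field()` implements
$d_{tot} = \lambda n/\mathrm{NA}^2 + n e/(M\,\mathrm{NA})$. The detector
term's $e$ (the smallest distance the sensor resolves) is exposed as a
parameter and defaults to half the 5.5 um pixel pitch; with $e = 2.75$
um the reference train gives $d_{tot} = 1.579$ um, which makes the
focusing accuracy roughly two fifths of the objective's depth of field.

## Problem sizes and numerical defaults

Default sampling was chosen to put discretization error well under the
metric tolerances: masks of 1024–4096 samples per axis (adaptively, so
the open annulus always spans at least 64 samples), focal windows of
$\pm 5$ um at 1025 samples for fields and 2001–4001 samples for 1-D
dark-ring profiles, and $N = 1000$ strips (the converged setting; 100
already agrees within 1% of peak). The acceptance computation uses a
4096-squared mask. The round-trip suite renders full 2048 x 1088 frames,
eight defocus values at twenty noise seeds each. Non-integer $\tau N$
inner-strip counts are rounded to the nearest integer with a warning.
Ties and degenerate inputs error early and loudly: empty apertures,
$\mathrm{NA} \ge n$, windows that end before the first minimum, frames
with no pixel above threshold.

## Known limitations

* The y-axis "dark ring" of the half-aperture is a minimum, not a zero;
  any resolution number for this geometry inherits the qualifying-depth
  convention documented above.
* The published table values for this configuration are not reproduced
  numerically by either model (their generating conventions are not
  recoverable); the package covers those tables with structure, trend
  and scaling properties instead, and the two genuinely non-monotone
  trends (y-axis minimum and one SNR step) are reported as computed.
* The detector model omits coherent effects, aberrations and
  fixed-pattern noise; the ring fill is uniform by declaration.
* Segmentation assumes at most one ring per half-plane per radial band;
  overlapping rings within ~3 pixels are merged, not deconvolved.
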