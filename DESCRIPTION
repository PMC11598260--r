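Package: depthsense
Title: Depth Sensing of Multi-Layer Reflective Surfaces by Semi-Annular
        Aperture Diffraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email =
        "author@example.org")
Description: Numerical toolkit for an active depth-sensing microscope channel
 that illuminates transparent, multi-layered samples through a semi-annular
 aperture diaphragm. Computes far-field (Fraunhofer) diffraction of
 semi-circular and semi-annular diaphragms both by an N-strip accumulation
 model and by direct transform of the exact aperture mask; extracts
 dark-ring positions, side-lobe signal-to-noise ratios and
 Rayleigh-criterion resolution from the computed fields; implements the
 triangulation relations linking detector spot radius to defocus; renders
 synthetic pixelated detector frames of focused spots and defocused
 half-ring spots for stacks of reflective surfaces; and recovers
 per-surface depth from such frames.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: EBImage,
 jsonlite,
 yaml,
 tiff,
 png,
 stats,
 utils,
 grDevices,
 graphics
Suggests: testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
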