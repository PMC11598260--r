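#' Semi-annular aperture diaphragm
#'
#' Geometry of the beam-shaping diaphragm: a half-annulus with outer radius
#' `b`, inner radius `a` and obscuration ratio `tau = a/b`, its flat edge
#' along the x-axis and the open half at `y >= 0`. `a = 0` gives the
#' semi-circular diaphragm. The `shape` argument also admits the full
#' annulus and the circumscribed `2b x b` rectangle, which serve as
#' closed-form validation apertures for the direct-transform oracle; the
#' strip model applies to the `"semi"` shape only.
#'
#' @param b_mm outer radius (mm).
#' @param a_mm inner radius (mm), `0 <= a < b`.
#' @param shape `"semi"` (default) for the half-annulus at `y >= 0`,
#'   `"full"` for the full annulus, `"rect"` for a rectangle of width `2b`
#'   (x) and height `b` (`0 <= y <= b`).
#' @return An object of class `aperture_spec`.
#' @examples
#' aperture_spec()            # the b = 10 mm, a = 8 mm design stop
#' aperture_spec(10, 0)       # semi-circular diaphragm
#' @export
aperture_spec <- function(b_mm = 10, a_mm = 8, shape = c("semi", "full", "rect")) {
  shape <- match.arg(shape)
  if (!is.finite(b_mm) || b_mm <= 0) stop("outer radius b must be positive")
  if (!is.finite(a_mm) || a_mm < 0) stop("inner radius a must be >= 0")
  if (a_mm >= b_mm) stop("degenerate aperture: inner radius must satisfy a < b")
  structure(list(
    b_um = b_mm * 1e3,
    a_um = a_mm * 1e3,
    tau = a_mm / b_mm,
    shape = shape,
    orientation = "flat edge on the x-axis, open half at y >= 0"
  ), class = "aperture_spec")
}

#' @export
print.aperture_spec <- function(x, ...) {
  cat(sprintf("<aperture_spec> %s, b = %g mm, a = %g mm (tau = %g)\n",
              x$shape, x$b_um / 1e3, x$a_um / 1e3, x$tau))
  invisible(x)
}

#' Sampled transmittance mask of the aperture
#'
#' Binary transmittance on a square grid covering `[-b, b]^2`: 1 where
#' `a <= sqrt(x0^2 + y0^2) <= b` and (for the half shape) `y0 >= 0`, else 0.
#' Errors if the open annulus width spans fewer than 64 samples, which is
#' too coarse for the transform oracle.
#'
#' @param aperture an [aperture_spec()].
#' @param samples grid points per axis.
#' @return A list of class `aperture_mask` with `x0_um`, `y0_um` (sample
#'   centres) and the 0/1 `transmittance` matrix indexed `[x0, y0]`.
#' @export
aperture_mask <- function(aperture, samples = 2048) {
  b <- aperture$b_um
  a <- aperture$a_um
  s <- seq(-b, b, length.out = samples)
  d <- s[2] - s[1]
  width <- if (aperture$shape == "rect") b else b - a
  if (width / d < 64)
    stop(sprintf(paste("sampling error: aperture width spans %.0f samples",
                       "(< 64); increase `samples`"), width / d))
  x0 <- matrix(s, samples, samples)
  y0 <- matrix(s, samples, samples, byrow = TRUE)
  m <- if (aperture$shape == "rect") {
    (y0 >= 0) & (y0 <= b)
  } else {
    r2 <- x0^2 + y0^2
    open <- (r2 <= b^2) & (r2 >= a^2)
    if (aperture$shape == "semi") open & (y0 >= 0) else open
  }
  structure(list(x0_um = s, y0_um = s, transmittance = m + 0,
                 step_um = d, aperture = aperture),
            class = "aperture_mask")
}

#' Strip decomposition of a half-aperture
#'
#' The accumulation model slices the half-aperture into `N` horizontal
#' strips of height `b/N` stacked from the flat edge. Two half-width rules
#' are provided: `"as_printed_linear"` shrinks the outer half-width linearly,
#' `w_n = b (N - n) / N`, with inner half-widths `a - (b/N) n` over the first
#' `round(a N / b)` strips; `"circular_chord"` uses the true circle chords at
#' the strip centres, `w_n = sqrt(b^2 - y_n^2)` and
#' `v_n = sqrt(max(0, a^2 - y_n^2))` with `y_n = (n + 1/2) b / N`. The chord
#' rule converges to the exact aperture; the linear rule reproduces the
#' accumulation formula literally.
#'
#' @param aperture an [aperture_spec()] with shape `"semi"`.
#' @param n_strips number of strips N (>= 1).
#' @param rule half-width rule (see Details).
#' @return A list of class `strip_decomposition` with the strip index `n`
#'   (0-based), `y_center_um`, `outer_half_width_um` and
#'   `inner_half_width_um` (0 where the strip misses the obscuration).
#' @examples
#' strip_half_widths(aperture_spec(10, 0), 4, "as_printed_linear")
#' @export
strip_half_widths <- function(aperture, n_strips,
                              rule = c("circular_chord", "as_printed_linear")) {
  rule <- match.arg(rule)
  if (aperture$shape != "semi")
    stop("the strip decomposition applies to the half-aperture shape only")
  if (n_strips < 1) stop("n_strips must be >= 1")
  n_strips <- as.integer(n_strips)
  b <- aperture$b_um
  a <- aperture$a_um
  n <- 0:(n_strips - 1)
  h <- b / n_strips
  if (rule == "as_printed_linear") {
    outer <- b * (n_strips - n) / n_strips
    m_exact <- aperture$tau * n_strips
    m <- round(m_exact)
    if (abs(m - m_exact) > 1e-9)
      warning(sprintf(paste("inner strip count tau*N = %.6g is not an integer;",
                            "rounded to %d"), m_exact, m))
    inner <- rep(0, n_strips)
    if (m > 0) inner[seq_len(m)] <- pmax(0, a - h * n[seq_len(m)])
    y_center <- n * h  # phase reference of the printed accumulation
  } else {
    y_center <- (n + 0.5) * h
    outer <- sqrt(pmax(0, b^2 - y_center^2))
    inner <- sqrt(pmax(0, a^2 - y_center^2))
  }
  structure(list(n = n, n_strips = n_strips, rule = rule,
                 strip_height_um = h, y_center_um = y_center,
                 outer_half_width_um = outer, inner_half_width_um = inner,
                 aperture = aperture),
            class = "strip_decomposition")
}

#' @export
print.strip_decomposition <- function(x, ...) {
  cat(sprintf("<strip_decomposition> N = %d, rule = %s, strip height %g um\n",
              x$n_strips, x$rule, x$strip_height_um))
  invisible(x)
}
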