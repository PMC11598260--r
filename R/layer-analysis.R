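# p-quantile of x under weights w
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p)[1]]
}

# Outer-edge radius of a half-ring as the steepest-descent (inflection)
# point of the azimuthally averaged radial intensity profile. The spot
# kernel that blurs the ring is symmetric, so the inflection of the smeared
# outer step stays at the true outer radius; the estimate is insensitive to
# brightness, to partial clipping and to the blur width. Profile bins are
# one pixel wide over the component's radial band, restricted to the ring's
# half-plane; sub-pixel position by parabolic refinement of the derivative.
ring_edge_radius <- function(px, r_all, cy, orient, r_range, pitch) {
  lo <- max(0, r_range[1] - 10 * pitch)
  hi <- r_range[2] + 10 * pitch
  half <- if (orient > 0) which(cy > 0) else which(cy < 0)
  sub_r <- r_all[, half]
  sub_i <- px[, half]
  inband <- sub_r >= lo & sub_r <= hi
  rb <- sub_r[inband]
  ib <- sub_i[inband]
  bins <- floor((rb - lo) / pitch) + 1L
  nb <- max(bins)
  tot <- rep(0, nb)
  rs <- rowsum(ib, bins)
  tot[as.integer(rownames(rs))] <- rs[, 1]
  cnt <- tabulate(bins, nbins = nb)
  prof <- ifelse(cnt > 0, tot / pmax(cnt, 1), 0)
  centers <- lo + (seq_len(nb) - 0.5) * pitch
  # outer edge: steepest descent in the outer half of the band
  d <- diff(prof)
  search <- which(centers[-1] > (lo + hi) / 2 - 5 * pitch)
  i <- search[which.min(d[search])]
  # parabolic refinement on the derivative
  if (i > 1 && i < length(d)) {
    y1 <- d[i - 1]; y2 <- d[i]; y3 <- d[i + 1]
    den <- y1 - 2 * y2 + y3
    delta <- if (den > 0) max(-0.5, min(0.5, 0.5 * (y1 - y3) / den)) else 0
  } else delta <- 0
  centers[i] + (0.5 + delta) * pitch
}

#' Detect spots and half-rings on a detector frame
#'
#' Thresholds the frame, closes small gaps (morphological closing, so shot
#' noise does not fragment a dim ring), and labels connected components
#' (8-connectivity). The threshold is the larger of
#' `threshold_fraction * max` (with the maximum capped at the sensor
#' saturation level) and a robust noise floor, `median + floor_sigmas *
#' sigma_bg`, where the background sigma comes from the upper-decile spread
#' (it survives quantized frames whose background is mostly exactly zero).
#' This keeps dim rings while rejecting read-noise speckle; all terms scale
#' with the frame, so segmentation is invariant to uniform intensity
#' scaling. Per component the function
#' reports the intensity-weighted centroid (relative to the frame centre),
#' the outer radius as the intensity-weighted 95th-percentile radial extent
#' of its pixels about the frame centre (weighting suppresses the dim blur
#' skirt of the spot kernel), the pixel count, and the orientation sign of
#' the ring opening: the sign of the centroid's y-offset, or 0 (focused)
#' when the offset is under one pixel.
#'
#' @param image a `detector_image`.
#' @param threshold_fraction fraction of the frame maximum.
#' @param min_pixels discard components smaller than this (speckle guard;
#'   keep it above the closing-brush area).
#' @param floor_sigmas robust noise-floor multiplier.
#' @param closing_brush diameter (pixels, odd) of the disc brush used to
#'   close gaps before labelling; 0 disables.
#' @return A data frame of class `spot_observations`: one row per detected
#'   spot with `centroid_x_um`, `centroid_y_um`, `outer_radius_um`,
#'   `orientation_sign`, `pixel_count`.
#' @export
segment_spots <- function(image, threshold_fraction = 0.01, min_pixels = 50,
                          floor_sigmas = 5, closing_brush = 5) {
  px <- image$pixels
  # reference level for the fractional threshold: a physical frame clips at
  # the sensor full well, so an unquantized (noiseless) frame must not push
  # the threshold above what the detector would actually record
  mx <- min(max(px), 2^image$bit_depth - 1)
  # robust background sigma from the upper-decile spread; unlike the MAD it
  # survives quantized frames whose background is mostly exactly zero
  med <- median(px)
  sigma_bg <- (quantile(px, 0.9, names = FALSE) - med) / qnorm(0.9)
  thr <- max(threshold_fraction * mx, med + floor_sigmas * sigma_bg)
  mask <- px > thr
  if (!any(mask)) stop("no spots: no pixel above the detection threshold")
  img <- EBImage::Image(mask * 1)
  if (closing_brush >= 3)
    img <- EBImage::closing(img, EBImage::makeBrush(closing_brush, "disc"))
  labels <- EBImage::imageData(EBImage::bwlabel(img))
  counts <- tabulate(labels[labels > 0])
  keep <- which(counts >= min_pixels)
  if (!length(keep)) stop("no spots: all components below min_pixels")
  w <- nrow(px); h <- ncol(px)
  pitch <- image$pitch_um
  cx <- (seq_len(w) - 0.5 - w / 2) * pitch
  cy <- (seq_len(h) - 0.5 - h / 2) * pitch
  r_all <- sqrt(outer(cx^2, cy^2, "+"))
  rows <- lapply(keep, function(lab) {
    idx <- which(labels == lab, arr.ind = TRUE)
    wgt <- px[idx]
    if (all(wgt <= 0)) return(NULL)  # closing artefact over empty pixels
    gx <- sum(cx[idx[, 1]] * wgt) / sum(wgt)
    gy <- sum(cy[idx[, 2]] * wgt) / sum(wgt)
    r <- sqrt(cx[idx[, 1]]^2 + cy[idx[, 2]]^2)
    orient <- if (abs(gy) < pitch) 0 else sign(gy)
    edge <- if (orient == 0) NA_real_ else
      ring_edge_radius(px, r_all, cy, orient, range(r), pitch)
    data.frame(centroid_x_um = gx, centroid_y_um = gy,
               outer_radius_um = weighted_quantile(r, pmax(wgt, 0), 0.95),
               edge_radius_um = edge,
               orientation_sign = orient, pixel_count = nrow(idx))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$centroid_y_um), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spot_observations", "data.frame")
  out
}

#' Per-surface defocus from spot observations
#'
#' Inverts the radius--defocus relation for each observed spot:
#' `z = sign * R * f_O / (f_I tan(theta))`; a focused observation
#' (orientation 0) maps to `z = 0`. The outer radius of a ring observation
#' is taken from the edge (inflection-point) estimate when available; the
#' fallback is the 95th-percentile radial-extent statistic debiased for the
#' annular fill: for a uniformly filled half-annulus with obscuration ratio
#' `tau` the 95th percentile of pixel radii sits at
#' `R sqrt(0.95 + 0.05 tau^2)`, so the measured statistic is divided by
#' that factor.
#'
#' @param observations a [segment_spots()] result.
#' @param train an [optical_train()].
#' @param ray a [marginal_ray_angle()] geometry.
#' @param aperture an [aperture_spec()] for the percentile fill debias, or
#'   `NULL` to use the raw statistic.
#' @param use_edge take `edge_radius_um` for rings when not `NA` (default).
#' @return A data frame of class `depth_estimate`: `z_um`,
#'   `outer_radius_um` (the radius used), `orientation_sign`,
#'   `pixel_count`.
#' @export
estimate_depths <- function(observations, train,
                            ray = marginal_ray_angle(train),
                            aperture = NULL, use_edge = TRUE) {
  if (!nrow(observations)) stop("no observations to estimate depths from")
  debias <- if (is.null(aperture)) 1 else
    sqrt(0.95 + 0.05 * aperture$tau^2)
  r <- ifelse(observations$orientation_sign == 0,
              observations$outer_radius_um,
              observations$outer_radius_um / debias)
  if (use_edge && !is.null(observations$edge_radius_um))
    r <- ifelse(observations$orientation_sign != 0 &
                  !is.na(observations$edge_radius_um),
                observations$edge_radius_um, r)
  out <- data.frame(z_um = defocus_from_radius(r, observations$orientation_sign,
                                               train, ray),
                    outer_radius_um = r,
                    orientation_sign = observations$orientation_sign,
                    pixel_count = observations$pixel_count)
  out <- merge_arc_observations(out, merge_tol_um = 3 * train$pixel_pitch_um)
  out <- out[order(out$z_um), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("depth_estimate", "data.frame")
  out
}

# A ring clipped by the detector edge splits into disconnected arcs that
# belong to one surface: observations with the same orientation whose outer
# radii agree within merge_tol are combined (pixel-count-weighted radius).
merge_arc_observations <- function(est, merge_tol_um) {
  done <- logical(nrow(est))
  rows <- list()
  for (i in order(-est$pixel_count)) {
    if (done[i]) next
    same <- !done & est$orientation_sign == est$orientation_sign[i] &
      abs(est$outer_radius_um - est$outer_radius_um[i]) <= merge_tol_um
    done[same] <- TRUE
    w <- est$pixel_count[same]
    rows[[length(rows) + 1]] <- data.frame(
      z_um = sum(est$z_um[same] * w) / sum(w),
      outer_radius_um = sum(est$outer_radius_um[same] * w) / sum(w),
      orientation_sign = est$orientation_sign[i],
      pixel_count = sum(w))
  }
  do.call(rbind, rows)
}

#' Resolvability of adjacent surfaces
#'
#' Two surfaces are resolvable when their axial separation exceeds both the
#' Rayleigh focusing accuracy `delta_z` and the pixel-equivalent object
#' distance `pitch * f_O / (f_I tan(theta))`; the active (larger) bound is
#' recorded as the limiting constraint.
#'
#' @param estimate a [estimate_depths()] result (>= 1 surface).
#' @param report a [resolution_report()] supplying `delta_z`, or `NULL` if
#'   `delta_z_um` is given directly.
#' @param train an [optical_train()].
#' @param ray a [marginal_ray_angle()] geometry.
#' @param delta_z_um focusing accuracy override (micrometres).
#' @return A list of class `depth_resolvability`: the estimate, a data
#'   frame `pairs` (`z_lo_um`, `z_hi_um`, `separation_um`, `resolvable`),
#'   `delta_z_um`, `pixel_equivalent_um` and `limiting_constraint`
#'   (`"rayleigh_dz"` or `"pixel_size"`).
#' @export
check_resolvability <- function(estimate, report = NULL, train,
                                ray = marginal_ray_angle(train),
                                delta_z_um = NULL) {
  if (is.null(delta_z_um)) {
    if (is.null(report)) stop("give a resolution report or delta_z_um")
    delta_z_um <- report$delta_z_um
  }
  pix_equiv <- train$pixel_pitch_um / (image_scale(train) * ray$tan_theta)
  bound <- max(delta_z_um, pix_equiv)
  limiting <- if (delta_z_um >= pix_equiv) "rayleigh_dz" else "pixel_size"
  z <- sort(estimate$z_um)
  pairs <- if (length(z) > 1) {
    sep <- diff(z)
    data.frame(z_lo_um = z[-length(z)], z_hi_um = z[-1],
               separation_um = sep, resolvable = sep >= bound)
  } else {
    data.frame(z_lo_um = numeric(0), z_hi_um = numeric(0),
               separation_um = numeric(0), resolvable = logical(0))
  }
  structure(list(estimate = estimate, pairs = pairs,
                 delta_z_um = delta_z_um, pixel_equivalent_um = pix_equiv,
                 limiting_constraint = limiting),
            class = "depth_resolvability")
}

#' @export
print.depth_resolvability <- function(x, ...) {
  cat(sprintf("<depth_resolvability> delta_z = %.3f um, pixel-equivalent = %.3f um (%s limits)\n",
              x$delta_z_um, x$pixel_equivalent_um, x$limiting_constraint))
  if (nrow(x$pairs)) print(x$pairs)
  invisible(x)
}
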