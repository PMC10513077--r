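#' Parametric curve specifications for synthetic slit scenes
#'
#' Constructors for the curve primitives understood by
#' [generate_sted_scene()]. Coordinates are in micrometres with the origin
#' at the field corner; each curve has a closed-form (or quadrature-exact)
#' arc length.
#'
#' @param from,to endpoints (um) of a straight segment.
#' @param center circle centre (um).
#' @param radius circle radius (um).
#' @param origin start point (um) of the sinusoid's axis.
#' @param length extent along the axis (um).
#' @param amplitude,period sinusoid amplitude and period (um).
#' @param phase phase offset (radians).
#' @return A `slit_curve` list.
#' @name slit_curves
NULL

#' @rdname slit_curves
#' @export
curve_segment <- function(from, to) {
  structure(list(type = "segment", from = as.numeric(from), to = as.numeric(to)),
            class = "slit_curve")
}

#' @rdname slit_curves
#' @export
curve_circle <- function(center, radius) {
  assert_scalar(radius, "radius", lo = 1e-9)
  structure(list(type = "circle", center = as.numeric(center), radius = radius),
            class = "slit_curve")
}

#' @rdname slit_curves
#' @export
curve_sinusoid <- function(origin, length, amplitude, period, phase = 0) {
  assert_scalar(length, "length", lo = 1e-9)
  assert_scalar(period, "period", lo = 1e-9)
  structure(list(type = "sinusoid", origin = as.numeric(origin), length = length,
                 amplitude = amplitude, period = period, phase = phase),
            class = "slit_curve")
}

# dense polyline sample of a curve; n chosen so chord error is negligible
curve_points <- function(cur, n = 4096L) {
  t <- seq(0, 1, length.out = n)
  switch(cur$type,
    segment = cbind(x = cur$from[1] + t * (cur$to[1] - cur$from[1]),
                    y = cur$from[2] + t * (cur$to[2] - cur$from[2])),
    circle = {
      a <- 2 * pi * t
      cbind(x = cur$center[1] + cur$radius * cos(a),
            y = cur$center[2] + cur$radius * sin(a))
    },
    sinusoid = {
      x <- t * cur$length
      cbind(x = cur$origin[1] + x,
            y = cur$origin[2] + cur$amplitude * sin(2 * pi * x / cur$period + cur$phase))
    },
    stop("unknown curve type: ", cur$type))
}

# closed-form arc length of an unclipped curve (quadrature for sinusoid)
curve_length <- function(cur) {
  switch(cur$type,
    segment = sqrt(sum((cur$to - cur$from)^2)),
    circle = 2 * pi * cur$radius,
    sinusoid = {
      k <- 2 * pi / cur$period
      integrate(function(x) sqrt(1 + (cur$amplitude * k * cos(k * x + cur$phase))^2),
                0, cur$length, rel.tol = 1e-10, subdivisions = 2000L)$value
    })
}

#' Generate a STED-like z-stack containing curves of known arc length
#'
#' Renders the supplied parametric curves as bright ridges of finite width
#' in a noisy 3D stack, emulating a nephrin-stained filtration-slit
#' z-stack. Each curve sits at a random depth and bleeds into neighbouring
#' slices with a Gaussian axial profile, so the maximum-intensity
#' projection contains all curves. Curves exiting the field are clipped
#' and the recorded true length is truncated accordingly.
#'
#' @param curves list of [slit_curves] objects.
#' @param field_um field side lengths (um), height then width.
#' @param ppm pixels per micron of the rendered stack.
#' @param n_slices number of z slices (>= 1).
#' @param ridge_sd_px in-plane Gaussian ridge width (sd, px).
#' @param noise_sd additive Gaussian noise sd on the 0..1 scale.
#' @param seed integer seed.
#' @return A list of class `slit_scene_truth`: `zstack` (H x W x Z array),
#'   `true_total_length_um`, `field_area_um2`, `ppm`.
#' @export
generate_sted_scene <- function(curves, field_um = c(20, 20), ppm = 12,
                                n_slices = 11L, ridge_sd_px = 1.2,
                                noise_sd = 0.03, seed = 1L) {
  stopifnot(length(curves) >= 1, n_slices >= 1)
  if (inherits(curves, "slit_curve")) curves <- list(curves)
  with_rng(seed, {
    H <- max(8L, round(field_um[1] * ppm)); W <- max(8L, round(field_um[2] * ppm))
    fh <- H / ppm; fw <- W / ppm
    stack <- array(0, dim = c(H, W, n_slices))
    total_len <- 0
    for (cur in curves) {
      pts <- curve_points(cur)
      inside <- pts[, "x"] >= 0 & pts[, "x"] <= fw & pts[, "y"] >= 0 & pts[, "y"] <= fh
      seg <- sqrt(rowSums(diff(pts)^2))
      if (all(inside)) {
        total_len <- total_len + curve_length(cur)
      } else {
        # clipped: count only chords with both ends in the field
        keep <- inside[-1] & inside[-length(inside)]
        total_len <- total_len + sum(seg[keep])
      }
      # render: accumulate a Gaussian ridge around the polyline
      z0 <- sample.int(n_slices, 1)
      plane <- matrix(0, H, W)
      pin <- pts[inside, , drop = FALSE]
      if (nrow(pin)) {
        cc <- pmin(W, pmax(1, round(pin[, "x"] * ppm)))
        rr <- pmin(H, pmax(1, round(pin[, "y"] * ppm)))
        plane[cbind(rr, cc)] <- 1
        plane <- EBImage::imageData(EBImage::gblur(plane, sigma = ridge_sd_px))
        plane <- plane / max(plane, 1e-9)
      }
      for (z in seq_len(n_slices)) {
        ax <- exp(-(z - z0)^2 / (2 * 1.5^2))
        stack[, , z] <- pmax(stack[, , z], 0.8 * ax * plane)
      }
    }
    stack <- stack + 0.05
    if (noise_sd > 0) stack <- stack + array(rnorm(length(stack), 0, noise_sd), dim(stack))
    stack <- pmin(pmax(stack, 0), 1)
    structure(list(zstack = stack, true_total_length_um = total_len,
                   field_area_um2 = fh * fw, ppm = ppm),
              class = "slit_scene_truth")
  })
}

#' Random sphere section-profile areas
#'
#' Samples areas of planar sections through a sphere of radius `radius`
#' by random planes, conditioned on intersection: the signed distance `u`
#' of the cutting plane from the centre is uniform on (-R, R) and the
#' profile area is pi (R^2 - u^2). The analytic mean profile area is
#' (2/3) pi R^2, the identity the stereological caliper-diameter
#' inversion relies on.
#'
#' @param radius sphere radius R (> 0).
#' @param n number of sections (>= 1).
#' @param seed integer seed.
#' @return numeric vector of `n` profile areas.
#' @export
sample_sphere_profiles <- function(radius, n, seed = 1L) {
  assert_scalar(radius, "radius", lo = 1e-12)
  assert_scalar(n, "n", lo = 1)
  with_rng(seed, {
    u <- runif(n, -radius, radius)
    pi * (radius^2 - u^2)
  })
}
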