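#' Five-parameter instrument pose
#'
#' Constructs the pose of a small fiducial/instrument relative to the detector
#' and the projection geometry: in-plane detector position `(x, y)` in pixels
#' (sub-pixel floats), forward angle `alpha` (the angle between the projected
#' instrument axis and the image x-axis, degrees), projection angle `tau`
#' (out-of-plane tilt of the instrument axis against the detector plane,
#' degrees) and depth `d` (source-to-object distance along the projection
#' normal, mm).
#'
#' Conventions: pixel coordinates run x to the right and y *down*; `alpha` is
#' measured from the +x axis toward +y (i.e. clockwise on screen, a positive
#' mathematical rotation in the x-right/y-down frame). `alpha` is normalized
#' to `(-180, 180]`; `tau` must lie in `[-90, 90]` — its sign cannot be
#' recovered from a single view, so reconstructed poses carry `|tau|`.
#'
#' @param x,y detector-plane position, px.
#' @param alpha forward angle, degrees.
#' @param tau projection angle, degrees, in `[-90, 90]`.
#' @param d depth (source-object distance), mm; must be positive.
#' @return An object of class `fp_pose`: a named list with fields
#'   `x`, `y`, `alpha`, `tau`, `d`.
#' @examples
#' pose(100, 100, alpha = 0, tau = 0, d = 1000)
#' @export
pose <- function(x, y, alpha = 0, tau = 0, d = 1000) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(alpha),
            is.numeric(tau), is.numeric(d), length(x) == 1L)
  if (!is.finite(d) || d <= 0) stop("pose: depth d must be positive")
  if (!is.finite(tau) || tau < -90 || tau > 90)
    stop("pose: tau must lie in [-90, 90] degrees")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 alpha = wrap_angle(alpha), tau = as.numeric(tau),
                 d = as.numeric(d)),
            class = "fp_pose")
}

#' @export
print.fp_pose <- function(x, ...) {
  cat(sprintf(
    "<pose>  x = %.3f px  y = %.3f px  alpha = %.3f deg  tau = %.3f deg  d = %.2f mm\n",
    x$x, x$y, x$alpha, x$tau, x$d))
  invisible(x)
}

#' @export
as.data.frame.fp_pose <- function(x, ...) {
  data.frame(x = x$x, y = x$y, alpha = x$alpha, tau = x$tau, d = x$d)
}

# wrap an angle in degrees to (-180, 180]
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

deg2rad <- function(a) a * pi / 180
rad2deg <- function(a) a * 180 / pi

#' Projection geometry of the c-arm-like imaging system
#'
#' Describes the pinhole geometry linking metric offsets at the object to
#' detector pixels: source-detector distance `d_sdd` (mm), detector pixel
#' spacing `delta_ds` (mm/px) and image dimensions. The derived constant
#' `c_d2p = delta_ds / d_sdd` converts a metric offset at depth `d` into
#' `offset / (c_d2p * d)` pixels.
#'
#' @param d_sdd source-detector distance, mm.
#' @param delta_ds detector pixel spacing, mm per pixel.
#' @param width,height image dimensions, px.
#' @return An object of class `fp_geometry`.
#' @examples
#' g <- projection_geometry(d_sdd = 1000, delta_ds = 0.5, width = 256, height = 256)
#' c_d2p(g)           # 5e-4
#' @export
projection_geometry <- function(d_sdd = 1000, delta_ds = 0.5,
                                width = 256L, height = 256L) {
  if (!is.finite(d_sdd) || d_sdd <= 0) stop("projection_geometry: d_sdd must be positive")
  if (!is.finite(delta_ds) || delta_ds <= 0) stop("projection_geometry: delta_ds must be positive")
  structure(list(d_sdd = as.numeric(d_sdd), delta_ds = as.numeric(delta_ds),
                 width = as.integer(width), height = as.integer(height)),
            class = "fp_geometry")
}

#' @export
print.fp_geometry <- function(x, ...) {
  cat(sprintf("<projection geometry>  d_sdd = %g mm  delta_ds = %g mm/px  image %d x %d px  (c_d2p = %g)\n",
              x$d_sdd, x$delta_ds, x$width, x$height, c_d2p(x)))
  invisible(x)
}

#' @rdname projection_geometry
#' @param geom an `fp_geometry` object.
#' @export
c_d2p <- function(geom) geom$delta_ds / geom$d_sdd

#' Pseudo-landmark placement on the instrument cross
#'
#' The six pseudo-landmarks sit on a metric cross rigidly attached to the
#' instrument: one leg along the instrument's rotational axis (the x-leg) and
#' one along its cross product with the projection direction (the y-leg),
#' adjacent landmarks 15 mm apart, sharing a central landmark at the pose
#' origin. The default layout places 3+1 landmarks on the x-leg (offsets
#' -15, 0, +15, +30 mm — the asymmetric +30 disambiguates the forward
#' direction) and 2+1 on the y-leg (-15, 0, +15 mm).
#'
#' @param x_offsets metric offsets along the instrument axis, mm; must
#'   include 0.
#' @param y_offsets metric offsets along the orthogonal leg, mm; must
#'   include 0.
#' @return An object of class `fp_placement`: a 6 x 2 matrix of local
#'   `(x_lp, y_lp)` offsets (mm) with attributes `x_leg` and `y_leg` giving
#'   the row indices of each leg (the shared central landmark is in both).
#' @examples
#' landmark_placement()
#' @export
landmark_placement <- function(x_offsets = c(-15, 0, 15, 30),
                               y_offsets = c(-15, 0, 15)) {
  if (!any(x_offsets == 0) || !any(y_offsets == 0))
    stop("landmark_placement: both legs must include the central landmark (offset 0)")
  x_off <- sort(unique(as.numeric(x_offsets)))
  y_off <- sort(unique(as.numeric(y_offsets)))
  # central landmark first, then the remaining x-leg, then the remaining y-leg
  off <- rbind(c(0, 0),
               cbind(x_off[x_off != 0], 0),
               cbind(0, y_off[y_off != 0]))
  rownames(off) <- NULL
  colnames(off) <- c("x_lp", "y_lp")
  structure(off,
            x_leg = which(off[, "y_lp"] == 0),
            y_leg = which(off[, "x_lp"] == 0),
            class = c("fp_placement", "matrix", "array"))
}

#' @export
print.fp_placement <- function(x, ...) {
  cat(sprintf("<landmark placement>  %d landmarks (x-leg %d, y-leg %d, shared center)\n",
              nrow(x), length(attr(x, "x_leg")), length(attr(x, "y_leg"))))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

# 2x2 rotation by alpha degrees in the x-right / y-down pixel frame:
# positive alpha turns +x toward +y.
rot2 <- function(alpha_deg) {
  a <- deg2rad(alpha_deg)
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Project the pseudo-landmark cross into the image (forward map)
#'
#' Maps the pose to the six image-plane landmark coordinates:
#' `p_i = (x, y) + (1 / (c_d2p * d)) * R(alpha) %*% (x_lp * cos(tau), y_lp)`.
#' Foreshortening by `cos(tau)` acts only on the instrument-axis leg; the
#' orthogonal leg lies in the detector-parallel plane by construction.
#'
#' @param pose an [pose()] object.
#' @param geom an [projection_geometry()] object.
#' @param placement an [landmark_placement()] object.
#' @return A 6 x 2 matrix of image coordinates (px), class `fp_landmarks`,
#'   rows index-aligned with `placement`.
#' @examples
#' p <- pose(100, 100, alpha = 0, tau = 0, d = 1000)
#' g <- projection_geometry(1000, 0.5)
#' landmarks_from_pose(p, g, landmark_placement())
#' @export
landmarks_from_pose <- function(pose, geom, placement = landmark_placement()) {
  stopifnot(inherits(pose, "fp_pose"), inherits(geom, "fp_geometry"),
            inherits(placement, "fp_placement"))
  scale <- 1 / (c_d2p(geom) * pose$d)            # px per mm at the object
  local <- cbind(placement[, 1] * cos(deg2rad(pose$tau)), placement[, 2])
  pts <- t(rot2(pose$alpha) %*% t(local)) * scale
  pts <- sweep(pts, 2, c(pose$x, pose$y), "+")
  colnames(pts) <- c("x", "y")
  structure(pts, class = c("fp_landmarks", "matrix", "array"))
}

#' Orthogonal (total-least-squares) line through a set of points
#'
#' Fits the line minimizing orthogonal distances via eigen-decomposition of
#' the 2 x 2 scatter matrix. With exactly two points this reduces to the
#' exact line through both. If `offsets` are supplied, the direction sign is
#' chosen to point from the most-negative-offset landmark toward the
#' most-positive one, which fixes the forward direction of the leg.
#'
#' @param points n x 2 matrix of image coordinates (n >= 2).
#' @param offsets optional numeric vector of the metric leg offsets
#'   (one per point) used to orient the direction.
#' @param degenerate_tol RMS spread (px) below which the leg is declared
#'   degenerate (projection-angle degeneracy); default 0.25 px.
#' @return A list with `centroid` (px pair), `direction` (unit vector),
#'   `rms` (orthogonal residual RMS, px), `spread_rms` (RMS point spread
#'   about the centroid, px) and logical `degenerate`.
#' @examples
#' fit_leg_line(rbind(c(0, 0), c(1, 0), c(2, 0)))
#' @export
fit_leg_line <- function(points, offsets = NULL, degenerate_tol = 0.25) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2)
  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  spread_rms <- sqrt(mean(rowSums(cen^2)))
  if (spread_rms < degenerate_tol) {
    return(list(centroid = ctr, direction = c(NA_real_, NA_real_),
                rms = NA_real_, spread_rms = spread_rms, degenerate = TRUE))
  }
  s <- crossprod(cen)                      # 2x2 scatter
  e <- eigen(s, symmetric = TRUE)
  dir <- e$vectors[, 1]                    # principal direction
  resid_var <- e$values[2] / nrow(points)
  if (!is.null(offsets)) {
    stopifnot(length(offsets) == nrow(points))
    span <- points[which.max(offsets), ] - points[which.min(offsets), ]
    if (sum(span * dir) < 0) dir <- -dir
  }
  list(centroid = ctr, direction = dir,
       rms = sqrt(max(resid_var, 0)), spread_rms = spread_rms,
       degenerate = FALSE)
}

#' Depth from the y-leg landmark spacing
#'
#' Inverts the pinhole magnification on the detector-parallel leg: for any
#' pair of y-leg landmarks (`x_lp = 0`),
#' `d = (1 / c_d2p) * |y_lp_i - y_lp_j| / ||p_i - p_j||`, averaged over all
#' distinct pairs. The y-leg is unaffected by the projection angle, so the
#' image distance between its landmarks measures magnification alone.
#'
#' @inheritParams landmarks_from_pose
#' @param landmarks an `fp_landmarks` matrix (predicted or exact).
#' @return Estimated depth, mm.
#' @export
estimate_depth <- function(landmarks, placement, geom) {
  iy <- attr(placement, "y_leg")
  stopifnot(length(iy) >= 2)
  pairs <- utils::combn(iy, 2)
  ests <- apply(pairs, 2, function(ij) {
    dlp <- abs(placement[ij[1], 2] - placement[ij[2], 2])
    if (dlp == 0) return(NA_real_)
    dpx <- sqrt(sum((landmarks[ij[1], ] - landmarks[ij[2], ])^2))
    if (dpx == 0) stop("estimate_depth: coincident y-leg image points")
    dlp / dpx
  })
  mean(ests, na.rm = TRUE) / c_d2p(geom)
}

#' Projection angle magnitude from x-leg foreshortening
#'
#' Inverts the foreshortening of the instrument-axis leg: for any pair of
#' x-leg landmarks (`y_lp = 0`),
#' `cos(tau) = c_d2p * d * ||p_i - p_j|| / |x_lp_i - x_lp_j|`, averaged over
#' all distinct pairs and clamped to `[0, 1]`. Only `|tau|` is recoverable
#' (`cos` is even); the result is reported in degrees, non-negative.
#'
#' @inheritParams estimate_depth
#' @param d depth estimate, mm (from [estimate_depth()]).
#' @return A numeric scalar `tau >= 0` in degrees, with attribute `clamped`
#'   (logical) indicating the cosine exceeded 1 and was clamped — a sign of
#'   noisy landmarks.
#' @export
estimate_projection_angle <- function(landmarks, placement, geom, d) {
  stopifnot(d > 0)
  ix <- attr(placement, "x_leg")
  stopifnot(length(ix) >= 2)
  pairs <- utils::combn(ix, 2)
  cosines <- apply(pairs, 2, function(ij) {
    dlp <- abs(placement[ij[1], 1] - placement[ij[2], 1])
    if (dlp == 0) return(NA_real_)
    dpx <- sqrt(sum((landmarks[ij[1], ] - landmarks[ij[2], ])^2))
    c_d2p(geom) * d * dpx / dlp
  })
  ct <- mean(cosines, na.rm = TRUE)
  clamped <- ct > 1
  ct <- min(max(ct, 0), 1)
  structure(rad2deg(acos(ct)), clamped = clamped)
}

#' Reconstruct the full pose from image landmarks (inverse map)
#'
#' Geometric inversion of the landmark projection: total-least-squares lines
#' are fitted through the two legs of the cross; their intersection yields
#' the in-plane position, the x-leg slope the forward angle, the y-leg
#' spacing the depth and the x-leg foreshortening the projection angle
#' magnitude.
#'
#' @inheritParams estimate_depth
#' @param min_leg_angle minimum angle (degrees) between the two fitted leg
#'   lines; below this the intersection is numerically meaningless and the
#'   reconstruction fails.
#' @param degenerate_tol passed to [fit_leg_line()].
#' @return A list of class `fp_pose_fit` with elements `pose` (an
#'   [pose()] with `tau >= 0`) and `diagnostics` (leg RMS residuals, leg
#'   angle, clamp flag, per-leg degeneracy flags). On failure (degenerate or
#'   near-parallel legs) an error of class `fp_reconstruction_error` is
#'   signalled.
#' @examples
#' g <- projection_geometry(1000, 0.5)
#' lp <- landmark_placement()
#' lm <- landmarks_from_pose(pose(100, 100, 25, 40, 980), g, lp)
#' pose_from_landmarks(lm, lp, g)$pose
#' @export
pose_from_landmarks <- function(landmarks, placement = landmark_placement(),
                                geom, min_leg_angle = 1,
                                degenerate_tol = 0.25) {
  ix <- attr(placement, "x_leg"); iy <- attr(placement, "y_leg")
  fx <- fit_leg_line(landmarks[ix, , drop = FALSE], placement[ix, 1],
                     degenerate_tol = degenerate_tol)
  fy <- fit_leg_line(landmarks[iy, , drop = FALSE], placement[iy, 2],
                     degenerate_tol = degenerate_tol)
  fail <- function(msg) {
    stop(structure(class = c("fp_reconstruction_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  if (fx$degenerate) fail("pose reconstruction failed: x-leg degenerate (projection angle near 90 deg)")
  if (fy$degenerate) fail("pose reconstruction failed: y-leg degenerate")
  # angle between the leg lines (undirected)
  cross <- abs(fx$direction[1] * fy$direction[2] - fx$direction[2] * fy$direction[1])
  leg_angle <- rad2deg(asin(min(cross, 1)))
  if (leg_angle < min_leg_angle)
    fail(sprintf("pose reconstruction failed: leg lines near-parallel (%.3f deg apart)", leg_angle))
  # intersection of c1 + t u1 and c2 + s u2
  a <- cbind(fx$direction, -fy$direction)
  ts <- solve(a, fy$centroid - fx$centroid)
  xy <- fx$centroid + ts[1] * fx$direction
  alpha <- rad2deg(atan2(fx$direction[2], fx$direction[1]))
  d <- estimate_depth(landmarks, placement, geom)
  tau <- estimate_projection_angle(landmarks, placement, geom, d)
  structure(list(
    pose = pose(xy[1], xy[2], alpha = alpha, tau = as.numeric(tau), d = d),
    diagnostics = list(x_leg_rms = fx$rms, y_leg_rms = fy$rms,
                       x_leg_spread = fx$spread_rms, y_leg_spread = fy$spread_rms,
                       leg_angle = leg_angle,
                       cos_tau_clamped = isTRUE(attr(tau, "clamped")))),
    class = "fp_pose_fit")
}

#' @export
print.fp_pose_fit <- function(x, ...) {
  print(x$pose)
  d <- x$diagnostics
  cat(sprintf("  leg residuals (px): x %.4f, y %.4f | leg angle %.2f deg%s\n",
              d$x_leg_rms, d$y_leg_rms, d$leg_angle,
              if (d$cos_tau_clamped) " | cos(tau) clamped" else ""))
  invisible(x)
}
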