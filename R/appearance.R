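#' Standard-pose patch specification
#'
#' The appearance-normalized patch is a `width x height` (92 x 48 by default)
#' crop in which the instrument always appears in *standard pose*: its
#' reference point at the `anchor` and its forward axis along the patch
#' +x direction. Patch pixels have a fixed metric pitch (mm per patch pixel)
#' at the object plane, so the instrument's apparent size is independent of
#' depth once the depth estimate is accurate.
#'
#' The default anchor (32, 24) is off-center in x so that the asymmetric
#' +30 mm landmark of the default cross stays inside the 92-px width; with
#' the default 0.7 mm/px pitch all six standard-pose landmarks fall inside
#' the patch (x-leg at u of about \{10.6, 32, 53.4, 74.9\}, y-leg at v of
#' about \{2.6, 24, 45.4\}). The pitch must exceed 30/48 = 0.625 mm/px for
#' the y-leg to fit; 0.7 keeps a ~2.6 px margin while maximizing metric
#' resolution.
#'
#' @param width,height patch dimensions, px.
#' @param anchor length-2 vector: patch coordinates of the instrument
#'   reference point under the standard pose (0-based, px).
#' @param pitch metric size of one patch pixel at the object plane, mm.
#' @return An object of class `fp_patch_spec`.
#' @export
patch_spec <- function(width = 92L, height = 48L, anchor = c(32, 24),
                       pitch = 0.7) {
  stopifnot(length(anchor) == 2, pitch > 0)
  if (anchor[1] <= 0 || anchor[1] >= width || anchor[2] <= 0 || anchor[2] >= height)
    stop("patch_spec: anchor must lie strictly inside the patch")
  structure(list(width = as.integer(width), height = as.integer(height),
                 anchor = as.numeric(anchor), pitch = as.numeric(pitch)),
            class = "fp_patch_spec")
}

#' @export
print.fp_patch_spec <- function(x, ...) {
  cat(sprintf("<patch spec>  %d x %d px, anchor (%g, %g), pitch %g mm/px\n",
              x$width, x$height, x$anchor[1], x$anchor[2], x$pitch))
  invisible(x)
}

#' Accuracy assumptions on the initial pose
#'
#' Bounds on the prior pose knowledge the estimator may assume: the initial
#' in-plane position is within `dx_initial` mm (radially) and the initial
#' forward angle within `dalpha_initial` degrees of the truth.
#'
#' @param dx_initial radial position bound, mm (default 2.5).
#' @param dalpha_initial forward-angle bound, degrees (default 30).
#' @return An object of class `fp_perturbation_config`.
#' @export
perturbation_config <- function(dx_initial = 2.5, dalpha_initial = 30) {
  stopifnot(dx_initial > 0, dalpha_initial > 0)
  structure(list(dx_initial = as.numeric(dx_initial),
                 dalpha_initial = as.numeric(dalpha_initial)),
            class = "fp_perturbation_config")
}

#' Draw a random in-plane perturbation of the prior pose
#'
#' Training-time variations of the prior knowledge are drawn in polar
#' coordinates, `R ~ U(0, dx_initial)` and `beta ~ U(0, 360)` degrees, with
#' the forward-angle offset `dalpha ~ N(0, (dalpha_initial / 3)^2)`. Drawing
#' the radius uniformly (not the area) and the angle offset from a normal
#' skews the samples toward configurations close to the standard pose, which
#' favors accuracy for good priors. `dalpha` is unbounded at training time;
#' use `clamp_alpha = TRUE` for test-time initial guesses that must honor
#' the stated accuracy assumption.
#'
#' Uses R's global RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param config an [perturbation_config()].
#' @param clamp_alpha clamp `dalpha` to `[-dalpha_initial, dalpha_initial]`.
#' @return A list of class `fp_perturbation` with fields `R` (mm), `beta`
#'   (degrees) and `dalpha` (degrees).
#' @export
sample_prior_perturbation <- function(config = perturbation_config(),
                                      clamp_alpha = FALSE) {
  r <- stats::runif(1, 0, config$dx_initial)
  beta <- stats::runif(1, 0, 360)
  dalpha <- stats::rnorm(1, 0, config$dalpha_initial / 3)
  if (clamp_alpha)
    dalpha <- min(max(dalpha, -config$dalpha_initial), config$dalpha_initial)
  structure(list(R = r, beta = beta, dalpha = dalpha),
            class = "fp_perturbation")
}

#' Apply an in-plane perturbation to a pose
#'
#' Displaces the pose by `R` mm in direction `beta` (converted to pixels at
#' the pose's depth) and rotates the forward angle by `dalpha`. Out-of-plane
#' components are untouched.
#'
#' @param pose an [pose()].
#' @param pert an `fp_perturbation`.
#' @param geom an [projection_geometry()].
#' @return The perturbed [pose()].
#' @export
perturb_pose <- function(pose, pert, geom) {
  px_per_mm <- 1 / (c_d2p(geom) * pose$d)
  b <- deg2rad(pert$beta)
  pose(pose$x + pert$R * cos(b) * px_per_mm,
       pose$y + pert$R * sin(b) * px_per_mm,
       alpha = wrap_angle(pose$alpha + pert$dalpha),
       tau = pose$tau, d = pose$d)
}

# similarity transform patch -> image for a given prior pose:
# p_img = A %*% (uv) + t with A = k * R(alpha), k = pitch / (c_d2p * d_hat)
patch_transform <- function(prior, geom, spec) {
  k <- spec$pitch / (c_d2p(geom) * prior$d)
  a <- rot2(prior$alpha) * k
  t <- c(prior$x, prior$y) - a %*% spec$anchor
  list(A = a, t = as.numeric(t))
}

#' Extract the appearance-normalized standard-pose patch
#'
#' Resamples the image so that the prior pose lands on the patch anchor with
#' its forward axis along patch +x, using bilinear interpolation with
#' edge-value padding, then z-scores the intensities (a constant crop maps
#' to all zeros). The metric scale inside the patch uses the prior's depth
#' estimate, so the patch is depth-normalized to the extent the estimate is
#' accurate.
#'
#' @param image numeric matrix (`height x width`), image coordinate `(x, y)`
#'   stored at `image[y + 1, x + 1]` (0-based pixel centers).
#' @param prior the prior [pose()] guess (its `d` field is the current depth
#'   estimate).
#' @inheritParams perturb_pose
#' @param spec an [patch_spec()].
#' @return An object of class `fp_patch`: list with `pixels`
#'   (`height x width` matrix, zero mean / unit variance), `A`, `t` (the
#'   patch-to-image similarity) and `spec`.
#' @export
extract_patch <- function(image, prior, geom, spec = patch_spec()) {
  stopifnot(is.matrix(image))
  h_img <- nrow(image); w_img <- ncol(image)
  if (prior$x < 0 || prior$x > w_img - 1 || prior$y < 0 || prior$y > h_img - 1)
    stop("extract_patch: prior position outside the image")
  tr <- patch_transform(prior, geom, spec)
  uv <- cbind(rep(0:(spec$width - 1L), each = spec$height),
              rep(0:(spec$height - 1L), times = spec$width))
  p_img <- uv %*% t(tr$A)
  xs <- p_img[, 1] + tr$t[1]
  ys <- p_img[, 2] + tr$t[2]
  vals <- bilinear_sample(image, xs, ys)
  px <- matrix(vals, nrow = spec$height, ncol = spec$width)
  mu <- mean(px)
  sdv <- sqrt(mean((px - mu)^2))
  px <- if (sdv > 0) (px - mu) / sdv else px * 0
  structure(list(pixels = px, A = tr$A, t = tr$t, spec = spec),
            class = "fp_patch")
}

#' @export
print.fp_patch <- function(x, ...) {
  cat(sprintf("<patch>  %d x %d px, mean %.2e, sd %.3f\n",
              x$spec$width, x$spec$height, mean(x$pixels),
              sqrt(mean((x$pixels - mean(x$pixels))^2))))
  invisible(x)
}

# bilinear interpolation with edge clamping (replicate padding)
bilinear_sample <- function(image, xs, ys) {
  h <- nrow(image); w <- ncol(image)
  xs <- pmin(pmax(xs, 0), w - 1)
  ys <- pmin(pmax(ys, 0), h - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- xs - x0; fy <- ys - y0
  v00 <- image[cbind(y0 + 1, x0 + 1)]
  v01 <- image[cbind(y0 + 1, x1 + 1)]
  v10 <- image[cbind(y1 + 1, x0 + 1)]
  v11 <- image[cbind(y1 + 1, x1 + 1)]
  (v00 * (1 - fx) + v01 * fx) * (1 - fy) + (v10 * (1 - fx) + v11 * fx) * fy
}

#' Map between patch and image coordinates
#'
#' `patch_to_image` applies the patch's similarity transform; its exact
#' inverse is `image_to_patch`.
#'
#' @param patch an `fp_patch`.
#' @param pts n x 2 matrix of coordinates (px).
#' @return n x 2 matrix of transformed coordinates.
#' @export
patch_to_image <- function(patch, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  sweep(pts %*% t(patch$A), 2, patch$t, "+")
}

#' @rdname patch_to_image
#' @export
image_to_patch <- function(patch, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  sweep(pts, 2, patch$t) %*% t(solve(patch$A))
}

#' Encode image landmarks as normalized regression targets
#'
#' Maps each landmark into patch coordinates through the inverse patch
#' transform, then normalizes by the patch dimensions: `u = x_patch / width`,
#' `v = y_patch / height`. Standard-pose training targets concentrate in
#' `[0, 1]`; values are deliberately *not* clipped (poor priors can push
#' landmarks outside the patch and clipping would corrupt the regression
#' target).
#'
#' @param landmarks an `fp_landmarks` 6 x 2 matrix (image px).
#' @param patch the `fp_patch` the targets refer to.
#' @return Numeric vector of length 12: `(u_1, v_1, ..., u_6, v_6)`.
#' @export
encode_targets <- function(landmarks, patch) {
  uv <- image_to_patch(patch, unclass(landmarks))
  as.numeric(t(sweep(uv, 2, c(patch$spec$width, patch$spec$height), "/")))
}

#' Decode a target vector back to image landmarks
#'
#' Exact inverse of [encode_targets()].
#'
#' @param vec numeric vector of length 12 (normalized patch coordinates).
#' @param patch the `fp_patch` the vector refers to.
#' @return An `fp_landmarks` 6 x 2 matrix (image px).
#' @export
decode_targets <- function(vec, patch) {
  stopifnot(length(vec) %% 2 == 0)
  uv <- matrix(vec, ncol = 2, byrow = TRUE)
  uv <- sweep(uv, 2, c(patch$spec$width, patch$spec$height), "*")
  pts <- patch_to_image(patch, uv)
  colnames(pts) <- c("x", "y")
  structure(pts, class = c("fp_landmarks", "matrix", "array"))
}
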