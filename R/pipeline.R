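# Estimation pipeline: the iterative estimate -> reconstruct -> re-crop loop,
# the five evaluation metrics with the projection-angle filter, and the
# seeded end-to-end experiment runner.

#' Iteratively estimate a pose from a single image
#'
#' Starting from an initial in-plane pose guess (assumed accurate to within
#' 2.5 mm and 30 degrees), each iteration (i) extracts the standard-pose
#' patch at the current prior, (ii) predicts the pseudo-landmark targets,
#' (iii) decodes them to image coordinates and (iv) reconstructs the pose
#' geometrically; the reconstructed in-plane components (and, by default,
#' the depth) become the next prior. Out-of-plane components are reported
#' from the final iteration.
#'
#' @param image numeric image matrix.
#' @param initial initial [pose()] guess (its `d` is the nominal
#'   source-object distance if unknown).
#' @param model a trained [`landmark_cnn`][build_regressor()] or an
#'   [oracle_regressor()].
#' @param geom an [projection_geometry()].
#' @param placement an [landmark_placement()].
#' @param spec an [patch_spec()].
#' @param n_iter refinement iterations (3 in the reference protocol;
#'   0 returns the initial pose unchanged).
#' @param update_depth feed the reconstructed depth into the next
#'   iteration's patch scale (`TRUE`, default) or keep the initial nominal
#'   depth (`FALSE`).
#' @param n_crops predict from this many deterministically offset crops per
#'   iteration (1 = the plain pipeline). With `n_crops > 1`, the prior is
#'   additionally displaced by fractions of a patch pixel and a fraction of
#'   a degree, each crop's prediction is decoded through its own transform,
#'   and the image-space landmarks are averaged before reconstruction —
#'   the same variance-reduction-by-averaging principle the geometric
#'   inversion applies over landmark pairs, applied to the regressor.
#' @param flip_average additionally average each crop's prediction with the
#'   prediction on the vertically mirrored patch (mapped back through the
#'   mirror, with the paired orthogonal-leg landmarks swapped). For a
#'   rotationally symmetric fiducial the mirrored patch shows the same
#'   scene, so this cancels the mirror-odd part of the regressor's bias.
#' @return An object of class `fp_trace`: list with `poses` (length
#'   `n_iter + 1`, the initial pose plus one refinement per iteration),
#'   `residuals` (landmark-to-line RMS per iteration), `failed` (logical)
#'   and `failure_message`. The final estimate is `poses[[length(poses)]]`.
#' @export
estimate_pose_iterative <- function(image, initial, model, geom,
                                    placement = landmark_placement(),
                                    spec = patch_spec(), n_iter = 3L,
                                    update_depth = TRUE, n_crops = 1L,
                                    flip_average = FALSE) {
  stopifnot(inherits(initial, "fp_pose"))
  poses <- list(initial)
  residuals <- numeric(0)
  failed <- FALSE
  msg <- NULL
  prior <- initial
  # deterministic crop offsets: (du, dv) patch px and dalpha deg
  offsets <- crop_offsets(n_crops)
  for (it in seq_len(n_iter)) {
    fit <- tryCatch({
      lm_acc <- matrix(0, nrow(placement), 2)
      for (ci in seq_len(nrow(offsets))) {
        off <- offsets[ci, ]
        mmshift <- off[1:2] * spec$pitch
        px_per_mm <- 1 / (c_d2p(geom) * prior$d)
        a <- deg2rad(prior$alpha)
        shift_img <- px_per_mm *
          c(mmshift[1] * cos(a) - mmshift[2] * sin(a),
            mmshift[1] * sin(a) + mmshift[2] * cos(a))
        pr_c <- pose(prior$x + shift_img[1], prior$y + shift_img[2],
                     wrap_angle(prior$alpha + off[3]), prior$tau, prior$d)
        patch <- extract_patch(image, pr_c, geom, spec)
        lm_acc <- lm_acc + predict_landmarks(model, patch, placement,
                                             flip_average = flip_average)
      }
      lm <- structure(lm_acc / nrow(offsets),
                      class = c("fp_landmarks", "matrix", "array"))
      pose_from_landmarks(lm, placement, geom)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- TRUE
      msg <- conditionMessage(fit)
      break
    }
    est <- fit$pose
    # tau sign is unrecoverable; carry |tau| forward
    prior <- pose(est$x, est$y, alpha = est$alpha, tau = est$tau,
                  d = if (update_depth) est$d else prior$d)
    poses[[it + 1L]] <- prior
    residuals[it] <- mean(c(fit$diagnostics$x_leg_rms, fit$diagnostics$y_leg_rms))
  }
  structure(list(poses = poses, residuals = residuals, failed = failed,
                 failure_message = msg, n_iter = n_iter),
            class = "fp_trace")
}

#' @export
print.fp_trace <- function(x, ...) {
  cat(sprintf("<iteration trace>  %d of %d iterations%s\n",
              length(x$poses) - 1L, x$n_iter,
              if (x$failed) paste0(" [FAILED: ", x$failure_message, "]") else ""))
  for (i in seq_along(x$poses)) {
    p <- x$poses[[i]]
    cat(sprintf("  %s x=%8.3f y=%8.3f alpha=%8.3f tau=%7.3f d=%8.2f\n",
                if (i == 1) "init" else sprintf("it %d", i - 1L),
                p$x, p$y, p$alpha, p$tau, p$d))
  }
  invisible(x)
}

#' @rdname estimate_pose_iterative
#' @param trace an `fp_trace`.
#' @export
final_pose <- function(trace) trace$poses[[length(trace$poses)]]

# predicted landmarks in image coordinates, optionally averaged with the
# mirror-consistent prediction on the vertically flipped patch
predict_landmarks <- function(model, patch, placement, flip_average = FALSE) {
  lm <- unclass(decode_targets(predict_targets(model, patch), patch))
  if (!flip_average || !inherits(model, "landmark_cnn")) return(lm)
  h <- patch$spec$height
  p2 <- patch
  p2$pixels <- patch$pixels[h:1, , drop = FALSE]
  uv <- matrix(predict_targets(model, p2), ncol = 2, byrow = TRUE)
  uv[, 2] <- ((h - 1) - uv[, 2] * h) / h          # undo the mirror
  iy <- attr(placement, "y_leg")
  swap <- match(-placement[iy, 2], placement[iy, 2])
  uv[iy, ] <- uv[iy[swap], , drop = FALSE]        # mirrored leg identities
  lm2 <- unclass(decode_targets(as.numeric(t(uv)), patch))
  (lm + lm2) / 2
}

# fixed sub-pixel / sub-degree crop displacements for prediction averaging
crop_offsets <- function(n_crops) {
  all_off <- rbind(c(0, 0, 0),
                   c(0.5, 0.25, 1.5),
                   c(-0.5, -0.25, -1.5),
                   c(-0.25, 0.5, -3),
                   c(0.25, -0.5, 3),
                   c(0.5, -0.25, -1.5),
                   c(-0.5, 0.25, 1.5),
                   c(0.25, 0.5, 3),
                   c(-0.25, -0.5, -3))
  all_off[seq_len(max(1L, min(n_crops, nrow(all_off)))), , drop = FALSE]
}

#' Evaluate predicted poses against ground truth
#'
#' Computes the five error measures: position error in px and in mm (the
#' Euclidean distance in the plane through the fiducial orthogonal to the
#' projection normal: `mm = px * c_d2p * d_true`), the signed forward-angle
#' error (degrees, in-plane), the absolute projection-angle error (degrees;
#' only `|tau|` is comparable from a single view), and the depth error (mm).
#' Cases whose ground-truth `|tau|` exceeds `tau_filter` are excluded from
#' the aggregates and flagged, since the forward angle degenerates as the
#' instrument axis aligns with the projection direction. Aggregates are
#' reported as mean +- sd plus median and 95th percentile.
#'
#' @param predicted list of predicted [pose()]s (entries may be `NULL` for
#'   failed reconstructions; these are counted and excluded).
#' @param truth list of ground-truth [pose()]s, index-aligned.
#' @param geom an [projection_geometry()].
#' @param tau_filter projection-angle filter threshold, degrees.
#' @return An object of class `fp_errors`: list with `cases` (per-case
#'   data frame incl. filter flags) and `aggregates` (one row per metric).
#' @export
evaluate_predictions <- function(predicted, truth, geom, tau_filter = 80) {
  stopifnot(length(predicted) == length(truth))
  n <- length(truth)
  cases <- data.frame(
    case = seq_len(n), pos_px = NA_real_, pos_mm = NA_real_,
    alpha_err = NA_real_, tau_err = NA_real_, depth_err = NA_real_,
    gt_tau = vapply(truth, function(p) p$tau, numeric(1)),
    failed = vapply(predicted, is.null, logical(1)))
  cases$filtered <- abs(cases$gt_tau) > tau_filter
  for (i in seq_len(n)) {
    if (cases$failed[i]) next
    p <- predicted[[i]]; g <- truth[[i]]
    dpx <- sqrt((p$x - g$x)^2 + (p$y - g$y)^2)
    cases$pos_px[i] <- dpx
    cases$pos_mm[i] <- dpx * c_d2p(geom) * g$d
    cases$alpha_err[i] <- ang_diff_deg(p$alpha, g$alpha)
    cases$tau_err[i] <- abs(abs(p$tau) - abs(g$tau))
    cases$depth_err[i] <- p$d - g$d
  }
  keep <- !cases$filtered & !cases$failed
  agg <- function(v, absolute = FALSE) {
    x <- v[keep]
    if (absolute) x <- abs(x)
    c(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
      q95 = unname(stats::quantile(x, 0.95, na.rm = TRUE)), max = max(x))
  }
  aggregates <- rbind(
    position_error_mm = agg(abs(cases$pos_mm)),
    position_error_px = agg(abs(cases$pos_px)),
    forward_angle_error_deg = agg(cases$alpha_err),
    projection_angle_error_deg = agg(cases$tau_err),
    depth_error_mm = agg(cases$depth_err))
  structure(list(cases = cases, aggregates = as.data.frame(aggregates),
                 n_filtered = sum(cases$filtered), n_failed = sum(cases$failed),
                 n_evaluated = sum(keep), tau_filter = tau_filter),
            class = "fp_errors")
}

#' @export
print.fp_errors <- function(x, ...) {
  cat(sprintf("<error report>  %d cases evaluated (%d filtered at |tau| > %g deg, %d failed)\n",
              x$n_evaluated, x$n_filtered, x$tau_filter, x$n_failed))
  print(round(x$aggregates, 4))
  invisible(x)
}

#' @export
summary.fp_errors <- function(object, ...) {
  a <- object$aggregates
  cat(sprintf(
    "Position error: %.4f +- %.4f mm (%.3f +- %.3f px); forward angle %.3f +- %.3f deg\n",
    a["position_error_mm", "mean"], a["position_error_mm", "sd"],
    a["position_error_px", "mean"], a["position_error_px", "sd"],
    a["forward_angle_error_deg", "mean"], a["forward_angle_error_deg", "sd"]))
  invisible(object)
}

#' Run a full seeded estimation experiment on a test dataset
#'
#' For every test image, draws `k` random initial poses around the ground
#' truth (within the stated prior-accuracy bounds: radius up to
#' `dx_initial` mm, angle clamped to `dalpha_initial`; the initial depth is
#' the nominal source-object distance, the initial projection angle 0 since
#' no out-of-plane prior is assumed), runs the iterative estimator, and
#' aggregates all predictions. With `model = "oracle"`, ground-truth
#' landmark injection replaces the CNN.
#'
#' @param ds a test `fp_dataset` with images in memory.
#' @param model a trained `landmark_cnn`, or the string `"oracle"`.
#' @param k initial poses per image.
#' @param n_iter refinement iterations.
#' @param pcfg an [perturbation_config()] for the initial-pose draws.
#' @param placement,spec pipeline components.
#' @param nominal_d initial depth estimate, mm (defaults to the midpoint of
#'   the generation depth range).
#' @param seed RNG seed for the initial-pose draws.
#' @param tau_filter evaluation filter, degrees.
#' @param update_depth see [estimate_pose_iterative()].
#' @return A list of class `fp_experiment`: `errors` (an `fp_errors`),
#'   `traces`, `truth`, and the resolved configuration.
#' @export
run_experiment <- function(ds, model, k = 10L, n_iter = 3L,
                           pcfg = perturbation_config(),
                           placement = landmark_placement(),
                           spec = patch_spec(), nominal_d = NULL,
                           seed = 1L, tau_filter = 80, update_depth = TRUE,
                           n_crops = 1L, flip_average = FALSE) {
  stopifnot(!is.null(ds$images))
  geom <- do.call(projection_geometry,
                  ds$config$geom[c("d_sdd", "delta_ds", "width", "height")])
  if (is.null(nominal_d)) nominal_d <- mean(ds$config$ranges$d_range)
  n_img <- length(ds$records)
  truth <- vector("list", n_img * k)
  traces <- vector("list", n_img * k)
  set.seed(seed)
  idx <- 0L
  for (i in seq_len(n_img)) {
    gt <- ds$records[[i]]$pose
    img <- ds$images[[i]]
    mdl <- if (identical(model, "oracle")) {
      oracle_regressor(landmarks_from_pose(gt, geom, placement))
    } else model
    for (j in seq_len(k)) {
      idx <- idx + 1L
      pert <- sample_prior_perturbation(pcfg, clamp_alpha = TRUE)
      init <- perturb_pose(pose(gt$x, gt$y, alpha = gt$alpha, tau = 0,
                                d = nominal_d),
                           pert, geom)
      traces[[idx]] <- estimate_pose_iterative(img, init, mdl, geom,
                                               placement, spec,
                                               n_iter = n_iter,
                                               update_depth = update_depth,
                                               n_crops = n_crops,
                                               flip_average = flip_average)
      truth[[idx]] <- gt
    }
  }
  predicted <- lapply(traces, function(tr)
    if (tr$failed) NULL else final_pose(tr))
  errors <- evaluate_predictions(predicted, truth, geom, tau_filter = tau_filter)
  structure(list(errors = errors, traces = traces, truth = truth,
                 config = list(k = k, n_iter = n_iter, seed = seed,
                               nominal_d = nominal_d, tau_filter = tau_filter,
                               update_depth = update_depth,
                               model = if (identical(model, "oracle")) "oracle"
                                       else "landmark_cnn")),
            class = "fp_experiment")
}

#' @export
print.fp_experiment <- function(x, ...) {
  cat(sprintf("<experiment>  model %s, k = %d initial poses, %d iterations, seed %d\n",
              x$config$model, x$config$k, x$config$n_iter, x$config$seed))
  print(x$errors)
  invisible(x)
}

#' Write experiment outputs to disk
#'
#' Per-case metrics as CSV, aggregates plus the resolved configuration and
#' seed as JSON — every run is reproducible from its output directory.
#'
#' @param exp an `fp_experiment`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(exp$errors$cases, file.path(dir, "cases.csv"),
                   row.names = FALSE)
  agg <- cbind(metric = rownames(exp$errors$aggregates), exp$errors$aggregates)
  jsonlite::write_json(
    list(aggregates = agg, config = exp$config,
         n_evaluated = exp$errors$n_evaluated,
         n_filtered = exp$errors$n_filtered, n_failed = exp$errors$n_failed),
    file.path(dir, "aggregates.json"),
    auto_unbox = TRUE, digits = I(17), dataframe = "rows", pretty = TRUE)
  invisible(dir)
}

#' Estimate a pose with the direct-regression (end-to-end) variant
#'
#' The comparison model: the same backbone regresses the 5 pose components
#' directly (normalized patch position, forward-angle offset in raw
#' degrees, projection angle, depth offset) instead of pseudo-landmarks;
#' the pose is read off the outputs without geometric reconstruction.
#'
#' @inheritParams estimate_pose_iterative
#' @param model a `landmark_cnn` trained with `target = "pose"` (5 outputs).
#' @return An `fp_trace`.
#' @export
estimate_pose_direct <- function(image, initial, model, geom,
                                 placement = landmark_placement(),
                                 spec = patch_spec(), n_iter = 3L) {
  stopifnot(model$arch$out_dim == 5L)
  poses <- list(initial)
  prior <- initial
  for (it in seq_len(n_iter)) {
    patch <- extract_patch(image, prior, geom, spec)
    out <- predict(model, patch)
    uv <- c(out[1] * spec$width, out[2] * spec$height)
    xy <- patch_to_image(patch, uv)
    prior <- pose(xy[1], xy[2],
                  alpha = wrap_angle(prior$alpha + out[3]),
                  tau = min(max(out[4], -90), 90),
                  d = max(prior$d + out[5] * 10, 1))
    poses[[it + 1L]] <- prior
  }
  structure(list(poses = poses, residuals = rep(NA_real_, n_iter),
                 failed = FALSE, failure_message = NULL, n_iter = n_iter),
            class = "fp_trace")
}
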