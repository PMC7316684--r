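# appearance normalization: prior perturbations, standard-pose patches,
# target encoding

test_that("prior perturbations follow the stated polar/normal law", {
  cfg <- perturbation_config(2.5, 30)
  set.seed(123)
  draws <- replicate(1e5, unlist(sample_prior_perturbation(cfg)))
  expect_true(all(draws["R", ] >= 0 & draws["R", ] <= 2.5))
  expect_true(all(draws["beta", ] >= 0 & draws["beta", ] < 360))
  # Monte-Carlo check of sd(dalpha) = 30/3 = 10 deg
  expect_equal(stats::sd(draws["dalpha", ]), 10, tolerance = 0.012)
  expect_equal(mean(draws["dalpha", ]), 0, tolerance = 0.15)

  # skew toward the standard pose: |dalpha| density is maximal at 0 and
  # decays monotonically across equal-width bins
  h <- hist(abs(draws["dalpha", ]), breaks = seq(0, 60, by = 5), plot = FALSE)
  counts <- h$counts[1:6]
  expect_true(all(diff(counts) < 0))

  # degenerate config is (almost) the identity
  tiny <- perturbation_config(1e-9, 1e-9)
  set.seed(1)
  p <- sample_prior_perturbation(tiny)
  expect_lt(p$R, 1e-9)
  expect_lt(abs(p$dalpha), 1e-8)

  # test-time clamping honors the stated accuracy bound
  set.seed(99)
  d2 <- replicate(2000, sample_prior_perturbation(cfg, clamp_alpha = TRUE)$dalpha)
  expect_true(all(abs(d2) <= 30))
})

test_that("perturb_pose displaces metrically and rotates in-plane only", {
  g <- fx_geom()
  p0 <- pose(128, 128, 10, 40, 1000)
  pert <- structure(list(R = 2, beta = 0, dalpha = 15), class = "fp_perturbation")
  p1 <- perturb_pose(p0, pert, g)
  expect_equal(p1$x, 128 + 2 * 2, tolerance = 1e-12)  # 2 mm at 2 px/mm
  expect_equal(p1$y, 128)
  expect_equal(p1$alpha, 25)
  expect_equal(p1$tau, 40)
  expect_equal(p1$d, 1000)
})

test_that("patch extraction is 92 x 48, normalized, and anchors the prior", {
  g <- fx_geom()
  spec <- patch_spec()
  # analytic image: bright Gaussian blob at the pose position
  p0 <- pose(140.3, 117.8, alpha = 35, tau = 0, d = 1000)
  xg <- outer(rep(1, 256), 0:255)
  yg <- outer(0:255, rep(1, 256))
  img <- exp(-((xg - p0$x)^2 + (yg - p0$y)^2) / (2 * 4^2))
  patch <- extract_patch(img, p0, g, spec)

  expect_identical(dim(patch$pixels), c(48L, 92L))
  expect_lt(abs(mean(patch$pixels)), 1e-9)
  expect_lt(abs(sqrt(mean((patch$pixels - mean(patch$pixels))^2)) - 1), 1e-9)

  # blob (intensity-weighted centroid of the positive part) sits at the anchor
  w <- pmax(patch$pixels, 0)
  u <- outer(rep(1, 48), 0:91); v <- outer(0:47, rep(1, 92))
  cen <- c(sum(w * u), sum(w * v)) / sum(w)
  expect_lt(sqrt(sum((cen - spec$anchor)^2)), 1)

  # constant image -> all-zero patch, no error
  pc <- extract_patch(matrix(0.7, 64, 64), pose(32, 32, 0, 0, 1000), g, spec)
  expect_true(all(pc$pixels == 0))

  # prior outside the image is refused
  expect_error(extract_patch(img, pose(500, 500, 0, 0, 1000), g, spec),
               "outside")
})

test_that("the forward axis maps to the patch +x axis", {
  g <- fx_geom()
  spec <- patch_spec()
  p0 <- pose(128, 128, alpha = -50, tau = 0, d = 1000)
  # bright ridge along the instrument axis through (x, y)
  xg <- outer(rep(1, 256), 0:255); yg <- outer(0:255, rep(1, 256))
  ax <- c(cos(-50 * pi / 180), sin(-50 * pi / 180))
  dist_perp <- abs(-(xg - p0$x) * ax[2] + (yg - p0$y) * ax[1])
  img <- exp(-dist_perp^2 / (2 * 1.5^2))
  patch <- extract_patch(img, p0, g, spec)
  # along-row intensity peaks at the anchor row for every column
  peak_rows <- apply(patch$pixels, 2, which.max) - 1
  expect_true(all(abs(peak_rows - spec$anchor[2]) <= 1))
})

test_that("appearance normalization makes the instrument pose-invariant", {
  # rendered at ground truth and cropped with a perfect prior, the
  # instrument must look the same regardless of its in-plane pose
  g <- fx_geom()
  f <- make_fiducial("screw")
  spec <- patch_spec()
  set.seed(71)
  ref <- NULL
  for (rep in 1:8) {
    p <- pose(runif(1, 110, 146), runif(1, 110, 146),
              alpha = runif(1, -180, 180), tau = 30, d = 900)
    img <- render_radiograph(f, p, g)
    patch <- extract_patch(img, p, g, spec)
    if (is.null(ref)) { ref <- patch$pixels; next }
    expect_gt(stats::cor(as.numeric(ref), as.numeric(patch$pixels)), 0.95)
  }
})

test_that("standard-pose landmarks encode inside [0, 1] and round-trip", {
  g <- fx_geom()
  lp <- fx_placement()
  spec <- patch_spec()
  img <- matrix(stats::runif(256 * 256), 256, 256)
  set.seed(5)
  for (p in fx_random_poses(20, tau_max = 80)) {
    patch <- extract_patch(img, p, g, spec)
    lm <- landmarks_from_pose(p, g, lp)
    tv <- encode_targets(lm, patch)
    expect_length(tv, 12)
    expect_true(all(is.finite(tv)))
    # exact prior => standard pose => targets inside the unit box
    expect_true(all(tv >= 0 & tv <= 1))
    # decode is the exact inverse
    lm2 <- decode_targets(tv, patch)
    expect_lt(max(abs(lm2 - lm)), 1e-9)
  }
  # corner conventions
  patch <- extract_patch(img, pose(128, 128, 20, 0, 1000), g, spec)
  at_origin <- patch_to_image(patch, c(0, 0))
  lm_one <- structure(rbind(at_origin, at_origin, at_origin,
                            at_origin, at_origin, at_origin),
                      class = c("fp_landmarks", "matrix", "array"))
  expect_equal(encode_targets(lm_one, patch), rep(0, 12), tolerance = 1e-10)
  at_corner <- patch_to_image(patch, c(92, 48))
  lm_c <- structure(matrix(rep(at_corner, each = 6), 6, 2),
                    class = c("fp_landmarks", "matrix", "array"))
  expect_equal(encode_targets(lm_c, patch), rep(1, 12), tolerance = 1e-10)

  # encode -> decode -> encode identity on random vectors
  set.seed(8)
  v <- stats::runif(12, -0.3, 1.3)
  expect_equal(encode_targets(decode_targets(v, patch), patch), v,
               tolerance = 1e-9)
})
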