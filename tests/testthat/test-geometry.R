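# geometry core: forward projection of the landmark cross and its closed-form
# inversion (line fits, magnification, foreshortening)

test_that("forward projection matches direct substitution cases", {
  g <- fx_geom()
  lp <- fx_placement()
  # 1/(c_d2p * d) = 2 px/mm at d = 1000
  lm <- landmarks_from_pose(pose(100, 100, alpha = 0, tau = 0, d = 1000), g, lp)
  i15 <- which(lp[, 1] == 15 & lp[, 2] == 0)
  expect_equal(unname(lm[i15, ]), c(130, 100), tolerance = 1e-12)
  i30 <- which(lp[, 1] == 30)
  expect_equal(unname(lm[i30, ]), c(160, 100), tolerance = 1e-12)

  # tau = 90 deg collapses the x-leg onto the position
  lm90 <- landmarks_from_pose(pose(100, 100, 0, 90, 1000), g, lp)
  ix <- attr(lp, "x_leg")
  expect_true(all(abs(lm90[ix, 1] - 100) < 1e-9))
  expect_true(all(abs(lm90[ix, 2] - 100) < 1e-9))
  # y-leg is untouched by tau
  iy <- attr(lp, "y_leg")
  expect_equal(lm90[iy, ], landmarks_from_pose(pose(100, 100, 0, 0, 1000), g, lp)[iy, ])

  # alpha = 90 deg turns +x toward +y (y runs down the image)
  lm_a <- landmarks_from_pose(pose(100, 100, 90, 0, 1000), g, lp)
  expect_equal(unname(lm_a[i15, ]), c(100, 130), tolerance = 1e-9)
})

test_that("orthogonal line fit recovers exact and noisy lines", {
  f <- fit_leg_line(rbind(c(0, 0), c(1, 0), c(2, 0)))
  expect_equal(f$centroid, c(1, 0))
  expect_equal(abs(f$direction), c(1, 0), tolerance = 1e-12)

  f2 <- fit_leg_line(rbind(c(0, 0), c(0, 2)))
  expect_equal(f2$centroid, c(0, 1))
  expect_equal(abs(f2$direction), c(0, 1), tolerance = 1e-12)

  # oriented by offsets
  f3 <- fit_leg_line(rbind(c(2, 0), c(0, 0)), offsets = c(-15, 15))
  expect_equal(f3$direction, c(-1, 0), tolerance = 1e-12)

  # noisy points around a known line: direction within 1 degree
  # (oracle: eigen-decomposition of the scatter is the TLS optimum; we check
  # against the generating direction at small noise)
  set.seed(42)
  for (rep in 1:20) {
    ang <- runif(1, 0, pi)
    t0 <- seq(-2, 2, length.out = 5)
    pts <- cbind(cos(ang) * t0, sin(ang) * t0) + matrix(rnorm(10, 0, 0.01), 5, 2)
    f4 <- fit_leg_line(pts)
    err <- acos(min(1, abs(sum(f4$direction * c(cos(ang), sin(ang)))))) * 180 / pi
    expect_lt(err, 1)
  }

  # coincident points are degenerate
  fd <- fit_leg_line(rbind(c(5, 5), c(5, 5), c(5.01, 5)))
  expect_true(fd$degenerate)
})

test_that("depth inversion matches the magnification relation", {
  g <- fx_geom()
  lp <- fx_placement()
  # y-leg +-15 mm at (100, 70) / (100, 130), center (100, 100):
  # d = (1/c_d2p) * 30 mm / 60 px = 1000 mm
  lm <- landmarks_from_pose(pose(100, 100, 0, 0, 1000), g, lp)
  iy <- attr(lp, "y_leg")
  expect_equal(sort(lm[iy, 2]), c(70, 100, 130))
  expect_equal(estimate_depth(lm, lp, g), 1000, tolerance = 1e-12)

  # halving all image offsets doubles the depth (inverse proportionality)
  lm_half <- lm
  lm_half[] <- sweep(sweep(unclass(lm), 2, c(100, 100)) * 0.5, 2, c(100, 100), "+")
  expect_equal(estimate_depth(lm_half, lp, g), 2000, tolerance = 1e-12)

  # round trip at random poses
  for (p in fx_random_poses(50, seed = 7)) {
    lm_p <- landmarks_from_pose(p, g, lp)
    expect_equal(estimate_depth(lm_p, lp, g), p$d, tolerance = 1e-9)
  }
})

test_that("projection-angle inversion recovers |tau| from foreshortening", {
  g <- fx_geom()
  lp <- fx_placement()
  # cos(30 deg): x-leg pair 30 mm apart projecting to 51.96... px at 2 px/mm
  lm <- landmarks_from_pose(pose(100, 100, 0, 30, 1000), g, lp)
  i15n <- which(lp[, 1] == -15); i15p <- which(lp[, 1] == 15)
  expect_equal(sqrt(sum((lm[i15p, ] - lm[i15n, ])^2)), 60 * cos(pi / 6),
               tolerance = 1e-12)
  tau <- estimate_projection_angle(lm, lp, g, d = 1000)
  expect_equal(as.numeric(tau), 30, tolerance = 1e-9)
  expect_false(attr(tau, "clamped"))

  # unforeshortened leg -> tau = 0
  lm0 <- landmarks_from_pose(pose(100, 100, 0, 0, 1000), g, lp)
  expect_equal(as.numeric(estimate_projection_angle(lm0, lp, g, 1000)), 0)

  # 45-degree round trip
  lm45 <- landmarks_from_pose(pose(100, 100, 10, 45, 1000), g, lp)
  expect_equal(as.numeric(estimate_projection_angle(lm45, lp, g, 1000)), 45,
               tolerance = 1e-6)

  # inflated image distances force cos > 1 -> clamp to tau = 0, flagged
  lm_in <- lm0
  lm_in[] <- sweep(sweep(unclass(lm0), 2, c(100, 100)) * 1.05, 2, c(100, 100), "+")
  tau_c <- estimate_projection_angle(lm_in, lp, g, 1000)
  expect_equal(as.numeric(tau_c), 0)
  expect_true(attr(tau_c, "clamped"))
})

test_that("full pose reconstruction inverts the forward map exactly", {
  g <- fx_geom()
  lp <- fx_placement()
  p0 <- pose(100, 100, 0, 0, 1000)
  fit <- pose_from_landmarks(landmarks_from_pose(p0, g, lp), lp, g)
  expect_equal(pose_vec(fit$pose), pose_vec(p0), tolerance = 1e-9)

  # collapsed x-leg (tau = 90) must fail loudly, not silently patch
  lm90 <- landmarks_from_pose(pose(100, 100, 0, 90, 1000), g, lp)
  expect_error(pose_from_landmarks(lm90, lp, g), class = "fp_reconstruction_error")
})

test_that("noisy reconstruction agrees with a nonlinear least-squares oracle", {
  g <- fx_geom()
  lp <- fx_placement()
  p0 <- pose(100, 100, 0, 0, 1000)
  lm0 <- landmarks_from_pose(p0, g, lp)

  # oracle: minimize the full forward-model residual over all 5 parameters
  nls_oracle <- function(lm_obs, start) {
    obj <- function(th) {
      pr <- landmarks_from_pose(pose(th[1], th[2], th[3], min(max(th[4], 0), 90),
                                     max(th[5], 1)), g, lp)
      sum((pr - lm_obs)^2)
    }
    stats::optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))$par
  }

  set.seed(11)
  for (rep in 1:10) {
    lm_n <- lm0 + matrix(rnorm(12, 0, 0.1), 6, 2)
    fit <- pose_from_landmarks(lm_n, lp, g)
    th_hat <- pose_vec(fit$pose)
    th_ora <- nls_oracle(lm_n, start = c(100, 100, 0, 5, 1000))
    expect_lt(sqrt(sum((th_hat[1:2] - c(100, 100))^2)), 0.15)  # position, px
    expect_lt(abs(th_hat[3]), 0.5)                             # alpha, deg
    # closed-form inversion tracks the full nonlinear LS fit
    expect_lt(sqrt(sum((th_hat[1:2] - th_ora[1:2])^2)), 0.1)
    expect_lt(abs(th_hat[3] - th_ora[3]), 0.5)
  }
})

test_that("pose <-> landmark equivariance and magnification properties hold", {
  g <- fx_geom()
  lp <- fx_placement()
  set.seed(3)
  for (p in fx_random_poses(25)) {
    lm <- landmarks_from_pose(p, g, lp)
    # translation equivariance
    p_t <- pose(p$x + 7.25, p$y - 3.5, p$alpha, p$tau, p$d)
    lm_t <- landmarks_from_pose(p_t, g, lp)
    expect_equal(unclass(lm_t), unclass(lm) + matrix(c(7.25, -3.5), 6, 2, byrow = TRUE),
                 tolerance = 1e-9, ignore_attr = TRUE)
    # rotation about (x, y) by delta
    delta <- 33
    p_r <- pose(p$x, p$y, wrap_angle_for_test(p$alpha + delta), p$tau, p$d)
    lm_r <- landmarks_from_pose(p_r, g, lp)
    rot <- matrix(c(cos(delta * pi / 180), sin(delta * pi / 180),
                    -sin(delta * pi / 180), cos(delta * pi / 180)), 2, 2)
    expected <- t(rot %*% t(sweep(unclass(lm), 2, c(p$x, p$y)))) +
      matrix(c(p$x, p$y), 6, 2, byrow = TRUE)
    expect_equal(unclass(lm_r), expected, tolerance = 1e-9, ignore_attr = TRUE)
    # magnification ~ 1/d
    p_2d <- pose(p$x, p$y, p$alpha, p$tau, 2 * p$d)
    lm_2d <- landmarks_from_pose(p_2d, g, lp)
    expect_equal(sweep(unclass(lm_2d), 2, c(p$x, p$y)),
                 sweep(unclass(lm), 2, c(p$x, p$y)) / 2, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("reconstruction error under fixed noise grows with |tau| toward 90", {
  g <- fx_geom()
  lp <- fx_placement()
  set.seed(19)
  # the x-leg foreshortens as cos(tau); its in-plane direction (the forward
  # angle) is what becomes unrecoverable as tau -> 90
  taus <- c(60, 70, 80, 85)
  med_err <- vapply(taus, function(tau) {
    errs <- replicate(120, {
      alpha <- runif(1, -180, 180)
      p <- pose(128, 128, alpha, tau, 1000)
      lm <- landmarks_from_pose(p, g, lp) + matrix(rnorm(12, 0, 0.1), 6, 2)
      fit <- tryCatch(pose_from_landmarks(lm, lp, g), error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      abs(ang_diff(fit$pose$alpha, alpha))
    })
    stats::median(errs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_err) > -0.05))  # non-decreasing up to MC jitter
  expect_gt(med_err[4], med_err[1])
})
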