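# synthetic radiograph simulator: fiducial meshes, projection rendering,
# pose sampling, dataset reproducibility

fx_custom_fiducial <- function(mesh, mu = 0.5) {
  structure(list(kind = "screw", vertices = mesh$vertices, faces = mesh$faces,
                 axis = c(1, 0, 0), reference_point = c(0, 0, 0),
                 attenuation = mu, bbox_diagonal = 1), class = "fp_fiducial")
}

test_that("fiducial models have the specified dimensions", {
  scr <- make_fiducial("screw")
  expect_equal(scr$bbox_diagonal, 6.5, tolerance = 0.01 / 6.5)

  drl <- make_fiducial("drill")
  # max cross-section diameter exactly 3 mm; tip apex at the origin
  expect_equal(2 * max(sqrt(drl$vertices[, 2]^2 + drl$vertices[, 3]^2)), 3,
               tolerance = 1e-9)
  expect_equal(max(drl$vertices[, 1]), 0)

  rob <- make_fiducial("robot")
  expect_gt(rob$bbox_diagonal, 13.15)     # full robot extends beyond the joint
  expect_error(make_fiducial("laser"))
})

test_that("fiducial meshes are watertight (even ray parity)", {
  set.seed(31)
  for (kind in c("screw", "drill", "robot")) {
    f <- make_fiducial(kind)
    # random rigid rotation, then vertical rays through the bbox
    th <- stats::runif(3, 0, 2 * pi)
    rz <- matrix(c(cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3)
    ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0, sin(th[2]), 0, cos(th[2])), 3)
    vw <- f$vertices %*% t(rz %*% ry)
    r <- apply(vw[, 1:2], 2, range)
    pts <- cbind(stats::runif(2000, r[1, 1], r[2, 1]),
                 stats::runif(2000, r[1, 2], r[2, 2]))
    hits <- fluoropose:::fp_vertical_hits(vw, f$faces, pts)
    expect_true(all(hits %% 2 == 0))
  }
})

test_that("rendering respects projection geometry", {
  g <- fx_geom()
  f <- make_fiducial("screw")
  p <- pose(128, 128, alpha = 25, tau = 30, d = 900)
  img <- render_radiograph(f, p, g)   # zero background
  s <- 1 / (c_d2p(g) * p$d)
  vw <- f$vertices %*% t(fluoropose:::fiducial_rotation(p$alpha, p$tau))
  px <- cbind(p$x + vw[, 1] * s, p$y + vw[, 2] * s)
  mask <- which(img < 1 - 1e-6, arr.ind = TRUE)
  xs <- mask[, 2] - 1; ys <- mask[, 1] - 1
  expect_true(all(xs >= floor(min(px[, 1])) - 1 & xs <= ceiling(max(px[, 1])) + 1))
  expect_true(all(ys >= floor(min(px[, 2])) - 1 & ys <= ceiling(max(px[, 2])) + 1))

  # doubling the depth halves the projected footprint diameter (+- 1 px)
  p_near <- pose(128, 128, 0, 0, 500)
  p_far <- pose(128, 128, 0, 0, 1000)
  diam <- function(p) {
    img <- render_radiograph(f, p, g)
    m <- which(img < 1 - 1e-6, arr.ind = TRUE)
    max(m[, 2]) - min(m[, 2])
  }
  expect_lt(abs(diam(p_near) / 2 - diam(p_far)), 1.5)

  # reference point projects to (x, y): centroid of a symmetric fiducial
  sph <- fx_custom_fiducial(mesh_sphere(2))
  img_s <- render_radiograph(sph, pose(120.3, 133.7, 10, 20, 900), g)
  w <- 1 - img_s
  xg <- outer(rep(1, 256), 0:255); yg <- outer(0:255, rep(1, 256))
  cen <- c(sum(w * xg), sum(w * yg)) / sum(w)
  expect_lt(sqrt(sum((cen - c(120.3, 133.7))^2)), 0.5)

  # out-of-view / beyond-detector poses refused
  expect_error(render_radiograph(f, pose(400, 128, 0, 0, 900), g), "field of view")
  expect_error(render_radiograph(f, pose(128, 128, 0, 0, 1200), g), "detector")
})

test_that("axis foreshortening between tau = 0 and 75 deg follows cos(tau)", {
  # path-length-weighted second moments: for a rotationally symmetric solid
  # the along-axis variance is cos(tau)^2 * var_axial + sin(tau)^2 * var_radial,
  # both measurable from the tau = 0 image. High-resolution geometry keeps
  # discretization below the 2% check tolerance.
  g <- projection_geometry(d_sdd = 1000, delta_ds = 0.125, width = 256, height = 256)
  # near-zero attenuation: after display normalization 1 - image is then
  # proportional to path length (Beer-Lambert linearized)
  f <- make_fiducial("screw", attenuation = 1e-3)
  moments <- function(tau) {
    p <- pose(128, 128, alpha = 0, tau = tau, d = 1000)  # 8 px/mm
    img <- render_radiograph(f, p, g)
    w <- 1 - img
    xg <- outer(rep(1, 256), 0:255); yg <- outer(0:255, rep(1, 256))
    cx <- sum(w * xg) / sum(w); cy <- sum(w * yg) / sum(w)
    c(va = sum(w * (xg - cx)^2) / sum(w),   # along-axis (alpha = 0)
      vr = sum(w * (yg - cy)^2) / sum(w))   # radial
  }
  m0 <- moments(0)
  m75 <- moments(75)
  ct <- cos(75 * pi / 180)
  pred <- ct^2 * m0["va"] + sin(75 * pi / 180)^2 * m0["vr"]
  expect_equal(unname(sqrt(m75["va"] / pred)), 1, tolerance = 0.02)
  # and the dominant along-axis compression really is the cos factor
  expect_equal(unname(sqrt((m75["va"] - sin(75 * pi / 180)^2 * m0["vr"]) / m0["va"])),
               ct, tolerance = 0.02 * ct + 0.02)
})

test_that("pose sampling respects ranges and is componentwise uniform", {
  rng <- sim_pose_ranges()
  g <- fx_geom()
  set.seed(77)
  draws <- t(replicate(10000, pose_vec(sample_pose(rng, g))))
  expect_true(all(draws[, 1] >= 96 & draws[, 1] <= 160))
  expect_true(all(draws[, 4] >= -85 & draws[, 4] <= 85))
  expect_true(all(draws[, 5] >= 800 & draws[, 5] <= 1000))
  for (j in c(1, 3, 4, 5)) {
    ct <- table(cut(draws[, j], breaks = 10))
    expect_gt(stats::chisq.test(ct)$p.value, 1e-4)
  }
  # point-mass ranges give the fixed pose
  fixed <- sim_pose_ranges(x_range = c(100, 100), y_range = c(110, 110),
                           alpha_range = c(12, 12), tau_range = c(-5, -5),
                           d_range = c(950, 950))
  p <- sample_pose(fixed, g)
  expect_equal(pose_vec(p), c(100, 110, 12, -5, 950))

  # test jitter must not exceed train jitter
  expect_error(sim_pose_ranges(jitter_train = c(0.5, 1), jitter_test = c(1, 1)),
               "jitter")
})

test_that("dataset generation is reproducible and self-consistent", {
  f <- make_fiducial("screw")
  g <- fx_geom()
  d1 <- generate_dataset(6, f, g, seed = 42)
  d2 <- generate_dataset(6, f, g, seed = 42)
  expect_identical(lapply(d1$records, function(r) pose_vec(r$pose)),
                   lapply(d2$records, function(r) pose_vec(r$pose)))
  expect_identical(d1$images, d2$images)
  # every record re-renders to exactly the stored image
  for (i in c(1, 4, 6))
    expect_identical(rerender_record(d1, i), d1$images[[i]])
  # different seed, different data
  d3 <- generate_dataset(6, f, g, seed = 43)
  expect_false(identical(d1$images[[1]], d3$images[[1]]))
})

test_that("dataset files round-trip: PGM, annotations, manifest, STL", {
  dir <- withr::local_tempdir()
  f <- make_fiducial("screw")
  g <- fx_geom()
  ds <- generate_dataset(5, f, g, seed = 9, dir = dir)
  # 16-bit PGM quantization error bounded by half a gray level
  img <- read_pgm(file.path(dir, "img_00001.pgm"))
  expect_lt(max(abs(img - ds$images[[1]])), 0.5 / 65535 + 1e-9)

  recs <- read_annotations(file.path(dir, "annotations.jsonl"))
  expect_length(recs, 5)
  for (i in 1:5)
    expect_identical(pose_vec(recs[[i]]$pose), pose_vec(ds$records[[i]]$pose))

  m <- read_manifest(file.path(dir, "manifest.json"))
  expect_identical(m$config$seed, 9L)
  # manifest referencing a missing image fails validation
  file.remove(file.path(dir, "img_00003.pgm"))
  expect_error(read_manifest(file.path(dir, "manifest.json")), "missing")

  # malformed / incomplete annotation records are reported with line numbers
  lines <- readLines(file.path(dir, "annotations.jsonl"))
  bad <- sub("\"alpha\":[^,]+,", "", lines[3])
  writeLines(c(lines[1:2], bad), file.path(dir, "bad.jsonl"))
  expect_error(read_annotations(file.path(dir, "bad.jsonl")), "alpha")

  # STL round trip preserves the surface
  stl <- file.path(dir, "screw.stl")
  write_stl(f, stl)
  m2 <- read_stl(stl)
  expect_identical(nrow(m2$faces), nrow(f$faces))
  tri_centroids <- function(m) {
    cen <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
              m$vertices[m$faces[, 3], ]) / 3
    cen[order(cen[, 1], cen[, 2], cen[, 3]), ]
  }
  expect_equal(tri_centroids(m2), tri_centroids(f), tolerance = 1e-6,
               ignore_attr = TRUE)
})
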