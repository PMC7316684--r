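# Synthetic radiograph simulator: parametric fiducial meshes, ray-traced
# Beer-Lambert projection over an anatomy-like random-field background, and
# reproducible dataset generation with exact ground-truth pose export.

## ---- triangle-mesh primitives (axis along local +x) -----------------------

mesh_empty <- function() list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3))

mesh_join <- function(a, b) {
  off <- nrow(a$vertices)
  list(vertices = rbind(a$vertices, b$vertices),
       faces = rbind(a$faces, b$faces + off))
}

#' Closed mesh primitives
#'
#' Watertight triangle meshes (mm) used to assemble parametric fiducials;
#' all primitives are oriented with their axis along local +x.
#'
#' @param radius radius, mm (`mesh_cone`: base radius).
#' @param x0,x1 axial extent, mm (`mesh_cone`: base at `x0`, apex at `x1`).
#' @param center sphere center (length-3, mm).
#' @param n circumferential segments.
#' @param nlat latitudinal bands for the sphere.
#' @return A list with `vertices` (n x 3 matrix, mm) and `faces`
#'   (n x 3 integer matrix, 1-based).
#' @export
mesh_cylinder <- function(radius, x0, x1, n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ring0 <- cbind(x0, radius * cos(th), radius * sin(th))
  ring1 <- cbind(x1, radius * cos(th), radius * sin(th))
  v <- rbind(ring0, ring1, c(x0, 0, 0), c(x1, 0, 0))
  c0 <- 2L * n + 1L; c1 <- 2L * n + 2L
  i <- seq_len(n); j <- c(seq_len(n)[-1], 1L)
  faces <- rbind(
    cbind(i, j, n + i),                # side
    cbind(j, n + j, n + i),
    cbind(j, i, c0),                   # cap x0
    cbind(n + i, n + j, c1))           # cap x1
  list(vertices = v, faces = matrix(as.integer(faces), ncol = 3))
}

#' @rdname mesh_cylinder
#' @export
mesh_cone <- function(radius, x0, x1, n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ring <- cbind(x0, radius * cos(th), radius * sin(th))
  v <- rbind(ring, c(x1, 0, 0), c(x0, 0, 0))
  apex <- n + 1L; base <- n + 2L
  i <- seq_len(n); j <- c(seq_len(n)[-1], 1L)
  faces <- rbind(cbind(i, j, apex),    # side
                 cbind(j, i, base))    # base cap
  list(vertices = v, faces = matrix(as.integer(faces), ncol = 3))
}

#' @rdname mesh_cylinder
#' @export
mesh_sphere <- function(radius, center = c(0, 0, 0), nlat = 12L, n = 24L) {
  phi <- seq(0, pi, length.out = nlat + 1L)[2:nlat]   # interior bands
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  grid <- expand.grid(th = th, phi = phi)
  v <- cbind(radius * cos(grid$phi),
             radius * sin(grid$phi) * cos(grid$th),
             radius * sin(grid$phi) * sin(grid$th))
  v <- rbind(v, c(radius, 0, 0), c(-radius, 0, 0))
  npole <- nrow(v) - 1L; spole <- nrow(v)
  idx <- function(b, k) (b - 1L) * n + ((k - 1L) %% n) + 1L
  faces <- NULL
  for (b in seq_len(length(phi) - 1L)) {
    for (k in seq_len(n)) {
      faces <- rbind(faces,
                     c(idx(b, k), idx(b, k + 1), idx(b + 1, k)),
                     c(idx(b, k + 1), idx(b + 1, k + 1), idx(b + 1, k)))
    }
  }
  for (k in seq_len(n)) {
    faces <- rbind(faces,
                   c(npole, idx(1L, k + 1), idx(1L, k)),
                   c(spole, idx(length(phi), k), idx(length(phi), k + 1)))
  }
  v <- sweep(v, 2, center, "+")
  list(vertices = v, faces = matrix(as.integer(faces), ncol = 3))
}

bbox_diagonal <- function(v) {
  r <- apply(v, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

## ---- fiducial models ------------------------------------------------------

#' Parametric fiducial models
#'
#' Builds the closed surface mesh, axis and pose reference point of the three
#' supported instruments:
#' * `"screw"` — head disk + shaft cylinder + conical tip, uniformly scaled
#'   so its bounding-box diagonal is 6.5 mm; the pose origin is the head
#'   center.
#' * `"drill"` — a 3 mm diameter cylinder with a conical tip; only the tip is
#'   pose-relevant (drill bending), so the pose origin is the tip apex.
#' * `"robot"` — spherical drill-head plus two cylinders separated by a
#'   flexible-joint gap, scaled so the bounding-box diagonal up to the joint
#'   is 13.15 mm; the pose origin is the drill-head center.
#'
#' @param kind `"screw"`, `"drill"` or `"robot"`.
#' @param attenuation relative linear attenuation coefficient (per mm path).
#' @param n circumferential mesh resolution.
#' @return An object of class `fp_fiducial`: list with `kind`, `vertices`
#'   (mm), `faces`, `axis` (local +x), `reference_point` (origin),
#'   `attenuation` and `bbox_diagonal`.
#' @examples
#' f <- make_fiducial("screw")
#' f$bbox_diagonal   # 6.5
#' @export
make_fiducial <- function(kind = c("screw", "drill", "robot"),
                          attenuation = 0.5, n = 24L) {
  kind <- match.arg(kind)
  m <- switch(kind,
    screw = {
      m <- mesh_join(mesh_cylinder(1.5, -1.2, 0, n),      # head disk
                     mesh_cylinder(0.8, 0, 4.0, n))       # shaft
      m <- mesh_join(m, mesh_cone(0.8, 4.0, 5.5, n))      # tip
      m$vertices <- m$vertices * (6.5 / bbox_diagonal(m$vertices))
      m
    },
    drill = {
      # tip apex at the origin, body extending along -x; diameter exactly 3 mm
      m <- mesh_join(mesh_cone(1.5, -2.0, 0, n),
                     mesh_cylinder(1.5, -14.0, -2.0, n))
      m
    },
    robot = {
      head <- mesh_sphere(1.6, c(0, 0, 0), nlat = 12L, n = n)
      seg1 <- mesh_cylinder(1.25, 1.2, 7.2, n)
      seg2 <- mesh_cylinder(1.25, 8.2, 14.2, n)
      m <- mesh_join(mesh_join(head, seg1), seg2)
      upto_joint <- rbind(head$vertices, seg1$vertices)
      m$vertices <- m$vertices * (13.15 / bbox_diagonal(upto_joint))
      m
    })
  structure(list(kind = kind, vertices = m$vertices, faces = m$faces,
                 axis = c(1, 0, 0), reference_point = c(0, 0, 0),
                 attenuation = attenuation,
                 bbox_diagonal = bbox_diagonal(m$vertices)),
            class = "fp_fiducial")
}

#' @export
print.fp_fiducial <- function(x, ...) {
  cat(sprintf("<fiducial '%s'>  %d vertices, %d faces, bbox diagonal %.3f mm, mu = %g /mm\n",
              x$kind, nrow(x$vertices), nrow(x$faces), x$bbox_diagonal,
              x$attenuation))
  invisible(x)
}

# rotation local instrument frame -> object frame (x,y in detector plane
# with y down, z along the projection normal)
fiducial_rotation <- function(alpha, tau) {
  a <- deg2rad(alpha); t <- deg2rad(tau)
  axis <- c(cos(t) * cos(a), cos(t) * sin(a), sin(t))
  ydir <- c(-sin(a), cos(a), 0)
  zdir <- c(-sin(t) * cos(a), -sin(t) * sin(a), cos(t))
  cbind(axis, ydir, zdir)
}

## ---- background surrogate -------------------------------------------------

#' Anatomy-surrogate background configuration
#'
#' The CT-anatomy background is emulated by a band-limited Gaussian random
#' field in the log (attenuation) domain: spatially smooth structures of
#' adjustable contrast, plus additive detector noise. A zero configuration
#' yields perfectly clean images.
#'
#' @param amplitude attenuation amplitude of the random field (log domain);
#'   0 disables the background.
#' @param corr_length correlation length of the field, px.
#' @param noise_sd additive detector noise standard deviation (intensity
#'   domain, image in `[0, 1]`).
#' @param contrast global scaling of the fiducial attenuation.
#' @return An object of class `fp_background`.
#' @export
background_config <- function(amplitude = 0, corr_length = 30, noise_sd = 0,
                              contrast = 1) {
  stopifnot(amplitude >= 0, corr_length > 0, noise_sd >= 0, contrast > 0)
  structure(list(amplitude = amplitude, corr_length = corr_length,
                 noise_sd = noise_sd, contrast = contrast),
            class = "fp_background")
}

# band-limited Gaussian random field, unit variance, via FFT filtering
gaussian_random_field <- function(h, w, corr_length) {
  white <- matrix(stats::rnorm(h * w), h, w)
  fx <- c(0:(floor(w / 2)), -((ceiling(w / 2) - 1):1)) / w
  fy <- c(0:(floor(h / 2)), -((ceiling(h / 2) - 1):1)) / h
  k2 <- outer(fy^2, rep(1, w)) + outer(rep(1, h), fx^2)
  filt <- exp(-2 * pi^2 * corr_length^2 * k2 / 4)
  f <- Re(stats::fft(stats::fft(white) * filt, inverse = TRUE)) / (h * w)
  (f - mean(f)) / stats::sd(f)
}

## ---- rendering ------------------------------------------------------------

#' Render a radiograph of a fiducial at a given pose
#'
#' Projects the fiducial mesh with the locally parallel-beam pinhole model
#' (rays along the projection normal, in-plane scale `1/(c_d2p * d)` px/mm,
#' so the rendered appearance is exactly consistent with the landmark
#' forward map), composites the Beer-Lambert fiducial transmission
#' multiplicatively over the background field in the log domain, adds
#' detector noise and affinely normalizes the display range to `[0, 1]`.
#' The instrument's reference point projects exactly to `(pose$x, pose$y)`.
#'
#' Uses R's global RNG for the background field and noise; seed with
#' [set.seed()] for reproducibility.
#'
#' @param fid an [make_fiducial()] object.
#' @param pose the ground-truth [pose()]; depth must satisfy
#'   `0 < d < d_sdd` and the position must lie inside the image.
#' @param geom an [projection_geometry()].
#' @param bg an [background_config()].
#' @return Numeric `height x width` matrix in `[0, 1]` (image coordinate
#'   `(x, y)` at `[y + 1, x + 1]`).
#' @export
render_radiograph <- function(fid, pose, geom, bg = background_config()) {
  w <- geom$width; h <- geom$height
  if (pose$x < 0 || pose$x > w - 1 || pose$y < 0 || pose$y > h - 1)
    stop("render_radiograph: pose outside the field of view")
  if (pose$d > geom$d_sdd)
    stop("render_radiograph: pose lies beyond the detector (d >= d_sdd)")
  s <- 1 / (c_d2p(geom) * pose$d)                       # px per mm
  vw <- fid$vertices %*% t(fiducial_rotation(pose$alpha, pose$tau))
  px_x <- pose$x + vw[, 1] * s
  px_y <- pose$y + vw[, 2] * s
  u0 <- max(0L, floor(min(px_x)) - 1L); u1 <- min(w - 1L, ceiling(max(px_x)) + 1L)
  v0 <- max(0L, floor(min(px_y)) - 1L); v1 <- min(h - 1L, ceiling(max(px_y)) + 1L)
  att <- matrix(0, h, w)
  if (u1 >= u0 && v1 >= v0) {
    sub <- fp_path_map(vw, fid$faces, pose$x, pose$y, s,
                       as.integer(u0), as.integer(u1),
                       as.integer(v0), as.integer(v1))
    att[(v0:v1) + 1L, (u0:u1) + 1L] <- sub
  }
  logt <- fid$attenuation * bg$contrast * att
  if (bg$amplitude > 0) {
    field <- gaussian_random_field(h, w, bg$corr_length)
    logt <- logt + bg$amplitude * (field - min(field))
  }
  img <- exp(-logt)
  if (bg$noise_sd > 0) img <- img + matrix(stats::rnorm(h * w, 0, bg$noise_sd), h, w)
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  img
}

## ---- pose sampling --------------------------------------------------------

#' Statistical pose-sampling ranges for dataset generation
#'
#' Independent uniform ranges per pose component, plus the train/test pose
#' jitter magnitudes (the additional noise applied to each drawn pose; the
#' test magnitude must not exceed the train magnitude, preserving realism
#' while increasing training variety).
#'
#' @param x_range,y_range in-plane position range, px.
#' @param alpha_range forward-angle range, degrees.
#' @param tau_range projection-angle range, degrees (draws beyond |80| are
#'   kept at generation time and filtered only at evaluation).
#' @param d_range depth range, mm.
#' @param jitter_train,jitter_test pose jitter magnitudes as
#'   `c(position_mm, angle_deg)`; `jitter_test <= jitter_train`
#'   componentwise.
#' @return An object of class `fp_pose_ranges`.
#' @export
sim_pose_ranges <- function(x_range = c(96, 160), y_range = c(96, 160),
                            alpha_range = c(-180, 180),
                            tau_range = c(-85, 85),
                            d_range = c(800, 1000),
                            jitter_train = c(1.0, 2.0),
                            jitter_test = c(0.5, 1.0)) {
  if (any(jitter_test > jitter_train))
    stop("sim_pose_ranges: test jitter must not exceed train jitter")
  structure(list(x_range = x_range, y_range = y_range,
                 alpha_range = alpha_range, tau_range = tau_range,
                 d_range = d_range, jitter_train = jitter_train,
                 jitter_test = jitter_test),
            class = "fp_pose_ranges")
}

#' Draw a random pose from the stated ranges
#'
#' Components are drawn independently and uniformly; optional jitter adds
#' truncated-to-range positional (mm, converted at the drawn depth) and
#' angular noise, emulating the noisy-pose generation of the synthetic
#' datasets.
#'
#' @param ranges an [sim_pose_ranges()].
#' @param geom an [projection_geometry()] (used to convert jitter mm to px).
#' @param jitter `"none"`, `"train"` or `"test"`.
#' @return A random [pose()].
#' @export
sample_pose <- function(ranges = sim_pose_ranges(), geom = projection_geometry(),
                        jitter = c("none", "train", "test")) {
  jitter <- match.arg(jitter)
  p <- pose(stats::runif(1, ranges$x_range[1], ranges$x_range[2]),
            stats::runif(1, ranges$y_range[1], ranges$y_range[2]),
            alpha = stats::runif(1, ranges$alpha_range[1], ranges$alpha_range[2]),
            tau = stats::runif(1, ranges$tau_range[1], ranges$tau_range[2]),
            d = stats::runif(1, ranges$d_range[1], ranges$d_range[2]))
  if (jitter != "none") {
    mag <- if (jitter == "train") ranges$jitter_train else ranges$jitter_test
    px_per_mm <- 1 / (c_d2p(geom) * p$d)
    ang <- stats::runif(1, 0, 2 * pi)
    r <- stats::runif(1, 0, mag[1]) * px_per_mm
    p <- pose(min(max(p$x + r * cos(ang), ranges$x_range[1]), ranges$x_range[2]),
              min(max(p$y + r * sin(ang), ranges$y_range[1]), ranges$y_range[2]),
              alpha = wrap_angle(p$alpha + stats::rnorm(1, 0, mag[2])),
              tau = min(max(p$tau + stats::rnorm(1, 0, mag[2]),
                            ranges$tau_range[1]), ranges$tau_range[2]),
              d = p$d)
  }
  p
}

## ---- dataset generation ---------------------------------------------------

#' Generate a reproducible synthetic dataset with exact ground truth
#'
#' Renders `n` radiographs at poses drawn from `ranges`, recording for each
#' image its ground-truth pose, generation seed and geometry. The whole
#' dataset is a pure function of `(configuration, seed)`: each image uses a
#' per-record seed derived from the master seed, so any single record can be
#' re-rendered bit-identically. Images are kept in memory and, if `dir` is
#' given, also written to disk as 16-bit grayscale PGM alongside JSON-lines
#' annotations and a JSON manifest.
#'
#' @param n number of images.
#' @param fid an [make_fiducial()].
#' @param geom an [projection_geometry()].
#' @param ranges an [sim_pose_ranges()].
#' @param bg an [background_config()].
#' @param split `"train"` or `"test"`; selects the pose-jitter magnitude.
#' @param seed master seed (integer).
#' @param dir optional output directory; created if missing.
#' @param keep_images keep rendered images in memory (default `TRUE`; set
#'   `FALSE` with `dir` for large on-disk datasets).
#' @return An object of class `fp_dataset`: list with `records` (one per
#'   image: `pose`, `seed`, `image` index/path), `images` (list of matrices,
#'   if kept), and the full generation configuration.
#' @export
generate_dataset <- function(n, fid = make_fiducial("screw"),
                             geom = projection_geometry(),
                             ranges = sim_pose_ranges(),
                             bg = background_config(),
                             split = c("train", "test"),
                             seed = 1L, dir = NULL, keep_images = TRUE) {
  split <- match.arg(split)
  jitter <- if (split == "train") "train" else "test"
  seed <- as.integer(seed)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  records <- vector("list", n)
  images <- if (keep_images) vector("list", n) else NULL
  written <- character(0)
  # a failed generation must not leave a half-written dataset behind
  on.exit(if (length(written)) suppressWarnings(file.remove(written)))
  for (i in seq_len(n)) {
    rec_seed <- (seed + 1013L * i) %% .Machine$integer.max
    set.seed(rec_seed)
    p <- sample_pose(ranges, geom, jitter = jitter)
    img <- render_radiograph(fid, p, geom, bg)
    path <- NULL
    if (!is.null(dir)) {
      path <- file.path(dir, sprintf("img_%05d.pgm", i))
      write_pgm(img, path)
      written <- c(written, path)
    }
    if (keep_images) images[[i]] <- img
    records[[i]] <- list(index = i, pose = p, seed = rec_seed,
                         fiducial = fid$kind, path = path)
  }
  ds <- structure(list(records = records, images = images,
                       config = list(n = n, fiducial = fid$kind,
                                     attenuation = fid$attenuation,
                                     geom = unclass(geom),
                                     ranges = unclass(ranges),
                                     bg = unclass(bg),
                                     split = split, seed = seed)),
                  class = "fp_dataset")
  if (!is.null(dir)) {
    write_annotations(ds, file.path(dir, "annotations.jsonl"))
    write_manifest(ds, file.path(dir, "manifest.json"))
  }
  on.exit()   # success: keep everything
  ds
}

#' @export
print.fp_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<synthetic dataset>  %d images, fiducial '%s', split '%s', seed %d\n",
              cfg$n, cfg$fiducial, cfg$split, cfg$seed))
  invisible(x)
}

#' Re-render a single dataset record
#'
#' Reconstructs the image of record `i` from its stored pose and seed;
#' bit-identical to the originally generated image.
#'
#' @param ds an `fp_dataset`.
#' @param i record index.
#' @param fid the fiducial used at generation time (rebuilt from the config
#'   by default).
#' @return The rendered image matrix.
#' @export
rerender_record <- function(ds, i, fid = NULL) {
  cfg <- ds$config
  if (is.null(fid)) fid <- make_fiducial(cfg$fiducial, attenuation = cfg$attenuation)
  geom <- do.call(projection_geometry, cfg$geom[c("d_sdd", "delta_ds", "width", "height")])
  bg <- do.call(background_config, cfg$bg)
  rec <- ds$records[[i]]
  set.seed(rec$seed)
  # replay the pose draw so the RNG state matches generation exactly
  ranges <- do.call(sim_pose_ranges, cfg$ranges)
  jitter <- if (cfg$split == "train") "train" else "test"
  p <- sample_pose(ranges, geom, jitter = jitter)
  stopifnot(abs(p$x - rec$pose$x) < 1e-12)
  render_radiograph(fid, p, geom, bg)
}
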