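# shared fixtures: default geometry, placement, and random pose draws

fx_geom <- function(width = 256L, height = 256L)
  projection_geometry(d_sdd = 1000, delta_ds = 0.5, width = width, height = height)

fx_placement <- function() landmark_placement()

# random poses in the central field of view; |tau| bounded away from the
# degeneracy unless asked otherwise
fx_random_poses <- function(n, tau_max = 80, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    pose(runif(1, 96, 160), runif(1, 96, 160),
         alpha = runif(1, -180, 180) |> (\(a) ifelse(a == -180, 180, a))(),
         tau   = runif(1, -tau_max, tau_max),
         d     = runif(1, 900, 1100))
  })
}

pose_vec <- function(p) c(p$x, p$y, p$alpha, p$tau, p$d)

wrap_angle_for_test <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

# smallest signed angular difference a - b in degrees
ang_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  ifelse(d == -180, 180, d)
}
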