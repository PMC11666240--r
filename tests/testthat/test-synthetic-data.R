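test_that("noise-free cohorts step exactly by drift plus shared drift", {
  op <- walk_config(n_tracks = 3, n_frames = 5, dt = 10,
                    drift = c(1, 0, 0), seed = 1)
  br <- walk_config(n_tracks = 2, n_frames = 5, dt = 10, seed = 2)
  ts <- simulate_cohorts(op, br, shared_drift = c(0, -1, 0))
  op_tracks <- Filter(function(tr) tr$cohort == "op_cell", ts$tracks)
  for (tr in op_tracks)
    expect_equal(unname(diff(tr$pos)),
                 matrix(rep(c(10, -10, 0), each = 4), ncol = 3))
  br_tracks <- Filter(function(tr) tr$cohort == "brain_cell", ts$tracks)
  for (tr in br_tracks)
    expect_equal(unname(diff(tr$pos)),
                 matrix(rep(c(0, -10, 0), each = 4), ncol = 3))
})

test_that("generators are bit-identical under a fixed seed", {
  cfgs <- list(walk_config(5, 10, diffusion = 0.05, persistence_p = 0.3,
                           start_spread = 20, seed = 99),
               walk_config(3, 10, diffusion = 0.01, seed = 7))
  a <- simulate_cohorts(cfgs[[1]], cfgs[[2]], shared_drift = c(0.1, 0, 0))
  b <- simulate_cohorts(cfgs[[1]], cfgs[[2]], shared_drift = c(0.1, 0, 0))
  expect_identical(a, b)
  expect_identical(make_point_cloud(10, 2, 10, 50, seed = 5),
                   make_point_cloud(10, 2, 10, 50, seed = 5))
  expect_identical(make_interface(120, 1000, roughness_px = 5, seed = 3),
                   make_interface(120, 1000, roughness_px = 5, seed = 3))
})

test_that("generated track sets pass validation and have the stated step variance", {
  cfg <- walk_config(n_tracks = 100, n_frames = 51, dt = 10,
                     diffusion = 0.05, seed = 13)
  ts <- simulate_cohorts(cfg, walk_config(2, 51, dt = 10, seed = 14))
  expect_s3_class(ts, "track_set")
  steps <- do.call(rbind, lapply(
    Filter(function(tr) tr$cohort == "op_cell", ts$tracks),
    function(tr) diff(tr$pos)))
  expect_gte(nrow(steps), 5000)
  v <- apply(steps, 2, var)
  expect_true(all(v > 2 * 0.05 * 10 * 0.85 & v < 2 * 0.05 * 10 * 1.15))
})

test_that("persistent walks keep the stationary step variance", {
  cfg <- walk_config(n_tracks = 100, n_frames = 51, dt = 10,
                     diffusion = 0.05, persistence_p = 0.5, seed = 21)
  ts <- simulate_cohorts(cfg, walk_config(2, 51, dt = 10, seed = 22))
  steps <- do.call(rbind, lapply(
    Filter(function(tr) tr$cohort == "op_cell", ts$tracks),
    function(tr) diff(tr$pos)))
  v <- apply(steps, 2, var)
  expect_true(all(v > 2 * 0.05 * 10 * 0.85 & v < 2 * 0.05 * 10 * 1.15))
  # lag-1 correlation near the configured persistence
  ml <- steps[, 1]
  idx <- seq_len(nrow(steps) - 1)
  within_track <- (idx %% 50) != 0   # avoid pairing across track joints
  r <- cor(ml[idx[within_track]], ml[idx[within_track] + 1])
  expect_equal(r, 0.5, tolerance = 0.1)
})

test_that("growth cones recover their intrinsic motion after drift subtraction", {
  ref_cfg <- walk_config(n_tracks = 5, n_frames = 21, dt = 10,
                         drift = c(1, 0, 0), seed = 31)
  reference <- simulate_cohorts(ref_cfg, walk_config(1, 21, dt = 10, seed = 32))
  reference$tracks <- Filter(function(tr) tr$cohort == "op_cell",
                             reference$tracks)
  gc_cfg <- walk_config(n_tracks = 4, n_frames = 21, dt = 10, seed = 33)
  gcs <- simulate_growth_cones(gc_cfg, reference,
                               intrinsic_drift = c(0, 1, 0))
  # raw steps combine tissue (+10 ml) and intrinsic (+10 dv) motion
  for (tr in gcs$tracks)
    expect_equal(unname(diff(tr$pos)),
                 matrix(rep(c(10, 10, 0), each = 20), ncol = 3))
  ds <- drift_series(reference, "op_cell")
  for (tr in gcs$tracks) {
    corr <- subtract_drift(tr, ds)
    expect_equal(unname(diff(corr$pos)),
                 matrix(rep(c(0, 10, 0), each = 20), ncol = 3))
  }
  # intrinsically stationary cones become stationary after correction
  still <- simulate_growth_cones(walk_config(2, 21, dt = 10, seed = 35),
                                 reference, intrinsic_drift = c(0, 0, 0))
  for (tr in still$tracks) {
    corr <- subtract_drift(tr, ds)
    expect_equal(unname(diff(corr$pos)), matrix(0, 20, 3))
  }
})

test_that("dorsally migrating cones show the configured displacement after correction", {
  set.seed(41)
  ref_cfg <- walk_config(n_tracks = 8, n_frames = 21, dt = 10,
                         drift = c(0.5, -0.4, 0), diffusion = 0.02, seed = 41)
  reference <- simulate_cohorts(ref_cfg, walk_config(1, 21, dt = 10, seed = 42))
  reference$tracks <- Filter(function(tr) tr$cohort == "op_cell",
                             reference$tracks)
  gcs <- simulate_growth_cones(
    walk_config(30, 21, dt = 10, diffusion = 0.02, seed = 43),
    reference, intrinsic_drift = c(0, 0.3, 0))
  ds <- drift_series(reference, "op_cell")
  net_dv <- vapply(gcs$tracks, function(tr) {
    corr <- subtract_drift(tr, ds)
    unname(corr$pos[21, "dv"] - corr$pos[1, "dv"])
  }, 0)
  # expectation 0.3 um/min * 200 min = 60 um, within 3 SE
  se <- sd(net_dv) / sqrt(length(net_dv))
  expect_lt(abs(mean(net_dv) - 60), 3 * se)
})

test_that("sinusoidal boundaries match an arc-length quadrature oracle", {
  straight <- make_boundary(boundary_config(100, 0, 3, 500))
  expect_equal(distortion_index(straight)$index, 1.0)
  for (amp in c(5, 10)) {
    cfg <- boundary_config(dv_span = 100, amplitude = amp, n_waves = 3,
                           n_vertices = 4000)
    got <- distortion_index(make_boundary(cfg))$index
    # independent oracle: fine numerical quadrature of the arc-length
    # integral of ml(dv) = A sin(2 pi w dv / L)
    L <- 100; w <- 3
    integrand <- function(s) sqrt(1 + (2 * pi * w * amp / L)^2 *
                                    cos(2 * pi * w * s / L)^2)
    want <- integrate(integrand, 0, L, subdivisions = 2000L,
                      rel.tol = 1e-10)$value / L
    expect_equal(got, want, tolerance = 1e-3)
  }
  # doubling the amplitude strictly increases the index
  idx <- vapply(c(2, 4, 8), function(a)
    distortion_index(make_boundary(boundary_config(100, a, 3, 4000)))$index, 0)
  expect_true(all(diff(idx) > 0))
})

test_that("synthetic interfaces respect gap and roughness bounds", {
  reg <- make_interface(gap_px = 120, region_length_px = 1000,
                        roughness_px = 5, seed = 2)
  th <- interface_thickness(reg, step_px = 100)
  expect_equal(th$n_samples, 10)
  expect_true(th$mean_nm >= 115 && th$mean_nm <= 125)
  expect_true(all(th$samples_nm >= 115 - 1e-6 & th$samples_nm <= 125 + 1e-6))
  expect_equal(interface_thickness(make_interface(40, 1000), 100)$mean_nm, 40)
  expect_error(make_interface(gap_px = 4, region_length_px = 100,
                              roughness_px = 5), "exceed")
})

test_that("point clouds respect containment and truth flags are recoverable", {
  cl <- make_point_cloud(n_main = 20, n_ectopic = 3, cluster_radius = 10,
                         ectopic_offset = 100, seed = 6)
  eb <- extent_box(cl)
  expect_true(all(c(eb$ml, eb$dv, eb$ap) <= 20))
  refound <- flag_ectopic(cl, link_dist = 15)
  expect_equal(refound$flags, cl$flags)
  noect <- make_point_cloud(12, 0, 10, 100, seed = 7)
  expect_true(all(flag_ectopic(noect, link_dist = 50)$flags == "main"))
  expect_error(make_point_cloud(5, 2, 10, 15, seed = 1), "ambiguous")
})

test_that("config validation rejects invalid parameters", {
  expect_error(walk_config(0, 10), "n_tracks")
  expect_error(walk_config(1, 1), "n_frames")
  expect_error(walk_config(1, 5, persistence_p = 1), "persistence_p")
  expect_error(walk_config(1, 5, diffusion = -1), "diffusion")
  expect_error(boundary_config(100, -1, 2, 100), "amplitude")
  expect_error(boundary_config(100, 1, 2, 1), "n_vertices")
})
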