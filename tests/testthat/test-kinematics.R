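test_that("MSD of pure drift is |v|^2 tau^2 and of a stationary track is 0", {
  v <- c(1, 0, 0)
  ts <- track_set(list(drift_track(v, n_frames = 4, dt = 1)), dt_nominal = 1)
  cur <- msd(ts, max_lag_fraction = 1)
  expect_equal(cur$lag, c(1, 2, 3))
  expect_equal(cur$msd, c(1, 4, 9))
  # general drift vector at all lags
  v2 <- c(0.3, -0.8, 0.5)
  ts2 <- track_set(list(drift_track(v2, n_frames = 12, dt = 10)),
                   dt_nominal = 10)
  cur2 <- msd(ts2, max_lag_fraction = 1)
  expect_equal(cur2$msd, sum(v2^2) * cur2$lag^2)
  still <- timed_track("s", c(0, 1, 2, 3), matrix(5, 4, 3))
  cur3 <- msd(track_set(list(still), dt_nominal = 1), max_lag_fraction = 1)
  expect_equal(cur3$msd, rep(0, 3))
})

test_that("msd() matches the brute-force double-loop oracle on random sets", {
  set.seed(7)
  for (rep in 1:20) {
    ts <- random_track_set()
    got <- msd(ts, max_lag_fraction = 0.5)
    want <- msd_brute_force(ts, max_lag_fraction = 0.5)
    expect_equal(got$lag, want$lag)
    expect_equal(got$msd, want$msd, tolerance = 1e-9)
    expect_equal(got$n_pairs, want$n_pairs)
  }
})

test_that("Brownian cohorts recover the diffusion coefficient from the MSD slope", {
  set.seed(11)
  D <- 0.05; dt <- 10
  cfg <- walk_config(n_tracks = 200, n_frames = 60, dt = dt, diffusion = D,
                     seed = 11)
  ts <- simulate_cohorts(cfg, walk_config(2, 60, dt = dt, seed = 12))
  cur <- msd(ts, cohort = "op_cell", max_lag_fraction = 0.5)
  slope <- msd_slope(cur, n_lags = 10)
  expect_gt(slope, 6 * D * 0.9)
  expect_lt(slope, 6 * D * 1.1)
})

test_that("total_displacement uses endpoint difference with nearest-sample rule", {
  t <- seq(0, 600, by = 10)
  pos <- cbind(ml = t * 12 / 600, dv = -t * 3 / 600, ap = t * 5 / 600)
  tr <- timed_track("a", t, pos)
  expect_equal(total_displacement(tr, "ml", 0, 600), 12)
  expect_equal(total_displacement(tr, "dv", 0, 600), -3)
  expect_equal(total_displacement(tr, "ap", 0, 600), 5)
  # query at t0 = 17 snaps to the sample at t = 20
  expect_equal(total_displacement(tr, "ml", 17, 600),
               unname(pos[t == 600, "ml"] - pos[t == 20, "ml"]))
  expect_error(total_displacement(tr, "ml", 300, 100), "greater")
  expect_error(total_displacement(tr, "ml", -50, 600), "outside")
})

test_that("drift_series averages reference steps frame-wise", {
  mk <- function(id, v) drift_track(v, n_frames = 6, dt = 10, id = id)
  ts <- track_set(list(mk("a", c(0.1, -0.2, 0)), mk("b", c(0.1, -0.2, 0)),
                       mk("c", c(0.1, -0.2, 0))), dt_nominal = 10)
  ds <- drift_series(ts, "op_cell")
  expect_equal(ds$step_ml, rep(1, 5))
  expect_equal(ds$step_dv, rep(-2, 5))
  expect_equal(ds$n_cells, rep(3L, 5))
  # opposite movers cancel
  ts2 <- track_set(list(mk("a", c(0.1, 0, 0)), mk("b", c(-0.1, 0, 0))),
                   dt_nominal = 10)
  ds2 <- drift_series(ts2, "op_cell")
  expect_equal(ds2$step_ml, rep(0, 5))
  # a track absent at later frames reduces n_cells there
  short <- drift_track(c(0.1, 0, 0), n_frames = 3, dt = 10, id = "s")
  ts3 <- track_set(list(mk("a", c(0.3, 0, 0)), short), dt_nominal = 10)
  ds3 <- drift_series(ts3, "op_cell")
  expect_equal(ds3$n_cells, c(2L, 2L, 1L, 1L, 1L))
  expect_equal(ds3$step_ml, c(2, 2, 3, 3, 3))
  expect_error(drift_series(ts3, "ncc"), "empty")
})

test_that("subtract_drift removes componentwise drift and is the identity on zero drift", {
  gc <- drift_track(c(0.1, 0.1, 0), n_frames = 6, dt = 10, id = "gc",
                    cohort = "growth_cone")
  ref <- track_set(list(drift_track(c(0.1, 0, 0), n_frames = 6, dt = 10)),
                   dt_nominal = 10)
  ds <- drift_series(ref, "op_cell")
  corr <- subtract_drift(gc, ds)
  expect_equal(unname(diff(corr$pos)),
               matrix(rep(c(0, 1, 0), each = 5), ncol = 3))
  # track equal to the reference motion becomes stationary
  self <- subtract_drift(ref$tracks[[1]], ds)
  expect_equal(unname(diff(self$pos)), matrix(0, 5, 3))
  # zero drift is the identity
  zero <- ds; zero$step_ml <- zero$step_dv <- zero$step_ap <- rep(0, nrow(ds))
  expect_equal(subtract_drift(gc, zero)$pos, gc$pos)
  # drift not covering the track errors
  shortdrift <- ds[1:2, ]
  attr(shortdrift, "dt") <- 10
  class(shortdrift) <- c("drift_series", "data.frame")
  expect_error(subtract_drift(gc, shortdrift), "does not cover")
})

test_that("subtracting a cohort's own drift zeroes its ensemble net displacement", {
  set.seed(3)
  cfg <- walk_config(n_tracks = 15, n_frames = 20, dt = 10,
                     drift = c(0.2, -0.1, 0), diffusion = 0.03, seed = 3)
  ts <- simulate_cohorts(cfg, walk_config(2, 20, dt = 10, seed = 4))
  ds <- drift_series(ts, "op_cell")
  op <- Filter(function(tr) tr$cohort == "op_cell", ts$tracks)
  nets <- t(vapply(op, function(tr) {
    ctr <- subtract_drift(tr, ds)
    ctr$pos[nrow(ctr$pos), ] - ctr$pos[1, ]
  }, c(ml = 0, dv = 0, ap = 0)))
  expect_equal(unname(colMeans(nets)), c(0, 0, 0), tolerance = 1e-9)
})

test_that("windowing yields the expected windows and persistence closed forms", {
  t <- seq(0, 1000, by = 10)
  tr <- timed_track("a", t, cbind(t * 0.01, t * 0.02, 0))
  ts <- track_set(list(tr), dt_nominal = 10)
  s <- windowed_summaries(ts, t_start = 200, window_len = 200, n_windows = 4)
  expect_equal(nrow(s), 4)
  expect_equal(s$t_start, c(200, 400, 600, 800))
  expect_equal(s$t_end, c(400, 600, 800, 1000))
  expect_error(windowed_summaries(ts, 200, 200, 5), "spans only")

  # straight two-step track: persistence 1, path length 5
  tr2 <- timed_track("b", c(0, 10, 20),
                     rbind(c(0, 0, 0), c(1.5, 2, 0), c(3, 4, 0)))
  s2 <- windowed_summaries(track_set(list(tr2), dt_nominal = 10),
                           t_start = 0, window_len = 20, n_windows = 1)
  expect_equal(s2$persistence, 1)
  expect_equal(s2$path_length, 5)
  expect_equal(s2$mean_speed, 0.25)

  # out-and-back: persistence 0
  tr3 <- timed_track("c", c(0, 10, 20),
                     rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)))
  s3 <- windowed_summaries(track_set(list(tr3), dt_nominal = 10),
                           0, 20, 1)
  expect_equal(s3$persistence, 0)

  # L-track: persistence sqrt(2)/2
  tr4 <- timed_track("d", c(0, 10, 20),
                     rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  s4 <- windowed_summaries(track_set(list(tr4), dt_nominal = 10),
                           0, 20, 1)
  expect_equal(s4$persistence, sqrt(2) / 2)
})

test_that("persistence stays in [0, 1] on random tracks", {
  set.seed(19)
  for (rep in 1:20) {
    ts <- random_track_set(max_tracks = 5, max_frames = 30, p_gap = 0.2)
    tmax <- max(vapply(ts$tracks, function(tr) max(tr$t), 0))
    s <- try(windowed_summaries(ts, 0, tmax, 1), silent = TRUE)
    if (inherits(s, "try-error")) next
    expect_true(all(s$persistence >= 0 & s$persistence <= 1 + 1e-12))
    expect_true(all(s$path_length + 1e-9 >=
                      sqrt(s$net_ml^2 + s$net_dv^2 + s$net_ap^2)))
  }
})

test_that("steps spanning gaps are excluded from speed but not from net displacement", {
  # samples at 0, 10, 30: the 10->30 step spans a gap
  tr <- timed_track("g", c(0, 10, 30),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0)))
  s <- windowed_summaries(track_set(list(tr), dt_nominal = 10), 0, 30, 1)
  expect_equal(s$path_length, 5)        # all consecutive displacements
  expect_equal(s$mean_speed, 0.1)       # in-grid distance 1 um / 10 min of data
  expect_equal(s$net_ml, 5)             # endpoints regardless of gaps
})

test_that("orientation angles follow the DV-reference convention", {
  mk <- function(d) timed_track("o", c(0, 10),
                                rbind(c(0, 0, 0), d))
  expect_equal(orientation_angle(mk(c(0, 5, 0))), 0)
  expect_equal(orientation_angle(mk(c(5, 0, 0))), 90)
  expect_equal(orientation_angle(mk(c(5, 5, 0))), 45)
  expect_equal(orientation_angle(mk(c(-5, 5, 0))), -45)
  expect_equal(orientation_angle(mk(c(0, -5, 0))), 180)
  expect_equal(orientation_angle(mk(c(5, 0, 5)), plane = "ml_ap"), 45)
  expect_warning(a <- orientation_angle(mk(c(0, 0, 5))), "undefined")
  expect_true(is.na(a))
})
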