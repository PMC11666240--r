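## Seeded generators of synthetic tracks, boundaries, EM interfaces and
## point clouds with the statistical structure the analyses assume. All
## generators are pure functions of (config, seed): identical inputs give
## bit-identical outputs.

#' Configuration of a drift + diffusion + persistence random walk
#'
#' Defines one cohort of simulated 3D tracks sampled on a regular time
#' grid, emulating the live-imaging regimes of the placode movies (10-min
#' frame interval over 600–1000 min). Steps are drift*dt plus AR(1) noise
#' with stationary per-axis variance 2*D*dt and lag-1 directional
#' correlation `persistence_p` (the generator parameter is distinct from
#' the measured net/path persistence statistic).
#'
#' @param n_tracks Number of tracks (>= 1).
#' @param n_frames Frames per track (>= 2).
#' @param dt Frame interval in minutes (default 10).
#' @param drift Cohort-intrinsic drift velocity, 3-vector in um/min.
#' @param diffusion Diffusion coefficient D in um^2/min (>= 0).
#' @param persistence_p Lag-1 step correlation in \[0, 1).
#' @param start_spread Half-width (um) of the uniform cube of start
#'   positions.
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   output.
#' @return An object of class `walk_config`.
#' @export
walk_config <- function(n_tracks, n_frames, dt = 10, drift = c(0, 0, 0),
                        diffusion = 0, persistence_p = 0,
                        start_spread = 0, seed = 1L) {
  if (n_tracks < 1L) stop("'n_tracks' must be >= 1")
  if (n_frames < 2L) stop("'n_frames' must be >= 2")
  if (dt <= 0) stop("'dt' must be > 0")
  drift <- as.numeric(drift)
  if (length(drift) != 3L) stop("'drift' must be a 3-vector (ml, dv, ap)")
  if (diffusion < 0) stop("'diffusion' must be >= 0")
  if (persistence_p < 0 || persistence_p >= 1)
    stop("'persistence_p' must be in [0, 1)")
  if (start_spread < 0) stop("'start_spread' must be >= 0")
  structure(list(n_tracks = as.integer(n_tracks),
                 n_frames = as.integer(n_frames), dt = dt, drift = drift,
                 diffusion = diffusion, persistence_p = persistence_p,
                 start_spread = start_spread, seed = as.integer(seed)),
            class = "walk_config")
}

## shared_drift: 3-vector (um/min) or function(t) -> 3-vector; evaluated at
## the start time of each frame interval.
shared_drift_fun <- function(shared_drift) {
  if (is.function(shared_drift)) return(shared_drift)
  v <- as.numeric(shared_drift)
  if (length(v) != 3L) stop("'shared_drift' must be a 3-vector or a function of t")
  function(t) v
}

simulate_walk_cohort <- function(cfg, shared_drift, cohort, id_prefix,
                                 drift_override = NULL) {
  stopifnot(inherits(cfg, "walk_config"))
  sfun <- shared_drift_fun(shared_drift)
  drift <- if (is.null(drift_override)) cfg$drift else as.numeric(drift_override)
  set.seed(cfg$seed)
  n <- cfg$n_frames
  t <- (seq_len(n) - 1L) * cfg$dt
  shared_step <- t(vapply(t[-n], function(tt) sfun(tt) * cfg$dt,
                          numeric(3L)))
  s2 <- 2 * cfg$diffusion * cfg$dt
  p <- cfg$persistence_p
  tracks <- vector("list", cfg$n_tracks)
  for (i in seq_len(cfg$n_tracks)) {
    start <- stats::runif(3L, -cfg$start_spread, cfg$start_spread)
    if (s2 > 0) {
      eps <- matrix(0, n - 1L, 3L)
      eps[1L, ] <- stats::rnorm(3L, 0, sqrt(s2))
      if (n > 2L) {
        innov_sd <- sqrt(s2 * (1 - p^2))
        for (k in 2:(n - 1L))
          eps[k, ] <- p * eps[k - 1L, ] + stats::rnorm(3L, 0, innov_sd)
      }
    } else {
      eps <- matrix(0, n - 1L, 3L)
    }
    steps <- sweep(eps, 2, drift * cfg$dt, `+`) + shared_step
    pos <- rbind(start, start + apply(steps, 2, cumsum))
    if (n == 2L) pos <- rbind(start, start + steps[1L, ])
    colnames(pos) <- c("ml", "dv", "ap")
    tracks[[i]] <- timed_track(paste0(id_prefix, "_", i), t, pos,
                               cohort = cohort)
  }
  tracks
}

#' Simulate coupled OP and brain cell cohorts
#'
#' Generates two cohorts of tracks (labelled `op_cell` and `brain_cell`)
#' each following its own drift + diffusion + persistence walk, with a
#' shared drift applied to both — emulating the forebrain-flexure movement
#' that carries OP and brain cells together.
#'
#' @param op_cfg,brain_cfg [walk_config()] objects with equal `dt` and
#'   `n_frames`.
#' @param shared_drift 3-vector in um/min, or a function of time returning
#'   one, applied to both cohorts.
#' @return A [track_set()].
#' @export
simulate_cohorts <- function(op_cfg, brain_cfg,
                             shared_drift = c(0, 0, 0)) {
  stopifnot(inherits(op_cfg, "walk_config"), inherits(brain_cfg, "walk_config"))
  if (op_cfg$dt != brain_cfg$dt)
    stop("op and brain configs must share dt")
  op <- simulate_walk_cohort(op_cfg, shared_drift, "op_cell", "op")
  br <- simulate_walk_cohort(brain_cfg, shared_drift, "brain_cell", "brain")
  track_set(c(op, br), dt_nominal = op_cfg$dt)
}

#' Simulate growth cones riding on a moving tissue
#'
#' Growth-cone positions are an intrinsic walk (own drift + diffusion)
#' plus the cumulative frame-wise mean motion of a reference cohort, so
#' that [subtract_drift()] with a drift series estimated from the
#' reference recovers the intrinsic kinematics by construction.
#'
#' @param cfg A [walk_config()] for the intrinsic walk; `cfg$n_frames`
#'   must not exceed the reference movie length.
#' @param reference A non-empty [track_set()] providing the tissue motion.
#' @param intrinsic_drift 3-vector in um/min overriding `cfg$drift`.
#' @return A [track_set()] of `growth_cone` tracks on the reference time
#'   grid.
#' @export
simulate_growth_cones <- function(cfg, reference,
                                  intrinsic_drift = cfg$drift) {
  stopifnot(inherits(cfg, "walk_config"), inherits(reference, "track_set"))
  if (!length(reference$tracks)) stop("'reference' track set is empty")
  if (reference$dt_nominal != cfg$dt)
    stop("cfg$dt must match the reference frame interval")
  ds <- drift_series(reference,
                     unique(vapply(reference$tracks, `[[`, "", "cohort")))
  if (cfg$n_frames - 1L > nrow(ds))
    stop("cfg$n_frames exceeds the reference movie length")
  gcs <- simulate_walk_cohort(cfg, c(0, 0, 0), "growth_cone", "gc",
                              drift_override = intrinsic_drift)
  cum <- rbind(0, apply(cbind(ds$step_ml, ds$step_dv, ds$step_ap), 2, cumsum))
  gcs <- lapply(gcs, function(tr) {
    k <- seq_len(length(tr$t))
    tr$pos <- tr$pos + cum[k, , drop = FALSE]
    tr
  })
  track_set(gcs, dt_nominal = cfg$dt)
}

#' Configuration of a synthetic sinusoidal boundary
#'
#' @param dv_span DV extent of the boundary in micrometres.
#' @param amplitude Sinusoid amplitude in micrometres (0 = straight).
#' @param n_waves Number of full waves over the span.
#' @param n_vertices Number of sampled vertices (>= 2).
#' @return An object of class `boundary_config`.
#' @export
boundary_config <- function(dv_span, amplitude, n_waves, n_vertices) {
  if (dv_span <= 0) stop("'dv_span' must be > 0")
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  if (n_waves < 0) stop("'n_waves' must be >= 0")
  if (n_vertices < 2L) stop("'n_vertices' must be >= 2")
  structure(list(dv_span = dv_span, amplitude = amplitude,
                 n_waves = n_waves, n_vertices = as.integer(n_vertices)),
            class = "boundary_config")
}

#' Generate a sinusoidal boundary polyline
#'
#' ml(dv) = amplitude * sin(2*pi*n_waves*dv/dv_span), sampled at
#' `n_vertices` equally spaced DV values, ordered ventral to dorsal. With
#' amplitude 0 the boundary is straight and its distortion index is 1.
#'
#' @param cfg A [boundary_config()].
#' @return A [boundary_polyline()].
#' @export
make_boundary <- function(cfg) {
  stopifnot(inherits(cfg, "boundary_config"))
  dv <- seq(0, cfg$dv_span, length.out = cfg$n_vertices)
  ml <- cfg$amplitude * sin(2 * pi * cfg$n_waves * dv / cfg$dv_span)
  boundary_polyline(cbind(ml, dv))
}

#' Generate a synthetic EM membrane interface
#'
#' Membrane A is a straight horizontal trace of the region length;
#' membrane B runs at `gap_px` plus a seeded zero-mean sinusoidal
#' perturbation bounded by `roughness_px`. Distances are in pixels.
#'
#' @param gap_px Nominal gap in pixels (> `roughness_px`).
#' @param region_length_px Region length in pixels.
#' @param roughness_px Perturbation bound in pixels (>= 0).
#' @param px_size_nm Pixel size in nanometres (default 1).
#' @param seed Integer RNG seed.
#' @return An [interface_region()].
#' @export
make_interface <- function(gap_px, region_length_px, roughness_px = 0,
                           px_size_nm = 1, seed = 1L) {
  if (roughness_px < 0) stop("'roughness_px' must be >= 0")
  if (gap_px <= roughness_px)
    stop("'gap_px' must exceed 'roughness_px' (membranes could touch)")
  x <- seq(0, region_length_px, by = 1)
  a <- boundary_polyline(cbind(x, rep(0, length(x))))
  if (roughness_px > 0) {
    set.seed(seed)
    f <- sample(1:4, 1L)
    phase <- stats::runif(1, 0, 2 * pi)
    perturb <- roughness_px * sin(2 * pi * f * x / region_length_px + phase)
  } else {
    perturb <- rep(0, length(x))
  }
  b <- boundary_polyline(cbind(x, gap_px + perturb))
  interface_region(a, b, region_length_px = region_length_px,
                   px_size_nm = px_size_nm)
}

#' Generate a labelled point cloud with known ectopic cells
#'
#' Main points are uniform in a ball of `cluster_radius`; ectopic points
#' are displaced from the cluster centre by at least `ectopic_offset`.
#' Truth flags are recorded, so detection by [flag_ectopic()] can be
#' scored against them. `ectopic_offset` must exceed twice the cluster
#' radius, otherwise the fixture would be ambiguous.
#'
#' @param n_main,n_ectopic Point counts (>= 0; at least one point total).
#' @param cluster_radius Main-cluster radius in micrometres.
#' @param ectopic_offset Minimal ectopic displacement in micrometres.
#' @param seed Integer RNG seed.
#' @return A [labeled_point_cloud()] with truth flags.
#' @export
make_point_cloud <- function(n_main, n_ectopic, cluster_radius,
                             ectopic_offset, seed = 1L) {
  if (n_main < 0 || n_ectopic < 0) stop("counts must be >= 0")
  if (n_main + n_ectopic < 1L) stop("need at least one point")
  if (n_ectopic > 0 && ectopic_offset <= 2 * cluster_radius)
    stop("'ectopic_offset' must exceed 2*cluster_radius (ambiguous fixture)")
  set.seed(seed)
  unit_dirs <- function(k) {
    m <- matrix(stats::rnorm(3L * k), ncol = 3L)
    m / sqrt(rowSums(m^2))
  }
  pts <- matrix(numeric(0), ncol = 3L)
  if (n_main > 0) {
    r <- cluster_radius * stats::runif(n_main)^(1 / 3)
    pts <- rbind(pts, unit_dirs(n_main) * r)
  }
  if (n_ectopic > 0) {
    r <- ectopic_offset + cluster_radius * stats::runif(n_ectopic)
    pts <- rbind(pts, unit_dirs(n_ectopic) * r)
  }
  labeled_point_cloud(pts,
                      flags = c(rep("main", n_main), rep("ectopic", n_ectopic)),
                      marker = "synthetic")
}
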