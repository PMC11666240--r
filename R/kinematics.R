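## Kinematic statistics for 3D tracks: MSD, directional displacement,
## tissue-drift estimation and subtraction, windowed speed/persistence,
## orientation angles.

track_frame_index <- function(track, dt) {
  k <- round((track$t - track$t[1L]) / dt)
  if (any(abs((track$t - track$t[1L]) / dt - k) > 1e-6))
    stop("track '", track$track_id, "': times off the dt grid")
  as.integer(k)
}

#' Ensemble 3D mean squared displacement
#'
#' For each lag tau = k*dt the per-track time-averaged MSD is the mean of
#' |r(t + tau) - r(t)|^2 over all sample pairs (t, t + tau) present in the
#' track (pairs with a missing endpoint, i.e. spanning a recording gap, are
#' skipped, never interpolated). Per-track curves are then averaged across
#' tracks with equal weight; the total number of displacement pairs per lag
#' is reported so weighted variants can be audited. For 3D diffusion with
#' coefficient D the expectation is 6*D*tau; for uniform drift v it is
#' |v|^2 tau^2.
#'
#' @param tracks A [track_set()].
#' @param cohort Optional cohort filter (character vector); `NULL` = all.
#' @param max_lag_fraction Largest lag, as a fraction of each track's
#'   duration (default 0.5: long-lag estimates rest on very few pairs).
#' @return An object of class `msd_curve`: a data frame with columns
#'   `lag` (minutes), `msd` (um^2), `n_pairs`, `n_tracks`, plus attributes
#'   `dt` and `n_tracks_total`.
#' @export
msd <- function(tracks, cohort = NULL, max_lag_fraction = 0.5) {
  stopifnot(inherits(tracks, "track_set"))
  if (!is.numeric(max_lag_fraction) || max_lag_fraction <= 0 ||
      max_lag_fraction > 1)
    stop("'max_lag_fraction' must be in (0, 1]")
  trs <- Filter(function(tr) length(tr$t) >= 2L, filter_cohort(tracks, cohort))
  if (!length(trs))
    stop("no track with >= 2 samples matches the cohort filter")
  dt <- tracks$dt_nominal
  per_track <- lapply(trs, function(tr) {
    k <- track_frame_index(tr, dt)
    K <- k[length(k)]
    grid <- matrix(NA_real_, nrow = K + 1L, ncol = 3L)
    grid[k + 1L, ] <- tr$pos
    kmax <- floor(max_lag_fraction * K)
    if (kmax < 1L) return(NULL)
    lag_k <- seq_len(kmax)
    m <- rep(NA_real_, kmax)
    np <- integer(kmax)
    for (L in lag_k) {
      d <- grid[(1L + L):(K + 1L), , drop = FALSE] -
        grid[1L:(K + 1L - L), , drop = FALSE]
      sq <- rowSums(d^2)
      ok <- !is.na(sq)
      np[L] <- sum(ok)
      if (np[L] > 0L) m[L] <- mean(sq[ok])
    }
    list(k = lag_k, msd = m, n = np)
  })
  per_track <- Filter(Negate(is.null), per_track)
  if (!length(per_track)) stop("max_lag_fraction too small: no usable lag")
  kmax_all <- max(vapply(per_track, function(p) max(p$k), 0L))
  msd_sum <- num <- pairs <- numeric(kmax_all)
  for (p in per_track) {
    ok <- !is.na(p$msd)
    idx <- p$k[ok]
    msd_sum[idx] <- msd_sum[idx] + p$msd[ok]
    num[idx] <- num[idx] + 1
    pairs[idx] <- pairs[idx] + p$n[ok]
  }
  keep <- num > 0
  if (!all(keep[seq_len(sum(keep))]))
    warning("some requested lags had no admissible pair and were omitted")
  out <- data.frame(lag = which(keep) * dt,
                    msd = msd_sum[keep] / num[keep],
                    n_pairs = pairs[keep],
                    n_tracks = num[keep])
  structure(out, class = c("msd_curve", "data.frame"),
            dt = dt, n_tracks_total = length(per_track))
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags (dt = %g min), %d tracks\n",
              nrow(x), attr(x, "dt"), attr(x, "n_tracks_total")))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @param x An `msd_curve`.
#' @param n_lags Number of initial lags used in the fit.
#' @param ... Passed to [stats::lm()].
#' @describeIn msd Slope of MSD versus lag over the first `n_lags` lags
#'   (ordinary least squares with intercept); for Brownian motion the slope
#'   estimates 6D.
#' @export
msd_slope <- function(x, n_lags = 10L, ...) {
  stopifnot(inherits(x, "msd_curve"))
  d <- utils::head(as.data.frame(x), n_lags)
  unname(stats::coef(stats::lm(msd ~ lag, data = d, ...))["lag"])
}

#' @export
plot.msd_curve <- function(x, log = "", ...) {
  plot(x$lag, x$msd, type = "b", pch = 16, log = log,
       xlab = "lag (min)", ylab = expression(MSD ~ (mu * m^2)), ...)
  invisible(x)
}

nearest_sample <- function(track, t0) {
  which.min(abs(track$t - t0))
}

#' Signed displacement along one embryonic axis
#'
#' Coordinate difference along `axis` between the sample nearest `t1` and
#' the sample nearest `t0` (nearest-sample rule, no extrapolation).
#'
#' @param track A [timed_track()].
#' @param axis `"ml"`, `"dv"` or `"ap"`.
#' @param t0,t1 Window bounds in minutes, `t0 < t1`, both within the
#'   track's time span.
#' @return Signed displacement in micrometres.
#' @export
total_displacement <- function(track, axis = c("ml", "dv", "ap"), t0, t1) {
  axis <- match.arg(axis)
  stopifnot(inherits(track, "timed_track"))
  if (t1 <= t0) stop("'t1' must be greater than 't0'")
  if (t0 < min(track$t) - 1e-9 || t1 > max(track$t) + 1e-9)
    stop("window [", t0, ", ", t1, "] outside track span [",
         min(track$t), ", ", max(track$t), "]")
  i0 <- nearest_sample(track, t0)
  i1 <- nearest_sample(track, t1)
  unname(track$pos[i1, axis] - track$pos[i0, axis])
}

#' Frame-wise mean motion of a reference cohort
#'
#' Estimates the shared tissue motion (e.g. the forebrain-flexure drift) as
#' the per-frame mean displacement of a reference cohort: for each frame t
#' on the nominal grid, the mean over reference tracks sampled at both t
#' and t + dt of r(t + dt) - r(t). Frames with no eligible reference cell
#' carry a zero step and a warning.
#'
#' @param tracks A [track_set()].
#' @param reference_cohort Cohort label(s) of the reference cells (e.g.
#'   `"op_cell"` cell bodies).
#' @return An object of class `drift_series`: data frame with columns `t`
#'   (frame start, minutes), `step_ml`, `step_dv`, `step_ap` (micrometres
#'   per frame interval) and `n_cells`; attribute `dt`.
#' @export
drift_series <- function(tracks, reference_cohort) {
  stopifnot(inherits(tracks, "track_set"))
  trs <- filter_cohort(tracks, reference_cohort)
  if (!length(trs)) stop("reference cohort is empty")
  dt <- tracks$dt_nominal
  t0 <- min(vapply(trs, function(tr) tr$t[1L], 0))
  t1 <- max(vapply(trs, function(tr) tr$t[length(tr$t)], 0))
  frames <- seq(t0, t1 - dt, by = dt)
  step <- matrix(0, nrow = length(frames), ncol = 3L,
                 dimnames = list(NULL, c("ml", "dv", "ap")))
  n_cells <- integer(length(frames))
  for (tr in trs) {
    k <- track_frame_index(tr, dt)
    tt <- tr$t[1L] + k * dt
    i_from <- match(round((frames - tr$t[1L]) / dt), k)
    i_to <- match(round((frames + dt - tr$t[1L]) / dt), k)
    ok <- !is.na(i_from) & !is.na(i_to)
    if (any(ok)) {
      step[ok, ] <- step[ok, ] + tr$pos[i_to[ok], , drop = FALSE] -
        tr$pos[i_from[ok], , drop = FALSE]
      n_cells[ok] <- n_cells[ok] + 1L
    }
  }
  has <- n_cells > 0L
  step[has, ] <- step[has, , drop = FALSE] / n_cells[has]
  if (any(!has))
    warning(sum(!has), " frame interval(s) had no reference cell; ",
            "zero drift step used there")
  structure(data.frame(t = frames, step_ml = step[, "ml"],
                       step_dv = step[, "dv"], step_ap = step[, "ap"],
                       n_cells = n_cells),
            class = c("drift_series", "data.frame"), dt = dt)
}

#' @export
print.drift_series <- function(x, ...) {
  cat(sprintf("<drift_series> %d frame intervals, dt = %g min, mean step (%.3g, %.3g, %.3g) um\n",
              nrow(x), attr(x, "dt"), mean(x$step_ml), mean(x$step_dv),
              mean(x$step_ap)))
  invisible(x)
}

drift_cumulative <- function(drift, from_t, at_t) {
  ## sum of mean steps over frame intervals in [from_t, at_t)
  dt <- attr(drift, "dt")
  if (at_t < from_t + dt / 2) return(c(ml = 0, dv = 0, ap = 0))
  need <- seq(from_t, at_t - dt, by = dt)
  idx <- match(round(need, 9), round(drift$t, 9))
  if (anyNA(idx))
    stop("drift series does not cover frame(s) at t = ",
         paste(need[is.na(idx)], collapse = ", "))
  c(ml = sum(drift$step_ml[idx]), dv = sum(drift$step_dv[idx]),
    ap = sum(drift$step_ap[idx]))
}

#' Subtract a reference-frame drift from a track
#'
#' Removes the shared tissue motion from a track: the corrected position at
#' frame n is r(t_n) minus the cumulative reference mean step over frame
#' intervals since the track's first sample, so the first corrected
#' position equals the raw one. Subtracting a drift built from a cohort of
#' identical movers turns each of them into a stationary track.
#'
#' @param track A [timed_track()].
#' @param drift A [drift_series()] covering the track's frame range.
#' @return A corrected [timed_track()].
#' @export
subtract_drift <- function(track, drift) {
  stopifnot(inherits(track, "timed_track"), inherits(drift, "drift_series"))
  corr <- t(vapply(track$t,
                   function(tt) drift_cumulative(drift, track$t[1L], tt),
                   c(ml = 0, dv = 0, ap = 0)))
  out <- track
  out$pos <- track$pos - corr
  out
}

step_in_grid <- function(dt, d_actual) abs(d_actual - dt) <= dt * 1e-6

#' Windowed speed, persistence and orientation summaries
#'
#' Cuts the movie into `n_windows` consecutive closed windows of length
#' `window_len` starting at `t_start` and summarises each track in each
#' window: path length (sum over all consecutive in-window displacements),
#' net displacement vector, mean speed (distance travelled divided by
#' elapsed time with data; steps spanning recording gaps are excluded
#' from both numerator and denominator), persistence (net
#' displacement magnitude over path length, in \[0, 1\]) and the ML-DV
#' orientation angle of the net displacement. A track contributes to a
#' window only if it has at least two samples inside it; a sample pair
#' straddling a window boundary is counted in the window containing its
#' first sample.
#'
#' @param tracks A [track_set()].
#' @param t_start Start of the first window (minutes, >= 0).
#' @param window_len Window length in minutes (> dt).
#' @param n_windows Number of consecutive windows.
#' @param drift Optional [drift_series()]; when given, summaries are
#'   computed on drift-corrected positions.
#' @param cohort Optional cohort filter.
#' @return A data frame of class `kinematic_summary` with one row per
#'   track x window: `track_id, cohort, window, t_start, t_end, mean_speed,
#'   persistence, net_ml, net_dv, net_ap, path_length, orientation_deg`.
#' @export
windowed_summaries <- function(tracks, t_start, window_len, n_windows,
                               drift = NULL, cohort = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  dt <- tracks$dt_nominal
  if (t_start < 0) stop("'t_start' must be >= 0")
  if (window_len <= dt) stop("'window_len' must exceed dt")
  if (n_windows < 1L) stop("'n_windows' must be >= 1")
  trs <- filter_cohort(tracks, cohort)
  if (!length(trs)) stop("no track matches the cohort filter")
  t_end_all <- max(vapply(trs, function(tr) max(tr$t), 0))
  if (t_start + n_windows * window_len > t_end_all + 1e-9)
    stop("requested windows end at ", t_start + n_windows * window_len,
         " min but the movie spans only ", t_end_all, " min")
  rows <- list()
  for (tr in trs) {
    pos <- tr$pos
    if (!is.null(drift)) pos <- subtract_drift(tr, drift)$pos
    for (w in seq_len(n_windows)) {
      a <- t_start + (w - 1L) * window_len
      b <- a + window_len
      inw <- which(tr$t >= a - 1e-9 & tr$t <= b + 1e-9)
      if (length(inw) < 2L) next
      tw <- tr$t[inw]
      pw <- pos[inw, , drop = FALSE]
      dtk <- diff(tw)
      steps <- diff(pw)
      step_len <- sqrt(rowSums(steps^2))
      path <- sum(step_len)                  # all consecutive displacements
      ok <- step_in_grid(dt, dtk)            # speed excludes gap-spanning steps
      path_speed <- sum(step_len[ok])
      elapsed <- sum(dtk[ok])
      net <- pw[length(inw), ] - pw[1L, ]
      net_mag <- sqrt(sum(net^2))
      persistence <- if (path > 0) net_mag / path else 0
      orientation <- if (net["ml"] == 0 && net["dv"] == 0) NA_real_ else
        atan2(net["ml"], net["dv"]) * 180 / pi
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = tr$track_id, cohort = tr$cohort, window = w,
        t_start = a, t_end = b,
        mean_speed = if (elapsed > 0) path_speed / elapsed else NA_real_,
        persistence = persistence,
        net_ml = unname(net["ml"]), net_dv = unname(net["dv"]),
        net_ap = unname(net["ap"]),
        path_length = path, orientation_deg = unname(orientation),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no track has >= 2 samples in any requested window")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("kinematic_summary", "data.frame"),
            dt = dt, drift_corrected = !is.null(drift))
}

#' Orientation of a track's net displacement
#'
#' The angle between the windowed net displacement and the reference
#' embryonic axis, in degrees within (-180, 180]. In the ML-DV plane the
#' reference axis is DV: pure dorsal movement is 0 degrees and pure lateral
#' (+ML) movement is +90 degrees; `"ml_ap"` uses AP as the reference axis.
#' Endpoints follow the nearest-sample rule of [total_displacement()].
#'
#' @param track A [timed_track()].
#' @param plane `"ml_dv"` or `"ml_ap"`.
#' @param window Optional `c(t0, t1)`; default is the whole track.
#' @return Angle in degrees, or `NA` (with a warning) when the in-plane
#'   net displacement is zero — such tracks are excluded from circular
#'   samples.
#' @export
orientation_angle <- function(track, plane = c("ml_dv", "ml_ap"),
                              window = NULL) {
  plane <- match.arg(plane)
  stopifnot(inherits(track, "timed_track"))
  if (is.null(window)) window <- range(track$t)
  i0 <- nearest_sample(track, window[1L])
  i1 <- nearest_sample(track, window[2L])
  d <- track$pos[i1, ] - track$pos[i0, ]
  ref <- if (plane == "ml_dv") d["dv"] else d["ap"]
  if (d["ml"] == 0 && ref == 0) {
    warning("track '", track$track_id,
            "': zero net in-plane displacement, orientation undefined")
    return(NA_real_)
  }
  unname(atan2(d["ml"], ref) * 180 / pi)
}
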