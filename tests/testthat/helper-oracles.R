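# Independent oracles and random-fixture builders used across test files.

# Random valid track set: up to `max_tracks` tracks, up to `max_frames`
# frames each, optional gaps (missing frames), dt = 10 min.
random_track_set <- function(max_tracks = 20, max_frames = 50,
                             p_gap = 0.15, dt = 10) {
  n_tracks <- sample(1:max_tracks, 1)
  tracks <- lapply(seq_len(n_tracks), function(i) {
    n <- sample(2:max_frames, 1)
    keep <- c(TRUE, runif(n - 2) > p_gap, TRUE)
    if (n == 2) keep <- c(TRUE, TRUE)
    t <- ((1:n) - 1)[keep] * dt
    pos <- matrix(rnorm(3 * sum(keep), sd = 5), ncol = 3)
    timed_track(paste0("tr", i), t, pos,
                cohort = sample(c("op_cell", "brain_cell"), 1))
  })
  track_set(tracks, dt_nominal = dt)
}

# Brute-force double-loop time-averaged MSD, averaged unweighted across
# tracks: independent of the production implementation.
msd_brute_force <- function(ts, max_lag_fraction = 0.5) {
  dt <- ts$dt_nominal
  acc <- list()
  for (tr in ts$tracks) {
    dur <- tr$t[length(tr$t)] - tr$t[1]
    kmax <- floor(max_lag_fraction * dur / dt)
    if (kmax < 1) next
    for (k in seq_len(kmax)) {
      tau <- k * dt
      sqs <- c()
      for (i in seq_along(tr$t)) {
        j <- which(abs(tr$t - (tr$t[i] + tau)) < 1e-6)
        if (length(j) == 1)
          sqs <- c(sqs, sum((tr$pos[j, ] - tr$pos[i, ])^2))
      }
      if (length(sqs))
        acc[[length(acc) + 1]] <- data.frame(lag = tau, m = mean(sqs),
                                             n = length(sqs))
    }
  }
  d <- do.call(rbind, acc)
  lags <- sort(unique(d$lag))
  data.frame(lag = lags,
             msd = sapply(lags, function(L) mean(d$m[d$lag == L])),
             n_pairs = sapply(lags, function(L) sum(d$n[d$lag == L])))
}

# Brute-force connected components at threshold: union-find on all pairs
# with distance <= link_dist.
components_brute_force <- function(points, link_dist) {
  n <- nrow(points)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- as.matrix(dist(points))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] <= link_dist) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# Straight-line track along a given velocity (um/min).
drift_track <- function(v, n_frames = 10, dt = 1, id = "drift",
                        cohort = "op_cell") {
  t <- (seq_len(n_frames) - 1) * dt
  timed_track(id, t, outer(t, v), cohort = cohort)
}
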