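COHORT_LEVELS <- c("op_cell", "brain_cell", "growth_cone", "ncc", "other")
SIDE_LEVELS <- c("left", "right", "unspecified")

## Axis convention used throughout: x = ML (+ lateral), y = DV (+ dorsal),
## z = AP (+ anterior), all in micrometres.
AXES_CONVENTION <- list(ml = "+x lateral", dv = "+y dorsal", ap = "+z anterior")

#' A single 3D track sampled at regular intervals
#'
#' The atom of all kinematic analyses: one tracked object (a cell nucleus or
#' an axonal growth cone) with its time-ordered 3D positions. Coordinates are
#' micrometres in the embryonic frame: `ml` mediolateral (+ lateral), `dv`
#' dorsoventral (+ dorsal), `ap` anteroposterior (+ anterior). Time is in
#' minutes. Missing frames (gaps) are permitted; downstream statistics skip
#' displacement pairs whose endpoints are not both sampled rather than
#' interpolating.
#'
#' @param track_id Character scalar identifying the track.
#' @param t Numeric vector of sampling times in minutes, strictly increasing.
#' @param pos Numeric matrix with one row per sample and columns
#'   `ml`, `dv`, `ap` (micrometres).
#' @param cohort One of `"op_cell"`, `"brain_cell"`, `"growth_cone"`,
#'   `"ncc"`, `"other"`.
#' @param embryo_id Character scalar, defaults to `"e1"`.
#' @param side `"left"`, `"right"` or `"unspecified"`.
#' @return An object of class `timed_track`.
#' @export
timed_track <- function(track_id, t, pos, cohort = "other",
                        embryo_id = "e1", side = "unspecified") {
  track_id <- as.character(track_id)
  cohort <- match.arg(cohort, COHORT_LEVELS)
  side <- match.arg(side, SIDE_LEVELS)
  t <- as.numeric(t)
  pos <- as.matrix(pos)
  if (ncol(pos) != 3L)
    stop("'pos' must have 3 columns (ml, dv, ap)")
  colnames(pos) <- c("ml", "dv", "ap")
  if (length(t) != nrow(pos))
    stop("length(t) must equal nrow(pos)")
  if (anyNA(t) || anyNA(pos) || any(!is.finite(t)) || any(!is.finite(pos)))
    stop("track '", track_id, "': non-finite time or coordinates")
  if (length(t) >= 2L && any(diff(t) <= 0))
    stop("track '", track_id, "': time must be strictly increasing")
  structure(
    list(track_id = track_id, cohort = cohort, embryo_id = embryo_id,
         side = side, t = t, pos = pos),
    class = "timed_track")
}

#' @export
print.timed_track <- function(x, ...) {
  cat(sprintf("<timed_track '%s'> cohort=%s embryo=%s side=%s, %d samples, t in [%g, %g] min\n",
              x$track_id, x$cohort, x$embryo_id, x$side,
              length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

n_samples <- function(track) length(track$t)

#' A set of tracks sharing a nominal frame interval
#'
#' @param tracks List of [timed_track()] objects.
#' @param dt_nominal Frame interval in minutes shared by all tracks. If
#'   `NULL`, inferred as the smallest positive time step found in the data.
#' @return An object of class `track_set` with fields `tracks`,
#'   `dt_nominal` and `axes` (the explicit axis convention).
#' @details Within a track, sampling times must sit on the `dt_nominal`
#'   grid anchored at the track's first sample; missing grid points are
#'   interpreted as gaps.
#' @export
track_set <- function(tracks, dt_nominal = NULL) {
  if (!is.list(tracks) || (length(tracks) && !all(vapply(tracks, inherits, TRUE, "timed_track"))))
    stop("'tracks' must be a list of timed_track objects")
  if (is.null(dt_nominal)) {
    steps <- unlist(lapply(tracks, function(tr) diff(tr$t)))
    if (!length(steps)) stop("cannot infer dt_nominal from tracks without steps")
    dt_nominal <- min(steps)
  }
  if (!is.numeric(dt_nominal) || dt_nominal <= 0)
    stop("'dt_nominal' must be a positive number of minutes")
  for (tr in tracks) {
    if (length(tr$t) < 2L) next
    k <- (tr$t - tr$t[1L]) / dt_nominal
    if (any(abs(k - round(k)) > 1e-6))
      stop("track '", tr$track_id, "': sampling times are not multiples of dt_nominal = ",
           dt_nominal)
  }
  structure(list(tracks = tracks, dt_nominal = dt_nominal, axes = AXES_CONVENTION),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  coh <- table(factor(vapply(x$tracks, `[[`, "", "cohort"), COHORT_LEVELS))
  cat(sprintf("<track_set> %d tracks, dt = %g min\n", length(x$tracks), x$dt_nominal))
  cat("  cohorts:", paste(sprintf("%s=%d", names(coh)[coh > 0], coh[coh > 0]),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.track_set <- function(x) length(x$tracks)

#' Combine track sets sharing a frame interval
#' @param ... `track_set` objects with identical `dt_nominal`.
#' @return A single `track_set`.
#' @export
c.track_set <- function(...) {
  sets <- list(...)
  dts <- vapply(sets, `[[`, 0, "dt_nominal")
  if (length(unique(dts)) != 1L)
    stop("cannot combine track sets with different dt_nominal")
  track_set(do.call(c, lapply(sets, `[[`, "tracks")), dt_nominal = dts[1L])
}

filter_cohort <- function(ts, cohort) {
  if (is.null(cohort)) return(ts$tracks)
  Filter(function(tr) tr$cohort %in% cohort, ts$tracks)
}

#' Convert a track set to a long data frame
#' @param x A `track_set`.
#' @param ... Unused.
#' @return A data frame with columns
#'   `track_id, cohort, embryo_id, side, t_min, x_um, y_um, z_um`.
#' @export
as.data.frame.track_set <- function(x, ...) {
  if (!length(x$tracks)) {
    return(data.frame(track_id = character(), cohort = character(),
                      embryo_id = character(), side = character(),
                      t_min = numeric(), x_um = numeric(),
                      y_um = numeric(), z_um = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$tracks, function(tr) {
    data.frame(track_id = tr$track_id, cohort = tr$cohort,
               embryo_id = tr$embryo_id, side = tr$side,
               t_min = tr$t, x_um = tr$pos[, "ml"],
               y_um = tr$pos[, "dv"], z_um = tr$pos[, "ap"],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Read 3D tracks from CSV
#'
#' Two dialects are supported. `"native"` expects the package's own long
#' format with header `track_id,cohort,embryo_id,side,t_min,x_um,y_um,z_um`.
#' `"fiji_manual_tracking"` ingests exports of the Fiji/ImageJ Manual
#' Tracking plugin (`Track n°,Slice n°,X,Y[,Z]`), converting slice indices
#' to minutes via `t = (slice - 1) * dt` and pixel coordinates to
#' micrometres via the supplied pixel size. Some plugin versions export no
#' Z column; in that case z is set to 0 with a warning and downstream
#' analyses are effectively 2D.
#'
#' @param path Path to a CSV file.
#' @param dialect `"native"` or `"fiji_manual_tracking"`.
#' @param dt Frame interval in minutes (required for the fiji dialect).
#' @param pixel_size_um Pixel size in micrometres (required for the fiji
#'   dialect; there is no default because acquisition pixel sizes vary).
#' @param cohort Cohort label applied to all fiji-dialect tracks.
#' @return A [track_set()].
#' @export
read_tracks <- function(path, dialect = c("native", "fiji_manual_tracking"),
                        dt = NULL, pixel_size_um = NULL, cohort = "other") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L && dialect == "native" && !ncol(df))
    stop("empty input file: ", path)
  if (dialect == "native") {
    required <- c("track_id", "cohort", "embryo_id", "side",
                  "t_min", "x_um", "y_um", "z_um")
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("missing column(s) in native track CSV: ",
           paste(missing, collapse = ", "))
    if (!nrow(df)) stop("empty input file (header only): ", path)
    tracks <- lapply(split(df, df$track_id), function(d) {
      o <- order(d$t_min)
      d <- d[o, , drop = FALSE]
      if (any(diff(d$t_min) <= 0))
        stop("non-monotonic (duplicated) time in track '", d$track_id[1L], "'")
      timed_track(d$track_id[1L], d$t_min,
                  cbind(ml = d$x_um, dv = d$y_um, ap = d$z_um),
                  cohort = d$cohort[1L], embryo_id = d$embryo_id[1L],
                  side = d$side[1L])
    })
    return(track_set(unname(tracks)))
  }
  ## fiji dialect
  if (is.null(dt) || is.null(pixel_size_um))
    stop("fiji_manual_tracking dialect requires 'dt' (min) and 'pixel_size_um'")
  find_col <- function(pattern) {
    hit <- grep(pattern, names(df), ignore.case = TRUE)
    if (length(hit)) hit[1L] else NA_integer_
  }
  i_track <- find_col("^Track")
  i_slice <- find_col("^Slice")
  i_x <- which(trimws(names(df)) %in% c("X", "x"))[1]
  i_y <- which(trimws(names(df)) %in% c("Y", "y"))[1]
  i_z <- which(trimws(names(df)) %in% c("Z", "z"))[1]
  for (need in c("Track" = i_track, "Slice" = i_slice, "X" = i_x, "Y" = i_y)) {
    if (is.na(need))
      stop("missing column in fiji export: ",
           names(c("Track" = i_track, "Slice" = i_slice, "X" = i_x, "Y" = i_y))[
             which(is.na(c(i_track, i_slice, i_x, i_y)))[1L]])
  }
  if (!nrow(df)) stop("empty input file (header only): ", path)
  has_z <- !is.na(i_z)
  if (!has_z)
    warning("fiji export has no Z column; z set to 0 (analysis is 2D)")
  tracks <- lapply(split(df, df[[i_track]]), function(d) {
    o <- order(d[[i_slice]])
    d <- d[o, , drop = FALSE]
    if (any(diff(d[[i_slice]]) <= 0))
      stop("non-monotonic (duplicated) slice index in track '",
           d[[i_track]][1L], "'")
    z <- if (has_z) d[[i_z]] * pixel_size_um else rep(0, nrow(d))
    timed_track(as.character(d[[i_track]][1L]),
                (d[[i_slice]] - 1) * dt,
                cbind(ml = d[[i_x]] * pixel_size_um,
                      dv = d[[i_y]] * pixel_size_um,
                      ap = z),
                cohort = cohort)
  })
  track_set(unname(tracks), dt_nominal = dt)
}

#' Write a track set to native CSV
#'
#' Writes the long-format native dialect; `read_tracks()` on the result
#' reconstructs an identical track set.
#'
#' @param ts A [track_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  df <- as.data.frame(ts)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write tracks to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' An ordered 2D boundary polyline
#'
#' Vertices trace a segmented tissue frontier (e.g. the brain/OP boundary)
#' in the ML-DV plane of one optical section, ordered ventral to dorsal,
#' coordinates in micrometres.
#'
#' @param vertices Two-column numeric matrix or data frame (`ml`, `dv`).
#' @return An object of class `boundary_polyline` (never closed).
#' @export
boundary_polyline <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop("'vertices' must have 2 columns (ml, dv)")
  colnames(v) <- c("ml", "dv")
  if (nrow(v) < 2L) stop("a boundary polyline needs at least 2 vertices")
  if (anyNA(v) || any(!is.finite(v))) stop("non-finite vertex coordinates")
  same <- rowSums(abs(diff(v))) == 0
  if (any(same)) stop("consecutive duplicate vertices in polyline")
  structure(list(vertices = v, closed = FALSE), class = "boundary_polyline")
}

#' @export
print.boundary_polyline <- function(x, ...) {
  cat(sprintf("<boundary_polyline> %d vertices, dv in [%g, %g] um, arc length %.3g um\n",
              nrow(x$vertices), min(x$vertices[, "dv"]), max(x$vertices[, "dv"]),
              polyline_length(x$vertices)))
  invisible(x)
}

polyline_length <- function(v) sum(sqrt(rowSums(diff(v)^2)))

#' Read a 2-column polyline CSV (ml_um, dv_um)
#' @param path CSV path with header `ml_um,dv_um`.
#' @return A [boundary_polyline()].
#' @export
read_polyline <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("ml_um", "dv_um"), names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  boundary_polyline(cbind(df$ml_um, df$dv_um))
}

#' Write a polyline to CSV
#' @param b A [boundary_polyline()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_polyline <- function(b, path) {
  utils::write.csv(data.frame(ml_um = b$vertices[, "ml"],
                              dv_um = b$vertices[, "dv"]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Labelled 3D point cloud of cell centroids
#'
#' @param points Numeric matrix with columns `ml`, `dv`, `ap` (micrometres).
#' @param flags Character or factor vector, one of `"main"`/`"ectopic"` per
#'   point. Ectopic cells are those physically separated from the main
#'   cluster; they are excluded from extent measurements.
#' @param marker Transgene / marker name (free text).
#' @return An object of class `labeled_point_cloud`.
#' @export
labeled_point_cloud <- function(points, flags = NULL, marker = "unspecified") {
  p <- as.matrix(points)
  if (ncol(p) != 3L) stop("'points' must have 3 columns (ml, dv, ap)")
  colnames(p) <- c("ml", "dv", "ap")
  if (is.null(flags)) flags <- rep("main", nrow(p))
  flags <- as.character(flags)
  if (length(flags) != nrow(p)) stop("'flags' must have one entry per point")
  if (!all(flags %in% c("main", "ectopic")))
    stop("flags must be 'main' or 'ectopic'")
  structure(list(points = p, flags = flags, marker = marker),
            class = "labeled_point_cloud")
}

#' @export
print.labeled_point_cloud <- function(x, ...) {
  cat(sprintf("<labeled_point_cloud> %d points (%d main, %d ectopic), marker '%s'\n",
              nrow(x$points), sum(x$flags == "main"),
              sum(x$flags == "ectopic"), x$marker))
  invisible(x)
}

#' Paired membranes of an EM interface region
#'
#' Geometry of a rectangular electron-microscopy region at a tissue
#' interface: two membrane traces in pixel units, the nominal region length
#' and the physical pixel size.
#'
#' @param membrane_a,membrane_b [boundary_polyline()] objects in pixel
#'   units (columns reused as generic x/y).
#' @param region_length_px Nominal region length in pixels (> 0).
#' @param px_size_nm Pixel size in nanometres (> 0).
#' @return An object of class `interface_region`.
#' @export
interface_region <- function(membrane_a, membrane_b, region_length_px,
                             px_size_nm) {
  stopifnot(inherits(membrane_a, "boundary_polyline"),
            inherits(membrane_b, "boundary_polyline"))
  if (!is.numeric(region_length_px) || region_length_px <= 0)
    stop("'region_length_px' must be > 0")
  if (!is.numeric(px_size_nm) || px_size_nm <= 0)
    stop("'px_size_nm' must be > 0")
  structure(list(membrane_a = membrane_a, membrane_b = membrane_b,
                 region_length_px = region_length_px,
                 px_size_nm = px_size_nm),
            class = "interface_region")
}

#' Extract the interface polyline between two labels of a segmentation mask
#'
#' Traces the shared frontier between two labelled tissue regions (e.g.
#' segmented OP and brain) inside a rectangular ROI of a 2D label mask.
#' The frontier is the chain of pixel edges separating `label_a` pixels
#' from 4-adjacent `label_b` pixels; its vertices are the pixel-corner
#' points along that chain, so the arc length equals the number of
#' interface pixel edges times the pixel size. Rows of the mask are the DV
#' axis (larger row index = more dorsal), columns the ML axis; the returned
#' polyline is ordered ventral to dorsal and scaled to micrometres.
#'
#' @param mask Integer matrix of labels, or path to a single-channel TIFF
#'   label image (read with `tiff::readTIFF(as.is = TRUE)`).
#' @param roi Integer vector `c(row_min, row_max, col_min, col_max)`
#'   (1-based, inclusive). Defaults to the whole mask.
#' @param label_a,label_b The two labels whose interface is traced.
#' @param pixel_size_um Pixel size in micrometres.
#' @return A [boundary_polyline()].
#' @export
boundary_from_mask <- function(mask, roi = NULL, label_a, label_b,
                               pixel_size_um) {
  if (is.character(mask)) {
    mask <- tiff::readTIFF(mask, as.is = TRUE)
    if (length(dim(mask)) == 3L) mask <- mask[, , 1L]
  }
  mask <- as.matrix(mask)
  if (is.null(roi)) roi <- c(1L, nrow(mask), 1L, ncol(mask))
  roi <- as.integer(roi)
  if (length(roi) != 4L || roi[1] < 1L || roi[2] > nrow(mask) ||
      roi[3] < 1L || roi[4] > ncol(mask) || roi[1] > roi[2] || roi[3] > roi[4])
    stop("invalid roi")
  sub <- mask[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  for (lab in c(label_a, label_b)) {
    if (!any(sub == lab)) stop("label ", lab, " absent in roi")
  }
  nr <- nrow(sub); nc <- ncol(sub)
  ## corner grid: (i, j), i in 0..nr (DV), j in 0..nc (ML); pixel (r, c)
  ## occupies corners (r-1..r, c-1..c). Collect unit segments of the a|b
  ## interface as pairs of corner ids.
  cid <- function(i, j) i * (nc + 1L) + j
  segs <- matrix(integer(), ncol = 2L)
  ## horizontal pixel neighbours -> vertical corner segment
  if (nc >= 2L) {
    L <- sub[, -nc, drop = FALSE]; R <- sub[, -1L, drop = FALSE]
    hit <- which((L == label_a & R == label_b) | (L == label_b & R == label_a),
                 arr.ind = TRUE)
    if (nrow(hit)) {
      r <- hit[, 1L]; c <- hit[, 2L]   # shared edge at column boundary c
      segs <- rbind(segs, cbind(cid(r - 1L, c), cid(r, c)))
    }
  }
  ## vertical pixel neighbours -> horizontal corner segment
  if (nr >= 2L) {
    U <- sub[-nr, , drop = FALSE]; D <- sub[-1L, , drop = FALSE]
    hit <- which((U == label_a & D == label_b) | (U == label_b & D == label_a),
                 arr.ind = TRUE)
    if (nrow(hit)) {
      r <- hit[, 1L]; c <- hit[, 2L]   # shared edge at row boundary r
      segs <- rbind(segs, cbind(cid(r, c - 1L), cid(r, c)))
    }
  }
  if (!nrow(segs))
    stop("labels ", label_a, " and ", label_b, " share no interface in roi")
  verts <- sort(unique(as.vector(segs)))
  idx <- match(segs, verts); dim(idx) <- dim(segs)
  nv <- length(verts)
  ## adjacency + connected components
  adj <- vector("list", nv)
  for (k in seq_len(nrow(idx))) {
    a <- idx[k, 1L]; b <- idx[k, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  deg <- lengths(adj)
  comp <- integer(nv)
  ncomp <- 0L
  for (s in seq_len(nv)) {
    if (comp[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v]) next
      comp[v] <- ncomp
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  if (ncomp > 1L)
    stop("interface has ", ncomp,
         " disjoint components in roi; tighten the roi")
  if (any(deg > 2L) || sum(deg == 1L) != 2L)
    stop("interface in roi does not form a single open path; tighten the roi")
  ## walk the path from one endpoint
  ends <- which(deg == 1L)
  ij <- cbind(i = verts %/% (nc + 1L), j = verts %% (nc + 1L))
  start <- ends[which.min(ij[ends, "i"])]   # ventral-most endpoint
  path <- integer(nv)
  path[1L] <- start
  prev <- 0L
  for (k in 2L:nv) {
    nxt <- setdiff(adj[[path[k - 1L]]], prev)
    prev <- path[k - 1L]
    path[k] <- nxt[1L]
  }
  v_um <- cbind(ml = (roi[3] - 1L + ij[path, "j"]) * pixel_size_um,
                dv = (roi[1] - 1L + ij[path, "i"]) * pixel_size_um)
  boundary_polyline(v_um)
}
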